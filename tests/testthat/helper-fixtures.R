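# deterministic fixtures built in code; no data files

rand_dna <- function(n, seed, letters = c("A", "C", "G", "T")) {
  withr::with_seed(seed, paste0(sample(letters, n, replace = TRUE), collapse = ""))
}

small_profile <- function() composition_profile(A = 30L, C = 25L, G = 20L, T = 25L)

write_temp_fasta <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "seqs.fasta")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# independent run counter: regex over the mask string, no rle
regex_run_lengths <- function(mask) {
  s <- paste0(as.integer(mask), collapse = "")
  m <- gregexpr("1+", s)[[1]]
  if (m[1] == -1) integer(0) else attr(m, "match.length")
}

# enumerate sequences over an alphabet up to a length
all_seqs <- function(alphabet, max_len) {
  unlist(lapply(seq_len(max_len), function(l) {
    g <- expand.grid(rep(list(alphabet), l), stringsAsFactors = FALSE)
    apply(g, 1, paste0, collapse = "")
  }))
}

count_gap_openings <- function(aln) {
  ca <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1]]
  st <- ifelse(ca == "-", 1L, ifelse(cb == "-", 2L, 0L))
  r <- rle(st)
  sum(r$values != 0L)
}
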