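#' Identity-run spectrum of an alignment
#'
#' Counts maximal runs of consecutive match columns by exact length.  A run
#' is a stretch of the per-column match mask equal to 1; a single mismatch or
#' gap column terminates it.  Runs longer than `max_tracked` are pooled into
#' one top bin; the matched columns inside that bin are kept in
#' `pooled_matches` so that mass conservation
#' (`sum(k * count_k) + pooled_matches == matches`) stays exact.
#'
#' @param x an `mm_alignment`, or a logical/0-1 vector used directly as the
#'   match mask.
#' @param max_tracked largest run length given its own bin (default 13, the
#'   longest identity cluster the cross-genome comparisons reach).
#' @return An object of class `mm_run_spectrum` with fields `run_counts`
#'   (named by run length, plus a `">max"` bin), `columns`, `matches`,
#'   `identity_percent`, `pooled_matches`.
#' @export
run_spectrum <- function(x, max_tracked = 13L) {
  mask <- if (inherits(x, "mm_alignment")) x$match_mask else as.logical(x)
  stopifnot(max_tracked >= 1)
  counts <- setNames(integer(max_tracked + 1L),
                     c(as.character(seq_len(max_tracked)),
                       paste0(">", max_tracked)))
  pooled <- 0L
  if (length(mask) > 0) {
    r <- rle(mask)
    lens <- r$lengths[r$values]
    if (length(lens) > 0) {
      tracked <- pmin(lens, max_tracked + 1L)
      tab <- tabulate(tracked, nbins = max_tracked + 1L)
      counts[] <- tab
      pooled <- sum(lens[lens > max_tracked])
    }
  }
  matches <- sum(mask)
  columns <- length(mask)
  structure(list(run_counts = counts, columns = columns, matches = matches,
                 identity_percent = if (columns > 0) 100 * matches / columns else NaN,
                 pooled_matches = as.integer(pooled),
                 max_tracked = as.integer(max_tracked)),
            class = "mm_run_spectrum")
}

#' @export
print.mm_run_spectrum <- function(x, ...) {
  cat(sprintf("<mm_run_spectrum> %d columns, %d matches (%.1f%% identity)\n",
              x$columns, x$matches, x$identity_percent))
  nz <- x$run_counts[x$run_counts > 0]
  if (length(nz)) print(nz) else cat("  (no runs)\n")
  invisible(x)
}

#' @export
tidy.mm_run_spectrum <- function(x, ...) {
  tibble(k = names(x$run_counts), count = as.integer(x$run_counts))
}

#' Run-length percentages of a spectrum
#'
#' Expresses the run counts at or above `min_n` (including the pooled top
#' bin) as percentages of their total, the bar-graph convention "percent of
#' total 3- to n-mers".
#'
#' @param spec an `mm_run_spectrum`.
#' @param min_n smallest run length included (default 3; 1- and 2-mers are
#'   tracked but excluded from bar-graph percentages).
#' @return A tibble with `k`, `count`, `percent`; zero rows when no run of
#'   length `>= min_n` exists.
#' @export
spectrum_percentages <- function(spec, min_n = 3L) {
  stopifnot(inherits(spec, "mm_run_spectrum"), min_n >= 1)
  ks <- names(spec$run_counts)
  keep <- c(as.character(seq(min_n, spec$max_tracked)),
            paste0(">", spec$max_tracked))
  keep <- intersect(keep, ks)
  counts <- spec$run_counts[keep]
  tot <- sum(counts)
  if (tot == 0) return(tibble(k = character(), count = integer(),
                              percent = double()))
  tibble(k = keep, count = as.integer(counts),
         percent = 100 * as.numeric(counts) / tot)
}

#' Sliding-frame scan for high-homology segments
#'
#' Slides a frame of `frame_len` residues over `a` in steps of `step`,
#' aligns every frame against `b` in seeded mode, and ranks frames by their
#' footprint identity percentage.  The reported `b` interval is the span of
#' `b` consumed under the frame's footprint.  Deterministic given its inputs;
#' ties rank the earlier frame first.
#'
#' @param a,b `mm_sequence` or character; frames slide over `a`.
#' @param scheme an [scoring_scheme()].
#' @param frame_len,step frame length and slide step (defaults 550 / 25, the
#'   scale of the published screen-shot frames).
#' @param top_k number of frames returned.
#' @return A tibble with `rank`, `a_start`, `a_end`, `b_start`, `b_end`,
#'   `identity_percent` and a `spectrum` list-column of `mm_run_spectrum`.
#' @export
find_top_frames <- function(a, b, scheme = scoring_scheme(),
                            frame_len = 550L, step = 25L, top_k = 5L) {
  a <- as_mm_sequence(a); b <- as_mm_sequence(b)
  n <- length(a)
  if (frame_len > n) stop("frame_len exceeds the length of a", call. = FALSE)
  if (frame_len > length(b)) stop("frame_len exceeds the length of b", call. = FALSE)
  stopifnot(step >= 1)
  starts <- unique(c(seq(1L, n - frame_len + 1L, by = step), n - frame_len + 1L))
  rows <- purrr::map(starts, function(s) {
    fr <- subsequence(a, s, s + frame_len - 1L)
    aln <- suppressWarnings(align_seeded(fr, b, scheme))
    fp <- frame_footprint(aln)
    sp <- run_spectrum(aln$match_mask[fp$cols])
    tibble(a_start = s, a_end = s + frame_len - 1L,
           b_start = fp$b_start, b_end = fp$b_end,
           identity_percent = sp$identity_percent,
           spectrum = list(sp))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$identity_percent, out$a_start), , drop = FALSE]
  out <- head(out, top_k)
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}

# columns spanned by the a-row residues, and the b interval consumed there
frame_footprint <- function(aln) {
  ca <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1]]
  ix <- which(ca != "-")
  first <- ix[1]; last <- ix[length(ix)]
  bcum <- cumsum(cb != "-")
  b_end <- bcum[last]
  b_start <- if (first > 1) bcum[first - 1] + 1L else 1L
  b_start <- min(b_start, max(b_end, 1L))
  list(cols = first:last, b_start = as.integer(b_start),
       b_end = as.integer(b_end))
}

#' Patch-string encoding of an alignment
#'
#' Renders each maximal match run as its decimal length and every non-match
#' column as one dot, left to right - the compact notation used to describe
#' patchy homology ("numbers are lengths of homologous matches, dots
#' non-homologies").  The encoding is lossless for run/column bookkeeping and
#' can be inverted with [parse_patch_string()].
#'
#' @param aln an `mm_alignment` or a logical mask.
#' @return A character scalar.
#' @export
patch_string <- function(aln) {
  mask <- if (inherits(aln, "mm_alignment")) aln$match_mask else as.logical(aln)
  if (length(mask) == 0) return("")
  r <- rle(mask)
  paste0(ifelse(r$values, as.character(r$lengths),
                vapply(r$lengths, function(l) strrep(".", l), character(1))),
         collapse = "")
}

#' Invert a patch string
#'
#' @param s a string produced by [patch_string()].
#' @return A list with `matches`, `columns`, and `run_lengths`.
#' @export
parse_patch_string <- function(s) {
  nums <- regmatches(s, gregexpr("[0-9]+", s))[[1]]
  runs <- as.integer(nums)
  dots <- nchar(gsub("[0-9]", "", s))
  list(matches = sum(runs), columns = sum(runs) + dots, run_lengths = runs)
}

#' Shared k-mers between two sequences
#'
#' Exact set intersection of all overlapping length-`k` substrings; used for
#' the oligopeptide-level comparison of translated products as well as for
#' nucleotide words.
#'
#' @param p,q `mm_sequence` of the same alphabet, or character scalars.
#' @param k word length (default 5).
#' @return Character vector of shared k-mers (possibly empty).
#' @export
shared_kmers <- function(p, q, k = 5L) {
  p <- as_mm_sequence(p, alphabet = guess_alpha(p))
  q <- as_mm_sequence(q, alphabet = guess_alpha(q))
  if (p$alphabet != q$alphabet)
    stop("sequences must share an alphabet", call. = FALSE)
  stopifnot(k >= 1)
  if (k > length(p) || k > length(q)) return(character(0))
  km <- function(s) {
    n <- nchar(s$residues)
    unique(substring(s$residues, 1:(n - k + 1), k:n))
  }
  sort(intersect(km(p), km(q)))
}

guess_alpha <- function(x) {
  if (inherits(x, "mm_sequence")) return(x$alphabet)
  if (grepl("[^ACGTUNacgtun]", x)) "peptide" else "nucleotide"
}

#' Maximal perfect annealing length between two strands
#'
#' Length of the longest contiguous block in which `a` base-pairs perfectly
#' (no gaps, strict Watson-Crick) with the reverse complement of `b` - the
#' duplex a pair of cohesive single-stranded ends could form.
#'
#' @param a,b nucleotide `mm_sequence` or character scalars.
#' @return Integer duplex length (0 when no base pair can form).
#' @export
duplex_length <- function(a, b) {
  a <- as_mm_sequence(a); b <- as_mm_sequence(b)
  rb <- reverse_complement(b)
  cpp_longest_common_substring(a$residues, rb$residues)
}
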