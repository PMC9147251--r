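test_that("global alignment handles the degenerate identity and all-mismatch cases", {
  aln <- align_global("ACGTACGT", "ACGTACGT")
  expect_equal(nchar(aln$gapped_a), 8)
  expect_true(all(aln$match_mask))
  expect_equal(aln$score, 8 * 1.9)

  aln2 <- align_global("AAAA", "CCCC")
  expect_equal(aln2$gapped_a, "AAAA")
  expect_equal(aln2$gapped_b, "CCCC")
  expect_false(any(aln2$match_mask))
})

test_that("global scores equal the exhaustive matching-enumeration oracle on random short pairs", {
  withr::local_seed(11)
  for (i in 1:150) {
    s1 <- rand_dna(sample(1:6, 1), seed = 100 + i)
    s2 <- rand_dna(sample(1:6, 1), seed = 200 + i)
    for (ef in c(TRUE, FALSE)) {
      sch <- scoring_scheme(end_gaps_free = ef)
      g <- align_global(s1, s2, sch)
      bf <- micromod:::cpp_brute_score(s1, s2, sch$match, sch$mismatch,
                                       sch$gap_open * sch$gap_scale,
                                       sch$gap_extend * sch$gap_scale, ef)
      expect_equal(g$score, bf, tolerance = 1e-12)
      expect_equal(audit_score(g), g$score, tolerance = 1e-9)
    }
  }
})

test_that("global score agrees with an independent affine-gap implementation", {
  # Biostrings costs an L-column gap gapOpening + L * gapExtension, so its
  # opening parameter is our (open - extend)
  withr::local_seed(5)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1.9, mismatch = 0,
                                                  baseOnly = TRUE)
  for (i in 1:10) {
    s1 <- rand_dna(160, seed = 300 + i)
    s2 <- rand_dna(190, seed = 400 + i)
    for (type in c("global", "overlap")) {
      sch <- scoring_scheme(end_gaps_free = type == "overlap")
      g <- align_global(s1, s2, sch)
      ref <- Biostrings::pairwiseAlignment(
        s1, s2, substitutionMatrix = mat,
        gapOpening = (sch$gap_open - sch$gap_extend) * sch$gap_scale,
        gapExtension = sch$gap_extend * sch$gap_scale,
        type = type, scoreOnly = TRUE)
      expect_equal(g$score, ref, tolerance = 1e-6)
    }
  }
})

test_that("global alignment is symmetric and self-consistent column by column", {
  for (i in 1:10) {
    s1 <- rand_dna(80, seed = 500 + i)
    s2 <- rand_dna(95, seed = 600 + i)
    ab <- align_global(s1, s2)
    ba <- align_global(s2, s1)
    expect_equal(ab$score, ba$score, tolerance = 1e-9)
    # removing gaps restores the inputs
    expect_equal(gsub("-", "", ab$gapped_a), s1)
    expect_equal(gsub("-", "", ab$gapped_b), s2)
    # no column with gaps in both rows
    ca <- strsplit(ab$gapped_a, "")[[1]]; cb <- strsplit(ab$gapped_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
    # mask is 1 exactly at equal non-gap non-N letters
    expect_equal(ab$match_mask, ca == cb & ca != "-" & ca != "N")
  }
})

test_that("with gaps priced out the global score reduces to Hamming matches", {
  for (i in 1:10) {
    s1 <- rand_dna(60, seed = 700 + i)
    s2 <- rand_dna(60, seed = 800 + i)
    sch <- scoring_scheme(match = 1, mismatch = 0, gap_open = 1e6,
                          gap_extend = 1e6, gap_scale = 1,
                          end_gaps_free = FALSE)
    g <- align_global(s1, s2, sch)
    hamming <- sum(strsplit(s1, "")[[1]] == strsplit(s2, "")[[1]])
    expect_equal(g$score, hamming)
  }
})

test_that("raising the gap opening penalty never adds gap openings", {
  for (i in 1:40) {
    s1 <- rand_dna(8, seed = 900 + i)
    s2 <- rand_dna(8, seed = 950 + i)
    ops <- vapply(c(1, 2, 4, 8), function(go) {
      count_gap_openings(align_global(s1, s2,
        scoring_scheme(gap_open = go, gap_extend = min(go, 1), gap_scale = 1,
                       end_gaps_free = FALSE)))
    }, numeric(1))
    expect_true(all(diff(ops) <= 0))
  }
})

test_that("N is never a match and scores as a mismatch", {
  aln <- align_global("ANNA", "ANNA")
  expect_equal(sum(aln$match_mask), 2)
  expect_equal(aln$score, 2 * 1.9)
})

test_that("local alignment recovers a planted identical segment and rejects noise", {
  motif <- rand_dna(30, seed = 21)
  a <- paste0(rand_dna(70, seed = 22), motif, rand_dna(70, seed = 23))
  b <- paste0(rand_dna(50, seed = 24), motif, rand_dna(90, seed = 25))
  aln <- align_local(a, b)
  expect_gte(aln$score, 30 * 5 - 20)
  core_a <- aln$a_interval[1]:aln$a_interval[2]
  expect_true(all(71:100 %in% core_a))

  empty <- align_local("AAAA", "CCCC")
  expect_equal(empty$score, 0)
  expect_equal(nchar(empty$gapped_a), 0)

  expect_equal(align_local(a, b)$score, align_local(b, a)$score)
  expect_warning(align_local("ACGT", "ACGT", scoring_scheme()),
                 "ill-posed")
})

test_that("local scores match the independent implementation and score-only path", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  for (i in 1:8) {
    s1 <- rand_dna(120, seed = 1000 + i)
    s2 <- rand_dna(150, seed = 1100 + i)
    full <- align_local(s1, s2)
    fast <- micromod:::cpp_local_score(s1, s2, 5, -4, 12, 4)
    ref <- Biostrings::pairwiseAlignment(s1, s2, substitutionMatrix = mat,
                                         gapOpening = 8, gapExtension = 4,
                                         type = "local", scoreOnly = TRUE)
    expect_equal(full$score, ref, tolerance = 1e-6)
    expect_equal(fast, ref, tolerance = 1e-6)
  }
})

test_that("seeded alignment reproduces the exact global result at moderate scale", {
  prof <- small_profile()
  for (i in 1:4) {
    a <- random_sequence(1500, prof, 30 + i)
    b <- random_sequence(1500, prof, 60 + i)
    g <- align_global(a, b)
    s <- align_seeded(a, b)
    expect_lte(s$score, g$score + 1e-9)       # banded is a lower bound ...
    expect_equal(s$score, g$score, tolerance = 1e-9)  # ... attained here
  }
  ident <- mm_sequence(rand_dna(10000, seed = 31), id = "self")
  s <- align_seeded(ident, ident)
  expect_equal(alignment_identity(s), 100)
  expect_equal(s$score, 10000 * 1.9)
})

test_that("the DP budget refuses oversized exact problems and points to seeded mode", {
  withr::local_options(micromod.dp_budget = 1e4)
  a <- mm_sequence(rand_dna(200, seed = 41))
  b <- mm_sequence(rand_dna(200, seed = 42))
  expect_error(align_global(a, b), "align_seeded")
  expect_s3_class(align_seeded(a, b, band_pad = 20L), "mm_alignment")
})

test_that("alignment export formats are faithful", {
  a <- mm_sequence(rand_dna(60, seed = 51), id = "qa")
  b <- mm_sequence(rand_dna(70, seed = 52), id = "qb")
  aln <- align_global(a, b)
  tab <- tibble::as_tibble(aln)
  expect_equal(nrow(tab), nchar(aln$gapped_a))
  expect_equal(sum(tab$match_flag), sum(aln$match_mask))
  out <- file.path(withr::local_tempdir(), "aln.fasta")
  write_alignment_fasta(aln, out)
  lines <- readLines(out)
  expect_equal(sum(startsWith(lines, ">")), 2)
  expect_equal(paste0(lines[2:(which(startsWith(lines, ">"))[2] - 1)],
                      collapse = ""), aln$gapped_a)
})
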