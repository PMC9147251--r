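new_alignment <- function(res, a, b, scheme, mode) {
  ca <- strsplit(res$gapped_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(res$gapped_b, "", fixed = TRUE)[[1]]
  mask <- ca == cb & ca != "-" & ca != "N"
  structure(list(
    gapped_a = res$gapped_a, gapped_b = res$gapped_b,
    score = res$score,
    a_id = a$id, b_id = b$id,
    a_interval = c(res$a_start, res$a_end),
    b_interval = c(res$b_start, res$b_end),
    match_mask = mask,
    mode = mode, scheme = scheme), class = "mm_alignment")
}

#' @export
print.mm_alignment <- function(x, ...) {
  cat(sprintf("<mm_alignment> %s vs %s (%s): %d columns, %d matches (%.1f%%), score %.2f\n",
              x$a_id, x$b_id, x$mode, length(x$match_mask),
              sum(x$match_mask), alignment_identity(x), x$score))
  invisible(x)
}

dp_budget <- function() getOption("micromod.dp_budget", 2e8)

#' Optimal global affine-gap alignment
#'
#' Three-state (Gotoh) dynamic program over the full matrix.  End gaps are
#' unpenalized when the scheme says so, and the traceback is deterministic
#' under the fixed tie-break order: diagonal over gap-in-a over gap-in-b.
#' `N` never counts as a match and scores as a mismatch.
#'
#' The full matrix is refused above the DP budget
#' (`options(micromod.dp_budget = )`, default 2e8 cells); use
#' [align_seeded()] for long pairs.
#'
#' @param a,b `mm_sequence` (nucleotide) or character scalars.
#' @param scheme an [scoring_scheme()].
#' @return An `mm_alignment`: equal-length gapped strings, score, 1-based
#'   aligned intervals, and a per-column logical match mask.
#' @export
align_global <- function(a, b, scheme = scoring_scheme()) {
  a <- as_mm_sequence(a); b <- as_mm_sequence(b)
  n <- length(a); m <- length(b)
  if (as.double(n) * m > dp_budget())
    stop(sprintf(paste0("DP budget exceeded (%d x %d cells): ",
                        "use align_seeded() for long pairs"), n, m),
         call. = FALSE)
  eff <- effective_gaps(scheme)
  res <- cpp_pair_align(a$residues, b$residues, scheme$match, scheme$mismatch,
                        eff$open, eff$extend, scheme$end_gaps_free, 0L,
                        -n, m)
  new_alignment(res, a, b, scheme, "global")
}

#' Optimal local affine-gap alignment
#'
#' Smith-Waterman-Gotoh.  The score is never negative; when no positive
#' scoring column pair exists the alignment is empty (score 0).  A scheme
#' whose expected column score against the two sequences' base frequencies is
#' non-negative makes the local optimum degenerate and triggers a warning.
#'
#' @inheritParams align_global
#' @export
align_local <- function(a, b, scheme = local_scheme()) {
  a <- as_mm_sequence(a); b <- as_mm_sequence(b)
  n <- length(a); m <- length(b)
  if (as.double(n) * m > dp_budget())
    stop("DP budget exceeded: use shorter sequences for local alignment",
         call. = FALSE)
  p_match <- sum(letter_freqs(a) * letter_freqs(b))
  if (scheme$match * p_match + scheme$mismatch * (1 - p_match) >= 0)
    warning("expected column score is non-negative: local mode is ill-posed",
            call. = FALSE)
  eff <- effective_gaps(scheme)
  res <- cpp_pair_align(a$residues, b$residues, scheme$match, scheme$mismatch,
                        eff$open, eff$extend, FALSE, 1L, -n, m)
  aln <- new_alignment(res, a, b, scheme, "local")
  aln
}

letter_freqs <- function(seq) {
  cmp <- composition(seq)
  f <- cmp$counts[c("A", "C", "G", "T")]
  f[is.na(f)] <- 0
  names(f) <- c("A", "C", "G", "T")
  f / max(1, cmp$length)
}

#' Seeded (banded) global alignment for long sequence pairs
#'
#' Word matches of length `ktuple` are binned by diagonal (Wilbur-Lipman),
#' smoothed over `diagonal_window` neighboring diagonals, and diagonals whose
#' hit count significantly exceeds the composition-based expectation are
#' retained (at most `best_diagonals`).  The affine DP then runs inside a
#' band that covers those diagonals plus the corner-to-corner diagonals, each
#' padded by `band_pad`.  The result's score is a lower bound on the exact
#' global score; with the default padding the two agree in practice for
#' same-scale pairs (the band comfortably contains the small off-diagonal
#' drift of optimal paths).
#'
#' @inheritParams align_global
#' @param band_pad band half-width added around retained diagonals; default
#'   `max(64, 3% of the shorter sequence)`.
#' @export
align_seeded <- function(a, b, scheme = scoring_scheme(), band_pad = NULL) {
  a <- as_mm_sequence(a); b <- as_mm_sequence(b)
  n <- length(a); m <- length(b)
  if (is.null(band_pad))
    band_pad <- max(64L, as.integer(ceiling(0.03 * min(n, m))))
  k <- scheme$ktuple
  hits <- cpp_diag_hits(a$residues, b$residues, k)
  win <- 2L * scheme$diagonal_window + 1L
  sm <- as.numeric(stats::filter(hits, rep(1, win), sides = 2))
  sm[is.na(sm)] <- 0
  # expected word hits per diagonal window under independence
  q <- sum(letter_freqs(a) * letter_freqs(b))^k
  diag_len <- pmin(seq_len(n + m - 1), n, m, rev(seq_len(n + m - 1)))
  mu <- pmax(diag_len - k + 1, 0) * q * win
  sig <- which(sm > mu + 6 * sqrt(pmax(mu, 1)))
  seed_diags <- integer(0)
  if (length(sig) > 0) {
    ord <- sig[order(sm[sig] - mu[sig], decreasing = TRUE)]
    seed_diags <- head(ord, scheme$best_diagonals) - n   # to d = j - i
  }
  anchor <- c(0L, m - n, seed_diags)
  band_lo <- min(anchor) - band_pad
  band_hi <- max(anchor) + band_pad
  cells <- as.double(n) * (band_hi - band_lo + 1)
  if (cells > 4 * dp_budget()) {
    # distant seed diagonals can blow the band up; fall back to the
    # corner-to-corner band, which the global path always needs
    band_lo <- min(0L, m - n) - band_pad
    band_hi <- max(0L, m - n) + band_pad
    cells <- as.double(n) * (band_hi - band_lo + 1)
  }
  if (cells > 4 * dp_budget())
    stop("seeded band exceeds the DP budget; reduce band_pad or sequence size",
         call. = FALSE)
  eff <- effective_gaps(scheme)
  res <- cpp_pair_align(a$residues, b$residues, scheme$match, scheme$mismatch,
                        eff$open, eff$extend, scheme$end_gaps_free, 0L,
                        band_lo, band_hi)
  if (length(seed_diags) == 0 && n >= k && m >= k && max(hits) == 0)
    warning("no word matches found between the sequences", call. = FALSE)
  new_alignment(res, a, b, scheme, "seeded")
}

#' Identity percentage of an alignment
#'
#' `scope = "columns"` divides match columns by all alignment columns,
#' including gap and free end-gap columns - the convention that makes overall
#' and segment homologies commensurable.  `scope = "footprint"` restricts to
#' the columns between the first and the last residue of the `a` row, which
#' is the natural scope when a short frame is aligned inside a long subject.
#'
#' @param aln an `mm_alignment`.
#' @param scope `"columns"` or `"footprint"`.
#' @return Percentage in `[0, 100]` (`NaN` for an empty alignment).
#' @export
alignment_identity <- function(aln, scope = c("columns", "footprint")) {
  scope <- match.arg(scope)
  mask <- aln$match_mask
  if (length(mask) == 0) return(NaN)
  if (scope == "footprint") {
    ca <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1]]
    ix <- which(ca != "-")
    if (length(ix) == 0) return(NaN)
    mask <- mask[ix[1]:ix[length(ix)]]
  }
  100 * sum(mask) / length(mask)
}

#' Column-by-column audit of an alignment score
#'
#' Recomputes the alignment score from the gapped strings alone: substitution
#' scores over residue columns plus affine costs over maximal gap runs, with
#' leading/trailing runs free when the scheme says so.  Equality with the
#' reported DP score is an internal invariant.
#'
#' @param aln an `mm_alignment`.
#' @return The recomputed score.
#' @export
audit_score <- function(aln) {
  ca <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1]]
  if (length(ca) == 0) return(0)
  scheme <- aln$scheme
  eff <- effective_gaps(scheme)
  resid <- ca != "-" & cb != "-"
  sub <- sum(ifelse(ca[resid] == cb[resid] & ca[resid] != "N",
                    scheme$match, scheme$mismatch))
  gap_state <- ifelse(ca == "-", 1L, ifelse(cb == "-", 2L, 0L))
  r <- rle(gap_state)
  runs <- which(r$values != 0L)
  if (length(runs) > 0 && aln$mode != "local" && scheme$end_gaps_free) {
    drop <- c(if (r$values[1] != 0L) 1L,
              if (r$values[length(r$values)] != 0L) length(r$values))
    runs <- setdiff(runs, drop)
  }
  gcost <- sum(eff$open + (r$lengths[runs] - 1) * eff$extend)
  sub - gcost
}

#' Per-column audit table of an alignment
#'
#' @param x an `mm_alignment`.
#' @param ... unused.
#' @return A tibble with `column`, `letter_a`, `letter_b`, `match_flag`.
#' @export
as_tibble.mm_alignment <- function(x, ...) {
  ca <- strsplit(x$gapped_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(x$gapped_b, "", fixed = TRUE)[[1]]
  tibble(column = seq_along(ca), letter_a = ca, letter_b = cb,
         match_flag = as.integer(x$match_mask))
}

#' Write an alignment as aligned FASTA (two gapped records)
#'
#' @param aln an `mm_alignment`.
#' @param path output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(setNames(c(aln$gapped_a, aln$gapped_b),
                                         c(aln$a_id, aln$b_id)))
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta",
                              width = 60L)
  invisible(path)
}
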