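#' Composition-matched random sequence
#'
#' Exact mode: a uniformly random permutation of the multiset of letters in
#' `profile`, so the composition of the output equals the profile exactly.
#' When `length` differs from the profile length the counts are rescaled to
#' `length` by largest remainder (frequency mode), then permuted.
#' Reproducible from `seed`; the caller's RNG state is left untouched.
#'
#' @param length output length.
#' @param profile an `mm_composition` template.
#' @param seed integer seed.
#' @param id sequence label.
#' @return An `mm_sequence` labelled as synthetic.
#' @export
random_sequence <- function(length, profile, seed, id = "random") {
  stopifnot(inherits(profile, "mm_composition"), length >= 1)
  counts <- profile$counts
  if (any(counts < 0)) stop("negative counts in profile", call. = FALSE)
  if (profile$length != length) {
    frac <- counts / profile$length * length
    counts <- floor(frac)
    rem <- length - sum(counts)
    if (rem > 0) {
      take <- order(frac - floor(frac), decreasing = TRUE)[seq_len(rem)]
      counts[take] <- counts[take] + 1
    }
  }
  pool <- rep(names(counts), counts)
  res <- with_seed(seed, paste0(sample(pool), collapse = ""))
  mm_sequence(res, id = id,
              source_note = sprintf("synthetic: composition-matched random, seed %d",
                                    as.integer(seed)))
}

#' Shuffle a sequence
#'
#' Global mode permutes all residues uniformly; windowed mode permutes within
#' consecutive blocks of `window` positions (the final block may be shorter).
#' Composition is conserved exactly in both modes.
#'
#' @param seq an `mm_sequence` (nucleotide).
#' @param seed integer seed.
#' @param window optional block width (`>= 2`) for local shuffling.
#' @return An `mm_sequence`.
#' @export
shuffle_sequence <- function(seq, seed, window = NULL) {
  seq <- as_mm_sequence(seq)
  ch <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  res <- with_seed(seed, {
    if (is.null(window)) {
      paste0(sample(ch), collapse = "")
    } else {
      if (window < 2) stop("window must be >= 2", call. = FALSE)
      blocks <- split(ch, ceiling(seq_along(ch) / window))
      paste0(unlist(lapply(blocks, sample), use.names = FALSE), collapse = "")
    }
  })
  mm_sequence(res, id = paste0(seq$id, "_shuffled"),
              source_note = sprintf("shuffle of %s, seed %d%s", seq$id,
                                    as.integer(seed),
                                    if (is.null(window)) ""
                                    else sprintf(", window %d", window)))
}

#' Fit a Gumbel (type-I extreme value) distribution to scores
#'
#' Method-of-moments start (`beta = sd * sqrt(6) / pi`,
#' `mu = mean - gamma * beta` with Euler-Mascheroni `gamma`), refined by
#' maximum likelihood.  Deterministic given the scores.
#'
#' @param scores numeric vector, at least 30 values with positive variance.
#' @return A list with `mu`, `beta`, and `converged`.
#' @export
fit_evd <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 30) stop("need at least 30 scores", call. = FALSE)
  s <- sd(scores)
  if (!is.finite(s) || s <= 0)
    stop("degenerate (constant) score vector", call. = FALSE)
  gamma <- 0.57721566490153286
  beta0 <- s * sqrt(6) / pi
  mu0 <- mean(scores) - gamma * beta0
  nll <- function(par) {
    beta <- par[2]
    if (beta <= 0) return(1e12)
    z <- (scores - par[1]) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- optim(c(mu0, beta0), nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  list(mu = fit$par[1], beta = fit$par[2], converged = fit$convergence == 0)
}

gumbel_upper_p <- function(x, mu, beta) {
  # upper-tail P(S >= x); computed via expm1 for numerical stability
  -expm1(-exp(-(x - mu) / beta))
}

#' Shuffle-test significance of an alignment score
#'
#' The observed score is the local alignment score of `a` against `b`; the
#' null sample consists of local scores of shuffled copies of `a` against the
#' same `b`.  A Gumbel law fitted to the shuffled scores gives the upper-tail
#' p-value of the observed score; the E-value equals the p-value under the
#' single-comparison convention (no database-size multiplier).
#'
#' @param a,b `mm_sequence` (nucleotide).
#' @param scheme local scoring scheme (see [local_scheme()]).
#' @param n_shuffles number of shuffles (`>= 30`; 1000 for full fidelity,
#'   100 is a reasonable desk scale).
#' @param seed master seed; shuffle `i` uses `fanout_seed(seed, i)`.
#' @return An `mm_shuffle_null` with the observed score, the shuffled score
#'   sample, fitted `mu` and `beta`, `p_value` and `e_value`.
#' @export
shuffle_significance <- function(a, b, scheme = local_scheme(),
                                 n_shuffles = 1000L, seed = 1L) {
  a <- as_mm_sequence(a); b <- as_mm_sequence(b)
  if (n_shuffles < 30) stop("n_shuffles must be at least 30", call. = FALSE)
  eff <- effective_gaps(scheme)
  obs <- cpp_local_score(a$residues, b$residues, scheme$match, scheme$mismatch,
                         eff$open, eff$extend)
  shuf <- vapply(seq_len(n_shuffles), function(i) {
    s <- shuffle_sequence(a, fanout_seed(seed, i))
    cpp_local_score(s$residues, b$residues, scheme$match, scheme$mismatch,
                    eff$open, eff$extend)
  }, numeric(1))
  fit <- fit_evd(shuf)
  p <- gumbel_upper_p(obs, fit$mu, fit$beta)
  structure(list(observed_score = obs, shuffled_scores = shuf,
                 mu = fit$mu, beta = fit$beta,
                 p_value = p, e_value = p,
                 n_shuffles = as.integer(n_shuffles), seed = as.integer(seed),
                 a_id = a$id, b_id = b$id),
            class = "mm_shuffle_null")
}

#' @export
print.mm_shuffle_null <- function(x, ...) {
  cat(sprintf(paste0("<mm_shuffle_null> %s vs %s: observed %.1f, ",
                     "Gumbel(mu %.2f, beta %.2f), E = %.3g (%d shuffles)\n"),
              x$a_id, x$b_id, x$observed_score, x$mu, x$beta, x$e_value,
              x$n_shuffles))
  invisible(x)
}

#' @export
tidy.mm_shuffle_null <- function(x, ...) {
  tibble(shuffle = seq_along(x$shuffled_scores), score = x$shuffled_scores)
}

#' @export
glance.mm_shuffle_null <- function(x, ...) {
  tibble(observed_score = x$observed_score, mu = x$mu, beta = x$beta,
         p_value = x$p_value, e_value = x$e_value, n_shuffles = x$n_shuffles)
}

#' Expected counts of maximal match runs under an i.i.d. null
#'
#' Closed form for the expected number of maximal 1-runs of exact length `k`
#' in an i.i.d. Bernoulli(`p`) match mask of length `N`:
#' interior term `(N - k - 1) p^k (1 - p)^2` plus boundary term
#' `2 p^k (1 - p)` for `k < N`, and `p^N` for `k = N`.  Serves as the
#' independent oracle for [run_spectrum()] on simulated masks.
#'
#' @param N mask length.
#' @param p per-column match probability.
#' @return A tibble with `k` and `expected`.
#' @export
expected_run_counts <- function(N, p) {
  stopifnot(N >= 1, p >= 0, p <= 1)
  k <- seq_len(N)
  e <- ifelse(k < N,
              pmax(N - k - 1, 0) * p^k * (1 - p)^2 + 2 * p^k * (1 - p),
              p^N)
  tibble(k = k, expected = e)
}

#' Ensemble spectrum of random sequence pairs
#'
#' Generates `n_pairs` independent pairs of exact-composition random
#' sequences, aligns each pair in seeded mode, and accumulates their
#' identity-run spectra - the randomized-control ensemble.  Pair `i` draws
#' its two sequences from `fanout_seed(seed, 2i-1)` and
#' `fanout_seed(seed, 2i)`.
#'
#' @param n_pairs number of pairs (desk default 50; 1000-sequence fidelity is
#'   a matter of compute time only).
#' @param length sequence length (default 29,903).
#' @param profile composition template (default [sarscov2_composition()]).
#' @param scheme an [scoring_scheme()].
#' @param seed master seed.
#' @param max_tracked top run-length bin (see [run_spectrum()]).
#' @return An `mm_ensemble`: aggregate `spectrum` (an `mm_run_spectrum`
#'   summed over pairs), per-pair tibble `pairs` (`pair`,
#'   `identity_percent`, `runs_gt10`), and `mean_identity`.
#' @export
ensemble_spectrum <- function(n_pairs = 50L, length = 29903L,
                              profile = sarscov2_composition(),
                              scheme = scoring_scheme(), seed = 1L,
                              max_tracked = 13L) {
  stopifnot(n_pairs >= 1)
  agg <- NULL
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    s1 <- random_sequence(length, profile, fanout_seed(seed, 2L * i - 1L),
                          id = sprintf("rand_%d_a", i))
    s2 <- random_sequence(length, profile, fanout_seed(seed, 2L * i),
                          id = sprintf("rand_%d_b", i))
    aln <- align_seeded(s1, s2, scheme)
    sp <- run_spectrum(aln, max_tracked = max_tracked)
    agg <- if (is.null(agg)) sp else add_spectra(agg, sp)
    lens_gt10 <- sum(sp$run_counts[as.character(11:max_tracked)]) +
      sp$run_counts[[paste0(">", max_tracked)]]
    rows[[i]] <- tibble(pair = i, identity_percent = sp$identity_percent,
                        runs_gt10 = as.integer(lens_gt10))
  }
  pairs <- dplyr::bind_rows(rows)
  structure(list(spectrum = agg, pairs = pairs,
                 mean_identity = mean(pairs$identity_percent),
                 n_pairs = as.integer(n_pairs), length = as.integer(length),
                 seed = as.integer(seed)),
            class = "mm_ensemble")
}

add_spectra <- function(x, y) {
  stopifnot(identical(names(x$run_counts), names(y$run_counts)))
  structure(list(run_counts = x$run_counts + y$run_counts,
                 columns = x$columns + y$columns,
                 matches = x$matches + y$matches,
                 identity_percent = 100 * (x$matches + y$matches) /
                   (x$columns + y$columns),
                 pooled_matches = x$pooled_matches + y$pooled_matches,
                 max_tracked = x$max_tracked),
            class = "mm_run_spectrum")
}

#' @export
print.mm_ensemble <- function(x, ...) {
  cat(sprintf("<mm_ensemble> %d pairs of length %d: mean identity %.2f%%\n",
              x$n_pairs, x$length, x$mean_identity))
  print(spectrum_percentages(x$spectrum), n = 5)
  invisible(x)
}

#' @export
tidy.mm_ensemble <- function(x, ...) {
  dplyr::mutate(spectrum_percentages(x$spectrum), n_pairs = x$n_pairs)
}
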