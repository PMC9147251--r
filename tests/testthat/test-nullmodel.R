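test_that("composition-matched randomization conserves the profile exactly and reproduces from seed", {
  prof <- small_profile()
  r1 <- random_sequence(100, prof, 5)
  r2 <- random_sequence(100, prof, 5)
  r3 <- random_sequence(100, prof, 6)
  expect_equal(r1$residues, r2$residues)
  expect_false(r1$residues == r3$residues)
  expect_equal(composition(r1)$counts[names(prof$counts)], prof$counts)
  # frequency mode rescales to the requested length
  r4 <- random_sequence(207, prof, 8)
  expect_equal(length(r4), 207)
  expect_equal(composition(r4)$length, 207L)
  # exact-length profile: a pure multiset permutation
  tiny <- composition_profile(A = 2L, C = 1L, G = 1L)
  r5 <- random_sequence(4, tiny, 9)
  expect_equal(sort(strsplit(r5$residues, "")[[1]]), c("A", "A", "C", "G"))
})

test_that("multiset permutations are uniform over distinct arrangements", {
  prof <- composition_profile(A = 3L, C = 2L, G = 1L)
  draws <- vapply(1:6000, function(i) random_sequence(6, prof, i)$residues,
                  character(1))
  tab <- table(draws)
  expect_equal(length(tab), choose(6, 3) * choose(3, 2))  # 60 arrangements
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-4)
})

test_that("shuffling conserves composition in global and windowed modes", {
  s <- mm_sequence(rand_dna(300, seed = 61))
  for (seed in 1:5) {
    expect_equal(composition(shuffle_sequence(s, seed))$counts,
                 composition(s)$counts)
    expect_equal(composition(shuffle_sequence(s, seed, window = 10))$counts,
                 composition(s)$counts)
  }
  expect_error(shuffle_sequence(s, 1, window = 1), "window")
  # windowed shuffle with window >= length is a single global block
  short <- mm_sequence("ACGTACGT")
  expect_equal(shuffle_sequence(short, 3, window = 8)$residues,
               shuffle_sequence(short, 3)$residues)
  # window-2 shuffling keeps every letter within one position of home
  for (seed in 1:10) {
    sh <- shuffle_sequence(short, seed, window = 2)
    orig <- strsplit(short$residues, "")[[1]]
    perm <- strsplit(sh$residues, "")[[1]]
    for (blk in seq(1, 8, 2))
      expect_setequal(perm[blk:(blk + 1)], orig[blk:(blk + 1)])
  }
})

test_that("the Gumbel fit recovers known parameters and obeys shift equivariance", {
  withr::local_seed(13)
  x <- 10 - 2 * log(-log(runif(10000)))  # Gumbel(mu = 10, beta = 2)
  f <- fit_evd(x)
  expect_equal(f$mu, 10, tolerance = 0.02)
  expect_equal(f$beta, 2, tolerance = 0.02)
  expect_error(fit_evd(rep(3, 100)), "degenerate")
  expect_error(fit_evd(x[1:10]), "at least 30")
  g <- fit_evd(x + 7)
  expect_equal(g$mu, f$mu + 7, tolerance = 1e-4)
  expect_equal(g$beta, f$beta, tolerance = 1e-4)
})

test_that("expected run counts match exhaustive enumeration and conserve mass", {
  # enumerate all 2^3 masks at N = 3 and count exact-length-k runs
  masks <- expand.grid(rep(list(c(0, 1)), 3))
  count_k <- function(mask, k) sum(regex_run_lengths(mask == 1) == k)
  for (k in 1:3) {
    enum <- mean(apply(masks, 1, count_k, k = k))
    expect_equal(expected_run_counts(3, 0.5)$expected[k], enum,
                 tolerance = 1e-12)
  }
  expect_equal(expected_run_counts(3, 0.5)$expected[1], 0.625)
  # degenerate limits
  expect_equal(sum(expected_run_counts(10, 0)$expected), 0)
  expect_equal(expected_run_counts(10, 1)$expected[10], 1)
  expect_equal(sum(expected_run_counts(10, 1)$expected[1:9]), 0)
  # mass conservation at arbitrary p
  for (p in c(0.25, 0.45, 0.6)) {
    e <- expected_run_counts(50, p)
    expect_equal(sum(e$k * e$expected), 50 * p, tolerance = 1e-9)
  }
})

test_that("simulated run spectra converge to the closed-form expectation", {
  withr::local_seed(14)
  N <- 10000; reps <- 200
  for (p in c(0.25, 0.45, 0.6)) {
    counts <- matrix(0, nrow = reps, ncol = 8)
    for (r in 1:reps) {
      sp <- run_spectrum(runif(N) < p, max_tracked = 13)
      counts[r, ] <- sp$run_counts[as.character(1:8)]
    }
    e <- expected_run_counts(N, p)$expected[1:8]
    se <- apply(counts, 2, sd) / sqrt(reps)
    expect_true(all(abs(colMeans(counts) - e) <= 3 * pmax(se, 1e-6) + 1e-9))
  }
})

test_that("shuffle significance separates planted homology from noise", {
  prof <- small_profile()
  a <- random_sequence(500, prof, 81)
  b <- random_sequence(500, prof, 82)
  null_pair <- shuffle_significance(a, b, n_shuffles = 100, seed = 83)
  expect_gte(null_pair$e_value, 0)
  expect_equal(null_pair$p_value, null_pair$e_value)
  # planted 200-nt copy drives E far below 0.01
  planted <- mm_sequence(paste0(substr(a$residues, 151, 350),
                                random_sequence(300, prof, 84)$residues),
                         id = "planted")
  sig <- shuffle_significance(a, planted, n_shuffles = 100, seed = 85)
  expect_lt(sig$e_value, 1e-4)
  expect_gt(sig$observed_score, max(sig$shuffled_scores))
  # p-value of the median shuffled score is near one half
  med <- stats::median(null_pair$shuffled_scores)
  p_med <- 1 - exp(-exp(-(med - null_pair$mu) / null_pair$beta))
  expect_gt(p_med, 0.3); expect_lt(p_med, 0.7)
  # E is monotone non-increasing in the observed score
  grid <- seq(min(null_pair$shuffled_scores), max(null_pair$shuffled_scores) + 50,
              length.out = 25)
  evals <- 1 - exp(-exp(-(grid - null_pair$mu) / null_pair$beta))
  expect_true(all(diff(evals) <= 1e-12))
  expect_error(shuffle_significance(a, b, n_shuffles = 10), "at least 30")
})

test_that("seed fan-out is deterministic and in integer range", {
  s <- vapply(0:1000, function(i) fanout_seed(42, i), integer(1))
  expect_true(all(s >= 1 & s <= 2^31 - 1))
  expect_equal(fanout_seed(42, 7), fanout_seed(42, 7))
  expect_false(fanout_seed(42, 7) == fanout_seed(42, 8))
  expect_false(fanout_seed(42, 7) == fanout_seed(43, 7))
})

test_that("small ensembles carry per-pair identities and reproducible aggregates", {
  prof <- small_profile()
  ens <- ensemble_spectrum(n_pairs = 3, length = 1200, profile = prof, seed = 5)
  expect_equal(nrow(ens$pairs), 3)
  expect_equal(ens$mean_identity, mean(ens$pairs$identity_percent))
  ens2 <- ensemble_spectrum(n_pairs = 3, length = 1200, profile = prof, seed = 5)
  expect_equal(ens$spectrum$run_counts, ens2$spectrum$run_counts)
  expect_equal(ens$pairs$identity_percent, ens2$pairs$identity_percent)
  td <- tidy(ens)
  expect_true(all(c("k", "count", "percent", "n_pairs") %in% names(td)))
})
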