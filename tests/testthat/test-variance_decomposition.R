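test_that("parallel-axis identity holds against the brute-force oracle", {
  set.seed(101)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    counts <- as.numeric(rpois(4^k, lambda = runif(1, 2, 50)))
    counts[1] <- counts[1] + 1  # guard against all-zero draws
    spec <- structure(list(k = k, counts = counts, W = sum(counts),
                           Nbar = sum(counts) / 4^k),
                      class = "kmer_spectrum")
    dec <- decompose_cv(spec)
    oracle <- brute_decompose(counts, k)
    expect_equal(dec$M2, oracle$M2, tolerance = 1e-12)
    expect_equal(dec$Mnf2, oracle$Mnf2, tolerance = 1e-12)
    expect_equal(dec$Mf2, oracle$Mf2, tolerance = 1e-12)
    expect_lt(abs(dec$M2 - (dec$Mnf2 + dec$Mf2)),
              1e-12 * max(dec$M2, 1e-300))
  }
})

test_that("constant spectra decompose to zero", {
  spec <- structure(list(k = 3L, counts = rep(5, 64), W = 320, Nbar = 5),
                    class = "kmer_spectrum")
  dec <- decompose_cv(spec)
  expect_equal(dec$M2, 0)
  expect_equal(dec$Mnf2, 0)
  expect_equal(dec$Mf2, 0)
})

test_that("expected m-set means reproduce the closed-form table rows", {
  # printed random-expectation cells at L = 2 Mb, k = 5, m = 2
  expect_equal(expected_mset_mean(2e6, 0.492, 5, 2, integer_values = TRUE),
               1983)
  expect_equal(expected_mset_mean(2e6, 0.691, 5, 2, integer_values = TRUE),
               880)
  # collapse at even composition
  expect_equal(expected_mset_mean(1e6, 0.5, 5, 0:5), rep(1e6 / 4^5, 6))
  # binomial row-sum identity: sum_m n_m mean_m = L
  for (p in c(0.3, 0.492, 0.6, 0.75)) {
    for (k in 2:6) {
      sizes <- mset_partition(k)$sizes
      expect_equal(sum(sizes * expected_mset_mean(2e6, p, k, 0:k)), 2e6)
    }
  }
  expect_error(expected_mset_mean(1e6, 0.5, 5, 6), "out of range")
})

test_that("nf variance limit has the symmetry, zero and printed values", {
  expect_equal(nf_variance_limit(0.5, 4), 0)
  expect_equal(nf_variance_limit(0.7, 2), 0.3456)
  expect_equal(nf_variance_limit(0.7, 3), brute_nf_limit(0.7, 3))
  expect_equal(nf_variance_limit(0.35, 4), brute_nf_limit(0.35, 4))
  # Table-7-style values for the two worked compositions
  expect_equal(nf_variance_limit(0.691, 5), 0.976, tolerance = 5e-4)
  expect_equal(nf_variance_limit(0.492, 5), 0.0013, tolerance = 0.05)
  # symmetry and monotonicity in |p - 0.5|
  for (k in 2:6) {
    expect_equal(nf_variance_limit(0.3, k), nf_variance_limit(0.7, k))
    vals <- vapply(c(0.55, 0.6, 0.65, 0.7, 0.8),
                   nf_variance_limit, numeric(1), k = k)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("measured Mnf2 of shuffles approaches the large-L limit", {
  rec <- exact_composition_sequence(4e5, 0.7, seed = 31)
  dec <- decompose_cv(count_kmers(rec, 4))
  lim <- nf_variance_limit(0.7, 4)
  expect_lt(abs(dec$Mnf2 - lim) / lim, 0.05)
})

test_that("crossover lengths match the closed-form sentence values", {
  expect_equal(crossover_length(0.7, 4), 316)
  expect_equal(crossover_length(0.7, 6), 2852)  # printed as 2851 (truncated)
  expect_equal(crossover_length(0.7, 2), 46)    # printed 42 is discrepant
  expect_identical(crossover_length(0.5, 4), Inf)
})

test_that("equivalent length of random sequences tracks the true length", {
  # pooled over replicates: the per-sequence Mf2 estimator has ~13%
  # relative SD at k = 4, so a small ensemble stabilizes the ratio
  for (p in c(0.5, 0.7)) {
    mf2 <- sapply(1:10, function(j) {
      rec <- random_sequence(1e5, p, seed = round(100 * p) + j)
      vapply(c(4, 6), function(k) decompose_cv(count_kmers(rec, k))$Mf2,
             numeric(1))
    })
    for (row in 1:2) {
      k <- c(4, 6)[row]
      gamma <- 1 - sum((p / 2)^(0:k) * ((1 - p) / 2)^(k - 0:k))
      ratio <- gamma * 4^k / mean(mf2[row, ]) / 1e5
      expect_gt(ratio, 0.85)
      expect_lt(ratio, 1.15)
    }
  }
})

test_that("gamma policies behave as documented", {
  rec <- random_sequence(2e5, 0.5, seed = 9)
  dec <- decompose_cv(count_kmers(rec, 4))
  le_unity <- equivalent_length(dec, p = 0.5, gamma_policy = "unity")
  expect_equal(le_unity$Le, 4^4 / dec$Mf2)
  le_an <- equivalent_length(dec, p = 0.5, gamma_policy = "analytic")
  expect_equal(le_an$gamma, 1 - 5 / 4^4)  # 1 - (k+1)/4^k at p = 0.5
  # montecarlo at k = 6, where the per-sequence estimator is tight
  rec6 <- exact_composition_sequence(2e5, 0.5, seed = 78)
  dec6 <- decompose_cv(count_kmers(rec6, 6))
  le_mc <- equivalent_length(dec6, p = 0.5, gamma_policy = "montecarlo",
                             L = rec6$length, n_cal = 8, seed = 77)
  expect_gt(le_mc$Le / rec6$length, 0.9)
  expect_lt(le_mc$Le / rec6$length, 1.1)
  expect_error(equivalent_length(dec, p = 0.5,
                                 gamma_policy = "montecarlo"),
               "requires L")

  const <- structure(list(k = 2L, counts = rep(2, 16), W = 32, Nbar = 2),
                     class = "kmer_spectrum")
  expect_error(equivalent_length(decompose_cv(const), p = 0.5),
               "zero fluctuating variance")
})

test_that("duplicating a sequence leaves its equivalent length unchanged", {
  x <- random_sequence(2e5, 0.5, seed = 13)
  xx <- seq_record("xx", paste0(x$residues, x$residues))
  le_x <- equivalent_length_of(x, 4)$Le
  le_xx <- equivalent_length_of(xx, 4)$Le
  # doubling by replication must not double Le
  expect_lt(le_xx / le_x, 1.4)
  expect_gt(le_xx / le_x, 0.6)
})

test_that("le_profile tracks length for shuffles and guards saturation", {
  rec <- random_sequence(4e5, 0.5, seed = 21)
  prof <- le_profile(rec, 3, lengths = c(2e4, 8e4), seed = 5)
  expect_equal(prof$n_segments, c(20, 5))
  # slope ~ 1 in log-log: Le ratio tracks the 4x length ratio
  ratio <- prof$le_mean[2] / prof$le_mean[1]
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6)

  expect_error(le_profile(rec, 3, lengths = 1e6), "shorter")

  # saturating input: segment lengths below 4 x asymptotic Le are refused
  sat <- rsd_simulate(rsd_params(L_target = 3e5, r = 0, seed = 3))$sequence
  le_sat <- equivalent_length_of(sat, 4)$Le
  expect_error(le_profile(sat, 4, lengths = round(le_sat)), "below 4")
})
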