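test_that("initial sequences have the requested length and bias", {
  set.seed(1)
  r <- rsd_init_sequence(64, 0.5)
  expect_equal(r$length, 64L)

  at_only <- rsd_init_sequence(200, 1 - 1e-12)
  expect_true(all(strsplit(at_only$residues, "")[[1]] %in% c("A", "T")))

  big <- rsd_init_sequence(1e5, 0.5)
  expect_lt(abs(big$p - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("growth stops in [target, target + 2 d_mean) with increasing log", {
  params <- rsd_params(L0 = 64, d_mean = 500, L_target = 5e4, seed = 3)
  sim <- rsd_simulate(params, keep_log = TRUE)
  expect_gte(sim$sequence$length, 5e4)
  expect_lt(sim$sequence$length, 5e4 + 2 * 500)
  expect_true(all(diff(sim$log[, "length_after"]) > 0))
  expect_true(all(sim$log[, "length"] >= 1 &
                    sim$log[, "length"] <= 2 * 500))
})

test_that("minimal growth from one base duplicates only existing content", {
  set.seed(5)
  grown <- rsd_grow(seq_record("init", "A"),
                    rsd_params(L0 = 1, d_mean = 1, L_target = 10))
  # segments are uniform on [1, 2*d_mean] capped at the current length,
  # so every event copies 1 or 2 bases and the result is all A
  expect_true(all(grown$log[, "length"] %in% c(1L, 2L)))
  expect_equal(unname(grown$log[1, "length"]), 1L)  # capped at L = 1
  expect_gte(grown$sequence$length, 10L)
  expect_lt(grown$sequence$length, 12L)
  expect_equal(grown$sequence$residues,
               strrep("A", grown$sequence$length))
})

test_that("the event log replays to the identical sequence", {
  set.seed(7)
  init <- rsd_init_sequence(64, 0.5)
  grown <- rsd_grow(init, rsd_params(L0 = 64, d_mean = 200,
                                     L_target = 2e4))
  expect_identical(rsd_replay(init$residues, grown$log),
                   grown$sequence$residues)
})

test_that("mutation counts and identity limits are exact", {
  rec <- random_sequence(1e4, 0.5, seed = 9)
  set.seed(11)
  same <- rsd_mutate(rec, 0)
  expect_identical(same$residues, rec$residues)
  expect_identical(attr(same, "n_mut"), 0L)

  mut <- rsd_mutate(rec, 0.73)
  expect_equal(attr(mut, "n_mut"), round(0.73 * 1e4))
  expect_equal(mut$length, rec$length)
})

test_that("the full pipeline is bit-identical under a fixed seed", {
  params <- rsd_params(L_target = 5e4, seed = 13)
  a <- rsd_simulate(params)
  b <- rsd_simulate(params)
  expect_identical(a$sequence$residues, b$sequence$residues)
  c <- rsd_simulate(rsd_params(L_target = 5e4, seed = 14))
  expect_false(identical(c$sequence$residues, a$sequence$residues))
})

test_that("mutations move duplication-only sequences toward randomness", {
  params <- rsd_params(L_target = 4e5, r = 0, seed = 17)
  dup_only <- rsd_simulate(params)$sequence
  le_dup <- equivalent_length_of(dup_only, 4, gamma_policy = "unity")$Le
  le_shuf <- equivalent_length_of(
    shuffle_matching_random(dup_only, seed = 1), 4,
    gamma_policy = "unity")$Le
  expect_lt(le_dup * 10, le_shuf)  # far less random than its shuffle

  set.seed(19)
  heavy <- rsd_mutate(dup_only, 3)
  le_heavy <- equivalent_length_of(heavy, 4, gamma_policy = "unity")$Le
  expect_gt(le_heavy, 20 * le_dup)  # heavy mutation erases the structure
})

test_that("equivalent length saturates with segment length for RSD input", {
  sim <- rsd_simulate(rsd_params(L_target = 1e6, seed = 23))$sequence
  prof <- le_profile(sim, 4, lengths = c(1e5, 5e5), seed = 3,
                     gamma_policy = "unity")
  expect_lt(prof$le_mean[2] / prof$le_mean[1], 2)  # not tracking 5x length
})

test_that("batch equivalent lengths are stable across final lengths", {
  les <- vapply(c(5e5, 1e6), function(L) {
    b <- simulate_batch(rsd_params(L_target = L, seed = 27), n = 3,
                        ks = 4)
    exp(mean(log(b$le_table$Le)))
  }, numeric(1))
  expect_lt(abs(log(les[2] / les[1])), log(2))  # insensitive beyond 0.5 Mb
})

test_that("simulate_batch returns coherent tables and chi-squares", {
  b <- simulate_batch(rsd_params(L_target = 3e5, seed = 31), n = 2,
                      ks = c(2, 4))
  expect_equal(nrow(b$le_table), 4L)
  expect_named(b$le_table, c("replicate", "k", "Le", "p", "L"))
  expect_gte(b$chi2, 0)
  expect_gte(b$chi2_per_sequence, b$chi2 - 1e-12)  # dispersion adds terms
  # determinism of the whole batch
  b2 <- simulate_batch(rsd_params(L_target = 3e5, seed = 31), n = 2,
                       ks = c(2, 4))
  expect_identical(b$le_table, b2$le_table)
})
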