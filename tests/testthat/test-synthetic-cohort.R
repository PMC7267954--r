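test_that("cohort truth validates its variance components and sites", {
  expect_error(cohort_truth(regions = data.frame(
    id = 1L, name = "r", amplitude = 1, sigma2_b = -1, sigma2_w = 1)),
    "non-negative")
  expect_error(cohort_truth(site_sizes = c(10, 10)), "sum")
  tr <- cohort_truth(regions = data.frame(
    id = 1L, name = "r", amplitude = 1, sigma2_b = 1, sigma2_w = 1),
    site_sizes = 36)
  expect_equal(tr$true_icc, 0.5)
})

test_that("zero within-subject variance gives identical repeat sessions", {
  tr <- small_truth(seed = 2, sigma2_b = c(1, 1), sigma2_w = c(0, 0),
                    n_subjects = 6, session_effects = c(0, 0, 0))
  st <- simulate_contrast_cohort(tr)
  expect_equal(st$values[, 1, st$mask], st$values[, 2, st$mask])
  expect_equal(st$values[, 1, st$mask], st$values[, 3, st$mask])
})

test_that("simulation is bit-reproducible given the seed", {
  a <- simulate_contrast_cohort(small_truth(seed = 7, n_subjects = 6))
  b <- simulate_contrast_cohort(small_truth(seed = 7, n_subjects = 6))
  expect_identical(a$values, b$values)
})

test_that("session effects shift all subjects equally and leave ICC unchanged", {
  base <- small_truth(seed = 9, n_subjects = 12)
  shifted <- base
  shifted$session_effects <- c(0, 3, -2)
  icc_a <- voxelwise_icc(simulate_contrast_cohort(base))$icc
  icc_b <- voxelwise_icc(simulate_contrast_cohort(shifted))$icc
  expect_equal(icc_a, icc_b, tolerance = 1e-9)
})

test_that("site offsets act as stable subject traits that raise ICC", {
  plain <- small_truth(seed = 12, n_subjects = 36,
                       site_sizes = c(12, 12, 12))
  offset <- plain
  offset$site_offsets <- c(-2, 0, 2)
  icc_plain <- voxelwise_icc(simulate_contrast_cohort(plain))$icc
  icc_off <- voxelwise_icc(simulate_contrast_cohort(offset))$icc
  expect_gt(median(icc_off, na.rm = TRUE), median(icc_plain, na.rm = TRUE))
})

test_that("empirical variance components converge at large n", {
  tr <- cohort_truth(
    n_subjects = 500, grid_dim = c(4, 4, 2),
    regions = data.frame(id = 1L, name = "r", amplitude = 0,
                         sigma2_b = 2, sigma2_w = 1),
    session_effects = c(0, 0, 0), site_sizes = 500, site_offsets = 0,
    seed = 31)
  st <- simulate_contrast_cohort(tr, subject_effect = "voxel")
  v <- which(st$mask)
  ms <- lapply(v, function(j) anova_components(st$values[, , j]))
  s2b_hat <- mean(vapply(ms, `[[`, numeric(1), "sigma2_b"))
  s2w_hat <- mean(vapply(ms, `[[`, numeric(1), "sigma2_w"))
  expect_equal(s2b_hat, 2, tolerance = 0.05)
  expect_equal(s2w_hat, 1, tolerance = 0.05)
})

test_that("mean estimated ICC tracks the simulated variance ratio", {
  # true ICC 0.5 from sigma2_b = sigma2_w
  devs <- vapply(1:5, function(s) {
    tr <- cohort_truth(
      n_subjects = 36, grid_dim = c(10, 10, 1),
      regions = data.frame(id = 1L, name = "r", amplitude = 0,
                           sigma2_b = 1, sigma2_w = 1),
      session_effects = c(0, 0, 0), site_sizes = 36, site_offsets = 0,
      seed = 40 + s)
    st <- simulate_contrast_cohort(tr, subject_effect = "voxel")
    mean(voxelwise_icc(st)$icc[st$mask])
  }, numeric(1))
  expect_lt(abs(mean(devs) - 0.5), 0.05)
})

test_that("noiseless BOLD simulation is exact and deterministic", {
  seqs <- generate_sequence(1, 10, c(3, 4), seed = 3)
  tr <- small_truth(seed = 3, n_subjects = 4, grid_dim = c(6, 6, 4))
  amps <- matrix(0, 2, 2, dimnames = list(c("1", "2"),
                                          c("congruent", "incongruent")))
  run0 <- simulate_bold_run(seqs, tr, amps, n_volumes = 40, noise_sd = 0,
                            seed = 5)
  expect_true(all(run0$bold == 0))
  expect_equal(dim(run0$bold), c(6, 6, 4, 40))
  expect_equal(dim(run0$motion), c(40, 6))

  amps1 <- amps; amps1["1", ] <- 1
  run1 <- simulate_bold_run(seqs, tr, amps1, n_volumes = 40, noise_sd = 0,
                            seed = 5)
  reg <- hrf_regressor(seqs$onset, seqs$duration, 40, 2)
  vox_in <- which(as.integer(tr$region_map) == 1L)[1]
  ts <- matrix(run1$bold, prod(dim(run1$bold)[1:3]), 40)[vox_in, ]
  expect_equal(ts, reg, tolerance = 1e-12)

  expect_error(simulate_bold_run(seqs, tr, amps1, n_volumes = 10, seed = 5),
               "past the end")
})

test_that("motion spikes appear at the requested volumes", {
  seqs <- generate_sequence(1, 10, c(3, 4), seed = 3)
  tr <- small_truth(seed = 3, n_subjects = 4, grid_dim = c(6, 6, 4))
  amps <- matrix(0, 2, 2, dimnames = list(c("1", "2"),
                                          c("congruent", "incongruent")))
  run <- simulate_bold_run(seqs, tr, amps, n_volumes = 40, noise_sd = 0,
                           spike_volumes = 20, seed = 5)
  m <- as.matrix(run$motion[, 1:3])
  d <- sqrt(rowSums(m^2))
  expect_equal(which.max(d), 20)
})

test_that("simulated behavior has the configured error structure", {
  seqs <- generate_sequence(2, 74, c(3, 5), seed = 61)
  bad <- simulate_behavior(seqs, n_subjects = 2, n_sessions = 1,
                           commission_rate = c(0.5, 0.5),
                           error_subject_sd = 0, seed = 61)
  q <- qc_runs(bad)
  expect_true(any(!q$pass))

  resp <- simulate_behavior(seqs, n_subjects = 36, seed = 62)
  expect_identical(resp, simulate_behavior(seqs, n_subjects = 36, seed = 62))
  # omissions carry no RT; RT present iff a response was made
  expect_true(all(is.na(resp$rt_ms[resp$omission_error])))
  expect_true(all(!is.na(resp$rt_ms[resp$response != "none"])))
  # median conflict cost near the configured 60 ms
  bsum <- behavioral_summary(resp)
  med <- tapply(bsum$median_rt_ms, bsum$condition, median)
  expect_lt(abs((med["incongruent"] - med["congruent"]) - 60), 15)
})
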