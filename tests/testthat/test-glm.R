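toy_seq <- function(onsets, congruent = rep(TRUE, length(onsets)),
                    emotion = rep("happy", length(onsets))) {
  data.frame(run_index = 1L, trial_index = seq_along(onsets),
             onset = onsets, duration = 1, face_emotion = emotion,
             word = toupper(ifelse(congruent, emotion,
                                   ifelse(emotion == "happy", "fear", "happy"))),
             congruent = congruent,
             adaptation_label = c("first", rep("cC", length(onsets) - 1)),
             isi_after = 4, stringsAsFactors = FALSE)
}

test_that("condition regressors peak 4-7 s after onset and designs assemble", {
  s <- toy_seq(10)
  d <- build_design(s, n_volumes = 30, tr = 2,
                    conditions = list(stim = function(x) rep(TRUE, nrow(x))))
  col <- d$X[, "stim"]
  peak_time <- (which.max(col) - 1) * 2
  expect_true(peak_time >= 14 && peak_time <= 17)  # onset 10 + HRF peak 4-7 s
  expect_true(all(c("trend_0", "trend_1", "trend_2") %in% colnames(d$X)))
  # 100 s cutoff on a 60 s run adds one cosine regressor
  expect_true("dct_1" %in% colnames(d$X))
})

test_that("empty conditions are dropped with a warning; collinear pairs warn", {
  s <- toy_seq(c(10, 20), congruent = c(TRUE, TRUE))
  expect_warning(
    d <- build_design(s, n_volumes = 40, tr = 2,
                      conditions = list(congruent = function(x) x$congruent,
                                        incongruent = function(x) !x$congruent)),
    "incongruent")
  expect_false("incongruent" %in% colnames(d$X))

  dup <- list(a = function(x) rep(TRUE, nrow(x)),
              b = function(x) rep(TRUE, nrow(x)))
  expect_warning(build_design(s, n_volumes = 40, tr = 2, conditions = dup),
                 "rank deficient")
  expect_error(build_design(toy_seq(100), n_volumes = 30, tr = 2),
               "past the end")
})

test_that("noiseless GLM recovers the generating amplitudes exactly", {
  seqs <- generate_sequence(1, 12, c(3, 4), seed = 8)
  tr <- small_truth(seed = 8, n_subjects = 2, grid_dim = c(6, 6, 4))
  amps <- matrix(c(1.0, 1.3, 0.4, 0.8), 2, 2, byrow = TRUE,
                 dimnames = list(c("1", "2"), c("congruent", "incongruent")))
  run <- simulate_bold_run(seqs, tr, amps, n_volumes = 45, noise_sd = 0,
                           seed = 8)
  d <- build_design(seqs, n_volumes = 45, tr = 2,
                    conditions = list(congruent = function(x) x$congruent,
                                      incongruent = function(x) !x$congruent))
  fit <- fit_glm(run$bold, d)
  lab <- as.integer(tr$region_map)
  for (rid in 1:2) {
    vox <- which(lab == rid)
    expect_lt(max(abs(fit$betas["congruent", vox] - amps[rid, "congruent"])),
              1e-8)
    expect_lt(max(abs(fit$betas["incongruent", vox] - amps[rid, "incongruent"])),
              1e-8)
  }
  # residuals orthogonal to every design column
  Y <- t(matrix(run$bold, prod(dim(run$bold)[1:3]), 45))
  res <- Y - d$X %*% fit$betas
  expect_lt(max(abs(crossprod(d$X, res))), 1e-6 * max(abs(Y)))
})

test_that("contrasts are linear combinations with named resolution", {
  seqs <- generate_sequence(1, 12, c(3, 4), seed = 9)
  tr <- small_truth(seed = 9, n_subjects = 2, grid_dim = c(6, 6, 4))
  amps <- matrix(c(0.7, 0.7, 0.2, 0.9), 2, 2, byrow = TRUE,
                 dimnames = list(c("1", "2"), c("congruent", "incongruent")))
  run <- simulate_bold_run(seqs, tr, amps, n_volumes = 45, noise_sd = 0, seed = 9)
  d <- build_design(seqs, n_volumes = 45, tr = 2,
                    conditions = list(congruent = function(x) x$congruent,
                                      incongruent = function(x) !x$congruent))
  fit <- fit_glm(run$bold, d)
  lab <- as.integer(tr$region_map)
  ic <- compute_contrast(fit, "incongruent-congruent")
  # equal amplitudes cancel; unequal leave the difference
  expect_lt(max(abs(ic[lab == 1])), 1e-8)
  expect_equal(unname(ic[lab == 2][1]), 0.7, tolerance = 1e-8)
  # linearity: c(a w1 + b w2) = a c(w1) + b c(w2)
  w1 <- c(congruent = 1); w2 <- c(incongruent = 1)
  lhs <- compute_contrast(fit, c(congruent = 2, incongruent = -3))
  rhs <- 2 * compute_contrast(fit, w1) - 3 * compute_contrast(fit, w2)
  expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-10)
  expect_error(compute_contrast(fit, "nosuch"), "not in design")
})

test_that("aliased design columns are dropped with a pivot report", {
  set.seed(10)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  Y <- matrix(rnorm(30 * 4), 30, 4)
  expect_warning(fit <- fit_glm(Y, X), "aliased")
  expect_equal(fit$dropped_columns, "c")
  expect_true(all(is.na(fit$betas["c", ])))
  expect_true(all(is.finite(fit$betas[c("a", "b"), ])))
})

test_that("the AR(1) option estimates autocorrelation and keeps betas unbiased", {
  set.seed(14)
  n <- 200
  X <- cbind(intercept = 1, x = rnorm(n))
  b <- c(2, 1.5)
  noise <- replicate(30, as.numeric(arima.sim(list(ar = 0.5), n, sd = 1)))
  Y <- matrix(X %*% b, n, 30) + noise
  fit <- fit_glm(Y, X, ar1 = TRUE)
  expect_gt(fit$rho, 0.3)
  expect_lt(fit$rho, 0.7)
  expect_lt(abs(mean(fit$betas["x", ]) - 1.5), 0.1)
  plain <- fit_glm(Y, X)
  expect_equal(plain$rho, 0)
})

test_that("second-level maps handle degenerate and antisymmetric cohorts", {
  identical_maps <- matrix(rep(c(1, 0), each = 6), 6, 2)
  sm <- second_level(identical_maps, grid_dim = c(2, 1, 1))
  expect_true(sm$capped[1])
  expect_equal(sm$t[1], 1e6)
  expect_equal(sm$t[2], 0)

  flip <- rbind(matrix(1, 3, 5), matrix(-1, 3, 5))
  sm2 <- second_level(flip)
  expect_true(all(abs(sm2$t) < 1e-12))
  expect_error(second_level(matrix(1, 1, 3)), "at least 2")
})

test_that("group t tracks the closed-form expectation on synthetic cohorts", {
  # amplitude 0.5, between-subject SD 0.5, n = 36 -> E[t] near 6
  ts <- vapply(1:8, function(s) {
    set.seed(300 + s)
    maps <- matrix(rnorm(36 * 50, 0.5, 0.5), 36, 50)
    mean(second_level(maps)$t)
  }, numeric(1))
  expect_lt(abs(mean(ts) - 6), 1)
})

test_that("cluster extraction respects size, connectivity and bookkeeping", {
  vol <- array(0, c(10, 10, 5))
  vol[2:4, 2:4, 2] <- 5            # 9 voxels
  vol[2:4, 2:4, 3] <- 5            # +9 -> 18-voxel blob
  vol[8:9, 8, 4] <- 5              # 2-voxel blob, below min_size
  cs <- extract_clusters(vol, threshold = 3, min_size = 10)
  expect_length(cs$clusters, 1)
  expect_equal(cs$clusters[[1]]$size, 18)
  expect_equal(cs$n_suprathreshold, 20)
  expect_equal(cs$n_dropped_voxels, 2)
  expect_equal(cs$clusters[[1]]$size + cs$n_dropped_voxels,
               cs$n_suprathreshold)

  expect_message(empty <- extract_clusters(vol, threshold = 10),
                 "uncorrected")
  expect_length(empty$clusters, 0)

  # 3-D plus shape: centre voxel with 2-voxel arms along each axis = 13
  plus <- array(0, c(9, 9, 9))
  plus[5, 5, 5] <- 10
  plus[c(3, 4, 6, 7), 5, 5] <- 9
  plus[5, c(3, 4, 6, 7), 5] <- 9
  plus[5, 5, c(3, 4, 6, 7)] <- 9
  cp <- extract_clusters(plus, threshold = 1, min_size = 10)
  expect_length(cp$clusters, 1)
  expect_equal(cp$clusters[[1]]$size, 13)
  expect_equal(cp$clusters[[1]]$peak, c(5L, 5L, 5L))

  # negative troughs count under two-sided thresholding, not one-sided
  vol2 <- array(0, c(6, 6, 3)); vol2[1:3, 1:3, 2] <- -5; vol2[5, 5, 2] <- 4
  two <- extract_clusters(vol2, threshold = 3, min_size = 2)
  expect_equal(two$clusters[[1]]$size, 9)
  one <- extract_clusters(vol2, threshold = 3, min_size = 1, two_sided = FALSE)
  expect_equal(length(one$clusters), 1)
  expect_equal(one$clusters[[1]]$peak_stat, 4)
})

test_that("Bonferroni FWE threshold is the qt bound; permutation is close on nulls", {
  set.seed(12)
  maps <- matrix(rnorm(20 * 100), 20, 100)
  sm <- second_level(maps)
  thr <- fwe_threshold(sm, alpha = 0.05)
  expect_equal(thr, qt(1 - 0.05 / 2 / 100, df = 19))
  perm <- fwe_threshold(sm, method = "permutation", maps = maps,
                        n_perm = 200, seed = 5)
  # permutation max-t on iid null data lands near (below) Bonferroni
  expect_true(perm > 2.5 && perm <= thr + 0.5)
})
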