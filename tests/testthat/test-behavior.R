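test_that("run QC applies the 25%/30% commission and total error thresholds", {
  mk <- function(n_com, n_om, n = 74) {
    toy_responses(rt = rep(600, n),
                  correct = c(rep(FALSE, n_com), rep(TRUE, n - n_com)),
                  omission = c(rep(FALSE, n - n_om), rep(TRUE, n_om)))
  }
  q1 <- qc_runs(mk(19, 0))
  expect_equal(q1$commission_rate, 19 / 74)
  expect_false(q1$pass)
  q2 <- qc_runs(mk(18, 4))
  expect_equal(q2$commission_rate, 18 / 74)
  expect_equal(q2$total_error_rate, 22 / 74)
  expect_true(q2$pass)
  expect_true(qc_runs(mk(0, 0))$pass)
})

test_that("RT filter removes error, post-error and 2 SD outlier trials", {
  # 9 trials at 600 ms and one at 2000 ms: the 2000 lies > 2 SD above the mean
  rt <- c(rep(600, 9), 2000)
  mu <- mean(rt); s <- sd(rt)
  expect_true(2000 > mu + 2 * s)   # oracle for the constructed values
  kept <- filter_rt_trials(toy_responses(rt))
  expect_equal(nrow(kept), 9)
  expect_equal(unname(attr(kept, "removal_counts")["rt_outlier"]), 1)

  # an error at trial 3 removes trials 3 and 4 regardless of RT
  correct <- rep(TRUE, 10); correct[3] <- FALSE
  kept2 <- filter_rt_trials(toy_responses(rep(600, 10), correct = correct))
  expect_equal(kept2$trial_index, setdiff(1:10, c(3, 4)))
  rc <- attr(kept2, "removal_counts")
  expect_equal(unname(rc["error"]), 1)
  expect_equal(unname(rc["post_error"]), 1)

  # an error on the last trial of run 1 does not spill into run 2
  runs <- rep(c(1L, 2L), each = 5)
  correct3 <- rep(TRUE, 10); correct3[5] <- FALSE
  kept3 <- filter_rt_trials(toy_responses(rep(600, 10), correct = correct3,
                                          run_index = runs))
  expect_true(all(kept3$trial_index[kept3$run_index == 2] == 1:5))
  expect_equal(unname(attr(kept3, "removal_counts")["post_error"]), 0)
})

test_that("RT filtering is idempotent", {
  set.seed(5)
  seq <- generate_sequence(2, 20, c(3, 4), seed = 5)
  resp <- simulate_behavior(seq, n_subjects = 4, n_sessions = 2, seed = 5)
  once <- filter_rt_trials(resp)
  twice <- filter_rt_trials(once)
  expect_equal(nrow(twice), nrow(once))
  expect_equal(sum(attr(twice, "removal_counts")), 0)
})

test_that("accuracy counts every trial, including outliers and post-error", {
  r <- toy_responses(rep(600, 74),
                     correct = c(rep(TRUE, 70), rep(FALSE, 4)))
  expect_equal(compute_accuracy(r)$accuracy, 70 / 74)
  r2 <- toy_responses(rep(600, 5), omission = rep(TRUE, 5))
  expect_equal(compute_accuracy(r2)$accuracy, 0)
  # the RT-outlier trial still counts toward accuracy
  r3 <- toy_responses(c(rep(600, 9), 2000, 650),
                      correct = c(rep(TRUE, 10), FALSE))
  expect_equal(compute_accuracy(r3)$accuracy, 10 / 11)
})

test_that("signed-rank z matches the standard test when Pratt is vacuous", {
  set.seed(9)
  x <- rnorm(25, 1); y <- rnorm(25)
  # no zeros, no ties: Pratt handling coincides with the plain test
  ours <- wilcoxon_z(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  expect_equal(ours$method, "wilcoxon_pratt")

  tie <- wilcoxon_z(rep(1, 10), rep(1, 10))
  expect_equal(tie$z, 0)
  expect_equal(tie$p, 1)
})

test_that("the sign test takes over when many paired differences are zero", {
  x <- c(rep(0, 6), 1, 2, 3, 4)
  res <- wilcoxon_z(x + 5, rep(5, 10))
  expect_equal(res$method, "sign")
  expect_equal(res$p, binom.test(4, 4)$p.value)
})

test_that("Stroop statistics recover the simulated 60 ms conflict cost", {
  seqs <- generate_sequence(2, 74, c(3, 5), seed = 21)
  resp <- simulate_behavior(seqs, n_subjects = 36, seed = 21)
  bsum <- behavioral_summary(resp)
  st <- stroop_stats(bsum)
  rt_rows <- subset(st$pairwise, measure == "rt" &
                      comparison == "incongruent vs congruent")
  expect_equal(nrow(rt_rows), 3)
  expect_true(all(abs(rt_rows$effect - 60) < 20))
  expect_true(all(rt_rows$p < st$alpha_adjusted))
  expect_equal(st$alpha_adjusted, 0.0125)
  # paired tests are invariant to a constant added to all RTs
  bsum2 <- bsum
  bsum2$median_rt_ms <- bsum2$median_rt_ms + 500
  st2 <- stroop_stats(bsum2)
  # invariance holds up to floating-point re-ranking of near-tied differences
  expect_equal(st2$pairwise$z, st$pairwise$z, tolerance = 0.02)
  expect_error(stroop_stats(bsum[bsum$subject == 1, ]), "2 complete pairs")
})

test_that("conflict-cost detection power is high at the simulated effect size", {
  hits <- 0L
  n_rep <- 25L
  seqs <- generate_sequence(2, 74, c(3, 5), seed = 100)
  for (b in seq_len(n_rep)) {
    resp <- simulate_behavior(seqs, n_subjects = 36, seed = 200 + b)
    bsum <- behavioral_summary(resp)
    st <- stroop_stats(bsum)
    p <- subset(st$pairwise, measure == "rt" & session == 1 &
                  comparison == "incongruent vs congruent")$p
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})

test_that("behavioral ICC table mirrors conditions and contrasts", {
  seqs <- generate_sequence(2, 74, c(3, 5), seed = 31)
  resp <- simulate_behavior(seqs, n_subjects = 36, seed = 31)
  bsum <- behavioral_summary(resp)
  tab <- behavioral_icc(bsum)
  expect_equal(nrow(tab), 14)
  expect_true(all(c("icc", "ci_low", "ci_high", "class") %in% names(tab)))
  expect_true(all(tab$ci_low <= tab$icc & tab$icc <= tab$ci_high))
  # a difference of two correlated conditions is less reliable than either
  cond <- tab[tab$kind == "rt" & tab$measure %in% c("congruent", "incongruent"), ]
  ctr <- tab[tab$kind == "rt" & tab$measure == "incongruent - congruent", ]
  expect_lt(ctr$icc, min(cond$icc))
})
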