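# explicit-loop two-way ANOVA mean squares, kept deliberately naive so it is
# an independent oracle for the vectorized implementation
oracle_mean_squares <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  gm <- sum(Y) / (n * k)
  BSS <- 0
  for (i in 1:n) BSS <- BSS + k * (mean(Y[i, ]) - gm)^2
  JSS <- 0
  for (t in 1:k) JSS <- JSS + n * (mean(Y[, t]) - gm)^2
  ESS <- 0
  for (i in 1:n) for (t in 1:k)
    ESS <- ESS + (Y[i, t] - mean(Y[i, ]) - mean(Y[, t]) + gm)^2
  list(BMS = BSS / (n - 1), JMS = JSS / (k - 1),
       EMS = ESS / ((n - 1) * (k - 1)))
}

oracle_icc31 <- function(Y) {
  ms <- oracle_mean_squares(Y)
  k <- ncol(Y)
  (ms$BMS - ms$EMS) / (ms$BMS + (k - 1) * ms$EMS)
}

# draw a random complete subjects x sessions matrix
random_matrix <- function(n, k, sd_b = 1, sd_w = 1) {
  s <- rnorm(n, 0, sd_b)
  matrix(s, n, k) + matrix(rnorm(n * k, 0, sd_w), n, k)
}

# tiny toy response table builder for behavioral filter tests
toy_responses <- function(rt, correct = rep(TRUE, length(rt)),
                          congruent = rep(TRUE, length(rt)),
                          run_index = rep(1L, length(rt)),
                          omission = rep(FALSE, length(rt))) {
  data.frame(subject = 1L, session = 1L, run_index = run_index,
             trial_index = stats::ave(run_index, run_index, FUN = seq_along),
             congruent = congruent,
             face_emotion = rep("happy", length(rt)),
             adaptation_label = "cC",
             response = ifelse(omission, "none",
                               ifelse(correct, "happy", "fear")),
             rt_ms = ifelse(omission, NA_real_, rt),
             correct = correct & !omission,
             commission_error = !correct & !omission,
             omission_error = omission,
             stringsAsFactors = FALSE)
}

# small cohort truth on a light grid for fast end-to-end tests
small_truth <- function(seed = 1, sigma2_b = c(0.8, 0.1),
                        sigma2_w = c(0.2, 0.9), n_subjects = 36,
                        grid_dim = c(10, 10, 6),
                        site_sizes = n_subjects, amplitude = c(2, 1.5),
                        session_effects = c(0, 0.05, -0.05)) {
  cohort_truth(
    n_subjects = n_subjects, grid_dim = grid_dim,
    regions = data.frame(id = 1:2, name = c("visual", "frontal"),
                         amplitude = amplitude,
                         sigma2_b = sigma2_b, sigma2_w = sigma2_w,
                         stringsAsFactors = FALSE),
    session_effects = session_effects,
    site_sizes = site_sizes, site_offsets = rep(0, length(site_sizes)),
    seed = seed)
}
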