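#' Define ground truth for a synthetic multi-site test-retest cohort
#'
#' Describes the population a synthetic cohort is drawn from: a 3-D integer
#' region map on a voxel grid, per-region activation amplitude and variance
#' components, additive session (time-point) effects, and per-site offsets.
#' The true ICC of region r is \code{sigma2_b / (sigma2_b + sigma2_w)}.
#'
#' Defaults mirror the study conditions the generator emulates: 36 subjects
#' scanned at 3 sessions (weeks 0, 2, 8) across 4 sites with sizes 12/4/6/14,
#' on a 24 x 24 x 16 grid of 4 mm voxels, with a posterior "visual-like"
#' region of high reliability and an anterior "frontal-like" region of low
#' reliability. Site offsets are subject-constant, so they inflate
#' between-subject variance (and hence ICC); set them to zero for pure
#' variance-component recovery tests.
#'
#' @param n_subjects number of subjects (default 36).
#' @param n_sessions sessions per subject (default 3).
#' @param grid_dim integer length-3 voxel grid (default \code{c(24, 24, 16)}).
#' @param regions data.frame with columns \code{id}, \code{name},
#'   \code{amplitude}, \code{sigma2_b}, \code{sigma2_w}; default two regions
#'   with true ICC 0.8 (visual-like) and 0.1 (frontal-like).
#' @param session_effects numeric length \code{n_sessions}, additive constants
#'   shared by all subjects (default \code{c(0, 0.05, -0.05)}).
#' @param site_sizes integer vector of subjects per site summing to
#'   \code{n_subjects}; defaults to the emulated study's 12/4/6/14 split for
#'   a 36-subject cohort and to a single site otherwise.
#' @param site_offsets additive constant per site (default 0 for all).
#' @param region_map optional integer array of shape \code{grid_dim} giving
#'   the region label (0 = background) of every voxel; by default one
#'   rectangular parcel is carved per region along the posterior-anterior
#'   axis.
#' @param seed integer seed stored with the truth.
#' @return list of class \code{cohort_truth} with the fields above plus
#'   \code{region_map} (integer array, 0 = background), \code{site} (site
#'   index per subject) and \code{true_icc} per region.
#' @export
cohort_truth <- function(n_subjects = 36, n_sessions = 3,
                         grid_dim = c(24, 24, 16),
                         regions = NULL,
                         session_effects = c(0, 0.05, -0.05),
                         site_sizes = NULL,
                         site_offsets = rep(0, length(site_sizes)),
                         region_map = NULL, seed = 1) {
  if (is.null(site_sizes))
    site_sizes <- if (n_subjects == 36) c(12, 4, 6, 14) else n_subjects
  if (!length(site_offsets)) site_offsets <- rep(0, length(site_sizes))
  if (is.null(regions)) {
    regions <- data.frame(
      id = c(1L, 2L),
      name = c("visual", "frontal"),
      amplitude = c(2.0, 1.5),
      sigma2_b = c(0.8, 0.1),
      sigma2_w = c(0.2, 0.9),
      stringsAsFactors = FALSE)
  }
  if (any(regions$sigma2_b < 0) || any(regions$sigma2_w < 0))
    stop("variance components must be non-negative")
  if (sum(site_sizes) != n_subjects)
    stop("site_sizes must sum to n_subjects")
  if (length(session_effects) != n_sessions)
    stop("session_effects must have length n_sessions")
  if (is.null(region_map)) {
    region_map <- .default_region_map(grid_dim, regions$id)
  } else {
    region_map <- array(as.integer(region_map), grid_dim)
    if (!all(setdiff(unique(as.integer(region_map)), 0L) %in% regions$id))
      stop("region_map contains labels absent from the regions table")
  }
  tot <- regions$sigma2_b + regions$sigma2_w
  structure(list(
    n_subjects = n_subjects, n_sessions = n_sessions, grid_dim = grid_dim,
    regions = regions, region_map = region_map,
    session_effects = session_effects,
    site = rep(seq_along(site_sizes), times = site_sizes),
    site_offsets = site_offsets,
    true_icc = ifelse(tot > 0, regions$sigma2_b / tot, NaN),
    seed = seed), class = "cohort_truth")
}

# carve one axial box per region along y (posterior -> anterior), with a
# one-voxel gap between regions when the grid allows it
.default_region_map <- function(grid_dim, ids) {
  map <- array(0L, grid_dim)
  nr <- length(ids)
  band <- function(frac_lo, frac_hi, n) {
    lo <- max(1L, min(n, round(n * frac_lo)))
    hi <- max(lo, min(n, round(n * frac_hi)))
    lo:hi
  }
  xr <- band(0.35, 0.65, grid_dim[1])
  zr <- band(0.40, 0.60, grid_dim[3])
  edges <- floor(seq(0, grid_dim[2], length.out = nr + 1))
  for (j in seq_len(nr)) {
    lo <- min(edges[j] + 1L, grid_dim[2])
    hi <- max(lo, edges[j + 1] - (j < nr))
    map[xr, lo:hi, zr] <- ids[j]
  }
  map
}

#' Simulate a subjects x sessions x voxels contrast stack with known ICC
#'
#' Draws per-region contrast values under the two-way variance-component
#' model: for voxel v in region r, subject i at session t,
#' \deqn{y = a_r + site(i) + s_{i,r} + d_t + e_{i,t,v}}
#' with subject effect \eqn{s_{i,r} ~ N(0, \sigma^2_{b,r})} drawn once per
#' subject x region (shared by that region's voxels, as regional activation
#' is), and session noise \eqn{e ~ N(0, \sigma^2_{w,r})} independent per
#' subject, session and voxel. Deterministic given \code{truth$seed}.
#'
#' With \code{subject_effect = "voxel"} the subject effect is instead drawn
#' independently per voxel, making every voxel an independent replicate of
#' the variance-component model — the appropriate mode for estimator
#' validation (spatially coherent activation is the realistic default).
#'
#' @param truth a \code{cohort_truth}.
#' @param subject_effect \code{"region"} (default) or \code{"voxel"}.
#' @return list of class \code{contrast_stack}: \code{values}
#'   (subjects x sessions x voxels), \code{mask} (logical, in-region voxels),
#'   \code{grid_dim}, \code{region_label} (integer per voxel), \code{truth}.
#' @export
simulate_contrast_cohort <- function(truth,
                                     subject_effect = c("region", "voxel")) {
  subject_effect <- match.arg(subject_effect)
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(truth$seed)
  n <- truth$n_subjects; k <- truth$n_sessions
  lab <- as.integer(truth$region_map)
  V <- length(lab)
  vals <- array(0, c(n, k, V))
  site_term <- truth$site_offsets[truth$site]
  for (j in seq_len(nrow(truth$regions))) {
    r <- truth$regions[j, ]
    vox <- which(lab == r$id)
    if (!length(vox)) next
    nv <- length(vox)
    if (subject_effect == "region") {
      s <- array(stats::rnorm(n, 0, sqrt(r$sigma2_b)), c(n, k, nv))
    } else {
      s_iv <- matrix(stats::rnorm(n * nv, 0, sqrt(r$sigma2_b)), n, nv)
      s <- array(s_iv[, rep(seq_len(nv), each = k)], c(n, k, nv))
    }
    eps <- array(stats::rnorm(n * k * nv, 0, sqrt(r$sigma2_w)), c(n, k, nv))
    d <- truth$session_effects
    vals[, , vox] <- r$amplitude + site_term + s + eps +
      rep(rep(d, each = n), times = nv)
  }
  structure(list(values = vals, mask = lab > 0, grid_dim = truth$grid_dim,
                 region_label = lab, truth = truth),
            class = "contrast_stack")
}

#' Simulate one event-related BOLD run with known condition amplitudes
#'
#' Builds a 4-D BOLD series on the truth's voxel grid: each condition's onset
#' train (unit-duration boxcars) is convolved with the canonical double-gamma
#' HRF and scaled by that condition's amplitude in each region, then linear
#' and quadratic drift and white Gaussian noise are added. A 6-parameter
#' motion table is generated as smooth random walks, with displacement spikes
#' injected at \code{spike_volumes}.
#'
#' @param seq a \code{task_sequence}; only trials of \code{run} are used.
#' @param truth a \code{cohort_truth} providing the region map.
#' @param amplitudes matrix regions x conditions of response amplitudes
#'   (rownames = region ids as character, colnames = condition names matched
#'   against \code{conditions}).
#' @param conditions named list mapping condition name to a logical index
#'   function over trials, e.g. \code{list(congruent = function(s) s$congruent)}.
#'   Default: congruent/incongruent.
#' @param run which run of \code{seq} to simulate (default 1).
#' @param tr repetition time, seconds (default 2).
#' @param n_volumes volumes in the run (default 202).
#' @param noise_sd white noise SD (default 1).
#' @param drift_lin,drift_quad drift coefficients over the run, in signal
#'   units full-scale (default 0).
#' @param spike_volumes integer volume indices given injected motion spikes.
#' @param seed integer seed.
#' @return list: \code{bold} (4-D array x,y,z,t), \code{motion} (data.frame,
#'   n_volumes x 6: trans_x/y/z mm, rot_x/y/z deg), \code{tr},
#'   \code{conditions} (onset lists used).
#' @export
simulate_bold_run <- function(seq, truth, amplitudes,
                              conditions = list(
                                congruent = function(s) s$congruent,
                                incongruent = function(s) !s$congruent),
                              run = 1, tr = 2, n_volumes = 202,
                              noise_sd = 1, drift_lin = 0, drift_quad = 0,
                              spike_volumes = integer(0), seed = 1) {
  s <- seq[seq$run_index == run, , drop = FALSE]
  run_dur <- n_volumes * tr
  if (nrow(s) && max(s$onset + s$duration) > run_dur)
    stop("sequence extends past the end of the run")
  set.seed(seed)
  V <- prod(truth$grid_dim)
  lab <- as.integer(truth$region_map)
  cond_names <- names(conditions)
  # condition regressors sampled at TR
  reg <- sapply(cond_names, function(cn) {
    idx <- conditions[[cn]](s)
    hrf_regressor(s$onset[idx], s$duration[idx], n_volumes, tr)
  })
  reg <- matrix(reg, n_volumes, length(cond_names))
  # signal per voxel: regions pick up amplitude x regressor
  Y <- matrix(0, n_volumes, V)
  for (j in seq_len(nrow(truth$regions))) {
    rid <- truth$regions$id[j]
    vox <- which(lab == rid)
    if (!length(vox)) next
    amp <- amplitudes[as.character(rid), cond_names]
    sig <- as.numeric(reg %*% as.numeric(amp))
    Y[, vox] <- sig
  }
  tt <- seq_len(n_volumes) / n_volumes
  drift <- drift_lin * (tt - mean(tt)) + drift_quad * ((tt - mean(tt))^2 - mean((tt - mean(tt))^2))
  Y <- Y + drift
  if (noise_sd > 0) Y <- Y + matrix(stats::rnorm(n_volumes * V, 0, noise_sd), n_volumes, V)
  bold <- array(t(Y), c(truth$grid_dim, n_volumes))
  # motion: smooth random walks; spikes add an abrupt displacement
  mp <- apply(matrix(stats::rnorm(n_volumes * 6, 0, 0.02), n_volumes, 6), 2, cumsum)
  mp <- stats::filter(mp, rep(1 / 5, 5), sides = 2)
  mp[is.na(mp)] <- 0
  mp <- matrix(mp, n_volumes, 6)
  if (length(spike_volumes)) mp[spike_volumes, 1:3] <- mp[spike_volumes, 1:3] + 2
  motion <- as.data.frame(mp)
  names(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  list(bold = bold, motion = motion, tr = tr, conditions = cond_names)
}

#' Simulate behavioral trial responses for a test-retest cohort
#'
#' Generates per-trial responses for every subject x session on a shared trial
#' sequence (all subjects perform the runs in the same order at every
#' session, as the emulated protocol does). Reaction time follows a
#' log-normal subject model with additive condition costs:
#' \deqn{RT = exp(N(\mu_i + u_{i,t} + d_t, \sigma_{rt})) +
#'   \delta_{stroop}[incongruent] + \delta_{fear}[fear\,face]}
#' where \eqn{\mu_i ~ N(log(base\_rt), subject\_sd)} is the stable subject
#' level, \eqn{u_{i,t} ~ N(0, session\_state\_sd)} is day-to-day state, and
#' \eqn{d_t} are fixed session effects. Commission errors are Bernoulli with
#' a higher rate on incongruent trials; omissions are Bernoulli and carry no
#' RT.
#'
#' @param seq a \code{task_sequence} shared by all subjects/sessions.
#' @param n_subjects default 36.
#' @param n_sessions default 3.
#' @param base_rt_ms median RT on congruent-happy trials, ms (default 660).
#' @param delta_stroop_ms mean incongruency cost, ms (default 60).
#' @param delta_fear_ms mean fear-face slowing, ms (default 30).
#' @param delta_stroop_subject_sd,delta_fear_subject_sd between-subject SD of
#'   the stable per-subject condition costs, ms (defaults 15 and 20): real
#'   cohorts show moderately reliable individual differences in these costs.
#' @param sigma_rt trial-level log-RT SD (default 0.18).
#' @param subject_sd between-subject SD of log base RT (default 0.12).
#' @param session_state_sd within-subject between-session SD of log base RT
#'   (default 0.08).
#' @param session_effects fixed additive log-RT session shifts (default 0s).
#' @param commission_rate length-2: c(congruent, incongruent) wrong-button
#'   probability for an average subject (default \code{c(0.02, 0.05)}).
#' @param error_subject_sd between-subject SD of the commission log-odds
#'   (default 0.5), giving stable individual differences in accuracy.
#' @param omission_rate no-response probability (default 0.005).
#' @param seed integer seed.
#' @return data.frame with one row per subject x session x trial: columns
#'   \code{subject}, \code{session}, \code{run_index}, \code{trial_index},
#'   \code{congruent}, \code{face_emotion}, \code{adaptation_label},
#'   \code{response}, \code{rt_ms}, \code{correct}, \code{commission_error},
#'   \code{omission_error}.
#' @export
simulate_behavior <- function(seq, n_subjects = 36, n_sessions = 3,
                              base_rt_ms = 660, delta_stroop_ms = 60,
                              delta_fear_ms = 30,
                              delta_stroop_subject_sd = 15,
                              delta_fear_subject_sd = 20,
                              sigma_rt = 0.18,
                              subject_sd = 0.12, session_state_sd = 0.08,
                              session_effects = rep(0, n_sessions),
                              commission_rate = c(0.02, 0.05),
                              error_subject_sd = 0.5,
                              omission_rate = 0.005, seed = 1) {
  set.seed(seed)
  nt <- nrow(seq)
  mu_i <- stats::rnorm(n_subjects, log(base_rt_ms), subject_sd)
  stroop_i <- stats::rnorm(n_subjects, delta_stroop_ms, delta_stroop_subject_sd)
  fear_i <- stats::rnorm(n_subjects, delta_fear_ms, delta_fear_subject_sd)
  err_i <- stats::rnorm(n_subjects, 0, error_subject_sd)
  out <- vector("list", n_subjects * n_sessions)
  idx <- 1L
  for (i in seq_len(n_subjects)) for (t in seq_len(n_sessions)) {
    u <- stats::rnorm(1, 0, session_state_sd)
    base <- exp(stats::rnorm(nt, mu_i[i] + u + session_effects[t], sigma_rt))
    rt <- base + stroop_i[i] * (!seq$congruent) +
      fear_i[i] * (seq$face_emotion == "fear")
    p_com <- stats::plogis(stats::qlogis(
      ifelse(seq$congruent, commission_rate[1], commission_rate[2])) + err_i[i])
    omit <- stats::runif(nt) < omission_rate
    commit <- !omit & stats::runif(nt) < p_com
    response <- ifelse(omit, "none",
                ifelse(commit,
                       ifelse(seq$face_emotion == "happy", "fear", "happy"),
                       seq$face_emotion))
    out[[idx]] <- data.frame(
      subject = i, session = t,
      run_index = seq$run_index, trial_index = seq$trial_index,
      congruent = seq$congruent, face_emotion = seq$face_emotion,
      adaptation_label = seq$adaptation_label,
      response = response,
      rt_ms = ifelse(omit, NA_real_, round(rt, 1)),
      correct = !omit & !commit,
      commission_error = commit, omission_error = omit,
      stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  do.call(rbind, out)
}
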