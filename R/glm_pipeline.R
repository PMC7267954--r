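#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF: a positive gamma peaking about 5-6 s after
#' stimulus onset minus a later undershoot gamma (peak 6, undershoot 16,
#' ratio 1/6), normalized to unit peak.
#'
#' @param t time since onset, seconds (vectorized).
#' @return HRF values.
#' @export
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(stats::dgamma(0:300 / 10, shape = 6, rate = 1) -
            stats::dgamma(0:300 / 10, shape = 16, rate = 1) / 6)
}

#' Build one HRF-convolved condition regressor sampled at the TR
#'
#' Places unit-height boxcars at the given onsets/durations on a fine time
#' grid, convolves with the double-gamma HRF, and samples at volume
#' acquisition times \code{(0:(n_volumes-1)) * tr}.
#'
#' @param onsets,durations event times and durations, seconds.
#' @param n_volumes number of volumes.
#' @param tr repetition time, seconds.
#' @param dt fine-grid step for the convolution (default 0.1 s).
#' @return numeric length \code{n_volumes}.
#' @export
hrf_regressor <- function(onsets, durations, n_volumes, tr, dt = 0.1) {
  run_dur <- n_volumes * tr
  ngrid <- ceiling(run_dur / dt) + 1L
  x <- numeric(ngrid)
  if (length(onsets)) {
    durations <- rep_len(durations, length(onsets))
    for (j in seq_along(onsets)) {
      i0 <- floor(onsets[j] / dt) + 1L
      i1 <- min(ngrid, ceiling((onsets[j] + durations[j]) / dt))
      x[i0:i1] <- x[i0:i1] + 1
    }
  }
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  conv <- stats::convolve(x, rev(h), type = "open")[seq_len(ngrid)] * dt
  conv[round((0:(n_volumes - 1)) * tr / dt) + 1L]
}

# Legendre polynomials of order 0..order on [-1, 1], sampled at n points
.legendre_trends <- function(n, order = 2) {
  x <- seq(-1, 1, length.out = n)
  cols <- list(rep(1, n))
  if (order >= 1) cols <- c(cols, list(x))
  if (order >= 2) cols <- c(cols, list((3 * x^2 - 1) / 2))
  if (order >= 3) cols <- c(cols, list((5 * x^3 - 3 * x) / 2))
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("trend_", 0:order)
  m
}

# discrete-cosine high-pass basis for a cutoff period (seconds)
.dct_highpass <- function(n_volumes, tr, period) {
  if (is.null(period) || !is.finite(period) || period <= 0) return(NULL)
  K <- floor(2 * n_volumes * tr / period)
  if (K < 1) return(NULL)
  t <- 0:(n_volumes - 1)
  m <- sapply(seq_len(K), function(j) cos(pi * j * t / (n_volumes - 1)))
  m <- matrix(m, n_volumes, K)
  colnames(m) <- paste0("dct_", seq_len(K))
  m
}

#' Default trial-type condition definitions for the conflict task
#'
#' Returns the standard regressor set: all face trials, congruent,
#' incongruent, happy/fear faces, happy/fear words, and the
#' conflict-adaptation cells iI and cI.
#'
#' @return named list of predicate functions over a \code{task_sequence}.
#' @export
task_conditions <- function() {
  list(
    all_faces   = function(s) rep(TRUE, nrow(s)),
    congruent   = function(s) s$congruent,
    incongruent = function(s) !s$congruent,
    happy_face  = function(s) s$face_emotion == "happy",
    fear_face   = function(s) s$face_emotion == "fear",
    happy_word  = function(s) s$word == "HAPPY",
    fear_word   = function(s) s$word == "FEAR",
    iI          = function(s) s$adaptation_label == "iI",
    cI          = function(s) s$adaptation_label == "cI")
}

#' Build a first-level design matrix
#'
#' Condition columns are HRF-convolved onset trains for each requested trial
#' type; nuisance columns are a second-order Legendre polynomial trend basis,
#' optional motion regressors, and a discrete-cosine high-pass basis with a
#' 100 s cutoff period (the conventional reading of a "100" high-pass
#' setting; a frequency of 100 Hz is physically impossible at a 2 s TR, so
#' the cutoff is interpreted as a period).
#'
#' @param seq a \code{task_sequence} (one run's trials; pass
#'   \code{seq[seq$run_index == r, ]} for run r).
#' @param n_volumes,tr run geometry.
#' @param motion optional matrix/data.frame of motion regressors (rows =
#'   volumes), e.g. from \code{\link{motion_regressors}}.
#' @param conditions named list of predicates as in
#'   \code{\link{task_conditions}} (the default); conditions with no matching
#'   trials are omitted with a warning.
#' @param hp_period high-pass cutoff period in seconds (default 100; NULL
#'   disables).
#' @param trend_order Legendre trend order (default 2).
#' @return list of class \code{design_matrix}: \code{X} (matrix with named
#'   columns), \code{condition_cols} (names of task columns), \code{tr}.
#' @export
build_design <- function(seq, n_volumes, tr, motion = NULL,
                         conditions = task_conditions(),
                         hp_period = 100, trend_order = 2) {
  if (nrow(seq) && max(seq$onset + seq$duration) > n_volumes * tr)
    stop("events extend past the end of the run")
  cond_cols <- list()
  for (cn in names(conditions)) {
    idx <- conditions[[cn]](seq)
    if (!any(idx)) {
      warning(sprintf("condition '%s' has no trials; column omitted", cn))
      next
    }
    cond_cols[[cn]] <- hrf_regressor(seq$onset[idx], seq$duration[idx],
                                     n_volumes, tr)
  }
  Xc <- if (length(cond_cols)) do.call(cbind, cond_cols) else
    matrix(numeric(0), n_volumes, 0)
  nuis <- .legendre_trends(n_volumes, trend_order)
  hp <- .dct_highpass(n_volumes, tr, hp_period)
  if (!is.null(hp)) nuis <- cbind(nuis, hp)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_volumes)
    colnames(motion) <- paste0("motion_", seq_len(ncol(motion)))
    nuis <- cbind(nuis, motion)
  }
  X <- cbind(Xc, nuis)
  if (qr(X)$rank < ncol(X))
    warning("design matrix is rank deficient (collinear columns)")
  structure(list(X = X, condition_cols = names(cond_cols), tr = tr),
            class = "design_matrix")
}

#' Fit a first-level GLM by ordinary least squares
#'
#' Voxel-wise OLS of the BOLD series on the design. Rank-deficient designs
#' are handled by dropping aliased columns (reported in
#' \code{dropped_columns}); their betas are NA. With \code{ar1 = TRUE} a
#' Cochrane-Orcutt step is applied: the lag-1 autocorrelation of the pooled
#' OLS residuals is estimated, data and design are quasi-differenced, and
#' the model is refit — a light-weight alternative to full prewhitening for
#' colored noise (synthetic noise is white by default, where plain OLS is
#' already maximum likelihood).
#'
#' @param bold 4-D array (x, y, z, t) or a time x voxels matrix.
#' @param design a \code{design_matrix} (or bare matrix).
#' @param mask optional logical vector/array over voxels.
#' @param ar1 apply a Cochrane-Orcutt AR(1) correction (default FALSE).
#' @return list of class \code{glm_fit}: \code{betas} (columns x voxels, NA
#'   outside mask), \code{sigma2} (residual variance per voxel), \code{dof},
#'   \code{column_names}, \code{dropped_columns}, \code{grid_dim},
#'   \code{mask}, \code{design}, and \code{rho} (estimated lag-1
#'   autocorrelation; 0 when \code{ar1 = FALSE}).
#' @export
fit_glm <- function(bold, design, mask = NULL, ar1 = FALSE) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (length(dim(bold)) == 4) {
    grid_dim <- dim(bold)[1:3]
    Y <- t(matrix(bold, prod(grid_dim), dim(bold)[4]))
  } else {
    grid_dim <- NULL
    Y <- as.matrix(bold)
  }
  stopifnot(nrow(Y) == nrow(X))
  V <- ncol(Y)
  if (is.null(mask)) mask <- rep(TRUE, V)
  mask <- as.logical(mask)
  qrX <- qr(X)
  r <- qrX$rank
  keep <- qrX$pivot[seq_len(r)]
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  if (length(dropped))
    warning(sprintf("dropping aliased design columns: %s",
                    paste(dropped, collapse = ", ")))
  Xk <- X[, sort(keep), drop = FALSE]
  Ym <- Y[, mask, drop = FALSE]
  fitq <- qr(Xk)
  bk <- qr.coef(fitq, Ym)
  res <- Ym - Xk %*% bk
  rho <- 0
  if (ar1) {
    nT <- nrow(res)
    rho <- sum(res[-1, ] * res[-nT, ]) / sum(res^2)
    Ym <- Ym[-1, , drop = FALSE] - rho * Ym[-nT, , drop = FALSE]
    Xk <- Xk[-1, , drop = FALSE] - rho * Xk[-nT, , drop = FALSE]
    fitq <- qr(Xk)
    bk <- qr.coef(fitq, Ym)
    res <- Ym - Xk %*% bk
  }
  B <- matrix(NA_real_, ncol(X), V,
              dimnames = list(colnames(X), NULL))
  dof <- nrow(Ym) - ncol(Xk)
  s2 <- colSums(res^2) / max(dof, 1)
  B[colnames(Xk), mask] <- bk
  sigma2 <- rep(NA_real_, V); sigma2[mask] <- s2
  structure(list(betas = B, sigma2 = sigma2, dof = dof,
                 column_names = colnames(X), dropped_columns = dropped,
                 grid_dim = grid_dim, mask = mask, design = X, rho = rho),
            class = "glm_fit")
}

#' Compute a named or weighted contrast of GLM betas
#'
#' Supported named contrasts: every single condition (e.g. "all_faces",
#' "congruent"), plus "incongruent-congruent", "fear_face-happy_face",
#' "fear_word-happy_word" and "iI-cI". Alternatively pass a named numeric
#' weight vector over design columns.
#'
#' @param fit a \code{glm_fit}.
#' @param contrast character name or named numeric weights.
#' @return numeric vector of contrast values per voxel (NA outside mask),
#'   with attribute \code{grid_dim} when known.
#' @export
compute_contrast <- function(fit, contrast) {
  if (is.character(contrast)) {
    parts <- strsplit(contrast, "-", fixed = TRUE)[[1]]
    w <- stats::setNames(numeric(length(parts)), parts)
    w[parts[1]] <- 1
    if (length(parts) == 2) w[parts[2]] <- -1
    if (length(parts) > 2) stop("unrecognized contrast name: ", contrast)
    contrast <- w
  }
  missing_cols <- setdiff(names(contrast), rownames(fit$betas))
  if (length(missing_cols))
    stop("contrast names not in design: ", paste(missing_cols, collapse = ", "))
  val <- as.numeric(t(fit$betas[names(contrast), , drop = FALSE]) %*%
                      as.numeric(contrast))
  attr(val, "grid_dim") <- fit$grid_dim
  val
}

#' Second-level one-sample t map across subjects
#'
#' Random-effects group analysis: one-sample t test of subject contrast
#' values against zero at each voxel, dof = n - 1. Voxels with zero
#' between-subject variance but nonzero mean are capped at +/- \code{t_cap}
#' and flagged.
#'
#' @param maps subjects x voxels matrix of contrast values (rows =
#'   subjects), or a list of per-subject vectors.
#' @param mask optional logical vector over voxels.
#' @param grid_dim optional spatial dimensions.
#' @param t_cap cap for degenerate-variance t values (default 1e6).
#' @return list of class \code{stat_map}: \code{t}, \code{p} (two-sided),
#'   \code{mean}, \code{dof}, \code{n}, \code{mask}, \code{grid_dim},
#'   \code{capped} (logical per voxel).
#' @export
second_level <- function(maps, mask = NULL, grid_dim = NULL, t_cap = 1e6) {
  if (is.list(maps) && !is.matrix(maps)) maps <- do.call(rbind, maps)
  n <- nrow(maps); V <- ncol(maps)
  if (n < 2) stop("second-level analysis needs at least 2 subjects")
  if (is.null(mask)) mask <- !apply(is.na(maps), 2, any)
  m <- colMeans(maps)
  s <- apply(maps, 2, stats::sd)
  se <- s / sqrt(n)
  tval <- m / se
  capped <- is.finite(m) & m != 0 & s == 0
  tval[capped] <- sign(m[capped]) * t_cap
  tval[is.finite(m) & m == 0 & s == 0] <- 0
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  tval[!mask] <- NA; p[!mask] <- NA
  structure(list(t = tval, p = p, mean = m, dof = n - 1, n = n,
                 mask = mask, grid_dim = grid_dim, capped = capped),
            class = "stat_map")
}

#' Voxel-level threshold controlling family-wise error
#'
#' Bonferroni across in-mask voxels (the conservative, assumption-light
#' stand-in for random-field FWE), or a sign-flip permutation max-t threshold
#' when subject maps and a permutation budget are supplied.
#'
#' @param stat a \code{stat_map}.
#' @param alpha family-wise alpha (default 0.05).
#' @param method "bonferroni" (default) or "permutation".
#' @param maps subjects x voxels matrix (required for permutation).
#' @param n_perm number of sign-flip permutations (default 1000).
#' @param seed seed for the permutation draw.
#' @return critical |t| value.
#' @export
fwe_threshold <- function(stat, alpha = 0.05, method = c("bonferroni", "permutation"),
                          maps = NULL, n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  Vm <- sum(stat$mask)
  if (method == "bonferroni")
    return(stats::qt(1 - alpha / 2 / Vm, df = stat$dof))
  if (is.null(maps)) stop("permutation thresholding needs the subject maps")
  set.seed(seed)
  n <- nrow(maps)
  mx <- numeric(n_perm)
  M <- maps[, stat$mask, drop = FALSE]
  for (b in seq_len(n_perm)) {
    fl <- sample(c(-1, 1), n, replace = TRUE)
    Mb <- M * fl
    m <- colMeans(Mb); s <- apply(Mb, 2, stats::sd)
    mx[b] <- max(abs(m / (s / sqrt(n))), na.rm = TRUE)
  }
  stats::quantile(mx, 1 - alpha, names = FALSE)
}

#' Extract supra-threshold clusters from a statistic map
#'
#' Connected components (6-face connectivity by default; 18 or 26
#' configurable) of voxels with |t| (or t, if \code{two_sided = FALSE})
#' exceeding the threshold; components smaller than \code{min_size} are
#' dropped but their voxel count is reported.
#'
#' @param stat a \code{stat_map} with \code{grid_dim} set, or a 3-D array of
#'   statistic values.
#' @param threshold voxel-level critical value (e.g. from
#'   \code{\link{fwe_threshold}}).
#' @param min_size minimum cluster extent in voxels (default 10).
#' @param connectivity 6, 18 or 26 (default 6).
#' @param two_sided threshold on |t| (default TRUE).
#' @return list of class \code{cluster_set}: \code{clusters} (each with
#'   \code{voxels} (linear indices), \code{size}, \code{peak} (xyz),
#'   \code{peak_stat}), \code{n_suprathreshold},
#'   \code{n_dropped_voxels}, \code{threshold}. When no voxel survives, the
#'   set is empty and a message suggests the uncorrected p < .001 fallback.
#' @export
extract_clusters <- function(stat, threshold, min_size = 10,
                             connectivity = 6, two_sided = TRUE) {
  if (inherits(stat, "stat_map")) {
    if (is.null(stat$grid_dim)) stop("stat_map has no grid_dim")
    vol <- array(stat$t, stat$grid_dim)
  } else vol <- stat
  dm <- dim(vol)
  vals <- if (two_sided) abs(vol) else vol
  supra <- which(!is.na(vals) & vals > threshold)
  if (!length(supra)) {
    message("no supra-threshold voxels; consider the uncorrected p < .001 fallback")
    return(structure(list(clusters = list(), n_suprathreshold = 0L,
                          n_dropped_voxels = 0L, threshold = threshold),
                     class = "cluster_set"))
  }
  offsets <- .neighbor_offsets(connectivity)
  insupra <- array(FALSE, dm); insupra[supra] <- TRUE
  labels <- array(0L, dm)
  nextlab <- 0L
  comp <- list()
  coord <- arrayInd(supra, dm)
  for (s0 in supra) {
    if (labels[s0] != 0L) next
    nextlab <- nextlab + 1L
    queue <- s0; labels[s0] <- nextlab
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members <- c(members, v)
      ci <- arrayInd(v, dm)
      for (o in seq_len(nrow(offsets))) {
        nb <- ci + offsets[o, , drop = FALSE]
        if (any(nb < 1) || any(nb > dm)) next
        li <- nb[1] + (nb[2] - 1L) * dm[1] + (nb[3] - 1L) * dm[1] * dm[2]
        if (insupra[li] && labels[li] == 0L) {
          labels[li] <- nextlab
          queue <- c(queue, li)
        }
      }
    }
    comp[[nextlab]] <- members
  }
  sizes <- lengths(comp)
  keep <- which(sizes >= min_size)
  clusters <- lapply(keep, function(j) {
    vx <- comp[[j]]
    pk <- vx[which.max(abs(vol[vx]))]
    list(voxels = sort(vx), size = length(vx),
         peak = as.integer(arrayInd(pk, dm)),
         peak_stat = vol[pk])
  })
  ord <- order(vapply(clusters, `[[`, numeric(1), "size"), decreasing = TRUE)
  structure(list(clusters = clusters[ord],
                 n_suprathreshold = length(supra),
                 n_dropped_voxels = sum(sizes[sizes < min_size]),
                 threshold = threshold),
            class = "cluster_set")
}

.neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  d <- rowSums(abs(g))
  if (connectivity == 6) g[d == 1, , drop = FALSE]
  else if (connectivity == 18) g[d <= 2, , drop = FALSE]
  else if (connectivity == 26) g
  else stop("connectivity must be 6, 18 or 26")
}
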