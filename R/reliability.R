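#' Two-way ANOVA mean squares for a subjects-by-sessions matrix
#'
#' Decomposes a complete subjects x sessions measurement matrix into the mean
#' squares of the two-way model with subjects as random effects and sessions
#' as fixed effects: between-subject (BMS), between-session (JMS) and residual
#' (EMS) mean squares. These are the ingredients of the ICC(3,1) consistency
#' estimator.
#'
#' Rows with any missing value are dropped (complete-case), with the count of
#' dropped subjects recorded in the result.
#'
#' @param Y numeric matrix, subjects in rows, sessions in columns (k >= 2).
#' @return list of class \code{variance_components}: \code{n}, \code{k},
#'   \code{BMS}, \code{JMS}, \code{EMS}, \code{grand_mean},
#'   \code{n_dropped}, and the derived variance components
#'   \code{sigma2_b = (BMS - EMS)/k} (floored at 0) and \code{sigma2_w = EMS}.
#' @export
anova_components <- function(Y) {
  Y <- as.matrix(Y)
  keep <- stats::complete.cases(Y)
  n_dropped <- sum(!keep)
  Y <- Y[keep, , drop = FALSE]
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L) stop("need at least 2 subjects with complete sessions")
  if (k < 2L) stop("need at least 2 sessions")
  gm <- mean(Y)
  rm_ <- rowMeans(Y); cm_ <- colMeans(Y)
  BMS <- k * sum((rm_ - gm)^2) / (n - 1)
  JMS <- n * sum((cm_ - gm)^2) / (k - 1)
  resid <- Y - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + gm
  EMS <- sum(resid^2) / ((n - 1) * (k - 1))
  structure(list(n = n, k = k, BMS = BMS, JMS = JMS, EMS = EMS,
                 grand_mean = gm, n_dropped = n_dropped,
                 sigma2_b = max((BMS - EMS) / k, 0), sigma2_w = EMS),
            class = "variance_components")
}

#' ICC(3,1): two-way mixed, consistency, single measurement
#'
#' Estimates the intraclass correlation for a test-retest design in which
#' subjects are random and sessions fixed, so that systematic session-to-
#' session shifts do not count against reliability. The primary estimator is
#' the Shrout-Fleiss mean-square form
#' \deqn{ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) EMS).}
#' A secondary mode (\code{form = "variance_ratio"}) computes the two-variance
#' expression \eqn{(\sigma^2_b - \sigma^2_w)/(\sigma^2_b + \sigma^2_w)} from
#' the estimated components; the two coincide when the components are plugged
#' in unfloored, but the mean-square form is the conventional estimator and is
#' the default.
#'
#' Negative estimates (within-subject variance exceeding between-subject
#' variance) are reported raw; they indicate a reliability of zero and are
#' classified as "poor". Set \code{floor_negative = TRUE} to present them as 0
#' (\code{negative_floored} records whether flooring occurred).
#'
#' @param Y subjects x sessions matrix.
#' @param form \code{"mean_squares"} (default) or \code{"variance_ratio"}.
#' @param floor_negative present negative estimates as 0 (default FALSE).
#' @param conf.level confidence level for the F-based interval (default 0.95).
#' @param scheme classification scheme, see \code{\link{classify_icc}}.
#' @return list of class \code{icc_result}: \code{icc}, \code{ci_low},
#'   \code{ci_high}, \code{n}, \code{k}, \code{class_label},
#'   \code{negative_floored}, \code{components}.
#' @examples
#' Y <- cbind(1:6, 1:6 + rnorm(6, 0, 0.1), 1:6 + rnorm(6, 0, 0.1))
#' icc31(Y)
#' @export
icc31 <- function(Y, form = c("mean_squares", "variance_ratio"),
                  floor_negative = FALSE, conf.level = 0.95,
                  scheme = "three_band") {
  form <- match.arg(form)
  vc <- anova_components(Y)
  denom_ms <- vc$BMS + (vc$k - 1) * vc$EMS
  if (form == "mean_squares") {
    icc <- if (denom_ms <= 0) NaN else (vc$BMS - vc$EMS) / denom_ms
  } else {
    s2b <- (vc$BMS - vc$EMS) / vc$k   # unfloored plug-in
    s2w <- vc$EMS
    icc <- if (s2b + s2w <= 0) NaN else (s2b - s2w) / (s2b + s2w)
  }
  floored <- FALSE
  if (floor_negative && is.finite(icc) && icc < 0) { icc <- 0; floored <- TRUE }
  ci <- icc_ci(vc, alpha = 1 - conf.level)
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 n = vc$n, k = vc$k,
                 class_label = classify_icc(icc, scheme),
                 negative_floored = floored, degenerate = !is.finite(icc),
                 form = form, components = vc),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f [%.3f, %.3f]  (n = %d, k = %d, %s)\n",
              x$icc, x$ci_low, x$ci_high, x$n, x$k, x$class_label))
  invisible(x)
}

#' F-based confidence interval for ICC(3,1)
#'
#' Shrout-Fleiss interval: with F = BMS/EMS on (n-1) and (n-1)(k-1) degrees of
#' freedom, the bounds are (FL - 1)/(FL + k - 1) and (FU - 1)/(FU + k - 1)
#' where FL = F / qf(1 - alpha/2, n-1, (n-1)(k-1)) and
#' FU = F * qf(1 - alpha/2, (n-1)(k-1), n-1).
#'
#' @param components a \code{variance_components} object (or a matrix, which
#'   is passed through \code{\link{anova_components}}).
#' @param alpha two-sided error rate (default 0.05).
#' @return numeric length-2 vector \code{c(ci_low, ci_high)}. When EMS = 0
#'   with BMS > 0 the interval degenerates to (1, 1) and is returned guarded
#'   as \code{c(1 - 1e-12, 1)}.
#' @export
icc_ci <- function(components, alpha = 0.05) {
  vc <- if (inherits(components, "variance_components")) components
        else anova_components(components)
  n <- vc$n; k <- vc$k
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  if (vc$EMS <= 0) {
    if (vc$BMS > 0) return(c(1 - 1e-12, 1))
    return(c(NaN, NaN))
  }
  Fobs <- vc$BMS / vc$EMS
  FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
  FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
  c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
}

#' Voxel-wise ICC(3,1) map from a contrast stack
#'
#' Applies the ICC(3,1) mean-square estimator independently at every in-mask
#' voxel of a subjects x sessions x voxels contrast stack. The computation is
#' vectorized across voxels (identical to calling \code{\link{icc31}} per
#' voxel). Out-of-mask or degenerate (zero total variance) voxels carry NaN.
#'
#' @param stack a \code{contrast_stack} (see
#'   \code{\link{simulate_contrast_cohort}}) or a 3-D array
#'   subjects x sessions x voxels.
#' @param with_ci also compute per-voxel 95\% CI bounds (default FALSE).
#' @return list: \code{icc} (numeric vector over voxels, NaN outside mask),
#'   \code{dim} (spatial grid dim, if known), \code{mask}, and when requested
#'   \code{ci_low}/\code{ci_high}.
#' @export
voxelwise_icc <- function(stack, with_ci = FALSE) {
  if (inherits(stack, "contrast_stack")) {
    arr <- stack$values; mask <- stack$mask; spatial_dim <- stack$grid_dim
  } else {
    arr <- stack; mask <- rep(TRUE, dim(arr)[3]); spatial_dim <- NULL
  }
  stopifnot(length(dim(arr)) == 3)
  n <- dim(arr)[1]; k <- dim(arr)[2]; V <- dim(arr)[3]
  ms <- .voxel_mean_squares(arr)
  denom <- ms$BMS + (k - 1) * ms$EMS
  icc <- ifelse(denom > 0, (ms$BMS - ms$EMS) / denom, NaN)
  icc[!mask] <- NaN
  out <- list(icc = icc, dim = spatial_dim, mask = mask, n = n, k = k)
  if (with_ci) {
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    Fobs <- ifelse(ms$EMS > 0, ms$BMS / ms$EMS, Inf)
    FL <- Fobs / stats::qf(0.975, df1, df2)
    FU <- Fobs * stats::qf(0.975, df2, df1)
    out$ci_low <- ifelse(is.finite(FL), (FL - 1) / (FL + k - 1), 1)
    out$ci_high <- ifelse(is.finite(FU), (FU - 1) / (FU + k - 1), 1)
    out$ci_low[!mask] <- NaN; out$ci_high[!mask] <- NaN
  }
  out
}

# vectorized two-way mean squares over the voxel dimension of an n x k x V array
.voxel_mean_squares <- function(arr) {
  n <- dim(arr)[1]; k <- dim(arr)[2]; V <- dim(arr)[3]
  M <- matrix(arr, n * k, V)           # rows index (subject, session)
  subj <- rep(seq_len(n), times = k)
  sess <- rep(seq_len(k), each = n)
  gm <- colMeans(M)
  sm <- rowsum(M, subj) / k            # n x V subject means
  tm <- rowsum(M, sess) / n            # k x V session means
  BMS <- k * colSums(sweep(sm, 2, gm)^2) / (n - 1)
  JMS <- n * colSums(sweep(tm, 2, gm)^2) / (k - 1)
  resid <- M - sm[subj, , drop = FALSE] - tm[sess, , drop = FALSE] +
    matrix(gm, n * k, V, byrow = TRUE)
  EMS <- colSums(resid^2) / ((n - 1) * (k - 1))
  list(BMS = BMS, JMS = JMS, EMS = EMS)
}

#' Median ICC per cluster or atlas region
#'
#' Summarizes a voxel-wise ICC map into the field's primary region-level
#' reliability statistic: the median of defined voxel ICCs within each region.
#' Regions come either from a \code{cluster_set} (the activation-defined
#' primary mode) or from an integer-labeled atlas volume (exploratory mode).
#' Undefined (NaN) voxels are excluded from medians; regions with no defined
#' voxel are flagged rather than classified.
#'
#' @param icc_map result of \code{\link{voxelwise_icc}} (or a bare numeric
#'   vector of voxel ICCs).
#' @param regions a \code{cluster_set} from \code{\link{extract_clusters}},
#'   or an integer vector/array of atlas labels (0 = background) with the
#'   same voxel count as the map.
#' @param region_names optional named character vector mapping label ids to
#'   region names.
#' @param scheme classification scheme for \code{\link{classify_icc}}.
#' @return data.frame of class \code{region_reliability}: columns \code{id},
#'   \code{name}, \code{k_voxels}, \code{median_icc}, \code{class},
#'   \code{defined}, sorted by median ICC descending.
#' @export
median_icc <- function(icc_map, regions, region_names = NULL,
                       scheme = "three_band") {
  icc <- if (is.list(icc_map)) icc_map$icc else icc_map
  if (inherits(regions, "cluster_set")) {
    ids <- seq_along(regions$clusters)
    voxsets <- lapply(regions$clusters, `[[`, "voxels")
    nm <- sprintf("cluster_%02d", ids)
  } else {
    lab <- as.integer(regions)
    if (length(lab) != length(icc))
      stop("atlas labels and ICC map differ in voxel count")
    ids <- sort(unique(lab[lab > 0]))
    voxsets <- lapply(ids, function(l) which(lab == l))
    nm <- if (!is.null(region_names)) unname(region_names[as.character(ids)])
          else sprintf("region_%03d", ids)
  }
  if (!length(ids)) {
    out <- data.frame(id = integer(), name = character(),
                      k_voxels = integer(), median_icc = numeric(),
                      class = character(), defined = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("region_reliability", "data.frame")
    return(out)
  }
  rows <- lapply(seq_along(ids), function(j) {
    v <- icc[voxsets[[j]]]
    v <- v[is.finite(v)]
    med <- if (length(v)) stats::median(v) else NaN
    data.frame(id = ids[j], name = nm[j], k_voxels = length(voxsets[[j]]),
               median_icc = med,
               class = if (is.finite(med)) classify_icc(med, scheme) else NA_character_,
               defined = length(v) > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.finite(out$median_icc), out$median_icc, -Inf)), ]
  rownames(out) <- NULL
  class(out) <- c("region_reliability", "data.frame")
  out
}

#' Classify an ICC value into reliability bands
#'
#' Primary three-band scheme: poor (ICC < 0.4), moderate-to-good
#' (0.4 <= ICC <= 0.75), excellent (ICC > 0.75); both boundaries belong to the
#' middle band. The alternate four-band scheme uses 0.4 / 0.6 / 0.8 cut
#' points: moderate at [0.4, 0.6), good at [0.6, 0.8), excellent at >= 0.8.
#' Negative values reflect a reliability of zero and are classified poor.
#'
#' @param icc numeric (vectorized).
#' @param scheme \code{"three_band"} (default) or \code{"four_band"}.
#' @return character vector of class labels.
#' @export
classify_icc <- function(icc, scheme = c("three_band", "four_band")) {
  scheme <- match.arg(scheme)
  out <- rep(NA_character_, length(icc))
  ok <- is.finite(icc)
  if (scheme == "three_band") {
    out[ok] <- ifelse(icc[ok] < 0.4, "poor",
               ifelse(icc[ok] <= 0.75, "moderate_good", "excellent"))
  } else {
    out[ok] <- ifelse(icc[ok] < 0.4, "poor",
               ifelse(icc[ok] < 0.6, "moderate",
               ifelse(icc[ok] < 0.8, "good", "excellent")))
  }
  out
}
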