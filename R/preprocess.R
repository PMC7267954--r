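#' Select the minimum-displacement reference volume by PCA
#'
#' Identifies the volume in which the head was closest to its typical
#' position, for use as a motion-correction reference. A temporary copy of
#' the series is Gaussian-smoothed, its temporal mean volume is removed, and
#' the volumes are decomposed by PCA. Each volume's factor vector (component
#' scores scaled by the component eigenvalues) is compared with the
#' component-wise median factor vector — a robust center of the data — and
#' the volume with the smallest Euclidean distance to that center is
#' returned.
#'
#' @param bold 4-D array (x, y, z, t), at least 3 volumes.
#' @param smooth_fwhm Gaussian smoothing FWHM in mm (default 6).
#' @param voxel_mm voxel edge length in mm (default 4, matching the
#'   acquisition the package emulates).
#' @return integer volume index (1-based).
#' @export
min_displacement_reference <- function(bold, smooth_fwhm = 6, voxel_mm = 4) {
  stopifnot(length(dim(bold)) == 4)
  nt <- dim(bold)[4]
  if (nt < 3) stop("need at least 3 volumes")
  sm <- gaussian_smooth(bold, fwhm = smooth_fwhm, voxel_mm = voxel_mm)
  M <- t(matrix(sm, prod(dim(sm)[1:3]), nt))     # volumes as rows
  M <- sweep(M, 2, colMeans(M))                  # remove temporal mean volume
  sv <- svd(M, nu = min(nt, 10), nv = 0)
  ncomp <- sum(sv$d > max(sv$d) * 1e-10)
  ncomp <- min(ncomp, ncol(sv$u))
  eig <- (sv$d[seq_len(ncomp)]^2) / max(nt - 1, 1)
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*% diag(sv$d[seq_len(ncomp)], ncomp)
  factors <- sweep(scores, 2, eig, `*`)          # scores scaled by eigenvalues
  center <- apply(factors, 2, stats::median)
  dist <- sqrt(rowSums(sweep(factors, 2, center)^2))
  which.min(dist)
}

#' Separable 3-D Gaussian smoothing of a volume series
#'
#' @param bold 4-D array (or 3-D single volume).
#' @param fwhm full width at half maximum, mm.
#' @param voxel_mm voxel edge, mm.
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(bold, fwhm = 6, voxel_mm = 4) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_mm   # in voxels
  if (sigma <= 0) return(bold)
  rad <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-rad:rad, sd = sigma)
  kern <- kern / sum(kern)
  smooth1 <- function(a, dim_i) {
    # convolve along dimension dim_i with edge renormalization
    perm <- c(dim_i, setdiff(seq_along(dim(a)), dim_i))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, d[1], prod(d[-1]))
    n <- d[1]
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (j in -rad:rad) {
      src <- (1:n) + j
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + kern[j + rad + 1] * m[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + kern[j + rad + 1]
    }
    out <- out / wsum
    ap <- array(out, d)
    aperm(ap, order(perm))
  }
  three <- length(dim(bold)) == 3
  if (three) bold <- array(bold, c(dim(bold), 1))
  for (i in 1:3) bold <- smooth1(bold, i)
  if (three) bold <- array(bold, dim(bold)[1:3])
  bold
}

#' Reduce 6 motion parameter time courses to principal-component regressors
#'
#' Rotations are converted to mm of arc displacement at a 50 mm head radius
#' so all six columns are commensurate, each column is mean-centered (not
#' variance-scaled: the decomposition must preserve which parameters carry
#' the most displacement variance), and PCA is applied; the smallest leading
#' set of components whose cumulative explained variance reaches
#' \code{variance_keep} is returned as time-course regressors. Constant
#' (zero-variance) columns are dropped before the decomposition.
#'
#' @param mpe matrix/data.frame with 6 columns (trans x/y/z in mm, rot x/y/z)
#'   and one row per volume (>= 7 rows).
#' @param variance_keep cumulative explained-variance target (default 0.85).
#' @param rot_unit "degrees" (default) or "radians".
#' @param head_radius_mm radius for rotation-to-displacement conversion
#'   (default 50).
#' @return matrix of component time courses (volumes x components) with
#'   attribute \code{explained} (per-component variance fractions).
#' @export
motion_regressors <- function(mpe, variance_keep = 0.85,
                              rot_unit = c("degrees", "radians"),
                              head_radius_mm = 50) {
  rot_unit <- match.arg(rot_unit)
  mpe <- as.matrix(mpe)
  if (ncol(mpe) != 6) stop("motion parameters must have 6 columns")
  if (nrow(mpe) < 7) stop("need at least 7 volumes")
  if (variance_keep <= 0 || variance_keep > 1)
    stop("variance_keep must be in (0, 1]")
  rot <- mpe[, 4:6, drop = FALSE]
  if (rot_unit == "degrees") rot <- rot * pi / 180
  m <- cbind(mpe[, 1:3, drop = FALSE], rot * head_radius_mm)
  sds <- apply(m, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all motion columns are constant")
  pc <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(expl) >= variance_keep - 1e-12)[1]
  out <- pc$x[, seq_len(ncomp), drop = FALSE]
  attr(out, "explained") <- expl[seq_len(ncomp)]
  out
}

#' Censor outlier volumes in a displacement metric series
#'
#' Flags volumes whose robust z-score — deviation from the local median in
#' units of the local MAD, computed in a sliding window — exceeds
#' \code{z_thresh}, and repairs them by cubic-spline interpolation over the
#' non-outlier volumes (nearest non-outlier value at the endpoints). The
#' window length and threshold defaults are configurable stand-ins for the
#' sliding-window censoring approach of the pipeline this package models.
#'
#' @param x numeric series (one value per volume, e.g. a global displacement
#'   metric).
#' @param window sliding window length in volumes (default 15).
#' @param z_thresh robust z threshold (default 4).
#' @return list: \code{outliers} (integer indices), \code{repaired} (series
#'   with outliers replaced; non-outlier values untouched), \code{z} (robust
#'   z per volume). If more than half the series is flagged the function
#'   refuses with an error of class \code{censor_failure}.
#' @export
censor_outliers <- function(x, window = 15, z_thresh = 4) {
  n <- length(x)
  half <- max(1L, window %/% 2L)
  z <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- x[lo:hi]
    med <- stats::median(w)
    madv <- stats::mad(w)
    dev <- x[i] - med
    z[i] <- if (madv > 0) dev / madv
            else if (abs(dev) <= .Machine$double.eps^0.5 * max(1, abs(med))) 0
            else Inf * sign(dev)   # deviant point in a locally constant window
  }
  out <- which(abs(z) > z_thresh)
  if (length(out) > n / 2)
    stop(structure(class = c("censor_failure", "error", "condition"),
                   list(message = "more than 50% of volumes flagged as outliers; refusing to censor",
                        call = sys.call())))
  rep_x <- x
  if (length(out)) {
    good <- setdiff(seq_len(n), out)
    interior <- out[out > min(good) & out < max(good)]
    if (length(interior))
      rep_x[interior] <- stats::spline(good, x[good], xout = interior,
                                       method = "natural")$y
    edges <- setdiff(out, interior)
    for (i in edges) rep_x[i] <- x[good[which.min(abs(good - i))]]
  }
  list(outliers = out, repaired = rep_x, z = z)
}

#' Read / write 6-column motion parameter text files
#'
#' Whitespace-separated, one row per volume: three translations (mm) then
#' three rotations.
#'
#' @param path file path.
#' @param mpe matrix/data.frame to write.
#' @return \code{read_motion} returns a numeric matrix with 6 columns.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("motion file must have 6 columns")
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' @rdname read_motion
#' @export
write_motion <- function(mpe, path) {
  utils::write.table(format(as.matrix(mpe), digits = 8), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
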