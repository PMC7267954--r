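#' Per-run behavioral quality control
#'
#' Computes commission and total (commission + omission) error rates for each
#' run and applies the exclusion thresholds: a run passes when its commission
#' rate is at most \code{commission_max} (default 25\%) and its total error
#' rate at most \code{total_max} (default 30\%). Subjects with any failing
#' run are flagged for exclusion.
#'
#' @param responses data.frame of trial responses with logical columns
#'   \code{commission_error} and \code{omission_error}; grouped by any of the
#'   id columns present among \code{subject}, \code{session},
#'   \code{run_index}.
#' @param commission_max commission-rate threshold (default 0.25).
#' @param total_max total-error-rate threshold (default 0.30).
#' @return data.frame with one row per run: id columns, \code{n_trials},
#'   \code{commission_rate}, \code{total_error_rate}, \code{pass}.
#' @export
qc_runs <- function(responses, commission_max = 0.25, total_max = 0.30) {
  idc <- intersect(c("subject", "session", "run_index"), names(responses))
  if (!length(idc)) { responses$run_index <- 1L; idc <- "run_index" }
  key <- interaction(responses[idc], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(responses, key), function(g) {
    cr <- mean(g$commission_error)
    tr <- mean(g$commission_error | g$omission_error)
    cbind(g[1, idc, drop = FALSE],
          data.frame(n_trials = nrow(g), commission_rate = cr,
                     total_error_rate = tr,
                     pass = cr <= commission_max & tr <= total_max))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Filter trials for reaction-time analysis
#'
#' Applies the three RT trial-exclusion rules, in order: (1) error trials
#' (commission or omission); (2) post-error trials, the trial immediately
#' following an error within the same run (post-error status does not cross
#' run boundaries, as runs are separated by rest); (3) RT outliers, trials
#' whose RT lies more than 2 standard deviations above or below the mean of
#' their subject x session x trial-type cell, with mean and SD computed over
#' the correct, non-post-error trials of that cell.
#'
#' The outlier bounds computed on first application are attached to the
#' result (attribute \code{rt_bounds}) and reused when the function is
#' applied again to already-filtered data, so filtering is idempotent: the
#' exclusion criterion is defined once per recording, not re-estimated on its
#' own output.
#'
#' @param responses trial response data.frame (see
#'   \code{\link{simulate_behavior}} for the column layout); must carry the
#'   trial-type columns named in \code{type_cols}.
#' @param type_cols columns defining the trial type whose mean/SD scope the
#'   outlier rule uses (default \code{"congruent"}).
#' @param sd_mult outlier width in SDs (default 2).
#' @return the retained rows, with attributes \code{removal_counts} (named
#'   integer vector: \code{error}, \code{post_error}, \code{rt_outlier}) and
#'   \code{rt_bounds} (per-cell bounds table).
#' @export
filter_rt_trials <- function(responses, type_cols = "congruent", sd_mult = 2) {
  if (!all(type_cols %in% names(responses)))
    stop("missing trial-type coding column(s): ",
         paste(setdiff(type_cols, names(responses)), collapse = ", "))
  idc <- intersect(c("subject", "session"), names(responses))
  runc <- intersect(c("run_index"), names(responses))
  carried_bounds <- attr(responses, "rt_bounds")
  ord <- do.call(order, responses[c(idc, runc, "trial_index")])
  responses <- responses[ord, , drop = FALSE]

  err <- responses$commission_error | responses$omission_error
  runkey <- interaction(responses[c(idc, runc)], drop = TRUE, lex.order = TRUE)
  prev_err <- stats::ave(err, runkey, FUN = function(e) c(FALSE, e[-length(e)]))
  post_err <- as.logical(prev_err) & !err

  cellkey <- interaction(responses[c(idc, type_cols)], drop = TRUE,
                         lex.order = TRUE)
  bounds <- carried_bounds
  if (is.null(bounds)) {
    base <- !err & !post_err & !is.na(responses$rt_ms)
    mu <- tapply(responses$rt_ms[base], cellkey[base], mean)
    sd_ <- tapply(responses$rt_ms[base], cellkey[base], stats::sd)
    sd_[is.na(sd_)] <- 0
    bounds <- data.frame(cell = names(mu),
                         lo = as.numeric(mu - sd_mult * sd_),
                         hi = as.numeric(mu + sd_mult * sd_),
                         stringsAsFactors = FALSE)
  }
  lo <- bounds$lo[match(as.character(cellkey), bounds$cell)]
  hi <- bounds$hi[match(as.character(cellkey), bounds$cell)]
  outlier <- !err & !post_err & !is.na(responses$rt_ms) &
    (responses$rt_ms < lo | responses$rt_ms > hi)
  outlier[is.na(outlier)] <- FALSE

  keep <- !err & !post_err & !outlier
  out <- responses[keep, , drop = FALSE]
  attr(out, "removal_counts") <- c(error = sum(err),
                                   post_error = sum(post_err),
                                   rt_outlier = sum(outlier))
  attr(out, "rt_bounds") <- bounds
  out
}

#' Accuracy per trial type
#'
#' Proportion of correct responses over all trials of each trial type; unlike
#' the RT filter, post-error trials and RT outliers are included (only the
#' response itself matters).
#'
#' @param responses trial response data.frame.
#' @param type_cols trial-type grouping columns (default \code{"congruent"}).
#' @return data.frame with id/type columns, \code{n_trials}, \code{n_correct},
#'   \code{accuracy}.
#' @export
compute_accuracy <- function(responses, type_cols = "congruent") {
  idc <- intersect(c("subject", "session"), names(responses))
  key <- interaction(responses[c(idc, type_cols)], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(responses, key), function(g) {
    cbind(g[1, c(idc, type_cols), drop = FALSE],
          data.frame(n_trials = nrow(g), n_correct = sum(g$correct),
                     accuracy = mean(g$correct)))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Subject-level behavioral summary (median RT and accuracy per condition)
#'
#' Median RT is computed on trials surviving \code{\link{filter_rt_trials}};
#' accuracy on all trials. Conditions summarized: congruent, incongruent,
#' happy face, fear face, and the adaptation cells iI and cI.
#'
#' @param responses trial response data.frame for the whole cohort.
#' @return data.frame: \code{subject}, \code{session}, \code{condition},
#'   \code{median_rt_ms}, \code{accuracy}, \code{n_rt_trials}.
#' @export
behavioral_summary <- function(responses) {
  conds <- list(
    congruent   = function(g) g$congruent,
    incongruent = function(g) !g$congruent,
    happy       = function(g) g$face_emotion == "happy",
    fear        = function(g) g$face_emotion == "fear",
    iI          = function(g) g$adaptation_label == "iI",
    cI          = function(g) g$adaptation_label == "cI")
  rt_ok <- filter_rt_trials(responses, type_cols = "congruent")
  key_all <- interaction(responses$subject, responses$session, drop = TRUE)
  key_rt <- interaction(rt_ok$subject, rt_ok$session, drop = TRUE)
  rows <- list()
  for (ss in levels(key_all)) {
    g_all <- responses[key_all == ss, , drop = FALSE]
    g_rt <- rt_ok[key_rt == ss, , drop = FALSE]
    for (cn in names(conds)) {
      sel_rt <- conds[[cn]](g_rt)
      sel_all <- conds[[cn]](g_all)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = g_all$subject[1], session = g_all$session[1],
        condition = cn,
        median_rt_ms = if (any(sel_rt)) stats::median(g_rt$rt_ms[sel_rt]) else NA_real_,
        accuracy = mean(g_all$correct[sel_all]),
        n_rt_trials = sum(sel_rt), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank z statistic with Pratt zero handling
#'
#' Paired-sample signed-rank test returning the normal-approximation z
#' statistic (the form clinical software reports). Zero differences are
#' handled by the Pratt convention: they take part in the ranking of absolute
#' differences and are then discarded; ties receive midranks. When more than
#' \code{sign_test_zero_frac} of the differences are zero the exact sign test
#' is used instead (zeros dropped), since the rank approximation degrades.
#'
#' @param x,y paired numeric vectors.
#' @param sign_test_zero_frac zero-fraction trigger for the sign test
#'   (default 0.25).
#' @return list: \code{z}, \code{p} (two-sided), \code{method}
#'   ("wilcoxon_pratt" or "sign"), \code{n}, \code{n_zero}.
#' @export
wilcoxon_z <- function(x, y, sign_test_zero_frac = 0.25) {
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  nz <- sum(d == 0)
  if (nz == n) return(list(z = 0, p = 1, method = "wilcoxon_pratt",
                           n = n, n_zero = nz))
  if (nz / n > sign_test_zero_frac) {
    npos <- sum(d > 0); nneg <- sum(d < 0)
    bt <- stats::binom.test(npos, npos + nneg)
    zs <- stats::qnorm(1 - bt$p.value / 2) * sign(npos - nneg)
    return(list(z = zs, p = bt$p.value, method = "sign", n = n, n_zero = nz))
  }
  r <- rank(abs(d))                    # zeros included in ranking (Pratt)
  rnz <- r[d != 0]
  wpos <- sum(r[d > 0])
  mu <- sum(rnz) / 2
  sig2 <- sum(rnz^2) / 4
  z <- (wpos - mu) / sqrt(sig2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), method = "wilcoxon_pratt",
       n = n, n_zero = nz)
}

#' Stroop and emotion statistics across subjects and sessions
#'
#' For each session: paired Wilcoxon signed-rank tests (z, two-sided p) of
#' incongruent vs congruent and fear vs happy, on median RT and on accuracy.
#' Across sessions: Friedman tests per measure. A Shapiro-Wilk normality
#' check of the paired differences is recorded per comparison (the gate that
#' motivates the nonparametric tests), and the Bonferroni-adjusted alpha for
#' the four within-session comparisons is reported.
#'
#' @param summary output of \code{\link{behavioral_summary}} (>= 2 subjects).
#' @param alpha nominal alpha (default 0.05); the adjusted threshold is
#'   \code{alpha / 4} = 0.0125 under the default.
#' @return list: \code{pairwise} (data.frame: session, measure, comparison,
#'   z, p, method, shapiro_p, n), \code{friedman} (data.frame: measure,
#'   condition-set, chisq, df, p), \code{alpha_adjusted}.
#' @export
stroop_stats <- function(summary, alpha = 0.05) {
  wide <- function(measure, cond) {
    s <- summary[summary$condition == cond, ]
    tapply(s[[measure]], list(s$subject, s$session), mean)
  }
  sessions <- sort(unique(summary$session))
  comps <- list(
    c("incongruent", "congruent"),
    c("fear", "happy"))
  measures <- c(rt = "median_rt_ms", acc = "accuracy")
  rows <- list()
  for (mn in names(measures)) for (cp in comps) {
    a <- wide(measures[[mn]], cp[1]); b <- wide(measures[[mn]], cp[2])
    for (t in sessions) {
      tc <- as.character(t)
      ok <- stats::complete.cases(a[, tc], b[, tc])
      if (sum(ok) < 2) stop("fewer than 2 complete pairs for ", cp[1], " vs ",
                            cp[2], " at session ", t)
      wz <- wilcoxon_z(a[ok, tc], b[ok, tc])
      dd <- a[ok, tc] - b[ok, tc]
      sw <- if (length(unique(dd)) > 1 && length(dd) >= 3)
        stats::shapiro.test(dd)$p.value else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        session = t, measure = mn,
        comparison = paste(cp, collapse = " vs "),
        effect = stats::median(dd), z = wz$z, p = wz$p, method = wz$method,
        shapiro_p = sw, n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  fr <- list()
  for (mn in names(measures)) for (cond in c("congruent", "incongruent",
                                             "happy", "fear")) {
    m <- wide(measures[[mn]], cond)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) >= 2 && ncol(m) >= 2) {
      ft <- stats::friedman.test(as.matrix(m))
      fr[[length(fr) + 1L]] <- data.frame(
        measure = mn, condition = cond,
        chisq = unname(ft$statistic), df = unname(ft$parameter),
        p = ft$p.value, stringsAsFactors = FALSE)
    }
  }
  list(pairwise = do.call(rbind, rows), friedman = do.call(rbind, fr),
       alpha_adjusted = alpha / 4)
}

#' Test-retest reliability of behavioral measures
#'
#' Builds subject x session matrices of median RT and accuracy for each
#' condition (congruent, incongruent, happy, fear) and for the contrast
#' measures (incongruent - congruent, fear - happy, iI - cI), and estimates
#' ICC(3,1) with its 95\% F-based confidence interval for each.
#'
#' @param summary output of \code{\link{behavioral_summary}}.
#' @param scheme classification scheme for \code{\link{classify_icc}}.
#' @return data.frame: \code{measure}, \code{kind} (rt/accuracy),
#'   \code{icc}, \code{ci_low}, \code{ci_high}, \code{class}, \code{n}.
#' @export
behavioral_icc <- function(summary, scheme = "three_band") {
  wide <- function(measure, cond) {
    s <- summary[summary$condition == cond, ]
    tapply(s[[measure]], list(s$subject, s$session), mean)
  }
  specs <- list(
    list("congruent",  "rt"), list("incongruent", "rt"),
    list("happy", "rt"), list("fear", "rt"),
    list("congruent", "accuracy"), list("incongruent", "accuracy"),
    list("happy", "accuracy"), list("fear", "accuracy"))
  contrasts <- list(
    list(c("incongruent", "congruent"), "rt"),
    list(c("fear", "happy"), "rt"),
    list(c("iI", "cI"), "rt"),
    list(c("incongruent", "congruent"), "accuracy"),
    list(c("fear", "happy"), "accuracy"),
    list(c("iI", "cI"), "accuracy"))
  col <- c(rt = "median_rt_ms", accuracy = "accuracy")
  rows <- list()
  add <- function(name, kind, Y) {
    Y <- Y[stats::complete.cases(Y), , drop = FALSE]
    r <- icc31(Y, scheme = scheme)
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = name, kind = kind, icc = r$icc,
      ci_low = r$ci_low, ci_high = r$ci_high,
      class = r$class_label, n = r$n, stringsAsFactors = FALSE)
  }
  for (sp in specs)
    add(sp[[1]], sp[[2]], wide(col[[sp[[2]]]], sp[[1]]))
  for (ct in contrasts) {
    a <- wide(col[[ct[[2]]]], ct[[1]][1])
    b <- wide(col[[ct[[2]]]], ct[[1]][2])
    add(paste(ct[[1]], collapse = " - "), ct[[2]], a - b)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
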