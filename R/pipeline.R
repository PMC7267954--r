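#' Number of volumes implied by an acquisition duration and TR
#'
#' @param minutes,seconds acquisition length (defaults 6 min 44 s).
#' @param tr repetition time in seconds (default 2).
#' @return integer volume count (202 under the defaults).
#' @export
acquisition_volumes <- function(minutes = 6, seconds = 44, tr = 2) {
  as.integer(round((minutes * 60 + seconds) / tr))
}

#' Participant exclusion cascade bookkeeping
#'
#' Tracks the sample from recruitment to analysis through the ordered
#' exclusion rules of a multi-site test-retest protocol: imaging quality
#' exclusions (excessive motion, incomplete sequence, ghosting/quality),
#' missing time-points or withdrawal, unusable behavioral data, behavioral
#' accuracy threshold failures, and removal of sites left with a single
#' participant. Defaults are the emulated study's printed counts and yield
#' an analyzed sample of 36.
#'
#' @param recruited starting sample (default 59).
#' @param excessive_motion,incomplete_scan,data_quality imaging exclusions
#'   (defaults 4, 1, 6).
#' @param missing_timepoint missing task data at a time-point or withdrawal
#'   (default 5).
#' @param behavior_unusable unusable behavioral recordings (default 4:
#'   one with no RTs recorded plus three with no responses recorded).
#' @param accuracy_fail below behavioral accuracy threshold (default 2).
#' @param single_site_n participants removed because their site would
#'   contribute only them (default 1).
#' @return data.frame with columns \code{stage}, \code{removed},
#'   \code{remaining}; the last \code{remaining} is the analyzed n.
#' @export
exclusion_cascade <- function(recruited = 59, excessive_motion = 4,
                              incomplete_scan = 1, data_quality = 6,
                              missing_timepoint = 5, behavior_unusable = 4,
                              accuracy_fail = 2, single_site_n = 1) {
  steps <- c(recruited = 0, excessive_motion = excessive_motion,
             incomplete_scan = incomplete_scan, data_quality = data_quality,
             missing_timepoint = missing_timepoint,
             behavior_unusable = behavior_unusable,
             accuracy_fail = accuracy_fail, single_site = single_site_n)
  remaining <- recruited - cumsum(steps)
  data.frame(stage = names(steps), removed = as.integer(steps),
             remaining = as.integer(remaining), stringsAsFactors = FALSE)
}

#' Synthetic space-filling parcellation of a voxel grid
#'
#' Partitions the grid into \code{n_regions} contiguous, nearly equal-sized
#' parcels (by linear voxel order). This is a synthetic stand-in atlas used
#' to exercise atlas-level median-ICC summarization at a realistic region
#' count; it carries no anatomical meaning.
#'
#' @param grid_dim length-3 integer grid dimensions.
#' @param n_regions number of labels (default 136).
#' @return integer array of labels 1..n_regions.
#' @export
synthetic_atlas <- function(grid_dim, n_regions = 136) {
  V <- prod(grid_dim)
  if (n_regions > V) stop("more regions than voxels")
  lab <- as.integer(cut(seq_len(V), breaks = n_regions, labels = FALSE))
  array(lab, grid_dim)
}

#' Write / read a statistic or ICC map as NIfTI-1
#'
#' @param values numeric vector or 3-D array of voxel values.
#' @param grid_dim spatial dimensions (ignored if \code{values} is an array).
#' @param path output path (".nii" or ".nii.gz").
#' @param voxel_mm isotropic voxel size for the header (default 4).
#' @return \code{write_map} returns the path invisibly; \code{read_map}
#'   returns a 3-D array.
#' @export
write_map <- function(values, grid_dim = NULL, path, voxel_mm = 4) {
  arr <- if (is.null(dim(values)) || length(dim(values)) != 3)
    array(as.numeric(values), grid_dim) else values
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim(arr))
}

#' Assemble a pipeline configuration
#'
#' Collects the cohort, task, acquisition, thresholding and reliability
#' settings for \code{\link{run_pipeline}}. Defaults reproduce the study
#' conditions the synthetic generator emulates: 36 subjects, 3 sessions,
#' 2 runs of 74 trials with 3-5 s jittered ISIs, TR 2 s, 202 volumes,
#' QC thresholds 25\%/30\%, RT filter at +/- 2 SD, minimum cluster extent
#' 10 voxels, FWE alpha 0.05.
#'
#' @param n_subjects,n_sessions cohort size (defaults 36, 3).
#' @param seed integer seed, mandatory source of all randomness.
#' @param grid_dim voxel grid (default \code{c(24, 24, 16)}).
#' @param n_runs,trials_per_run,isi_range task structure.
#' @param tr,n_volumes acquisition geometry.
#' @param fwe_alpha,min_cluster thresholding.
#' @param icc_scheme "three_band" or "four_band".
#' @param regions truth regions passed to \code{\link{cohort_truth}} (NULL
#'   for the two-region default).
#' @param atlas_regions parcel count for the synthetic atlas summary
#'   (default 136; 0 disables).
#' @param behavior_trials trials per run used for the behavioral simulation
#'   (default \code{trials_per_run}).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_subjects = 36, n_sessions = 3, seed = 1,
                            grid_dim = c(24, 24, 16),
                            n_runs = 2, trials_per_run = 74,
                            isi_range = c(3, 5),
                            tr = 2, n_volumes = 202,
                            fwe_alpha = 0.05, min_cluster = 10,
                            icc_scheme = "three_band",
                            regions = NULL, atlas_regions = 136,
                            behavior_trials = trials_per_run) {
  stopifnot(n_sessions >= 2, fwe_alpha > 0, fwe_alpha < 1, min_cluster >= 1)
  structure(list(n_subjects = n_subjects, n_sessions = n_sessions,
                 seed = seed, grid_dim = grid_dim, n_runs = n_runs,
                 trials_per_run = trials_per_run, isi_range = isi_range,
                 tr = tr, n_volumes = n_volumes, fwe_alpha = fwe_alpha,
                 min_cluster = min_cluster, icc_scheme = icc_scheme,
                 regions = regions, atlas_regions = atlas_regions,
                 behavior_trials = behavior_trials),
            class = "pipeline_config")
}

#' Run the full simulate / behave / map / ICC / report pipeline
#'
#' Executes, in order: trial-sequence generation, behavioral simulation with
#' QC and statistics, contrast-level cohort simulation, second-level group
#' mapping with Bonferroni voxel-level FWE thresholding and cluster
#' extraction (session 1 defines the activation clusters), voxel-wise
#' ICC(3,1) mapping, and median-ICC summarization per cluster and per
#' synthetic atlas parcel. All stages derive their randomness from
#' \code{config$seed}; a rerun with the same configuration is identical.
#'
#' @param config a \code{pipeline_config}.
#' @param out_dir optional directory; when given, tables, maps and a run log
#'   are written there via \code{\link{render_tables}}.
#' @return list of class \code{pipeline_result}: \code{config},
#'   \code{truth}, \code{qc}, \code{behavior_summary}, \code{stroop},
#'   \code{behavior_icc}, \code{stack}, \code{stat_map}, \code{threshold},
#'   \code{clusters}, \code{icc_map}, \code{cluster_table},
#'   \code{atlas_table}, \code{notes}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_subjects < 2)
    stop("reliability stage requires n >= 2 subjects")
  notes <- c(
    "high-pass: 100 interpreted as cutoff period in seconds (DCT basis)",
    "FWE: Bonferroni across in-mask voxels (stand-in for random-field FWE)",
    "ICC form: Shrout-Fleiss mean-square ICC(3,1), consistency")

  seq <- generate_sequence(config$n_runs, config$behavior_trials,
                           config$isi_range, seed = config$seed)
  behav <- simulate_behavior(seq, n_subjects = config$n_subjects,
                             n_sessions = config$n_sessions,
                             seed = config$seed + 1L)
  qc <- qc_runs(behav)
  bsum <- behavioral_summary(behav)
  stroop <- stroop_stats(bsum)
  bicc <- behavioral_icc(bsum, scheme = config$icc_scheme)

  truth <- cohort_truth(n_subjects = config$n_subjects,
                        n_sessions = config$n_sessions,
                        grid_dim = config$grid_dim,
                        regions = config$regions,
                        seed = config$seed + 2L)
  stack <- simulate_contrast_cohort(truth)

  sess1 <- t(stack$values[, 1, ])            # subjects x voxels
  stat <- second_level(t(sess1), mask = stack$mask,
                       grid_dim = config$grid_dim)
  thr <- fwe_threshold(stat, alpha = config$fwe_alpha)
  clus <- extract_clusters(stat, thr, min_size = config$min_cluster)
  if (!length(clus$clusters))
    notes <- c(notes, "no FWE-significant clusters; uncorrected p < .001 fallback suggested")

  iccmap <- voxelwise_icc(stack)
  cluster_table <- if (length(clus$clusters))
    median_icc(iccmap, clus, scheme = config$icc_scheme) else
    median_icc(iccmap, structure(list(clusters = list()), class = "cluster_set"))
  atlas_table <- if (config$atlas_regions > 0)
    median_icc(iccmap, synthetic_atlas(config$grid_dim, config$atlas_regions),
               scheme = config$icc_scheme) else NULL

  res <- structure(list(config = config, truth = truth, qc = qc,
                        behavior_summary = bsum, stroop = stroop,
                        behavior_icc = bicc, stack = stack, stat_map = stat,
                        threshold = thr, clusters = clus, icc_map = iccmap,
                        cluster_table = cluster_table,
                        atlas_table = atlas_table, notes = notes),
                   class = "pipeline_result")
  if (!is.null(out_dir)) render_tables(res, out_dir)
  res
}

#' Render pipeline outputs as CSV tables, NIfTI maps and a run log
#'
#' Writes the behavioral summary and test table, the behavioral ICC table
#' with confidence intervals, the cluster reliability table (extent, peak
#' statistic and location, median ICC) and the atlas reliability table, plus
#' the group t map and voxel-wise ICC map as NIfTI-1 volumes and a log of
#' the analysis-decision flags in effect.
#'
#' @param res a \code{pipeline_result}.
#' @param out_dir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
render_tables <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[name] <<- p
  }
  wcsv(res$qc, "run_qc.csv")
  wcsv(res$behavior_summary, "behavior_summary.csv")
  wcsv(res$stroop$pairwise, "behavior_tests.csv")
  wcsv(res$behavior_icc, "behavior_icc.csv")
  ct <- res$cluster_table
  if (nrow(ct)) {
    peaks <- do.call(rbind, lapply(res$clusters$clusters[ct$id], function(cl)
      data.frame(K = cl$size, peak_t = cl$peak_stat,
                 x = cl$peak[1], y = cl$peak[2], z = cl$peak[3])))
    ct <- cbind(ct[c("id", "median_icc", "class")], peaks)
    ct <- ct[c("id", "K", "peak_t", "x", "y", "z", "median_icc", "class")]
  }
  wcsv(ct, "cluster_reliability.csv")
  if (!is.null(res$atlas_table)) wcsv(res$atlas_table, "atlas_reliability.csv")
  gm <- file.path(out_dir, "group_t.nii.gz")
  write_map(res$stat_map$t, res$config$grid_dim, gm)
  paths["group_t.nii.gz"] <- gm
  im <- file.path(out_dir, "icc_map.nii.gz")
  icc <- res$icc_map$icc
  icc[!is.finite(icc)] <- NA
  write_map(icc, res$config$grid_dim, im)
  paths["icc_map.nii.gz"] <- im
  log <- file.path(out_dir, "run_log.txt")
  writeLines(c(sprintf("seed: %d", res$config$seed),
               sprintf("n_subjects: %d  n_sessions: %d",
                       res$config$n_subjects, res$config$n_sessions),
               sprintf("fwe_alpha: %g  min_cluster: %d  threshold_t: %.4f",
                       res$config$fwe_alpha, res$config$min_cluster,
                       res$threshold),
               res$notes), log)
  paths["run_log.txt"] <- log
  invisible(paths)
}
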