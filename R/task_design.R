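#' Generate a counterbalanced emotional-conflict trial sequence
#'
#' Builds an event-related face-word Stroop sequence: happy or fearful faces
#' with the word "HAPPY" or "FEAR" superimposed. Each run is exactly
#' counterbalanced for congruency (face emotion matches the word) and for face
#' emotion within each congruency cell. Stimuli last 1 s; inter-stimulus
#' intervals are jittered uniformly on \code{isi_range} and rounded to 0.1 s.
#' Runs start after a fixed lead-in fixation.
#'
#' Trial order is shuffled uniformly under the marginal-balance constraints and
#' re-shuffled until every conflict-adaptation cell (cC, cI, iC, iI) has at
#' least \code{min_adaptation} instances per run, so the iI-cI contrast is
#' estimable on every generated sequence.
#'
#' @param n_runs number of runs (default 2).
#' @param trials_per_run trials in each run; must be divisible by 4 so that
#'   congruency and face emotion can both be balanced (default 74 is handled
#'   by balancing emotion within congruency as evenly as possible; only
#'   evenness of \code{trials_per_run} is required).
#' @param isi_range length-2 numeric, low/high inter-stimulus interval in
#'   seconds (default \code{c(3, 5)}).
#' @param seed integer seed; the sequence is a deterministic function of the
#'   arguments and this seed.
#' @param lead_in_s fixation before the first trial, seconds (default 10).
#' @param min_adaptation minimum count per adaptation cell per run when
#'   \code{trials_per_run} is large enough to support it (default 10).
#' @return An object of class \code{task_sequence}: a data.frame with one row
#'   per trial and columns \code{run_index}, \code{trial_index}, \code{onset},
#'   \code{duration}, \code{face_emotion}, \code{word}, \code{congruent},
#'   \code{adaptation_label}, \code{isi_after}; attributes \code{n_runs} and
#'   \code{seed}.
#' @examples
#' seq <- generate_sequence(2, 74, c(3, 5), seed = 7)
#' table(seq$run_index, seq$congruent)
#' @export
generate_sequence <- function(n_runs = 2, trials_per_run = 74,
                              isi_range = c(3, 5), seed = 1,
                              lead_in_s = 10, min_adaptation = 10) {
  if (n_runs < 1 || trials_per_run < 1)
    stop("n_runs and trials_per_run must be positive")
  if (trials_per_run %% 2 != 0)
    stop("trials_per_run must be even to counterbalance congruency")
  if (length(isi_range) != 2 || isi_range[1] > isi_range[2] || isi_range[1] < 0)
    stop("isi_range must be c(low, high) with 0 <= low <= high")

  # scale the per-cell requirement down for tiny runs used in tests
  min_cell <- min(min_adaptation, max(0L, trials_per_run %/% 8L))

  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    half <- trials_per_run / 2L
    # emotion balanced exactly per run and as evenly as possible within each
    # congruency cell: when the cells are odd-sized, one cell gets the extra
    # happy face and the other the extra fearful face
    h1 <- if (half %% 2 == 0) half / 2 else (half + sample(c(-1, 1), 1)) / 2
    h2 <- half - h1
    cell_emotions <- function(n_happy, n) {
      sample(c(rep("happy", n_happy), rep("fear", n - n_happy)))
    }
    repeat {
      congruent <- sample(rep(c(TRUE, FALSE), each = half))
      emo <- character(trials_per_run)
      emo[congruent]  <- cell_emotions(h1, half)
      emo[!congruent] <- cell_emotions(h2, half)
      prev <- c(NA, congruent[-trials_per_run])
      lab <- ifelse(is.na(prev), "first",
                    paste0(ifelse(prev, "c", "i"), ifelse(congruent, "C", "I")))
      counts <- table(factor(lab, levels = c("cC", "cI", "iC", "iI")))
      if (all(counts >= min_cell)) break
    }
    isi <- round(stats::runif(trials_per_run, isi_range[1], isi_range[2]), 1)
    onset <- lead_in_s + cumsum(c(0, (1 + isi)[-trials_per_run]))
    word <- toupper(ifelse(congruent, emo, ifelse(emo == "happy", "fear", "happy")))
    runs[[r]] <- data.frame(
      run_index = r,
      trial_index = seq_len(trials_per_run),
      onset = round(onset, 3),
      duration = 1.0,
      face_emotion = emo,
      word = word,
      congruent = congruent,
      adaptation_label = lab,
      isi_after = isi,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  structure(out, n_runs = n_runs, seed = seed, class = c("task_sequence", "data.frame"))
}

#' Code conflict-adaptation labels on an existing trial sequence
#'
#' Labels every trial by the congruency transition from the preceding trial in
#' the same run: cC, cI, iC, iI (previous congruency, current congruency).
#' The first trial of each run is labeled \code{"first"}; labels never cross
#' run boundaries.
#'
#' @param seq a \code{task_sequence} (or data.frame with \code{run_index},
#'   \code{trial_index}, \code{onset}, \code{congruent}).
#' @return the sequence with \code{adaptation_label} (re)computed.
#' @export
code_adaptation <- function(seq) {
  seq <- seq[order(seq$run_index, seq$trial_index), , drop = FALSE]
  for (r in unique(seq$run_index)) {
    i <- which(seq$run_index == r)
    if (is.unsorted(seq$onset[i], strictly = TRUE))
      stop("onsets must be strictly increasing within a run")
    cong <- seq$congruent[i]
    prev <- c(NA, cong[-length(cong)])
    seq$adaptation_label[i] <- ifelse(
      is.na(prev), "first",
      paste0(ifelse(prev, "c", "i"), ifelse(cong, "C", "I")))
  }
  seq
}

#' Write / read a trial sequence as a BIDS-style events table
#'
#' Tab-separated, UTF-8, with header \code{onset}, \code{duration},
#' \code{trial_type}, \code{isi_after}. \code{trial_type} encodes run,
#' congruency, face emotion and adaptation label as
#' \code{run-<r>_<congruent|incongruent>_<happy|fear>_<label>}, so the
#' write/read round trip is the identity on all fields.
#'
#' @param seq a \code{task_sequence}.
#' @param path file path to write to / read from.
#' @return \code{write_events} returns \code{path} invisibly;
#'   \code{read_events} returns a \code{task_sequence}.
#' @export
write_events <- function(seq, path) {
  tt <- sprintf("run-%02d_%s_%s_%s", seq$run_index,
                ifelse(seq$congruent, "congruent", "incongruent"),
                seq$face_emotion, seq$adaptation_label)
  df <- data.frame(onset = sprintf("%.3f", seq$onset),
                   duration = sprintf("%.3f", seq$duration),
                   trial_type = tt,
                   isi_after = sprintf("%.3f", seq$isi_after))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) {
    out <- data.frame(run_index = integer(), trial_index = integer(),
                      onset = numeric(), duration = numeric(),
                      face_emotion = character(), word = character(),
                      congruent = logical(), adaptation_label = character(),
                      isi_after = numeric(), stringsAsFactors = FALSE)
    return(structure(out, n_runs = 0L, class = c("task_sequence", "data.frame")))
  }
  onset <- suppressWarnings(as.numeric(df$onset))
  if (anyNA(onset))
    stop(sprintf("non-numeric onset at line %d of %s",
                 which(is.na(onset))[1] + 1L, path))
  dur <- suppressWarnings(as.numeric(df$duration))
  isi <- suppressWarnings(as.numeric(df$isi_after))
  if (anyNA(dur) || anyNA(isi))
    stop(sprintf("malformed row at line %d of %s",
                 which(is.na(dur) | is.na(isi))[1] + 1L, path))
  parts <- strsplit(df$trial_type, "_", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad))
    stop(sprintf("malformed trial_type at line %d of %s", bad[1] + 1L, path))
  m <- do.call(rbind, parts)
  run <- as.integer(sub("run-", "", m[, 1], fixed = TRUE))
  congruent <- m[, 2] == "congruent"
  emo <- m[, 3]
  word <- toupper(ifelse(congruent, emo, ifelse(emo == "happy", "fear", "happy")))
  out <- data.frame(run_index = run,
                    trial_index = stats::ave(run, run, FUN = seq_along),
                    onset = onset, duration = dur, face_emotion = emo,
                    word = word, congruent = congruent,
                    adaptation_label = m[, 4], isi_after = isi,
                    stringsAsFactors = FALSE)
  structure(out, n_runs = length(unique(run)),
            class = c("task_sequence", "data.frame"))
}
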