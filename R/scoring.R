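#' Target labels for the two TMT versions
#'
#' Version A labels targets `"1"`..`"25"`; version B alternates numbers and
#' letters (`"1"`, `"A"`, `"2"`, `"B"`, ..., `"13"`), 25 targets in full.
#'
#' @param version `"A"` or `"B"`.
#' @param n Number of targets (25 for an experimental trial, 8 for a
#'   training trial).
#' @return Character vector of labels in click order.
#' @export
tmt_labels <- function(version = c("A", "B"), n = 25) {
  version <- match.arg(version)
  if (n < 1 || n > 25) stop("n must be between 1 and 25")
  if (version == "A") return(as.character(seq_len(n)))
  full <- character(25)
  full[seq(1, 25, by = 2)] <- as.character(1:13)
  full[seq(2, 24, by = 2)] <- LETTERS[1:12]
  full[seq_len(n)]
}

#' Target layout for a TMT trial
#'
#' Holds the ordered target positions (screen pixels), the visible circle
#' diameter and the larger area-of-interest (AOI) diameter used to classify
#' fixations as guiding or searching. Angular target positions are cached at
#' construction.
#'
#' @param version `"A"` or `"B"`.
#' @param centers_px n x 2 matrix of target centers (pixels), in click
#'   order.
#' @param labels Optional target labels; defaults to
#'   `tmt_labels(version, n)`. A full 25-target layout must carry the
#'   canonical labels of its version.
#' @param circle_diameter Visible target circle diameter (deg); clicks
#'   inside this circle count as hits.
#' @param aoi_diameter Classification circle diameter (deg); fixations
#'   within this radius of a target center are assigned to it.
#' @param geom A [screen_geometry()].
#' @return An object of class `tmt_layout`.
#' @export
target_layout <- function(version, centers_px, labels = NULL,
                          circle_diameter = 1.35, aoi_diameter = 3.25,
                          geom = screen_geometry()) {
  version <- match.arg(version, c("A", "B"))
  centers_px <- .as_xy(centers_px, "target center")
  n <- nrow(centers_px)
  if (is.null(labels)) labels <- tmt_labels(version, n)
  if (length(labels) != n) stop("labels must match the number of targets")
  if (n == 25 && !identical(labels, tmt_labels(version, 25))) {
    stop("a full 25-target layout must use the canonical version ", version,
         " labels")
  }
  if (aoi_diameter <= circle_diameter) {
    stop("aoi_diameter must exceed circle_diameter")
  }
  on_x <- centers_px[, 1] >= 0 & centers_px[, 1] <= geom$res_x_px
  on_y <- centers_px[, 2] >= 0 & centers_px[, 2] <= geom$res_y_px
  if (!all(on_x & on_y)) stop("all target centers must be on-screen")
  structure(
    list(version = version,
         targets = data.frame(label = labels,
                              x_px = centers_px[, 1],
                              y_px = centers_px[, 2]),
         centers_deg = px_to_deg(centers_px, geom),
         circle_diameter = circle_diameter,
         aoi_diameter = aoi_diameter,
         geom = geom),
    class = "tmt_layout"
  )
}

#' @export
print.tmt_layout <- function(x, ...) {
  cat(sprintf("<tmt_layout> version %s, %d targets (circle %g deg, AOI %g deg)\n",
              x$version, nrow(x$targets), x$circle_diameter,
              x$aoi_diameter))
  invisible(x)
}

#' @rdname layout_io
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "tmt_layout"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# version=%s circle_diameter=%g aoi_diameter=%g",
                     layout$version, layout$circle_diameter,
                     layout$aoi_diameter), con)
  utils::write.table(layout$targets, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write target layouts
#'
#' Layouts are stored as TSV (`label`, `x_px`, `y_px`) with a single
#' `#`-prefixed header line carrying the version and diameters.
#'
#' @param layout A `tmt_layout`.
#' @param path File path.
#' @inheritParams target_layout
#' @return `read_layout()` returns a `tmt_layout`; `write_layout()` the
#'   path, invisibly.
#' @name layout_io
#' @export
read_layout <- function(path, geom = screen_geometry()) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(
    sub(".*=", "", kv),
    sub("=.*", "", kv)
  )
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          colClasses = c(label = "character"))
  target_layout(meta[["version"]], as.matrix(df[, c("x_px", "y_px")]),
                labels = df$label,
                circle_diameter = as.numeric(meta[["circle_diameter"]]),
                aoi_diameter = as.numeric(meta[["aoi_diameter"]]),
                geom = geom)
}

#' Classify a fixation against the target layout
#'
#' A fixation is `"guiding"` if its centroid lies within the AOI radius
#' (`aoi_diameter / 2`) of the *current* target's center, `"searching"` if
#' it lies within that radius of any other (past or future) target, and
#' `"unassigned"` otherwise. When the centroid is within the radius of
#' several targets the nearest center wins; exact ties go to the current
#' target.
#'
#' @param centroid Length-2 angular position (deg) of the fixation.
#' @param layout A [target_layout()].
#' @param current_index Index (1-based, click order) of the target that is
#'   current at the fixation's onset.
#' @return A list with `role` (`"guiding"`, `"searching"` or
#'   `"unassigned"`) and `target` (assigned target index, `NA` if
#'   unassigned).
#' @export
classify_fixation <- function(centroid, layout, current_index) {
  stopifnot(inherits(layout, "tmt_layout"))
  n <- nrow(layout$targets)
  if (current_index < 1 || current_index > n) {
    stop("current_index out of range")
  }
  d <- angular_distance(matrix(centroid, nrow = n, ncol = 2, byrow = TRUE),
                        layout$centers_deg)
  within <- which(d <= layout$aoi_diameter / 2)
  if (!length(within)) {
    return(list(role = "unassigned", target = NA_integer_))
  }
  dmin <- min(d[within])
  cand <- within[d[within] == dmin]
  tgt <- if (current_index %in% cand) current_index else cand[1]
  list(role = if (tgt == current_index) "guiding" else "searching",
       target = as.integer(tgt))
}

# Index of the target current at time t: targets advance at the timestamp
# of each hit, inclusively (a fixation starting exactly at a hit belongs to
# the next target).
.current_index_at <- function(t, hit_times, n_targets) {
  pmin(1L + vapply(t, function(tt) sum(hit_times <= tt), integer(1)),
       n_targets)
}

#' A single TMT trial record
#'
#' Bundles the layout, detected (merged) fixations and saccades, click log
#' and condition labels for one trial, with integrity checks: the trial must
#' end with a hit on the final target, hits must advance the sequence one at
#' a time, and all event timestamps must lie within the trial window.
#'
#' @param subject Subject identifier.
#' @param test_type `"A"` or `"B"`.
#' @param instruction `"accuracy"` or `"speed"`.
#' @param start_t Trial start (space-bar press), ms.
#' @param end_t Trial end (final hit), ms.
#' @param fixations,saccades Event data frames (see [detect_events()]),
#'   fixations assumed merged.
#' @param clicks Data frame `t_ms`, `x_px`, `y_px`, `hit` (logical),
#'   `target_index`.
#' @param layout A [target_layout()].
#' @return An object of class `tmt_trial`.
#' @export
trial_record <- function(subject, test_type, instruction, start_t, end_t,
                         fixations, saccades, clicks, layout) {
  test_type <- match.arg(test_type, c("A", "B"))
  instruction <- match.arg(instruction, c("accuracy", "speed"))
  stopifnot(inherits(layout, "tmt_layout"))
  if (!(start_t < end_t)) stop("trial integrity: start_t must precede end_t")
  n <- nrow(layout$targets)
  hits <- clicks[clicks$hit, , drop = FALSE]
  if (!nrow(hits) || !identical(as.integer(hits$target_index),
                                seq_len(n))) {
    stop("trial integrity: hits must advance targets 1..", n,
         " exactly once each")
  }
  if (abs(hits$t_ms[n] - end_t) > 1e-9) {
    stop("trial integrity: end_t must equal the final hit time")
  }
  ts <- c(fixations$onset, fixations$offset, saccades$onset,
          saccades$offset, clicks$t_ms)
  if (length(ts) && (min(ts) < start_t - 1e-9 || max(ts) > end_t + 1e-9)) {
    stop("trial integrity: event timestamps outside [start_t, end_t]")
  }
  structure(
    list(subject = subject, test_type = test_type,
         instruction = instruction, start_t = start_t, end_t = end_t,
         fixations = fixations, saccades = saccades, clicks = clicks,
         layout = layout),
    class = "tmt_trial"
  )
}

#' @export
print.tmt_trial <- function(x, ...) {
  cat(sprintf(
    "<tmt_trial> subject %s, TMT-%s/%s: %.2f s, %d fixations, %d clicks\n",
    x$subject, x$test_type, x$instruction, (x$end_t - x$start_t) / 1000,
    nrow(x$fixations), nrow(x$clicks)))
  invisible(x)
}

#' Classify all fixations of a trial
#'
#' Applies [classify_fixation()] to every fixation, using the target that is
#' current at the fixation's *onset* (a fixation cannot be guided by a
#' target that only becomes current after it ends).
#'
#' @param trial A [trial_record()].
#' @return The trial's fixation data frame with added columns
#'   `current_index`, `role` and `target` (assigned target index).
#' @export
classify_fixations <- function(trial) {
  stopifnot(inherits(trial, "tmt_trial"))
  fx <- trial$fixations
  hits <- trial$clicks[trial$clicks$hit, , drop = FALSE]
  n <- nrow(trial$layout$targets)
  fx$current_index <- if (nrow(fx)) {
    .current_index_at(fx$onset, hits$t_ms, n)
  } else integer(0)
  cls <- lapply(seq_len(nrow(fx)), function(i) {
    classify_fixation(c(fx$x_deg[i], fx$y_deg[i]), trial$layout,
                      fx$current_index[i])
  })
  fx$role <- vapply(cls, `[[`, character(1), "role")
  fx$target <- vapply(cls, `[[`, integer(1), "target")
  fx
}

#' Eye-hand spans of a trial
#'
#' For each target, the span is the time between the onset of the *first*
#' guiding fixation on that target (after it became current and before its
#' hit click) and the hit click itself; the eyes lead the hand, so spans are
#' strictly positive. Targets never fixated while current contribute no
#' span (missing, not zero).
#'
#' @param trial A [trial_record()].
#' @return Named numeric vector of spans in seconds (names are target
#'   labels); length 0 if no target had a qualifying guiding fixation.
#' @export
eye_hand_span <- function(trial) {
  stopifnot(inherits(trial, "tmt_trial"))
  fx <- classify_fixations(trial)
  hits <- trial$clicks[trial$clicks$hit, , drop = FALSE]
  n <- nrow(trial$layout$targets)
  spans <- numeric(0)
  for (k in seq_len(n)) {
    t_hit <- hits$t_ms[k]
    became <- if (k == 1) trial$start_t else hits$t_ms[k - 1]
    cand <- fx[fx$role == "guiding" & fx$target == k &
                 fx$onset >= became & fx$onset < t_hit, , drop = FALSE]
    if (nrow(cand)) {
      s <- (t_hit - min(cand$onset)) / 1000
      spans <- c(spans, stats::setNames(s, trial$layout$targets$label[k]))
    }
  }
  spans
}

#' Scanpath length over a fixation sequence
#'
#' Sum of Euclidean angular distances between consecutive fixation
#' centroids; 0 for fewer than two fixations.
#'
#' @param fixations Fixation data frame ordered by onset (columns `x_deg`,
#'   `y_deg`).
#' @return Total length in degrees of visual angle.
#' @export
scanpath_length <- function(fixations) {
  n <- nrow(fixations)
  if (is.null(n) || n < 2) return(0)
  sum(sqrt(diff(fixations$x_deg)^2 + diff(fixations$y_deg)^2))
}

#' Score one trial
#'
#' Computes the eight trial-level test scores: trial duration (s), mean
#' fixation duration (ms), mean saccade amplitude (deg), number of
#' fixations, numbers of guiding and searching fixations, mean eye-hand
#' span (s) and scanpath length (deg). Fixations on no AOI are
#' "unassigned": counted in `n_fixations` (unless
#' `include_unassigned = FALSE`) but in neither subtype, so
#' `n_guiding + n_searching <= n_fixations`.
#'
#' @param trial A [trial_record()].
#' @param include_unassigned Should unassigned fixations count towards
#'   `n_fixations`? Default `TRUE`.
#' @return One-row data frame with columns `subject`, `test_type`,
#'   `instruction`, `trial_duration`, `mean_fixation_duration`,
#'   `mean_saccade_amplitude`, `n_fixations`, `n_guiding`, `n_searching`,
#'   `mean_eye_hand_span`, `scanpath_length`.
#' @export
score_trial <- function(trial, include_unassigned = TRUE) {
  stopifnot(inherits(trial, "tmt_trial"))
  fx <- classify_fixations(trial)
  spans <- eye_hand_span(trial)
  n_fix <- if (include_unassigned) nrow(fx) else sum(fx$role != "unassigned")
  data.frame(
    subject = trial$subject,
    test_type = trial$test_type,
    instruction = trial$instruction,
    trial_duration = (trial$end_t - trial$start_t) / 1000,
    mean_fixation_duration = if (nrow(fx)) mean(fx$duration) else NA_real_,
    mean_saccade_amplitude = if (nrow(trial$saccades)) {
      mean(trial$saccades$amplitude)
    } else NA_real_,
    n_fixations = n_fix,
    n_guiding = sum(fx$role == "guiding"),
    n_searching = sum(fx$role == "searching"),
    mean_eye_hand_span = if (length(spans)) mean(spans) else NA_real_,
    scanpath_length = scanpath_length(fx),
    stringsAsFactors = FALSE
  )
}

#' Score a list of trials
#'
#' @param trials List of [trial_record()] objects.
#' @inheritParams score_trial
#' @return Long-format data frame, one row per trial.
#' @export
score_trials <- function(trials, include_unassigned = TRUE) {
  do.call(rbind, lapply(trials, score_trial,
                        include_unassigned = include_unassigned))
}

#' Average repeated trials into one row per design cell
#'
#' Collapses a trial-level score table to one row per
#' subject x test_type x instruction cell (mean of each measure, `NA`
#' ignored), the unit of analysis for the mixed models.
#'
#' @param scores Score table from [score_trials()] or [read_scores()].
#' @return Aggregated score table.
#' @export
aggregate_scores <- function(scores) {
  measures <- .score_measures()
  out <- stats::aggregate(scores[measures],
                          by = scores[c("subject", "test_type",
                                        "instruction")],
                          FUN = function(v) mean(v, na.rm = TRUE))
  for (m in measures) out[[m]][is.nan(out[[m]])] <- NA_real_
  out[order(out$subject, out$test_type, out$instruction), , drop = FALSE]
}

.score_measures <- function() {
  c("trial_duration", "mean_fixation_duration", "mean_saccade_amplitude",
    "n_fixations", "n_guiding", "n_searching", "mean_eye_hand_span",
    "scanpath_length")
}

#' Read and write long-format score tables
#'
#' Tab-separated text with exactly the score columns of [score_trial()].
#'
#' @param scores Score table.
#' @param path File path.
#' @return `read_scores()` returns the score data frame; `write_scores()`
#'   the path, invisibly.
#' @name scores_io
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname scores_io
#' @export
read_scores <- function(path) {
  utils::read.delim(path, sep = "\t",
                    colClasses = c(subject = "character"))
}
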