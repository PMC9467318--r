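#' Detect fixations, saccades and blinks in a gaze-sample stream
#'
#' Parses a raw gaze recording into oculomotor events. Samples are first
#' converted to degrees of visual angle ([px_to_deg()]); angular speed is
#' estimated by central differences over `smooth_window` samples and
#' acceleration by a central difference of the speed signal. A sample is
#' labelled saccadic while speed exceeds `vel_thresh` OR |acceleration|
#' exceeds `acc_thresh`; maximal runs of saccadic samples become saccades and
#' the intervening runs become fixations. Runs of two or more invalid
#' samples become blink intervals that terminate any open event (events are
#' never interpolated across blinks); isolated single invalid samples are
#' skipped without splitting.
#'
#' Event boundaries tile the recording: within a valid segment, an event's
#' offset is the timestamp of the first sample of the next event (the last
#' sample for the final event of a segment), so fixation, saccade and gap
#' durations sum to the valid recording span.
#'
#' @param samples Data frame with columns `t_ms` (strictly increasing),
#'   `x_px`, `y_px`, `valid` (logical).
#' @param params A [detection_params()].
#' @param geom A [screen_geometry()].
#'
#' @return An object of class `gaze_events`: a list with data frames
#'   `fixations` (`onset`, `offset`, `duration` ms, centroid `x_deg`,
#'   `y_deg`), `saccades` (`onset`, `offset`, `duration`, `amplitude` deg,
#'   `peak_velocity` deg/s) and `blinks` (`onset`, `offset`).
#' @export
detect_events <- function(samples, params = detection_params(),
                          geom = screen_geometry()) {
  stopifnot(inherits(params, "detection_params"),
            inherits(geom, "screen_geometry"))
  samples <- .validate_samples(samples)
  n <- nrow(samples)
  ok <- samples$valid & is.finite(samples$x_px) & is.finite(samples$y_px)

  empty <- .empty_events()
  if (sum(ok) < 2) {
    warning("fewer than 2 valid gaze samples; no events detected")
    return(empty)
  }

  # Blink intervals: runs of >= 2 invalid samples.
  r <- rle(!ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blink_runs <- which(r$values & r$lengths >= 2L)
  blinks <- data.frame(onset = samples$t_ms[starts[blink_runs]],
                       offset = samples$t_ms[ends[blink_runs]])

  # Valid segments: maximal index ranges between blink runs; single invalid
  # samples inside a segment are dropped without splitting it.
  if (length(blink_runs)) {
    cuts <- cbind(starts[blink_runs] - 1L, ends[blink_runs] + 1L)
    seg_starts <- c(1L, cuts[, 2])
    seg_ends <- c(cuts[, 1], n)
  } else {
    seg_starts <- 1L
    seg_ends <- n
  }

  fix_list <- list()
  sac_list <- list()
  for (s in seq_along(seg_starts)) {
    idx <- seq.int(seg_starts[s], length.out = max(0L, seg_ends[s] - seg_starts[s] + 1L))
    idx <- idx[ok[idx]]
    if (length(idx) < 2) next
    seg <- .parse_segment(samples$t_ms[idx],
                          px_to_deg(cbind(samples$x_px[idx],
                                          samples$y_px[idx]), geom),
                          params)
    fix_list[[length(fix_list) + 1L]] <- seg$fixations
    sac_list[[length(sac_list) + 1L]] <- seg$saccades
  }

  fixations <- do.call(rbind, c(fix_list, list(empty$fixations)))
  saccades <- do.call(rbind, c(sac_list, list(empty$saccades)))
  fixations <- fixations[order(fixations$onset), , drop = FALSE]
  saccades <- saccades[order(saccades$onset), , drop = FALSE]
  rownames(fixations) <- rownames(saccades) <- NULL

  if (params$min_fix_dur > 0) {
    fixations <- fixations[fixations$duration >= params$min_fix_dur, ,
                           drop = FALSE]
  }

  structure(list(fixations = fixations, saccades = saccades,
                 blinks = blinks),
            class = "gaze_events")
}

.validate_samples <- function(samples) {
  need <- c("t_ms", "x_px", "y_px", "valid")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    stop("samples must be a data frame with columns t_ms, x_px, y_px, valid")
  }
  if (nrow(samples) && any(diff(samples$t_ms) <= 0)) {
    stop("sample timestamps must be strictly increasing")
  }
  samples$valid <- as.logical(samples$valid)
  samples
}

.empty_events <- function() {
  list(
    fixations = data.frame(onset = numeric(0), offset = numeric(0),
                           duration = numeric(0), x_deg = numeric(0),
                           y_deg = numeric(0)),
    saccades = data.frame(onset = numeric(0), offset = numeric(0),
                          duration = numeric(0), amplitude = numeric(0),
                          peak_velocity = numeric(0)),
    blinks = data.frame(onset = numeric(0), offset = numeric(0))
  )
}

# Speed (deg/s) by central differences over a window of w samples (clamped
# one-sided at segment edges), and acceleration (deg/s^2) as the central
# difference of the speed signal.
.segment_kinematics <- function(t, pos, w) {
  m <- length(t)
  h <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(m) - h, 1L)
  hi <- pmin(seq_len(m) + h, m)
  dt <- (t[hi] - t[lo]) / 1000                       # s
  speed <- sqrt((pos[hi, 1] - pos[lo, 1])^2 +
                  (pos[hi, 2] - pos[lo, 2])^2) / dt  # deg/s
  alo <- pmax(seq_len(m) - 1L, 1L)
  ahi <- pmin(seq_len(m) + 1L, m)
  accel <- (speed[ahi] - speed[alo]) / ((t[ahi] - t[alo]) / 1000)
  list(speed = speed, accel = accel)
}

.parse_segment <- function(t, pos, params) {
  m <- length(t)
  kin <- .segment_kinematics(t, pos, params$smooth_window)
  lab <- kin$speed > params$vel_thresh | abs(kin$accel) > params$acc_thresh

  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # Tiling offsets: next run's first timestamp, last sample at segment end.
  off_idx <- ifelse(ends < m, ends + 1L, m)

  sac <- which(r$values)
  fix <- which(!r$values & r$lengths >= 2L)

  saccades <- data.frame(
    onset = t[starts[sac]],
    offset = t[off_idx[sac]],
    amplitude = angular_distance(pos[starts[sac], , drop = FALSE],
                                 pos[ends[sac], , drop = FALSE]),
    peak_velocity = vapply(sac, function(k) {
      max(kin$speed[starts[k]:ends[k]])
    }, numeric(1))
  )
  saccades$duration <- saccades$offset - saccades$onset
  saccades <- saccades[, c("onset", "offset", "duration", "amplitude",
                           "peak_velocity")]

  fixations <- data.frame(
    onset = t[starts[fix]],
    offset = t[off_idx[fix]],
    x_deg = vapply(fix, function(k) mean(pos[starts[k]:ends[k], 1]),
                   numeric(1)),
    y_deg = vapply(fix, function(k) mean(pos[starts[k]:ends[k], 2]),
                   numeric(1))
  )
  fixations$duration <- fixations$offset - fixations$onset
  fixations <- fixations[, c("onset", "offset", "duration", "x_deg",
                             "y_deg")]
  list(fixations = fixations, saccades = saccades)
}

#' @export
print.gaze_events <- function(x, ...) {
  cat(sprintf("<gaze_events> %d fixations, %d saccades, %d blinks\n",
              nrow(x$fixations), nrow(x$saccades), nrow(x$blinks)))
  invisible(x)
}

#' Merge nearby fixations
#'
#' Consecutive fixations whose centroids are less than `merge_dist` apart
#' are replaced by a single fixation spanning from the onset of the first to
#' the offset of the second, with a duration-weighted mean centroid. The
#' rule is applied iteratively left-to-right until stable, so a freshly
#' merged fixation is immediately re-checked against its successor using the
#' merged centroid.
#'
#' @param fixations Fixation data frame as produced by [detect_events()],
#'   ordered by onset.
#' @param params A [detection_params()]; only `merge_dist` is used.
#' @return A fixation data frame of the same shape.
#' @export
merge_fixations <- function(fixations, params = detection_params()) {
  if (nrow(fixations) < 2) return(fixations)
  fx <- fixations
  i <- 1L
  while (i < nrow(fx)) {
    d <- angular_distance(c(fx$x_deg[i], fx$y_deg[i]),
                          c(fx$x_deg[i + 1L], fx$y_deg[i + 1L]))
    if (d < params$merge_dist) {
      w <- c(fx$duration[i], fx$duration[i + 1L])
      if (sum(w) <= 0) w <- c(1, 1)
      fx$x_deg[i] <- sum(w * c(fx$x_deg[i], fx$x_deg[i + 1L])) / sum(w)
      fx$y_deg[i] <- sum(w * c(fx$y_deg[i], fx$y_deg[i + 1L])) / sum(w)
      fx$offset[i] <- fx$offset[i + 1L]
      fx$duration[i] <- fx$offset[i] - fx$onset[i]
      fx <- fx[-(i + 1L), , drop = FALSE]
    } else {
      i <- i + 1L
    }
  }
  rownames(fx) <- NULL
  fx
}

# Remove saccades absorbed by fixation merging (fully inside a fixation
# span), mirroring the merge semantics of online parsers.
.absorb_saccades <- function(saccades, fixations) {
  if (!nrow(saccades) || !nrow(fixations)) return(saccades)
  keep <- vapply(seq_len(nrow(saccades)), function(i) {
    !any(saccades$onset[i] >= fixations$onset &
           saccades$offset[i] <= fixations$offset)
  }, logical(1))
  out <- saccades[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect events and apply fixation merging in one step
#'
#' Convenience wrapper: [detect_events()], then [merge_fixations()], then
#' removal of saccades absorbed into merged fixations.
#'
#' @inheritParams detect_events
#' @return A `gaze_events` object with merged fixations.
#' @export
process_gaze <- function(samples, params = detection_params(),
                         geom = screen_geometry()) {
  ev <- detect_events(samples, params, geom)
  ev$fixations <- merge_fixations(ev$fixations, params)
  ev$saccades <- .absorb_saccades(ev$saccades, ev$fixations)
  ev
}

#' Read and write gaze-sample and event tables
#'
#' Gaze samples are exchanged as tab-separated text with header
#' `t_ms, x_px, y_px, valid`; events as TSV with an `event` type column and
#' the union of fixation/saccade/blink columns (`NA` where not applicable).
#'
#' @param path File path.
#' @param samples Gaze-sample data frame.
#' @param events A `gaze_events` object.
#' @return `read_gaze()` returns a gaze-sample data frame; `read_events()`
#'   returns a `gaze_events` object; the writers return the path invisibly.
#' @name gaze_io
NULL

#' @rdname gaze_io
#' @export
read_gaze <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  .validate_samples(df)
}

#' @rdname gaze_io
#' @export
write_gaze <- function(samples, path) {
  samples <- .validate_samples(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname gaze_io
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "gaze_events"))
  cols <- c("event", "onset", "offset", "duration", "x_deg", "y_deg",
            "amplitude", "peak_velocity")
  pad <- function(df, type) {
    if (!nrow(df)) {
      return(stats::setNames(as.data.frame(matrix(numeric(0), 0,
                                                  length(cols))), cols))
    }
    df$event <- type
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA_real_
    df[, cols]
  }
  out <- rbind(pad(events$fixations, "fixation"),
               pad(events$saccades, "saccade"),
               pad(events$blinks, "blink"))
  out <- out[order(out$onset), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname gaze_io
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  pick <- function(type, cols) {
    out <- df[df$event == type, cols, drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(
    list(fixations = pick("fixation",
                          c("onset", "offset", "duration", "x_deg", "y_deg")),
         saccades = pick("saccade",
                         c("onset", "offset", "duration", "amplitude",
                           "peak_velocity")),
         blinks = pick("blink", c("onset", "offset"))),
    class = "gaze_events"
  )
}
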