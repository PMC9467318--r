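#' Screen geometry for gaze-angle conversion
#'
#' Describes the physical display and viewing distance needed to convert
#' gaze positions from screen pixels to degrees of visual angle. Defaults
#' correspond to a 19-inch CRT at 1024 x 768 (36 cm x 27 cm) viewed from
#' 71 cm, a common desktop eye-tracking setup.
#'
#' @param width_cm,height_cm Physical display size in cm.
#' @param res_x_px,res_y_px Display resolution in pixels.
#' @param distance_cm Viewing (eye-to-screen) distance in cm.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(c(612, 384), geom)
#' @export
screen_geometry <- function(width_cm = 36, height_cm = 27,
                            res_x_px = 1024, res_y_px = 768,
                            distance_cm = 71) {
  vals <- c(width_cm = width_cm, height_cm = height_cm,
            res_x_px = res_x_px, res_y_px = res_y_px,
            distance_cm = distance_cm)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be strictly positive and finite")
  }
  structure(
    list(width_cm = width_cm, height_cm = height_cm,
         res_x_px = res_x_px, res_y_px = res_y_px,
         distance_cm = distance_cm,
         pitch_x = width_cm / res_x_px,
         pitch_y = height_cm / res_y_px,
         center_px = c(res_x_px / 2, res_y_px / 2)),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %g x %g px (%g x %g cm) at %g cm\n",
              x$res_x_px, x$res_y_px, x$width_cm, x$height_cm,
              x$distance_cm))
  invisible(x)
}

# Coerce a pixel/degree position argument to an n x 2 numeric matrix.
.as_xy <- function(p, what = "position") {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) {
    if (length(p) != 2) stop(what, " must have exactly two coordinates")
    p <- matrix(as.numeric(p), nrow = 1)
  }
  p <- unname(as.matrix(p))
  if (ncol(p) != 2) stop(what, " must be a 2-column matrix or length-2 vector")
  storage.mode(p) <- "double"
  p
}

#' Convert screen-pixel positions to degrees of visual angle
#'
#' Uses a per-axis arctangent about the screen center (not a small-angle
#' linearization): theta = atan((p - center) * pitch / distance). The screen
#' center maps to (0, 0); x increases rightward and y downward, matching the
#' pixel convention.
#'
#' @param p A length-2 vector `(x_px, y_px)` or an n x 2 matrix/data frame.
#' @param geom A [screen_geometry()].
#'
#' @return An n x 2 matrix with columns `theta_x`, `theta_y` (degrees), or a
#'   length-2 vector if `p` was a vector.
#' @seealso [deg_to_px()] for the exact inverse.
#' @export
px_to_deg <- function(p, geom = screen_geometry()) {
  stopifnot(inherits(geom, "screen_geometry"))
  vec <- is.null(dim(p))
  p <- .as_xy(p, "pixel position")
  if (!all(is.finite(p))) stop("non-finite pixel coordinate")
  out <- cbind(
    theta_x = atan((p[, 1] - geom$center_px[1]) * geom$pitch_x /
                     geom$distance_cm) * 180 / pi,
    theta_y = atan((p[, 2] - geom$center_px[2]) * geom$pitch_y /
                     geom$distance_cm) * 180 / pi
  )
  if (vec) c(out) else out
}

#' Convert degrees of visual angle to screen-pixel positions
#'
#' Exact inverse of [px_to_deg()].
#'
#' @param theta A length-2 vector `(theta_x, theta_y)` in degrees or an
#'   n x 2 matrix.
#' @inheritParams px_to_deg
#' @return Pixel coordinates in the same shape as the input.
#' @export
deg_to_px <- function(theta, geom = screen_geometry()) {
  stopifnot(inherits(geom, "screen_geometry"))
  vec <- is.null(dim(theta))
  theta <- .as_xy(theta, "angular position")
  if (!all(is.finite(theta))) stop("non-finite angular coordinate")
  out <- cbind(
    x_px = geom$center_px[1] +
      tan(theta[, 1] * pi / 180) * geom$distance_cm / geom$pitch_x,
    y_px = geom$center_px[2] +
      tan(theta[, 2] * pi / 180) * geom$distance_cm / geom$pitch_y
  )
  if (vec) c(out) else out
}

#' Euclidean distance in degree-of-visual-angle space
#'
#' Distances between angular positions are Euclidean in `(theta_x, theta_y)`
#' space, the convention used throughout for saccade amplitudes, fixation
#' merging, AOI classification and scanpath length.
#'
#' @param a,b Length-2 vectors or n x 2 matrices of angular positions
#'   (degrees).
#' @return Numeric vector of distances (degrees).
#' @export
angular_distance <- function(a, b) {
  a <- .as_xy(a, "angular position")
  b <- .as_xy(b, "angular position")
  sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
}

#' Event-detection parameters
#'
#' Thresholds for saccade/fixation parsing of a gaze-sample stream. The
#' defaults mirror a standard video-oculography online parser: a saccade is
#' flagged while angular velocity exceeds 30 deg/s or absolute acceleration
#' exceeds 8000 deg/s^2; fixations closer than 1 degree are merged.
#'
#' @param vel_thresh Saccade velocity threshold (deg/s).
#' @param acc_thresh Saccade acceleration threshold (deg/s^2). Set to `Inf`
#'   for a pure velocity criterion.
#' @param merge_dist Centroid distance below which consecutive fixations are
#'   merged (deg).
#' @param min_fix_dur Minimum fixation duration (ms); 0 keeps everything.
#' @param smooth_window Odd number of samples for the central-difference
#'   velocity estimate (default 3, i.e. one sample each side).
#'
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(vel_thresh = 30, acc_thresh = 8000,
                             merge_dist = 1, min_fix_dur = 0,
                             smooth_window = 3) {
  if (any(c(vel_thresh, merge_dist, min_fix_dur) < 0) || acc_thresh < 0) {
    stop("detection parameters must be non-negative")
  }
  if (smooth_window < 3 || smooth_window %% 2 != 1) {
    stop("smooth_window must be an odd integer >= 3")
  }
  structure(
    list(vel_thresh = vel_thresh, acc_thresh = acc_thresh,
         merge_dist = merge_dist, min_fix_dur = min_fix_dur,
         smooth_window = as.integer(smooth_window)),
    class = "detection_params"
  )
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(paste0("<detection_params> vel %g deg/s, acc %g deg/s^2, ",
                     "merge %g deg, min fix %g ms, window %d\n"),
              x$vel_thresh, x$acc_thresh, x$merge_dist, x$min_fix_dur,
              x$smooth_window))
  invisible(x)
}
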