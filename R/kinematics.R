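#' Kinematic series
#'
#' One per-frame kinematic parameter for one trial. Two series types
#' exist: "frame" series (beak distance, beak angle) with one value per
#' frame, and "step" series (movement) with one value per consecutive
#' frame pair — entry t is the displacement between frames t-1 and t
#' (0-based), so a step series has one entry fewer than the track has
#' frames. Values are `NA` wherever any input landmark is missing.
#'
#' @param parameter parameter name, e.g. "beak_distance".
#' @param values numeric vector with NA for missing.
#' @param unit "px" or "deg".
#' @param trial_id source trial.
#' @param series_type "frame" or "step".
#' @return an object of class `kinematic_series`.
#' @export
kinematic_series <- function(parameter, values, unit, trial_id,
                             series_type = c("frame", "step")) {
  structure(list(parameter = parameter, unit = unit,
                 trial_id = trial_id, values = as.numeric(values),
                 series_type = match.arg(series_type)),
            class = "kinematic_series")
}

#' @method print kinematic_series
#' @export
print.kinematic_series <- function(x, ...) {
  v <- x$values
  cat(sprintf("<kinematic_series '%s' (%s), trial '%s'>\n",
              x$parameter, x$unit, x$trial_id))
  cat(sprintf("  %d %s values, %.2f%% missing",
              length(v), x$series_type, 100 * mean(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("; range [%.3g, %.3g]", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @method as.data.frame kinematic_series
#' @export
as.data.frame.kinematic_series <- function(x, ...) {
  data.frame(trial_id = x$trial_id, parameter = x$parameter,
             frame = seq_along(x$values) - 1L, value = x$values)
}

#' Beak distance
#'
#' Per-frame Euclidean distance in pixels between the upper and lower
#' beak landmarks, d = sqrt((xu - xl)^2 + (yu - yl)^2). A wider gap means
#' a more open beak; the parameter quantifies beak-opening responses.
#' Missing whenever either landmark is missing that frame.
#'
#' @param view a `bound_track` from [bind_scheme].
#' @return a [kinematic_series] ("frame" type, px).
#' @export
beak_distance <- function(view) {
  u <- role_xy(view, "beak_upper"); l <- role_xy(view, "beak_lower")
  kinematic_series("beak_distance", sqrt((u$x - l$x)^2 + (u$y - l$y)^2),
                   "px", view$track$trial_id, "frame")
}

#' Beak angle
#'
#' Per-frame unsigned angle, in degrees, at the beak fulcrum P0 between
#' the rays P0->P1 (upper beak) and P0->P2 (lower beak):
#' alpha = atan2(|det(n2; n1)|, dot(n2, n1)), where n1, n2 are the unit
#' vectors along the two rays, det is the 2x2 determinant and |.| the
#' absolute value. The result lies in \[0, 180\] and equals the clamped
#' arccos of the unit-vector dot product. When P1 or P2 coincides with P0
#' the angle is undefined and the value is missing, as it is whenever any
#' of the three landmarks is missing.
#'
#' @param view a `bound_track` from [bind_scheme].
#' @return a [kinematic_series] ("frame" type, deg).
#' @export
beak_angle <- function(view) {
  p0 <- role_xy(view, "beak_fulcrum")
  p1 <- role_xy(view, "beak_upper")
  p2 <- role_xy(view, "beak_lower")
  u1x <- p1$x - p0$x; u1y <- p1$y - p0$y
  u2x <- p2$x - p0$x; u2y <- p2$y - p0$y
  n1 <- sqrt(u1x^2 + u1y^2); n2 <- sqrt(u2x^2 + u2y^2)
  degen <- !is.na(n1) & !is.na(n2) & (n1 == 0 | n2 == 0)
  u1x <- u1x / n1; u1y <- u1y / n1
  u2x <- u2x / n2; u2y <- u2y / n2
  dt <- abs(u2x * u1y - u2y * u1x)   # |det(n2; n1)| = |sin alpha|
  dp <- u2x * u1x + u2y * u1y        # dot(n2, n1)   =  cos alpha
  a <- atan2(dt, dp) * 180 / pi
  a[degen] <- NA_real_
  kinematic_series("beak_angle", a, "deg", view$track$trial_id, "frame")
}

#' Landmark movement
#'
#' Per-step Euclidean displacement in pixels of one landmark between
#' consecutive frames, d = sqrt((x_f1 - x_f2)^2 + (y_f1 - y_f2)^2).
#' Strictly adjacent frames only: if either endpoint frame is missing,
#' the step is missing (displacement is never computed across a masked
#' gap). Used for eye-corner (head), elbow and leg movement, and for
#' stationary reference points as negative controls.
#'
#' @param view a `bound_track` from [bind_scheme].
#' @param role a movement role ("eye_corner", "elbow", "leg") or a
#'   reference-point label.
#' @return a [kinematic_series] ("step" type, px) with
#'   `n_frames(track) - 1` entries.
#' @export
movement <- function(view, role) {
  p <- role_xy(view, role)
  dx <- diff(p$x); dy <- diff(p$y)
  kinematic_series(paste0("movement_", role), sqrt(dx^2 + dy^2),
                   "px", view$track$trial_id, "step")
}
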