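# Signal primitives shared by the detector, the generators and the
# evaluation code.

#' Acceleration signal magnitude vector
#'
#' Euclidean norm of a tri-axial accelerometer reading,
#' \eqn{|a| = \sqrt{A_x^2 + A_y^2 + A_z^2}}, in units of g. At rest the
#' magnitude is 1 g (gravity); it drops towards 0 g while the body is in
#' free fall and spikes above 2 g on impact or vigorous movement, which is
#' why the detector thresholds this single scalar rather than any one axis:
#' the norm is invariant to how the device is oriented on the body.
#'
#' @param ax,ay,az acceleration components in g. Vectors are accepted and
#'   recycled to a common length.
#' @return Numeric vector of magnitudes in g (non-negative).
#' @examples
#' accel_magnitude(1, 0, 0)        # 1: device at rest
#' accel_magnitude(0.3, 0.4, 1.2)  # 1.3
#' @export
accel_magnitude <- function(ax, ay, az) {
  if (!is.numeric(ax) || !is.numeric(ay) || !is.numeric(az))
    stop("acceleration components must be numeric")
  n <- max(length(ax), length(ay), length(az))
  ax <- rep_len(ax, n); ay <- rep_len(ay, n); az <- rep_len(az, n)
  if (any(!is.finite(ax)) || any(!is.finite(ay)) || any(!is.finite(az)))
    stop("acceleration components must be finite")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Is a heart-rate reading outside the normal range?
#'
#' A reading is abnormal when it lies strictly outside the configured normal
#' range `[nhr_low, nhr_high]` (default 60--100 bpm); the bounds themselves
#' count as normal. Below the range is bradycardia, above is tachycardia --
#' either one arms the fall detector.
#'
#' @param hr heart rate(s) in bpm; must be positive.
#' @param cfg a [detector_config()].
#' @return Logical vector, `TRUE` where the reading is abnormal.
#' @examples
#' is_hr_abnormal(80)    # FALSE
#' is_hr_abnormal(114)   # TRUE (tachycardia)
#' is_hr_abnormal(60)    # FALSE: bounds are normal
#' @export
is_hr_abnormal <- function(hr, cfg = detector_config()) {
  cfg <- as_detector_config(cfg)
  if (!is.numeric(hr) || any(!is.finite(hr)) || any(hr <= 0))
    stop("heart rate must be finite and positive (bpm)")
  hr < cfg$nhr_low | hr > cfg$nhr_high
}
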