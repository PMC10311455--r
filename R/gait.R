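#' Gait waveform specification
#'
#' Describes the periodic knee-flexion waveform the hexapod replays: a child
#' walking stride (defaults: 1 s stride sampled at 100 Hz, 15 cycles).  The
#' waveform is a periodic cubic spline through `keypoints` — a two-column
#' matrix of (gait-percent, knee angle in degrees) control points whose first
#' and last angles must match so cycles join smoothly.  The default keypoints
#' sketch the canonical two-peak paediatric walking pattern (stance flexion
#' peak near 20 deg, swing peak near 65 deg); they are a generator convention,
#' meant to be replaced with digitized subject data where available.
#'
#' @param stride_time stride duration (s).
#' @param sample_rate output sampling rate (Hz).
#' @param n_cycles number of gait cycles to generate.
#' @param keypoints two-column matrix / data frame: gait percent in `[0, 100]`
#'   and knee angle (degrees).
#' @param amplitude_scale multiplicative scale applied to the keypoint angles.
#' @return an object of class `gait_waveform_spec`.
#' @export
gait_waveform_spec <- function(stride_time = 1, sample_rate = 100,
                               n_cycles = 15,
                               keypoints = default_gait_keypoints(),
                               amplitude_scale = 1) {
  check_number(stride_time, "stride_time", 0, strict_lower = TRUE)
  check_number(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  check_number(n_cycles, "n_cycles", 1)
  check_number(amplitude_scale, "amplitude_scale", 0, strict_lower = TRUE)
  kp <- as.matrix(keypoints)
  if (ncol(kp) != 2L || nrow(kp) < 2L)
    stop_invalid("'keypoints' must be a >=2-row, 2-column (percent, degrees) table")
  if (is.unsorted(kp[, 1], strictly = TRUE) ||
      kp[1, 1] != 0 || kp[nrow(kp), 1] != 100)
    stop_invalid("keypoint gait-percents must increase strictly from 0 to 100")
  if (abs(kp[1, 2] - kp[nrow(kp), 2]) > 1e-9)
    stop_invalid("waveform must be periodic: first and last keypoint angles must match")
  structure(list(stride_time = stride_time, sample_rate = sample_rate,
                 n_cycles = as.integer(n_cycles), keypoints = kp,
                 amplitude_scale = amplitude_scale),
            class = "gait_waveform_spec")
}

#' @rdname gait_waveform_spec
#' @export
default_gait_keypoints <- function() {
  cbind(percent = c(0, 15, 40, 72, 100),
        angle_deg = c(5, 20, 8, 65, 5))
}

#' Generate a knee-angle gait waveform
#'
#' Evaluates the periodic spline through the spec's keypoints over one stride
#' and tiles it `n_cycles` times, giving a C2-continuous waveform across cycle
#' boundaries.  Errors if the interpolated waveform (spline overshoot
#' included) leaves the phantom's 2--81 degree mechanical range.
#'
#' @param spec a [gait_waveform_spec()].
#' @return a [knee_trajectory()] with `n_cycles * stride_time * sample_rate`
#'   samples.
#' @examples
#' traj <- generate_gait_waveform(gait_waveform_spec(n_cycles = 2))
#' range(rad2deg(traj$theta_k))
#' @export
generate_gait_waveform <- function(spec) {
  stopifnot(inherits(spec, "gait_waveform_spec"))
  ang <- spec$keypoints[, 2] * spec$amplitude_scale
  tk <- spec$keypoints[, 1] / 100 * spec$stride_time
  f <- stats::splinefun(tk, ang, method = "periodic")
  n_per <- round(spec$stride_time * spec$sample_rate)
  if (abs(n_per - spec$stride_time * spec$sample_rate) > 1e-9)
    stop_invalid("stride_time * sample_rate must be an integer number of samples")
  t_cycle <- seq(0, by = 1 / spec$sample_rate, length.out = n_per)
  # probe on a fine grid so spline overshoot beyond the keypoints is caught
  probe <- f(seq(0, spec$stride_time, length.out = 2000))
  if (min(probe) < 2 - 1e-9 || max(probe) > 81 + 1e-9)
    stop_invalid(paste0(
      "gait waveform [%.2f, %.2f] deg leaves the phantom mechanical ",
      "range [2, 81] deg; adjust keypoints or amplitude_scale"),
      min(probe), max(probe))
  one <- f(t_cycle)
  time <- seq(0, by = 1 / spec$sample_rate,
              length.out = n_per * spec$n_cycles)
  knee_trajectory(time, deg2rad(rep(one, spec$n_cycles)))
}
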