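#' Zero-phase low-pass Butterworth filter
#'
#' A 4th-order (by default) low-pass Butterworth design applied
#' forward-backward, giving zero phase lag and unit DC gain; the effective
#' magnitude response is the squared single-pass response,
#' `|H(f)|^2 = 1 / (1 + (f/fc)^(2*order))`.  The order is per pass (no
#' cutoff-frequency correction is applied), matching common motion-capture
#' practice.  Edge transients are reduced by odd-reflection padding of about
#' three filter time constants before filtering.
#'
#' @param x numeric series sampled uniformly at `fs`.
#' @param fs sampling rate (Hz).
#' @param cutoff low-pass cutoff frequency (Hz); must be below Nyquist.
#' @param order filter order per pass.
#' @return the filtered series, same length as `x`.
#' @export
zero_phase_lowpass <- function(x, fs, cutoff = 6, order = 4) {
  check_number(fs, "fs", 0, strict_lower = TRUE)
  check_number(cutoff, "cutoff", 0, strict_lower = TRUE)
  check_number(order, "order", 1)
  if (cutoff >= fs / 2)
    stop_invalid("cutoff (%.3g Hz) must be below the Nyquist frequency (%.3g Hz)",
                 cutoff, fs / 2)
  if (any(!is.finite(x))) stop_invalid("series contains non-finite values")
  n <- length(x)
  if (n < 8L) stop_invalid("series too short to filter (need >= 8 samples)")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  p <- min(n - 1L, as.integer(ceiling(6 * fs / cutoff)))
  padded <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  # filter relative to the first sample of each pass: the unit DC gain makes
  # the offset exact and removes the step transient of zero initial state
  one_pass <- function(v) {
    off <- v[1]
    as.numeric(signal::filter(bf, v - off)) + off
  }
  y <- rev(one_pass(rev(one_pass(padded))))
  y[(p + 1):(p + n)]
}

#' Cubic-spline resampling to a higher rate
#'
#' Interpolates a uniformly sampled series onto a uniform grid at
#' `target_rate` spanning the same interval, using a cubic spline
#' (Forsythe-Malcolm-Moler end conditions, so cubic polynomials are
#' reproduced exactly).  Original samples are reproduced at coincident times.
#'
#' @param time time stamps (s), uniform.
#' @param x series values.
#' @param target_rate output rate (Hz).
#' @return a list with `time` and `x` on the target grid.
#' @export
resample_spline <- function(time, x, target_rate) {
  if (length(time) < 4L)
    stop_invalid("need at least 4 samples for spline resampling")
  check_uniform_time(time)
  check_number(target_rate, "target_rate", 0, strict_lower = TRUE)
  f <- stats::splinefun(time, x, method = "fmm")
  n_out <- floor((time[length(time)] - time[1]) * target_rate + 1e-9) + 1
  t_out <- time[1] + seq(0, by = 1 / target_rate, length.out = n_out)
  list(time = t_out, x = f(t_out))
}

# expected marker column sets
joint_marker_names <- function() {
  paste0(rep(c("hip", "knee", "ankle"), each = 2), c("_med", "_lat"))
}
marker_cols <- function(marker) paste0(marker, c("_x", "_y", "_z"))

#' Joint centres from medial/lateral marker pairs
#'
#' The midpoint of each joint's medial and lateral markers gives its centre of
#' rotation; projection onto the sagittal (x, y) plane then drops the
#' mediolateral coordinate.
#'
#' @param markers a marker recording data frame: column `time` plus
#'   `<marker>_x/_y/_z` columns for the six joint markers (`hip_med`,
#'   `hip_lat`, `knee_med`, `knee_lat`, `ankle_med`, `ankle_lat`).
#' @return a data frame with `time` and `hip_x, hip_y, knee_x, knee_y,
#'   ankle_x, ankle_y` (m).
#' @export
joint_centers <- function(markers) {
  stopifnot(is.data.frame(markers))
  need <- c("time", unlist(lapply(joint_marker_names(), marker_cols)))
  missing <- setdiff(need, names(markers))
  if (length(missing))
    stop_invalid("marker recording is missing column(s): %s",
                 paste(missing, collapse = ", "))
  out <- data.frame(time = markers$time)
  for (j in c("hip", "knee", "ankle")) {
    for (axis in c("x", "y")) {
      med <- markers[[paste0(j, "_med_", axis)]]
      lat <- markers[[paste0(j, "_lat_", axis)]]
      out[[paste0(j, "_", axis)]] <- (med + lat) / 2
    }
  }
  out
}

#' Segment angles and accelerations from joint centres
#'
#' Computes, on the joint-centre time base: segment global angles `theta_f`
#' (hip-to-knee) and `theta_t` (knee-to-ankle), both measured from the
#' downward vertical with anterior (+x) positive; the knee flexion angle
#' `theta_k = theta_f - theta_t`; COM positions placed `pf`/`pt` from the knee
#' along each measured segment; and angular / COM linear accelerations by
#' second-order central finite differences (one-sided at the series ends,
#' which are flagged in `edge`).
#'
#' @param centers output of [joint_centers()], already filtered and resampled.
#' @param params a [phantom_params()] object.
#' @return a data frame of class `processed_recording`: `time`, `theta_k`,
#'   `theta_f`, `theta_t`, `alpha_f`, `alpha_t` (angular accelerations,
#'   rad/s^2), `ddx_f`, `ddy_f`, `ddx_t`, `ddy_t` (COM accelerations, m/s^2)
#'   and a logical `edge` flag.
#' @export
angles_and_accels <- function(centers, params) {
  params <- as_phantom_params(params)
  stopifnot(is.data.frame(centers))
  dt <- check_uniform_time(centers$time)

  theta_f <- atan2(centers$knee_x - centers$hip_x,
                   -(centers$knee_y - centers$hip_y))
  theta_t <- atan2(centers$ankle_x - centers$knee_x,
                   -(centers$ankle_y - centers$knee_y))
  theta_k <- theta_f - theta_t

  # COM positions from measured joint centres: pf/pt from the knee towards
  # the hip / the ankle along each measured (not nominal) segment
  fvx <- centers$hip_x - centers$knee_x
  fvy <- centers$hip_y - centers$knee_y
  flen <- sqrt(fvx^2 + fvy^2)
  com_f_x <- centers$knee_x + params$pf * fvx / flen
  com_f_y <- centers$knee_y + params$pf * fvy / flen
  tvx <- centers$ankle_x - centers$knee_x
  tvy <- centers$ankle_y - centers$knee_y
  tlen <- sqrt(tvx^2 + tvy^2)
  com_t_x <- centers$knee_x + params$pt * tvx / tlen
  com_t_y <- centers$knee_y + params$pt * tvy / tlen

  n <- nrow(centers)
  out <- data.frame(
    time = centers$time,
    theta_k = theta_k, theta_f = theta_f, theta_t = theta_t,
    alpha_f = second_derivative(theta_f, dt),
    alpha_t = second_derivative(theta_t, dt),
    ddx_f = second_derivative(com_f_x, dt),
    ddy_f = second_derivative(com_f_y, dt),
    ddx_t = second_derivative(com_t_x, dt),
    ddy_t = second_derivative(com_t_y, dt),
    edge = c(TRUE, rep(FALSE, max(0, n - 2)), TRUE)[seq_len(n)]
  )
  class(out) <- c("processed_recording", "data.frame")
  out
}

#' Spring deflection angle from spring-end markers
#'
#' The signed angle opened at the knee centre between the thigh-side and
#' shank-side spring-end markers, minus the configured mounting angle, so
#' zero corresponds to the spring free (undeflected) pose.  With the default
#' mounting the two spring arms are antiparallel (along the thigh and shank)
#' at full extension, i.e. `mount_angle = pi`.
#'
#' @param markers a marker recording containing `spring_end_thigh_*` and
#'   `spring_end_shank_*` columns (brace mode).
#' @param centers output of [joint_centers()] on the same time base.
#' @param mount_angle arm opening angle (rad) at zero spring deflection.
#' @return spring deflection angle series (rad).
#' @export
spring_angle_from_markers <- function(markers, centers, mount_angle = pi) {
  need <- c(marker_cols("spring_end_thigh"), marker_cols("spring_end_shank"))
  missing <- setdiff(need, names(markers))
  if (length(missing))
    stop_invalid("spring-end markers absent in brace mode: missing %s",
                 paste(missing, collapse = ", "))
  thigh <- atan2(markers$spring_end_thigh_y - centers$knee_y,
                 markers$spring_end_thigh_x - centers$knee_x)
  shank <- atan2(markers$spring_end_shank_y - centers$knee_y,
                 markers$spring_end_shank_x - centers$knee_x)
  d <- thigh - shank - mount_angle
  # wrap to (-pi, pi]
  d - 2 * pi * ceiling((d - pi) / (2 * pi))
}

#' Fuse the three load-cell channels into the vertical ankle force
#'
#' Per-sample sum of the three vertical load-cell channels, optionally
#' low-pass filtered with the same zero-phase Butterworth specification used
#' for markers.
#'
#' @param forces a force recording data frame: `time`, `lc1`, `lc2`, `lc3`
#'   (N).
#' @param cutoff filter cutoff (Hz); `NULL` skips filtering.
#' @param order filter order per pass.
#' @return data frame with `time` and `Fay` (N).
#' @export
fuse_load_cells <- function(forces, cutoff = 6, order = 4) {
  stopifnot(is.data.frame(forces))
  need <- c("time", "lc1", "lc2", "lc3")
  extra_lc <- grep("^lc[0-9]+$", names(forces), value = TRUE)
  if (!all(need %in% names(forces)) || length(extra_lc) != 3L)
    stop_invalid("force recording must have exactly columns time, lc1, lc2, lc3")
  dt <- check_uniform_time(forces$time)
  Fay <- forces$lc1 + forces$lc2 + forces$lc3
  if (!is.null(cutoff)) Fay <- zero_phase_lowpass(Fay, 1 / dt, cutoff, order)
  data.frame(time = forces$time, Fay = Fay)
}

#' Tracking error between achieved and target knee kinematics
#'
#' Root-mean-square error, in degrees, of an achieved knee trajectory against
#' the commanded one.  The target is spline-resampled onto the achieved time
#' grid first.
#'
#' @param actual,target [knee_trajectory()] objects (or data frames with
#'   `time`, `theta_k` in rad).
#' @return RMSE in degrees.
#' @export
tracking_rmse <- function(actual, target) {
  stopifnot(is.data.frame(actual), is.data.frame(target))
  f <- stats::splinefun(target$time, target$theta_k, method = "fmm")
  tt <- actual$time
  if (tt[1] < min(target$time) - 1e-9 ||
      tt[length(tt)] > max(target$time) + 1e-9)
    stop_invalid("achieved trajectory extends beyond the target's time span")
  err <- rad2deg(actual$theta_k - f(tt))
  sqrt(mean(err^2))
}
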