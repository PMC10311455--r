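#' Hexapod height for a target knee angle
#'
#' The phantom hangs from a fixed hip with the ankle driven vertically by a
#' hexapod platform, hip directly above ankle.  With femur length `lf`, shank
#' length `lt` and knee flexion angle `theta_k` (0 = full extension, flexion
#' positive), the law of cosines gives the hip-to-ankle vertical distance
#' `z = sqrt(lf^2 + lt^2 - 2*lf*lt*cos(pi - theta_k))`.  `z` is continuous and
#' strictly decreasing in `theta_k` on (0, pi): raising the ankle flexes the
#' knee.
#'
#' @param params a [phantom_params()] object.
#' @param theta_k knee flexion angle(s) in radians, in `[0, pi)`.
#' @return vertical hip-to-ankle distance(s) in metres.
#' @seealso [knee_angle_from_height()] for the inverse.
#' @examples
#' p <- phantom_params(lf = 0.3, lt = 0.3)
#' hexapod_height(p, 0)            # 0.6: fully extended
#' hexapod_height(p, deg2rad(60))  # 0.3 * sqrt(3)
#' @export
hexapod_height <- function(params, theta_k) {
  params <- as_phantom_params(params)
  if (!is.numeric(theta_k) || any(!is.finite(theta_k)))
    stop_invalid("'theta_k' must be finite")
  if (any(theta_k < 0 | theta_k >= pi))
    stop_invalid("'theta_k' must lie in [0, pi) rad (got %.4g)",
                 theta_k[which(theta_k < 0 | theta_k >= pi)[1]])
  sqrt(params$lf^2 + params$lt^2 -
         2 * params$lf * params$lt * cos(pi - theta_k))
}

#' Knee angle for a hexapod height
#'
#' Inverse of [hexapod_height()].  Defined on the open interval
#' `(|lf - lt|, lf + lt)`; the endpoints are mechanical singularities (at
#' `z = lf + lt` the hip, knee and ankle axes are colinear, which the physical
#' phantom excludes with a hard stop).
#'
#' @inheritParams hexapod_height
#' @param z vertical hip-to-ankle distance(s) in metres.
#' @return knee flexion angle(s) in radians.
#' @export
knee_angle_from_height <- function(params, z) {
  params <- as_phantom_params(params)
  if (!is.numeric(z) || any(!is.finite(z)))
    stop_invalid("'z' must be finite")
  lo <- abs(params$lf - params$lt)
  hi <- params$lf + params$lt
  if (any(z <= lo | z >= hi))
    stop_invalid(paste0(
      "infeasible geometry: z must lie strictly inside (%.4g, %.4g) m; ",
      "z = lf + lt is the colinear mechanical singularity"), lo, hi)
  cosarg <- (params$lf^2 + params$lt^2 - z^2) / (2 * params$lf * params$lt)
  pi - acos(pmin(1, pmax(-1, cosarg)))
}

# segment global angles for a knee flexion angle, both measured from the
# downward vertical with anterior (+x) positive; theta_k = theta_f - theta_t.
# With the ankle directly below the hip the femur tilts anterior
# (theta_f > 0) and the shank posterior (theta_t < 0) for theta_k > 0.
segment_angles <- function(params, theta_k) {
  theta_f <- atan2(params$lt * sin(theta_k),
                   params$lf + params$lt * cos(theta_k))
  list(theta_f = theta_f, theta_t = theta_f - theta_k)
}

#' Planar joint positions of the phantom
#'
#' Sagittal-plane coordinates (x anterior, y up, hip at the origin) of the
#' hip, knee and ankle centres for given knee angles.  The ankle sits directly
#' below the hip at `(0, -z)`; the knee is displaced into the anterior
#' half-plane for flexion (the sign convention is a package choice, stated
#' here because the hardware leaves it free).
#'
#' @inheritParams hexapod_height
#' @return a list with matrices `hip`, `knee`, `ankle` (columns `x`, `y`, one
#'   row per angle) and vectors `theta_f`, `theta_t` (segment global angles
#'   from the downward vertical, anterior positive).
#' @export
joint_positions <- function(params, theta_k) {
  params <- as_phantom_params(params)
  z <- hexapod_height(params, theta_k)
  ang <- segment_angles(params, theta_k)
  n <- length(theta_k)
  hip <- cbind(x = numeric(n), y = numeric(n))
  knee <- cbind(x = params$lf * sin(ang$theta_f),
                y = -params$lf * cos(ang$theta_f))
  ankle <- cbind(x = numeric(n), y = -z)
  list(hip = hip, knee = knee, ankle = ankle,
       theta_f = ang$theta_f, theta_t = ang$theta_t)
}

#' Knee-angle trajectory container
#'
#' A uniform time series of knee flexion angles (radians).  Simulation inputs
#' outside the phantom's mechanical range of 2--81 degrees are clamped with a
#' warning; analysis inputs only warn (recorded hardware data may overshoot).
#'
#' @param time time stamps (s), strictly increasing and uniform.
#' @param theta_k knee flexion angles (rad).
#' @param clamp clamp out-of-range angles into the mechanical range
#'   (simulation inputs) rather than merely warning.
#' @return a data frame of class `knee_trajectory` with columns `time`,
#'   `theta_k` and attributes `sample_rate`.
#' @export
knee_trajectory <- function(time, theta_k, clamp = FALSE) {
  if (length(time) != length(theta_k))
    stop_invalid("'time' and 'theta_k' lengths differ")
  dt <- check_uniform_time(time)
  if (any(!is.finite(theta_k))) stop_invalid("'theta_k' must be finite")
  lo <- deg2rad(2); hi <- deg2rad(81)
  if (any(theta_k < lo | theta_k > hi)) {
    warning(sprintf(
      "knee trajectory leaves the phantom mechanical range [2, 81] deg (%d samples)%s",
      sum(theta_k < lo | theta_k > hi), if (clamp) "; clamping" else ""),
      call. = FALSE)
    if (clamp) theta_k <- pmin(hi, pmax(lo, theta_k))
  }
  structure(data.frame(time = time, theta_k = theta_k),
            sample_rate = 1 / dt, class = c("knee_trajectory", "data.frame"))
}

#' Plan a hexapod drive trajectory
#'
#' Maps a knee-angle trajectory to the vertical hexapod height command by
#' applying [hexapod_height()] sample-wise; the time grid is preserved.
#'
#' @param traj a [knee_trajectory()].
#' @param params a [phantom_params()] object.
#' @return a data frame of class `hexapod_command` with columns `time`, `z`
#'   (m).
#' @export
plan_hexapod_trajectory <- function(traj, params) {
  params <- as_phantom_params(params)
  stopifnot(is.data.frame(traj), all(c("time", "theta_k") %in% names(traj)))
  z <- tryCatch(hexapod_height(params, traj$theta_k), error = function(e) {
    bad <- which(!is.finite(traj$theta_k) | traj$theta_k < 0 |
                   traj$theta_k >= pi)[1]
    stop_invalid("infeasible knee angle at sample %d: %s", bad,
                 conditionMessage(e))
  })
  structure(data.frame(time = traj$time, z = z),
            class = c("hexapod_command", "data.frame"))
}

#' Write a hexapod command as CSV
#'
#' Two columns, `time_s` and `z_m` — a portable stand-in for a motion-platform
#' vendor export.
#'
#' @param cmd a `hexapod_command` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hexapod_csv <- function(cmd, path) {
  stopifnot(is.data.frame(cmd), all(c("time", "z") %in% names(cmd)))
  utils::write.csv(data.frame(time_s = cmd$time, z_m = cmd$z), path,
                   row.names = FALSE)
  invisible(path)
}
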