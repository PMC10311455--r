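#' Run the full analysis pipeline on a phantom recording
#'
#' Mirrors the hardware processing chain: zero-phase low-pass filtering of
#' marker and load-cell streams (default 4th order, 6 Hz), spline resampling
#' of the markers to the load-cell rate, joint-centre estimation, sagittal
#' segment kinematics with finite-difference accelerations, the per-sample
#' Newton-Euler solve for the knee moment, and work-loop statistics over the
#' interior gait cycles (the first and last `trim_cycles` cycles are dropped
#' to clear filter and differentiation edge effects).
#'
#' If the marker recording contains spring-end markers (brace condition) the
#' spring deflection angle is estimated from them and a spring-angle-adjusted
#' profile plus the deflection regression are produced; otherwise the spring
#' angle is taken equal to the knee angle (the braceless assumption).
#'
#' @param markers marker recording data frame (see [simulate_phantom()] /
#'   [read_marker_csv()]).
#' @param forces force recording data frame (`time`, `lc1`..`lc3`).
#' @param params a [phantom_params()] object.
#' @param stride_time gait stride duration (s), used to segment cycles.
#' @param cutoff low-pass cutoff (Hz) for markers and load cells.
#' @param order Butterworth order per pass.
#' @param trim_cycles number of cycles dropped at each end.
#' @param filter set `FALSE` to bypass filtering (for validation on
#'   noise-free data).
#' @param mount_angle spring-arm mounting angle (rad), see
#'   [spring_angle_from_markers()].
#' @param target optional commanded [knee_trajectory()]; adds the tracking
#'   RMSE (degrees) to the result.
#' @return an object of class `phantom_analysis`: list with `processed`
#'   (kinematics + `theta_s` + `Fay`), `loads` (knee moment series),
#'   `profile_knee`, `profile_spring` ([assistance_profile()] objects fitted
#'   over the interior cycles), `deflection` (regression, brace only),
#'   `rmse_deg`, `analysis_idx`, `samples_per_cycle`.
#' @export
analyze_phantom <- function(markers, forces, params, stride_time = 1,
                            cutoff = 6, order = 4, trim_cycles = 1,
                            filter = TRUE, mount_angle = pi, target = NULL) {
  params <- as_phantom_params(params)
  stopifnot(is.data.frame(markers), is.data.frame(forces))
  dt_m <- check_uniform_time(markers$time, "marker time")
  dt_f <- check_uniform_time(forces$time, "force time")
  marker_rate <- 1 / dt_m
  force_rate <- 1 / dt_f

  # 1. filter every marker coordinate at its native rate
  mk <- markers
  if (filter) {
    for (col in setdiff(names(mk), "time"))
      mk[[col]] <- zero_phase_lowpass(mk[[col]], marker_rate, cutoff, order)
  }

  # 2. spline-resample markers to the load-cell rate
  if (abs(marker_rate - force_rate) > 1e-6 * force_rate) {
    res <- lapply(setdiff(names(mk), "time"), function(col)
      resample_spline(mk$time, mk[[col]], force_rate)$x)
    t_new <- resample_spline(mk$time, mk[[2]], force_rate)$time
    mk <- data.frame(time = t_new,
                     stats::setNames(as.data.frame(res),
                                     setdiff(names(mk), "time")))
  }

  # 3. fuse + filter load cells, align the two streams
  fused <- fuse_load_cells(forces, cutoff = if (filter) cutoff else NULL,
                           order = order)
  n <- min(nrow(mk), nrow(fused))
  mk <- mk[seq_len(n), , drop = FALSE]
  fused <- fused[seq_len(n), , drop = FALSE]

  # 4. kinematics
  centers <- joint_centers(mk)
  proc <- angles_and_accels(centers, params)
  has_spring_markers <- all(marker_cols("spring_end_thigh") %in% names(mk))
  proc$theta_s <- if (has_spring_markers)
    spring_angle_from_markers(mk, centers, mount_angle)
  else proc$theta_k
  proc$Fay <- fused$Fay

  # 5. knee moment
  loads <- solve_knee_moment(proc, params, fused$Fay)

  # 6. interior-cycle work-loop statistics
  spc <- as.integer(round(stride_time * force_rate))
  # the marker stream ends one marker frame before the load-cell stream, so a
  # >90%-complete final cycle still counts: only trimmed cycles may be partial
  n_cycles <- n %/% spc
  if (n - n_cycles * spc >= 0.9 * spc) n_cycles <- n_cycles + 1L
  if (n_cycles < 2 * trim_cycles + 1)
    stop_invalid("recording too short: %d complete cycle(s), need > %d",
                 n_cycles, 2 * trim_cycles)
  idx <- (trim_cycles * spc + 1L):min((n_cycles - trim_cycles) * spc, n)

  # a static hold has no work loop: emit the loads without profiles
  static <- stats::var(proc$theta_k[idx]) == 0
  profile_knee <- if (!static)
    assistance_profile(proc$theta_k[idx], loads$M[idx], basis = "knee",
                       samples_per_cycle = spc)
  profile_spring <- if (!static)
    adjusted_profile(loads$M[idx], proc$theta_s[idx],
                     samples_per_cycle = spc)
  deflection <- if (has_spring_markers && !static)
    deflection_regression(proc$theta_s[idx], proc$theta_k[idx])
  else NULL

  rmse <- if (!is.null(target)) {
    achieved <- data.frame(time = proc$time[idx], theta_k = proc$theta_k[idx])
    tracking_rmse(achieved, target)
  } else NA_real_

  structure(list(processed = proc, loads = loads,
                 profile_knee = profile_knee,
                 profile_spring = profile_spring,
                 deflection = deflection, rmse_deg = rmse,
                 analysis_idx = idx, samples_per_cycle = spc,
                 n_cycles_analyzed = n_cycles - 2 * trim_cycles,
                 has_spring_markers = has_spring_markers,
                 settings = list(stride_time = stride_time, cutoff = cutoff,
                                 order = order, trim_cycles = trim_cycles,
                                 filter = filter,
                                 mount_angle = mount_angle)),
            class = "phantom_analysis")
}

#' @export
print.phantom_analysis <- function(x, ...) {
  cat(sprintf("Phantom analysis: %d interior cycles of %d samples\n",
              x$n_cycles_analyzed, x$samples_per_cycle))
  if (is.null(x$profile_knee)) {
    cat("  static hold: no work-loop profiles (knee moment series only)\n")
    return(invisible(x))
  }
  cat(sprintf("  knee-basis stiffness:   %.3f +/- %.3f N m/rad, x-int %.3f deg, AUC %.3f\n",
              x$profile_knee$slope, x$profile_knee$slope_se,
              x$profile_knee$x_intercept_deg, x$profile_knee$auc_ratio))
  cat(sprintf("  spring-basis stiffness: %.3f +/- %.3f N m/rad, x-int %.3f deg, AUC %.3f\n",
              x$profile_spring$slope, x$profile_spring$slope_se,
              x$profile_spring$x_intercept_deg, x$profile_spring$auc_ratio))
  if (!is.null(x$deflection))
    cat(sprintf("  brace deflection: theta_s = %.3f * theta_k %+.2f deg (R^2 %.4f)\n",
                x$deflection$slope, x$deflection$offset_deg,
                x$deflection$r_squared))
  if (!is.na(x$rmse_deg))
    cat(sprintf("  tracking RMSE vs target: %.2f deg\n", x$rmse_deg))
  invisible(x)
}
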