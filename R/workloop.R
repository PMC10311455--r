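#' Fit an assistance profile to a work loop
#'
#' The central estimator of the package: an ordinary-least-squares fit of the
#' exoskeleton knee moment against a joint angle, pooled over all analysed
#' gait cycles.  The fitted slope is the assistance (quasi-)stiffness in
#' N m/rad; the x-intercept, reported in degrees, is the engagement offset —
#' the angle at which the device starts delivering net extensor moment.  When
#' cycle structure is supplied, the per-cycle enclosed work-loop area over the
#' total positive work (the AUC hysteresis ratio) and per-cycle slopes (for
#' dispersion) are computed as well.
#'
#' @param angle angle series (rad): knee angle or spring deflection angle.
#' @param moment knee moment series (N m), same length.
#' @param basis which angle the profile is expressed on: `"knee"` or
#'   `"spring"`.
#' @param samples_per_cycle optional cycle length in samples; enables the
#'   hysteresis ratio and per-cycle slopes.  The series should then contain a
#'   whole number of cycles (a trailing closing sample is tolerated).
#' @return an object of class `assistance_profile` with components `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `x_intercept_deg`,
#'   `x_intercept_defined`, `r_squared`, `auc_ratio` (or `NA`), `n_samples`,
#'   `n_cycles`, `basis`, `per_cycle_slope`, and the pooled `angle`/`moment`
#'   data for plotting.
#' @seealso [workloop_hysteresis()], [adjusted_profile()],
#'   [deflection_regression()]
#' @examples
#' th <- deg2rad(seq(5, 65, length.out = 200))
#' fit <- assistance_profile(th, 15.9 * th)
#' coef(fit)
#' @export
assistance_profile <- function(angle, moment,
                               basis = c("knee", "spring"),
                               samples_per_cycle = NULL) {
  basis <- match.arg(basis)
  if (length(angle) != length(moment))
    stop_invalid("'angle' and 'moment' lengths differ")
  ok <- is.finite(angle) & is.finite(moment)
  if (!all(ok)) {
    angle <- angle[ok]
    moment <- moment[ok]
  }
  n <- length(angle)
  if (n < 3L) stop_invalid("need at least 3 finite samples to fit")
  if (stats::var(angle) <= 0)
    stop_invalid("degenerate regression: angle series has zero variance")

  fit <- stats::lm(moment ~ angle)
  cf <- stats::coef(fit)
  # an exact line is a legitimate validation input: silence the perfect-fit note
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  slope <- unname(cf["angle"])
  intercept <- unname(cf["(Intercept)"])
  x_defined <- is.finite(slope) && slope != 0
  x_int <- if (x_defined) rad2deg(-intercept / slope) else NaN
  r2 <- suppressWarnings(summary(fit)$r.squared)

  auc <- NA_real_
  n_cycles <- NA_integer_
  per_cycle <- NULL
  if (!is.null(samples_per_cycle)) {
    spc <- as.integer(samples_per_cycle)
    n_cycles <- n %/% spc
    if (n_cycles < 1L)
      stop_invalid("series shorter than one cycle (%d < %d samples)", n, spc)
    auc <- workloop_hysteresis(moment, angle, spc)
    per_cycle <- vapply(seq_len(n_cycles), function(k) {
      idx <- ((k - 1L) * spc + 1L):(k * spc)
      a <- angle[idx]
      if (stats::var(a) <= 0) return(NA_real_)
      unname(stats::coef(stats::lm(moment[idx] ~ a))[2])
    }, numeric(1))
  }

  structure(list(slope = slope, slope_se = unname(se["angle"]),
                 intercept = intercept,
                 intercept_se = unname(se["(Intercept)"]),
                 x_intercept_deg = x_int, x_intercept_defined = x_defined,
                 r_squared = r2, auc_ratio = auc,
                 n_samples = n, n_cycles = n_cycles, basis = basis,
                 per_cycle_slope = per_cycle,
                 angle = angle, moment = moment, lm = fit),
            class = "assistance_profile")
}

#' @export
print.assistance_profile <- function(x, ...) {
  cat(sprintf("Assistance profile (%s-angle basis, %d samples%s)\n",
              x$basis, x$n_samples,
              if (!is.na(x$n_cycles)) sprintf(", %d cycles", x$n_cycles) else ""))
  cat(sprintf("  stiffness:   %.3f +/- %.3f N m/rad\n", x$slope, x$slope_se))
  cat(sprintf("  x-intercept: %s deg\n",
              if (x$x_intercept_defined) sprintf("%.3f", x$x_intercept_deg)
              else "undefined (zero slope)"))
  if (!is.na(x$auc_ratio))
    cat(sprintf("  AUC hysteresis ratio: %.3f\n", x$auc_ratio))
  cat(sprintf("  R^2 = %.5f\n", x$r_squared))
  invisible(x)
}

#' @export
summary.assistance_profile <- function(object, ...) {
  out <- object[c("basis", "slope", "slope_se", "intercept", "intercept_se",
                  "x_intercept_deg", "x_intercept_defined", "r_squared",
                  "auc_ratio", "n_samples", "n_cycles")]
  if (!is.null(object$per_cycle_slope)) {
    out$per_cycle_slope_mean <- mean(object$per_cycle_slope, na.rm = TRUE)
    out$per_cycle_slope_sd <- stats::sd(object$per_cycle_slope, na.rm = TRUE)
  }
  class(out) <- "summary.assistance_profile"
  out
}

#' @export
print.summary.assistance_profile <- function(x, ...) {
  cat(sprintf("Assistance profile summary (%s basis)\n", x$basis))
  cat(sprintf("  slope      %.4f N m/rad (SE %.4f)\n", x$slope, x$slope_se))
  cat(sprintf("  intercept  %.4f N m (SE %.4f)\n", x$intercept,
              x$intercept_se))
  cat(sprintf("  x-intercept %.4f deg\n", x$x_intercept_deg))
  cat(sprintf("  R^2 %.5f over %d samples", x$r_squared, x$n_samples))
  if (!is.na(x$n_cycles)) cat(sprintf(" in %d cycles", x$n_cycles))
  cat("\n")
  if (!is.na(x$auc_ratio))
    cat(sprintf("  AUC hysteresis ratio %.4f\n", x$auc_ratio))
  if (!is.null(x$per_cycle_slope_mean))
    cat(sprintf("  per-cycle slope %.4f +/- %.4f N m/rad\n",
                x$per_cycle_slope_mean, x$per_cycle_slope_sd))
  invisible(x)
}

#' @export
coef.assistance_profile <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.assistance_profile <- function(object, angle = NULL, ...) {
  if (is.null(angle)) angle <- object$angle
  object$intercept + object$slope * angle
}

#' @export
residuals.assistance_profile <- function(object, ...) {
  object$moment - predict(object)
}

#' @export
plot.assistance_profile <- function(x, ...) {
  graphics::plot(rad2deg(x$angle), x$moment, pch = ".", col = "grey40",
                 xlab = sprintf("%s angle (deg)", x$basis),
                 ylab = "knee moment (N m)",
                 main = sprintf("Work loop, %s basis", x$basis), ...)
  graphics::abline(a = x$intercept, b = x$slope * pi / 180, col = "red3",
                   lwd = 2)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "slope %.2f N m/rad, x-int %.2f deg%s", x$slope, x$x_intercept_deg,
    if (!is.na(x$auc_ratio)) sprintf(", AUC %.2f", x$auc_ratio) else ""))
  invisible(x)
}

#' Work-loop hysteresis (AUC ratio)
#'
#' Energy lost per cycle relative to energy delivered: the enclosed area of
#' each moment-angle loop, `|integral of M d(theta)|` by trapezoidal
#' integration around the closed cycle, summed over cycles, divided by the
#' total positive work (the sum of positive trapezoidal increments
#' `M * d(theta)`).  A purely elastic loop (loading and unloading on one
#' line) gives exactly 0.
#'
#' @param moment knee moment series (N m).
#' @param angle angle series (rad).
#' @param samples_per_cycle cycle length in samples; the series must contain
#'   at least one whole cycle.
#' @return the unitless hysteresis ratio.
#' @export
workloop_hysteresis <- function(moment, angle, samples_per_cycle) {
  if (length(moment) != length(angle))
    stop_invalid("'moment' and 'angle' lengths differ")
  spc <- as.integer(samples_per_cycle)
  n_cycles <- length(angle) %/% spc
  if (n_cycles < 1L)
    stop_invalid("need a whole number of cycles (>= 1 of %d samples)", spc)
  enclosed <- 0
  positive <- 0
  for (k in seq_len(n_cycles)) {
    i0 <- (k - 1L) * spc + 1L
    idx <- i0:(i0 + spc - 1L)
    # close the loop: use the next cycle's first sample when available,
    # otherwise wrap to this cycle's own first sample
    close_i <- if (i0 + spc <= length(angle)) i0 + spc else i0
    a <- c(angle[idx], angle[close_i])
    m <- c(moment[idx], moment[close_i])
    da <- diff(a)
    mbar <- (m[-1] + m[-length(m)]) / 2
    work <- mbar * da
    enclosed <- enclosed + abs(sum(work))
    positive <- positive + sum(work[work > 0])
  }
  if (positive <= 0)
    stop_invalid("undefined hysteresis: total positive work is not positive")
  enclosed / positive
}

#' Spring-angle-adjusted assistance profile
#'
#' Refits the assistance profile on the spring deflection angle instead of
#' the knee angle, removing the soft-tissue (brace compliance) contribution
#' from the profile.  In the braceless condition the spring angle equals the
#' knee angle by construction, so the adjusted profile is identical to the
#' knee-basis one.
#'
#' @param moment knee moment series (N m).
#' @param spring_angle spring deflection series (rad); for braceless data
#'   pass the knee angle.
#' @inheritParams assistance_profile
#' @return an `assistance_profile` with `basis = "spring"`.
#' @export
adjusted_profile <- function(moment, spring_angle, samples_per_cycle = NULL) {
  assistance_profile(spring_angle, moment, basis = "spring",
                     samples_per_cycle = samples_per_cycle)
}

#' Characterize torsional springs from bench tests
#'
#' For each torsion recording: zero-phase low-pass filtering (default 10 Hz,
#' 4th order) of angle and moment, then an OLS fit of moment on angle.  The
#' cumulative stiffness of the spring pack is the sum of the per-spring
#' slopes.
#'
#' @param recordings a `torsion_recording` or a list of them
#'   ([simulate_torsion_test()] or [read_torsion_csv()]).
#' @param cutoff filter cutoff (Hz); `NULL` skips filtering.
#' @param order filter order per pass.
#' @return an object of class `spring_characterization`: data frame `springs`
#'   (per-spring `stiffness`, `se`, `r_squared`, `n`), `cumulative` and
#'   `cumulative_se`.
#' @examples
#' recs <- lapply(1:4, function(i) simulate_torsion_test(4.15))
#' characterize_springs(recs)$cumulative  # 16.6
#' @export
characterize_springs <- function(recordings, cutoff = 10, order = 4) {
  if (inherits(recordings, "torsion_recording")) recordings <- list(recordings)
  if (!length(recordings)) stop_invalid("need at least one torsion recording")
  rows <- lapply(recordings, function(rec) {
    stopifnot(is.data.frame(rec),
              all(c("time", "angle", "moment") %in% names(rec)))
    dt <- check_uniform_time(rec$time)
    ang <- rec$angle
    mom <- rec$moment
    if (!is.null(cutoff)) {
      ang <- zero_phase_lowpass(ang, 1 / dt, cutoff, order)
      mom <- zero_phase_lowpass(mom, 1 / dt, cutoff, order)
    }
    if (stats::var(ang) <= 0)
      stop_invalid("degenerate regression: constant-angle torsion recording")
    fit <- stats::lm(mom ~ ang)
    data.frame(stiffness = unname(stats::coef(fit)[2]),
               se = suppressWarnings(sqrt(diag(stats::vcov(fit)))[2]),
               r_squared = suppressWarnings(summary(fit)$r.squared),
               n = length(ang))
  })
  springs <- do.call(rbind, rows)
  rownames(springs) <- NULL
  structure(list(springs = springs,
                 cumulative = sum(springs$stiffness),
                 cumulative_se = sqrt(sum(springs$se^2))),
            class = "spring_characterization")
}

#' @export
print.spring_characterization <- function(x, ...) {
  cat(sprintf("Torsional spring characterization (%d spring(s))\n",
              nrow(x$springs)))
  for (i in seq_len(nrow(x$springs)))
    cat(sprintf("  spring %d: %.3f +/- %.3f N m/rad\n", i,
                x$springs$stiffness[i], x$springs$se[i]))
  cat(sprintf("  cumulative: %.3f +/- %.3f N m/rad\n", x$cumulative,
              x$cumulative_se))
  invisible(x)
}

#' Brace-deflection regression
#'
#' OLS fit of the spring deflection angle on the knee angle over the pooled
#' analysed cycles.  A slope below one and a negative offset (in degrees)
#' quantify how much the soft tissue absorbs of the knee's rotation before it
#' reaches the spring.
#'
#' @param spring_angle spring deflection series (rad).
#' @param knee_angle knee angle series (rad), same length.
#' @return a list with `slope` (unitless), `offset_deg`, `slope_se`,
#'   `offset_se_deg`, `r_squared`, `n`.
#' @export
deflection_regression <- function(spring_angle, knee_angle) {
  if (length(spring_angle) != length(knee_angle))
    stop_invalid("'spring_angle' and 'knee_angle' lengths differ")
  ok <- is.finite(spring_angle) & is.finite(knee_angle)
  spring_angle <- spring_angle[ok]
  knee_angle <- knee_angle[ok]
  if (stats::var(knee_angle) <= 0)
    stop_invalid("degenerate regression: knee-angle series has zero variance")
  fit <- stats::lm(spring_angle ~ knee_angle)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  list(slope = unname(cf[2]), offset_deg = rad2deg(unname(cf[1])),
       slope_se = unname(se[2]), offset_se_deg = rad2deg(unname(se[1])),
       r_squared = summary(fit)$r.squared, n = length(knee_angle))
}

#' Relative difference between work-loop and bench stiffness
#'
#' Percentage by which an inverse-dynamics assistance stiffness falls short
#' of (positive) or exceeds (negative) the bench cumulative spring stiffness,
#' `100 * (K_torsion - slope) / K_torsion`.
#'
#' @param profile_slope assistance-profile slope (N m/rad).
#' @param torsion_stiffness bench cumulative stiffness (N m/rad).
#' @return percentage difference.
#' @export
stiffness_relative_difference <- function(profile_slope, torsion_stiffness) {
  check_number(profile_slope, "profile_slope")
  check_number(torsion_stiffness, "torsion_stiffness", 0,
               strict_lower = TRUE)
  100 * (torsion_stiffness - profile_slope) / torsion_stiffness
}
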