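#' Torsional-spring exoskeleton model
#'
#' Parameters of the passive knee exoskeleton mounted on the phantom.  Two
#' mounting modes mirror the hardware: `"braceless"` clamps the springs
#' straight to the bones, so spring deflection equals knee flexion and full
#' extension is zero deflection; `"brace"` loads the springs through cuffs on
#' the ballistic-gel soft tissue, whose compression makes the spring angle lag
#' the knee angle approximately linearly, `theta_s = c * theta_k + d`.
#' `"none"` removes the exoskeleton (free pin knee).
#'
#' The delivered knee moment is linear-elastic plus a viscous loss standing in
#' for the gel's viscoelasticity:
#' `M = Ks * (theta_s - theta_free) + damping_b * dtheta_s/dt`,
#' extensor positive.  A negative `theta_free` encodes spring pre-tension at
#' full extension, keeping the springs engaged through the whole gait cycle.
#'
#' @param mode `"none"`, `"brace"` or `"braceless"`.
#' @param Ks cumulative torsional stiffness of the spring pack (N m/rad),
#'   expressed on the spring-deflection angle.
#' @param theta_free spring free angle (rad): deflection at which the elastic
#'   moment is zero.
#' @param damping_b viscous loss coefficient (N m s/rad) on the spring
#'   deflection rate.
#' @param compliance_c,compliance_d brace-deflection line: slope (unitless)
#'   and offset (rad) of spring angle vs knee angle.  Forced to (1, 0) in
#'   braceless mode.
#' @return an object of class `exo_model`.
#' @examples
#' exo_model("braceless", Ks = 16.6)
#' exo_model("brace", Ks = 15.2, compliance_c = 0.96,
#'           compliance_d = deg2rad(-7.4))
#' @export
exo_model <- function(mode = c("none", "brace", "braceless"),
                      Ks = 0, theta_free = 0, damping_b = 0,
                      compliance_c = 1, compliance_d = 0) {
  mode <- match.arg(mode)
  check_number(Ks, "Ks", 0)
  check_number(damping_b, "damping_b", 0)
  check_number(theta_free, "theta_free")
  check_number(compliance_c, "compliance_c")
  check_number(compliance_d, "compliance_d")
  if (mode == "none" && Ks != 0)
    stop_invalid("mode = 'none' forces Ks = 0 (no exoskeleton mounted)")
  if (mode == "braceless" && (compliance_c != 1 || compliance_d != 0))
    stop_invalid(paste0(
      "mode = 'braceless' forces compliance_c = 1, compliance_d = 0: ",
      "bone mounting makes spring deflection equal knee flexion"))
  structure(list(mode = mode, Ks = Ks, theta_free = theta_free,
                 damping_b = damping_b, compliance_c = compliance_c,
                 compliance_d = compliance_d),
            class = "exo_model")
}

#' @export
print.exo_model <- function(x, ...) {
  cat("Exoskeleton model, mode =", x$mode, "\n")
  if (x$mode != "none") {
    cat(sprintf("  Ks = %.3f N m/rad, theta_free = %.2f deg, damping_b = %.3f N m s/rad\n",
                x$Ks, rad2deg(x$theta_free), x$damping_b))
    cat(sprintf("  compliance: theta_s = %.3f * theta_k %+.2f deg\n",
                x$compliance_c, rad2deg(x$compliance_d)))
  }
  invisible(x)
}

#' Spring deflection for a knee angle
#'
#' Applies the linear brace-compliance map `theta_s = c * theta_k + d`
#' (identity in braceless mode).
#'
#' @param exo an [exo_model()] with mode `"brace"` or `"braceless"`.
#' @param theta_k knee flexion angle(s), rad.
#' @return spring deflection angle(s), rad.
#' @export
brace_deflection <- function(exo, theta_k) {
  stopifnot(inherits(exo, "exo_model"))
  if (exo$mode == "none")
    stop_invalid("no exoskeleton mounted (mode = 'none'): no spring deflection")
  exo$compliance_c * theta_k + exo$compliance_d
}

#' Spring moment for a deflection state
#'
#' Elastic-plus-viscous exoskeleton moment,
#' `M = Ks * (theta_s - theta_free) + damping_b * theta_s_dot`, reported as a
#' knee-extensor (flexion-opposing) moment, extensor positive.
#'
#' @param exo an [exo_model()] with mode `"brace"` or `"braceless"`.
#' @param theta_s spring deflection angle(s), rad.
#' @param theta_s_dot spring deflection rate(s), rad/s.
#' @return moment(s), N m.
#' @export
spring_moment <- function(exo, theta_s, theta_s_dot = 0) {
  stopifnot(inherits(exo, "exo_model"))
  if (exo$mode == "none")
    stop_invalid("no exoskeleton mounted (mode = 'none'): no spring moment")
  exo$Ks * (theta_s - exo$theta_free) + exo$damping_b * theta_s_dot
}
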