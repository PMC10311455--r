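#' Phantom body-segment parameters
#'
#' Bundles the rigid-body parameters of the two-link phantom leg: the femur
#' linkage (hip to knee) and the tibia/fibula linkage (knee to ankle).  The
#' bundled defaults for inertias, weights and centre-of-mass offsets are the
#' bench-measured values for the three hardware configurations of the phantom
#' (bare leg, brace-mounted exoskeleton, braceless/bone-mounted exoskeleton);
#' pick them with `condition`.  Segment lengths are not part of that table and
#' default to child anthropometry (0.32 m each for a 1.31 m stature model);
#' override them if your phantom differs.
#'
#' @param condition which hardware configuration the inertial defaults
#'   describe: `"bare"` (no spring or brace), `"brace"`, or `"braceless"`.
#' @param lf,lt femur and tibia/fibula linkage lengths (m).
#' @param wf,wt linkage weights (N). Masses are derived as `w/g`.
#' @param If,It linkage moments of inertia about each COM (kg m^2).
#' @param pf,pt COM-to-knee distances along each linkage (m).
#' @param g gravitational acceleration (m/s^2).
#' @return an object of class `phantom_params`: a list with fields
#'   `lf, lt, mf, mt, wf, wt, If, It, pf, pt, g`.
#' @examples
#' p <- phantom_params("braceless")
#' p$mf * p$g  # = p$wf
#' @export
phantom_params <- function(condition = c("braceless", "brace", "bare"),
                           lf = 0.32, lt = 0.32,
                           wf = NULL, wt = NULL,
                           If = NULL, It = NULL,
                           pf = NULL, pt = NULL,
                           g = GRAVITY) {
  condition <- match.arg(condition)
  defaults <- list(
    bare      = list(If = 1.1e-2, It = 1.4e-2, wf = 13.1, wt = 24.1,
                     pf = 0.13, pt = 0.15),
    brace     = list(If = 1.3e-2, It = 1.7e-2, wf = 16.2, wt = 26.9,
                     pf = 0.11, pt = 0.15),
    braceless = list(If = 1.3e-2, It = 1.6e-2, wf = 15.4, wt = 25.8,
                     pf = 0.11, pt = 0.15)
  )[[condition]]
  if (is.null(wf)) wf <- defaults$wf
  if (is.null(wt)) wt <- defaults$wt
  if (is.null(If)) If <- defaults$If
  if (is.null(It)) It <- defaults$It
  if (is.null(pf)) pf <- defaults$pf
  if (is.null(pt)) pt <- defaults$pt

  check_number(lf, "lf", 0, strict_lower = TRUE)
  check_number(lt, "lt", 0, strict_lower = TRUE)
  check_number(wf, "wf", 0, strict_lower = TRUE)
  check_number(wt, "wt", 0, strict_lower = TRUE)
  check_number(If, "If", 0, strict_lower = TRUE)
  check_number(It, "It", 0, strict_lower = TRUE)
  check_number(pf, "pf", 0, strict_lower = TRUE)
  check_number(pt, "pt", 0, strict_lower = TRUE)
  check_number(g, "g", 0, strict_lower = TRUE)
  if (pf > lf) stop_invalid("pf (%.3f) must not exceed lf (%.3f)", pf, lf)
  if (pt > lt) stop_invalid("pt (%.3f) must not exceed lt (%.3f)", pt, lt)

  structure(
    list(condition = condition, lf = lf, lt = lt,
         mf = wf / g, mt = wt / g, wf = wf, wt = wt,
         If = If, It = It, pf = pf, pt = pt, g = g),
    class = "phantom_params")
}

#' @export
print.phantom_params <- function(x, ...) {
  cat("Phantom body-segment parameters (", x$condition, " condition)\n",
      sep = "")
  cat(sprintf("  femur:       lf = %.3f m, wf = %.1f N (mf = %.2f kg), If = %.1e kg m^2, pf = %.2f m\n",
              x$lf, x$wf, x$mf, x$If, x$pf))
  cat(sprintf("  tibia/fibula: lt = %.3f m, wt = %.1f N (mt = %.2f kg), It = %.1e kg m^2, pt = %.2f m\n",
              x$lt, x$wt, x$mt, x$It, x$pt))
  cat(sprintf("  g = %.2f m/s^2\n", x$g))
  invisible(x)
}

as_phantom_params <- function(x) {
  if (inherits(x, "phantom_params")) return(x)
  if (is.list(x)) return(do.call(phantom_params, x))
  stop_invalid("cannot interpret 'params' as phantom parameters")
}
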