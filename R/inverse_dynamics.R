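# Shared geometry for the two-link Newton-Euler equations.
# Frame: x anterior, y up, hip at the origin.  theta_f, theta_t are segment
# global angles from the downward vertical, anterior positive; with gamma =
# theta - pi/2 the counter-clockwise orientation of each segment, CCW angular
# acceleration equals the second derivative of theta for both links.
# Returns the joint and COM positions and the COM-relative moment arms.
newton_euler_geometry <- function(params, theta_f, theta_t) {
  kx <- params$lf * sin(theta_f)
  ky <- -params$lf * cos(theta_f)
  ax <- kx + params$lt * sin(theta_t)
  ay <- ky - params$lt * cos(theta_t)
  com_f_x <- kx * (1 - params$pf / params$lf)
  com_f_y <- ky * (1 - params$pf / params$lf)
  com_t_x <- kx + params$pt * sin(theta_t)
  com_t_y <- ky - params$pt * cos(theta_t)
  list(
    kx = kx, ky = ky, ax = ax, ay = ay,
    com_f_x = com_f_x, com_f_y = com_f_y,
    com_t_x = com_t_x, com_t_y = com_t_y,
    # shank arms about the shank COM
    rA_x = ax - com_t_x, rA_y = ay - com_t_y,
    rK_x = kx - com_t_x, rK_y = ky - com_t_y,
    # femur arms about the femur COM
    rK2_x = kx - com_f_x, rK2_y = ky - com_f_y,
    rH_x = -com_f_x, rH_y = -com_f_y)
}

#' Assemble the per-sample knee-moment linear system
#'
#' Builds the six Newton-Euler equations of the two-link phantom at one time
#' sample as a 6x6 linear system `A x = b` in the unknowns
#' `x = (Fax, Fkx, Fky, Fhx, Fhy, M)`, with the measured vertical ankle force
#' `Fay` on the right-hand side.  The equations are force balance (`sum F =
#' m a`) and moment balance about each link's COM (`sum M = I alpha`, CCW
#' positive), with the knee moment `M` acting with opposite sign on the two
#' links; `M > 0` is a knee-extensor moment.  The equations are derived from
#' the free-body diagrams of the two links rather than transcribed; the
#' derivation is laid out in the methods vignette and is cross-checked in the
#' test suite against an independent formulation taking moments about the
#' ankle and hip.
#'
#' @param state one sample of a [angles_and_accels()] processed recording: a
#'   list/row with `theta_f`, `theta_t`, `alpha_f`, `alpha_t`, `ddx_f`,
#'   `ddy_f`, `ddx_t`, `ddy_t`.
#' @param params a [phantom_params()] object.
#' @param Fay measured vertical ankle force at this sample (N, upward
#'   positive).
#' @return a list with the 6x6 matrix `A`, right-hand side `b`, and the
#'   unknown names.
#' @export
assemble_system <- function(state, params, Fay) {
  params <- as_phantom_params(params)
  vals <- unlist(state[c("theta_f", "theta_t", "alpha_f", "alpha_t",
                         "ddx_f", "ddy_f", "ddx_t", "ddy_t")])
  if (any(!is.finite(vals)) || !is.finite(Fay))
    stop_invalid("non-finite state or Fay in inverse-dynamics sample")
  g <- newton_euler_geometry(params, state$theta_f, state$theta_t)
  A <- matrix(0, 6, 6,
              dimnames = list(NULL, c("Fax", "Fkx", "Fky", "Fhx", "Fhy", "M")))
  b <- numeric(6)
  # shank, sum Fx
  A[1, c("Fax", "Fkx")] <- 1
  b[1] <- params$mt * state$ddx_t
  # shank, sum Fy (Fay known)
  A[2, "Fky"] <- 1
  b[2] <- params$mt * state$ddy_t + params$wt - Fay
  # shank, sum M about COM
  A[3, "Fax"] <- -g$rA_y
  A[3, "Fkx"] <- -g$rK_y
  A[3, "Fky"] <- g$rK_x
  A[3, "M"] <- 1
  b[3] <- params$It * state$alpha_t - g$rA_x * Fay
  # femur, sum Fx (knee reaction is -Fk)
  A[4, c("Fkx", "Fhx")] <- c(-1, 1)
  b[4] <- params$mf * state$ddx_f
  # femur, sum Fy
  A[5, c("Fky", "Fhy")] <- c(-1, 1)
  b[5] <- params$mf * state$ddy_f + params$wf
  # femur, sum M about COM (reaction moment -M)
  A[6, "Fkx"] <- g$rK2_y
  A[6, "Fky"] <- -g$rK2_x
  A[6, "Fhx"] <- -g$rH_y
  A[6, "Fhy"] <- g$rH_x
  A[6, "M"] <- -1
  b[6] <- params$If * state$alpha_f
  list(A = A, b = b, unknowns = colnames(A))
}

#' Solve the knee moment over a processed recording
#'
#' Runs the per-sample linear solve of [assemble_system()] over a processed
#' recording fused with the load-cell force, giving the knee assistance
#' moment and all pin-joint reaction forces.  Samples with a numerically
#' singular system are returned as `NaN` (with one warning) rather than
#' aborting the series; edge samples inherit the recording's `edge` flag so
#' they can be trimmed from work-loop statistics.
#'
#' @param rec a `processed_recording` from [angles_and_accels()].
#' @param params a [phantom_params()] object.
#' @param Fay vertical ankle force series (N), same length as `rec` rows
#'   (e.g. from [fuse_load_cells()]).
#' @return a data frame of class `knee_moment_series` with `time`, `M`,
#'   `Fax`, `Fay`, `Fkx`, `Fky`, `Fhx`, `Fhy`, `edge`; the maximum condition
#'   number encountered is in `attr(, "max_condition")`.
#' @export
solve_knee_moment <- function(rec, params, Fay) {
  params <- as_phantom_params(params)
  stopifnot(inherits(rec, "data.frame"))
  n <- nrow(rec)
  if (length(Fay) != n)
    stop_invalid("'Fay' length (%d) does not match recording (%d rows)",
                 length(Fay), n)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("Fax", "Fkx", "Fky", "Fhx", "Fhy", "M")))
  max_kappa <- 0
  n_singular <- 0L
  for (i in seq_len(n)) {
    sys <- assemble_system(rec[i, ], params, Fay[i])
    x <- tryCatch(solve(sys$A, sys$b), error = function(e) NULL)
    if (is.null(x)) {
      n_singular <- n_singular + 1L
      out[i, ] <- NaN
    } else {
      out[i, ] <- x
      max_kappa <- max(max_kappa, kappa(sys$A, exact = FALSE))
    }
  }
  if (n_singular > 0)
    warning(sprintf("%d singular sample(s) returned as NaN", n_singular),
            call. = FALSE)
  res <- data.frame(time = rec$time, M = out[, "M"],
                    Fax = out[, "Fax"], Fay = Fay,
                    Fkx = out[, "Fkx"], Fky = out[, "Fky"],
                    Fhx = out[, "Fhx"], Fhy = out[, "Fhy"],
                    edge = if ("edge" %in% names(rec)) rec$edge else FALSE)
  attr(res, "max_condition") <- max_kappa
  class(res) <- c("knee_moment_series", "data.frame")
  res
}

#' Write a knee-moment series as CSV
#'
#' @param loads a `knee_moment_series` from [solve_knee_moment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_moment_csv <- function(loads, path) {
  stopifnot(is.data.frame(loads))
  utils::write.csv(
    data.frame(time_s = loads$time, M_Nm = loads$M,
               Fax_N = loads$Fax, Fay_N = loads$Fay,
               Fkx_N = loads$Fkx, Fky_N = loads$Fky,
               Fhx_N = loads$Fhx, Fhy_N = loads$Fhy,
               flag_edge = as.integer(loads$edge)),
    path, row.names = FALSE)
  invisible(path)
}
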