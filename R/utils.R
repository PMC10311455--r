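#' Degree / radian conversion
#'
#' All angles are radians inside the package; files, reports and the CLI use
#' degrees. These helpers do the boundary conversion.
#'
#' @param x numeric vector of angles.
#' @return numeric vector.
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

# standard gravity used throughout (m/s^2)
GRAVITY <- 9.81

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_invalid("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_invalid("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stop_invalid("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# uniform-grid check; returns the step
check_uniform_time <- function(time, what = "time", tol = 1e-9) {
  if (length(time) < 2L) stop_invalid("'%s' needs at least 2 samples", what)
  dt <- diff(time)
  if (any(dt <= 0)) stop_invalid("'%s' must be strictly increasing", what)
  if (max(dt) - min(dt) > tol * max(abs(dt)))
    stop_invalid("'%s' must lie on a uniform grid", what)
  mean(dt)
}

# second derivative on a uniform grid: central in the interior, one-sided
# (3-point, first-order) at the two ends.  The ends are flagged downstream.
second_derivative <- function(y, dt) {
  n <- length(y)
  if (n < 3L) stop_invalid("need at least 3 samples to differentiate twice")
  d2 <- numeric(n)
  d2[2:(n - 1)] <- (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]) / dt^2
  d2[1] <- (y[3] - 2 * y[2] + y[1]) / dt^2
  d2[n] <- (y[n] - 2 * y[n - 1] + y[n - 2]) / dt^2
  d2
}

# first derivative on a uniform grid: central interior, one-sided ends
first_derivative <- function(y, dt) {
  n <- length(y)
  if (n < 2L) stop_invalid("need at least 2 samples to differentiate")
  d1 <- numeric(n)
  if (n >= 3L) {
    d1[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  }
  d1[1] <- (y[2] - y[1]) / dt
  d1[n] <- (y[n] - y[n - 1]) / dt
  d1
}

# run `expr` with the RNG seeded by `seed`, restoring global RNG state after
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
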