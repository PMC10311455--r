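#' Sensor-noise specification
#'
#' Gaussian measurement noise applied to the synthetic recordings: i.i.d. on
#' every marker coordinate and every load-cell channel.  The same seed and
#' spec give bit-identical recordings.
#'
#' @param marker_sigma marker coordinate noise SD (m).
#' @param force_sigma load-cell channel noise SD (N).
#' @param seed RNG seed used for the recording noise.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(marker_sigma = 2e-4, force_sigma = 0.5, seed = 1L) {
  check_number(marker_sigma, "marker_sigma", 0)
  check_number(force_sigma, "force_sigma", 0)
  check_number(seed, "seed")
  structure(list(marker_sigma = marker_sigma, force_sigma = force_sigma,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Forward-simulate the instrumented phantom
#'
#' Drives the two-link phantom through a prescribed knee trajectory (the
#' position-controlled hexapod imposes the kinematics, so no ODE integration
#' is involved), applies the exoskeleton spring/brace model, solves the
#' Newton-Euler reaction forces with the spring moment known and the vertical
#' ankle force unknown, and emits marker and load-cell recordings at their
#' native sensor rates plus a noise-free ground-truth log.
#'
#' All dynamic quantities are produced on the force-rate (1000 Hz) grid, with
#' accelerations taken as the same second-order central differences the
#' analysis pipeline uses, so a noise-free simulation and the analysis chain
#' are discretely consistent with each other down to solver round-off.
#' Markers are emitted by subsampling that grid (the marker rate must divide
#' the force rate); medial/lateral markers sit symmetrically about the
#' sagittal plane at `+/- lateral_offset`, and in brace mode two spring-end
#' markers ride on the spring arms at radius `spring_arm` from the knee.
#' Load is split equally across the three load cells before noise.
#'
#' @param params a [phantom_params()] object.
#' @param traj a [knee_trajectory()] (any uniform rate; resampled internally).
#' @param exo an [exo_model()].
#' @param noise a [noise_spec()].
#' @param marker_rate marker output rate (Hz); must divide `force_rate`.
#' @param force_rate load-cell output and simulation rate (Hz).
#' @param lateral_offset mediolateral half-distance of joint marker pairs (m).
#'   It cancels in the midpoint computation, so its value is immaterial to
#'   downstream results.
#' @param spring_arm spring-end marker radius from the knee centre (m).
#' @param mount_angle spring-arm opening angle at zero deflection (rad).
#' @return an object of class `phantom_sim`: list with data frames `markers`
#'   (time + `<marker>_x/_y/_z`, m), `forces` (time, lc1..lc3, N), `truth`
#'   (noise-free time, theta_k, theta_s, M, Fay at the force rate), `loads`
#'   (all noise-free joint reactions) and the echoed inputs.
#' @examples
#' p <- phantom_params("braceless")
#' traj <- generate_gait_waveform(gait_waveform_spec(n_cycles = 2))
#' sim <- simulate_phantom(p, traj, exo_model("braceless", Ks = 16.6),
#'                         noise_spec(0, 0))
#' max(abs(sim$truth$M - 16.6 * sim$truth$theta_k))
#' @export
simulate_phantom <- function(params, traj, exo = exo_model("none"),
                             noise = noise_spec(), marker_rate = 100,
                             force_rate = 1000, lateral_offset = 0.05,
                             spring_arm = 0.06, mount_angle = pi) {
  params <- as_phantom_params(params)
  stopifnot(inherits(exo, "exo_model"), inherits(noise, "noise_spec"))
  if (!is.data.frame(traj) || !all(c("time", "theta_k") %in% names(traj)))
    stop_invalid("'traj' must be a knee_trajectory (time, theta_k)")
  dt_in <- check_uniform_time(traj$time)
  if (abs(force_rate / marker_rate - round(force_rate / marker_rate)) > 1e-9)
    stop_invalid("marker_rate must divide force_rate")
  dec <- as.integer(round(force_rate / marker_rate))

  # clamp simulation inputs into the mechanical range (warns if needed)
  traj <- knee_trajectory(traj$time, traj$theta_k, clamp = TRUE)

  # knee angle on the simulation (force-rate) grid
  if (abs(1 / dt_in - force_rate) < 1e-6 * force_rate) {
    time <- traj$time
    theta_k <- traj$theta_k
  } else {
    rs <- resample_spline(traj$time, traj$theta_k, force_rate)
    time <- rs$time
    theta_k <- rs$x
  }
  n <- length(time)
  dt <- 1 / force_rate

  ang <- segment_angles(params, theta_k)
  geo <- newton_euler_geometry(params, ang$theta_f, ang$theta_t)

  # exoskeleton knee moment from the spring law
  if (exo$mode == "none") {
    theta_s <- rep(NA_real_, n)
    M <- numeric(n)
  } else {
    theta_s <- brace_deflection(exo, theta_k)
    M <- spring_moment(exo, theta_s, first_derivative(theta_s, dt))
  }

  # accelerations by the same discrete operator the analysis uses
  alpha_f <- second_derivative(ang$theta_f, dt)
  alpha_t <- second_derivative(ang$theta_t, dt)
  ddx_f <- second_derivative(geo$com_f_x, dt)
  ddy_f <- second_derivative(geo$com_f_y, dt)
  ddx_t <- second_derivative(geo$com_t_x, dt)
  ddy_t <- second_derivative(geo$com_t_y, dt)

  # forward Newton-Euler solve: M known, six reaction components unknown
  # unknowns (Fax, Fay, Fkx, Fky, Fhx, Fhy)
  loads <- matrix(NA_real_, n, 6,
                  dimnames = list(NULL,
                                  c("Fax", "Fay", "Fkx", "Fky", "Fhx", "Fhy")))
  A <- matrix(0, 6, 6)
  for (i in seq_len(n)) {
    A[] <- 0
    A[1, c(1, 3)] <- 1                                   # shank sum Fx
    A[2, c(2, 4)] <- 1                                   # shank sum Fy
    A[3, 1] <- -geo$rA_y[i]; A[3, 2] <- geo$rA_x[i]      # shank sum M(COM)
    A[3, 3] <- -geo$rK_y[i]; A[3, 4] <- geo$rK_x[i]
    A[4, c(3, 5)] <- c(-1, 1)                            # femur sum Fx
    A[5, c(4, 6)] <- c(-1, 1)                            # femur sum Fy
    A[6, 3] <- geo$rK2_y[i]; A[6, 4] <- -geo$rK2_x[i]    # femur sum M(COM)
    A[6, 5] <- -geo$rH_y[i]; A[6, 6] <- geo$rH_x[i]
    b <- c(params$mt * ddx_t[i],
           params$mt * ddy_t[i] + params$wt,
           params$It * alpha_t[i] - M[i],
           params$mf * ddx_f[i],
           params$mf * ddy_f[i] + params$wf,
           params$If * alpha_f[i] + M[i])
    loads[i, ] <- solve(A, b)
  }
  Fay <- loads[, "Fay"]

  # marker positions (noise-free) on the marker grid
  mi <- seq(1, n, by = dec)
  mk <- data.frame(time = time[mi])
  joint_xy <- list(hip = cbind(0, 0)[rep(1, n), , drop = FALSE],
                   knee = cbind(geo$kx, geo$ky),
                   ankle = cbind(geo$ax, geo$ay))
  for (j in names(joint_xy)) {
    for (side in c("med", "lat")) {
      zoff <- if (side == "med") -lateral_offset else lateral_offset
      mk[[paste0(j, "_", side, "_x")]] <- joint_xy[[j]][mi, 1]
      mk[[paste0(j, "_", side, "_y")]] <- joint_xy[[j]][mi, 2]
      mk[[paste0(j, "_", side, "_z")]] <- rep(zoff, length(mi))
    }
  }
  if (exo$mode == "brace") {
    a_thigh <- ang$theta_f + pi / 2         # CCW angle of the knee->hip ray
    a_shank <- a_thigh - mount_angle - theta_s
    mk$spring_end_thigh_x <- (geo$kx + spring_arm * cos(a_thigh))[mi]
    mk$spring_end_thigh_y <- (geo$ky + spring_arm * sin(a_thigh))[mi]
    mk$spring_end_thigh_z <- rep(lateral_offset, length(mi))
    mk$spring_end_shank_x <- (geo$kx + spring_arm * cos(a_shank))[mi]
    mk$spring_end_shank_y <- (geo$ky + spring_arm * sin(a_shank))[mi]
    mk$spring_end_shank_z <- rep(lateral_offset, length(mi))
  }

  forces <- data.frame(time = time, lc1 = Fay / 3, lc2 = Fay / 3,
                       lc3 = Fay / 3)

  # measurement noise
  mk_noisy <- mk
  forces_noisy <- forces
  with_seed(noise$seed, {
    if (noise$marker_sigma > 0) {
      for (col in setdiff(names(mk), "time"))
        mk_noisy[[col]] <- mk[[col]] +
          stats::rnorm(nrow(mk), 0, noise$marker_sigma)
    }
    if (noise$force_sigma > 0) {
      for (col in c("lc1", "lc2", "lc3"))
        forces_noisy[[col]] <- forces[[col]] +
          stats::rnorm(n, 0, noise$force_sigma)
    }
  })

  truth <- data.frame(time = time, theta_k = theta_k, theta_s = theta_s,
                      M = M, Fay = Fay)
  structure(list(markers = mk_noisy, forces = forces_noisy, truth = truth,
                 loads = as.data.frame(loads),
                 params = params, exo = exo, noise = noise,
                 marker_rate = marker_rate, force_rate = force_rate,
                 lateral_offset = lateral_offset, spring_arm = spring_arm,
                 mount_angle = mount_angle),
            class = "phantom_sim")
}

#' @export
print.phantom_sim <- function(x, ...) {
  cat(sprintf("Phantom simulation: %.1f s, exo mode '%s'\n",
              max(x$truth$time), x$exo$mode))
  cat(sprintf("  markers: %d samples @ %g Hz; load cells: %d samples @ %g Hz\n",
              nrow(x$markers), x$marker_rate, nrow(x$forces), x$force_rate))
  cat(sprintf("  noise: marker %.2g m, force %.2g N (seed %d)\n",
              x$noise$marker_sigma, x$noise$force_sigma, x$noise$seed))
  invisible(x)
}

#' Simulate a torsional-spring bench test
#'
#' Emulates loading a single spring on a materials-testing machine over a
#' triangle wave (default 45 degree amplitude, 1 Hz, 14 cycles, recorded at
#' 99.9 Hz).  The moment follows the elastic line `Ks * angle`, optionally
#' with a rate-sign-symmetric hysteretic offset and Gaussian noise.
#'
#' @param Ks_single stiffness of this spring (N m/rad).
#' @param amplitude triangle amplitude (rad).
#' @param freq triangle frequency (Hz).
#' @param n_cycles number of loading cycles.
#' @param rate recording rate (Hz); must exceed `2 * freq`.
#' @param moment_sigma moment noise SD (N m).
#' @param hysteresis_offset half-width (N m) of a symmetric loading/unloading
#'   moment split, `+h` while deflecting and `-h` while returning.
#' @param seed RNG seed for the noise.
#' @return a data frame of class `torsion_recording` with `time` (s), `angle`
#'   (rad) and `moment` (N m).
#' @export
simulate_torsion_test <- function(Ks_single, amplitude = deg2rad(45),
                                  freq = 1, n_cycles = 14, rate = 99.9,
                                  moment_sigma = 0, hysteresis_offset = 0,
                                  seed = 1L) {
  check_number(Ks_single, "Ks_single", 0)
  check_number(amplitude, "amplitude", 0, strict_lower = TRUE)
  check_number(freq, "freq", 0, strict_lower = TRUE)
  check_number(n_cycles, "n_cycles", 1)
  check_number(rate, "rate", 2 * freq, strict_lower = TRUE)
  check_number(moment_sigma, "moment_sigma", 0)
  check_number(hysteresis_offset, "hysteresis_offset", 0)
  n <- floor(n_cycles / freq * rate) + 1
  time <- seq(0, by = 1 / rate, length.out = n)
  u <- (time * freq) %% 1
  tri <- ifelse(u < 0.25, 4 * u, ifelse(u < 0.75, 2 - 4 * u, 4 * u - 4))
  dtri_sign <- ifelse(u < 0.25 | u >= 0.75, 1, -1)
  angle <- amplitude * tri
  moment <- Ks_single * angle + hysteresis_offset * dtri_sign
  if (moment_sigma > 0)
    moment <- moment + with_seed(seed, stats::rnorm(n, 0, moment_sigma))
  structure(data.frame(time = time, angle = angle, moment = moment),
            rate = rate, class = c("torsion_recording", "data.frame"))
}
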