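test_that("zero-phase filter has unit DC gain and the analytic rolloff", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  mid <- 500:2500  # clear of residual edge transients

  expect_equal(zero_phase_lowpass(rep(2.5, 1000), fs, 6, 4), rep(2.5, 1000))

  # passband: 1 Hz through a 6 Hz cutoff is preserved within 1 %
  y1 <- zero_phase_lowpass(sin(2 * pi * t), fs, 6, 4)
  expect_equal(max(abs(y1[mid])), 1, tolerance = 0.01)

  # the forward-backward pass realizes the squared Butterworth magnitude:
  # check at 3 Hz (measurable) and that 50 Hz is crushed to the |H|^2 level
  y3 <- zero_phase_lowpass(sin(2 * pi * 3 * t), fs, 6, 4)
  expect_equal(max(abs(y3[mid])), 1 / (1 + (3 / 6)^8), tolerance = 1e-4)
  y50 <- zero_phase_lowpass(sin(2 * pi * 50 * t), fs, 6, 4)
  expect_lt(max(abs(y50[mid])), 1e-7)  # analytic |H|^2 = 4.3e-8

  expect_error(zero_phase_lowpass(sin(t), 10, 6, 4), "Nyquist")
})

test_that("filtered below-cutoff sinusoid has zero lag", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  y <- zero_phase_lowpass(x, fs, 6, 4)
  cc <- stats::ccf(y[200:800], x[200:800], lag.max = 10, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
})

test_that("spline resampling reproduces cubics exactly and sinusoids closely", {
  tm <- seq(0, 1, by = 0.01)
  cub <- 2 + 3 * tm - tm^2 + 0.5 * tm^3
  rs <- resample_spline(tm, cub, 1000)
  expect_equal(rs$x, 2 + 3 * rs$time - rs$time^2 + 0.5 * rs$time^3,
               tolerance = 1e-12)

  expect_equal(unique(resample_spline(tm, rep(4, length(tm)), 1000)$x), 4)

  tm2 <- seq(0, 2, by = 0.01)
  s <- sin(2 * pi * 2 * tm2)
  rs2 <- resample_spline(tm2, s, 1000)
  err <- abs(rs2$x - sin(2 * pi * 2 * rs2$time))
  interior <- rs2$time > 0.02 & rs2$time < 1.98
  expect_lt(max(err[interior]), 1e-6)  # h^4 f'''' / 384 ~ 6.5e-7
  expect_lt(max(err), 2e-6)            # FMM end conditions at the edges

  expect_error(resample_spline(c(0, 0.1, 0.2), c(1, 2, 3), 1000), "4 samples")
})

test_that("joint centers are medial/lateral midpoints projected to sagittal", {
  sim <- sim_braceless_bypass()
  ctr <- joint_centers(sim$markers)
  # against the geometric joint positions
  jp <- joint_positions(sim$params, sim$truth$theta_k)
  expect_lt(max(abs(ctr$knee_x - jp$knee[, "x"])), 1e-12)
  expect_lt(max(abs(ctr$knee_y - jp$knee[, "y"])), 1e-12)
  expect_lt(max(abs(ctr$ankle_y - jp$ankle[, "y"])), 1e-12)

  # midpoint linearity: displacing one marker by delta moves the center by half
  mk <- sim$markers
  mk$knee_med_x <- mk$knee_med_x + 0.01
  ctr2 <- joint_centers(mk)
  expect_equal(ctr2$knee_x - ctr$knee_x, rep(0.005, nrow(ctr)))

  mk$knee_lat_y <- NULL
  expect_error(joint_centers(mk), "knee_lat_y")
})

test_that("scaling marker coordinates scales lengths but not angles", {
  sim <- sim_braceless_bypass()
  p <- sim$params
  ctr <- joint_centers(sim$markers)
  mk2 <- sim$markers
  for (col in setdiff(names(mk2), "time")) mk2[[col]] <- 2 * mk2[[col]]
  ctr2 <- joint_centers(mk2)
  seg <- sqrt((ctr$knee_x - ctr$hip_x)^2 + (ctr$knee_y - ctr$hip_y)^2)
  seg2 <- sqrt((ctr2$knee_x - ctr2$hip_x)^2 + (ctr2$knee_y - ctr2$hip_y)^2)
  expect_equal(seg2, 2 * seg, tolerance = 1e-12)
  a1 <- angles_and_accels(ctr, p)
  a2 <- angles_and_accels(ctr2, phantom_params(p$condition, lf = 2 * p$lf,
                                               lt = 2 * p$lt))
  expect_equal(a2$theta_k, a1$theta_k, tolerance = 1e-12)
})

test_that("segment kinematics recover prescribed angles and accelerations", {
  p <- phantom_params()
  # static pose: zero accelerations, theta_k recovered
  th0 <- deg2rad(35)
  jp <- joint_positions(p, rep(th0, 200))
  ctr <- data.frame(time = seq(0, by = 1e-3, length.out = 200),
                    hip_x = jp$hip[, "x"], hip_y = jp$hip[, "y"],
                    knee_x = jp$knee[, "x"], knee_y = jp$knee[, "y"],
                    ankle_x = jp$ankle[, "x"], ankle_y = jp$ankle[, "y"])
  pr <- angles_and_accels(ctr, p)
  expect_lt(max(abs(pr$ddx_f)), 1e-9)
  expect_lt(max(abs(pr$alpha_t)), 1e-9)
  expect_equal(pr$theta_k, rep(th0, 200), tolerance = 1e-12)

  # full extension: both segments vertical
  jp0 <- joint_positions(p, rep(0, 10))
  ctr0 <- data.frame(time = seq(0, by = 1e-3, length.out = 10),
                     hip_x = jp0$hip[, "x"], hip_y = jp0$hip[, "y"],
                     knee_x = jp0$knee[, "x"], knee_y = jp0$knee[, "y"],
                     ankle_x = jp0$ankle[, "x"], ankle_y = jp0$ankle[, "y"])
  pr0 <- angles_and_accels(ctr0, p)
  expect_equal(pr0$theta_f, pr0$theta_t)
  expect_equal(pr0$theta_k, rep(0, 10))

  # sinusoidal knee angle: discrete second derivative matches -A w^2 sin
  A <- deg2rad(10); w <- 2 * pi
  tm <- seq(0, 2, by = 1e-3)
  th <- deg2rad(30) + A * sin(w * tm)
  jps <- joint_positions(p, th)
  ctrs <- data.frame(time = tm,
                     hip_x = jps$hip[, "x"], hip_y = jps$hip[, "y"],
                     knee_x = jps$knee[, "x"], knee_y = jps$knee[, "y"],
                     ankle_x = jps$ankle[, "x"], ankle_y = jps$ankle[, "y"])
  prs <- angles_and_accels(ctrs, p)
  ddk <- prs$alpha_f - prs$alpha_t
  ref <- -A * w^2 * sin(w * tm)
  interior <- 50:(length(tm) - 50)
  expect_lt(max(abs(ddk[interior] - ref[interior])), 1e-3 * A * w^2)
})

test_that("spring angle from markers matches the generator ground truth", {
  sim <- fixture("sim_brace_bypass", function()
    simulate_phantom(phantom_params("brace"), default_gait(2), brace_exo(),
                     noise_spec(0, 0), marker_rate = 1000))
  ctr <- joint_centers(sim$markers)
  th_s <- spring_angle_from_markers(sim$markers, ctr)
  expect_lt(max(abs(th_s - sim$truth$theta_s)), 1e-9)

  # rigid rotation of the whole marker set leaves the relative angle alone
  rot <- 0.3
  mk <- sim$markers
  for (m in c("hip_med", "hip_lat", "knee_med", "knee_lat", "ankle_med",
              "ankle_lat", "spring_end_thigh", "spring_end_shank")) {
    x <- mk[[paste0(m, "_x")]]; y <- mk[[paste0(m, "_y")]]
    mk[[paste0(m, "_x")]] <- cos(rot) * x - sin(rot) * y
    mk[[paste0(m, "_y")]] <- sin(rot) * x + cos(rot) * y
  }
  th_s_rot <- spring_angle_from_markers(mk, joint_centers(mk))
  expect_equal(th_s_rot, th_s, tolerance = 1e-9)

  # free pose: arms at the mounting angle -> zero deflection
  mk0 <- data.frame(time = 0:9 / 100,
                    knee_x = 0, knee_y = 0,
                    spring_end_thigh_x = 0, spring_end_thigh_y = 0.06,
                    spring_end_thigh_z = 0,
                    spring_end_shank_x = 0, spring_end_shank_y = -0.06,
                    spring_end_shank_z = 0)
  ctr0 <- data.frame(time = mk0$time, knee_x = 0, knee_y = 0)
  expect_equal(spring_angle_from_markers(mk0, ctr0), rep(0, 10))

  expect_error(spring_angle_from_markers(sim_braceless_bypass()$markers,
                                         ctr), "spring-end")
})

test_that("load-cell fusion sums channels and enforces the schema", {
  tm <- seq(0, 0.099, by = 1e-3)
  f <- data.frame(time = tm, lc1 = rep(1, 100), lc2 = rep(2, 100),
                  lc3 = rep(3, 100))
  expect_equal(fuse_load_cells(f, cutoff = NULL)$Fay, rep(6, 100))
  expect_equal(fuse_load_cells(f)$Fay, rep(6, 100))  # DC through the filter
  f0 <- f; f0$lc1 <- f0$lc2 <- f0$lc3 <- 0
  expect_equal(fuse_load_cells(f0, cutoff = NULL)$Fay, rep(0, 100))
  expect_error(fuse_load_cells(f[, c("time", "lc1", "lc2")]), "lc3")

  # noise-free simulation: unfiltered fusion equals the solved Fay
  sim <- sim_braceless_bypass()
  expect_lt(max(abs(fuse_load_cells(sim$forces, cutoff = NULL)$Fay -
                      sim$truth$Fay)), 1e-9)
})

test_that("tracking RMSE matches closed forms", {
  tm <- seq(0, 5 - 0.01, by = 0.01)
  target <- knee_trajectory(tm, deg2rad(30 + 10 * sin(2 * pi * tm)))
  expect_equal(tracking_rmse(target, target), 0)
  shifted <- knee_trajectory(tm, target$theta_k + deg2rad(2))
  expect_equal(tracking_rmse(shifted, target), 2, tolerance = 1e-9)
  wobble <- knee_trajectory(tm, target$theta_k + deg2rad(1) * sin(2 * pi * tm))
  expect_equal(tracking_rmse(wobble, target), 1 / sqrt(2), tolerance = 1e-3)
})
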