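test_that("profile fit on an exact line recovers slope and zero intercept", {
  th <- deg2rad(seq(2, 70, length.out = 500))
  fit <- assistance_profile(th, 15.9 * th)
  expect_equal(fit$slope, 15.9, tolerance = 1e-12)
  expect_equal(fit$x_intercept_deg, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("regressions agree with the closed-form normal equations", {
  set.seed(8)
  th <- runif(2000, 0.05, 1.2)
  M <- 14 * th - 0.5 + rnorm(2000, 0, 0.3)
  fit <- assistance_profile(th, M)
  ref <- ols_oracle(th, M)
  expect_equal(fit$slope, unname(ref["slope"]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(ref["intercept"]), tolerance = 1e-12)
  # deflection regression equals the oracle on the same inputs
  ths <- 0.96 * th + rnorm(2000, 0, 1e-3)
  dr <- deflection_regression(ths, th)
  ref2 <- ols_oracle(th, ths)
  expect_lt(abs(dr$slope - ref2["slope"]), 1e-12)
  expect_lt(abs(deg2rad(dr$offset_deg) - ref2["intercept"]), 1e-12)
})

test_that("zero moment gives a flagged undefined x-intercept", {
  th <- deg2rad(seq(2, 70, length.out = 300))
  fit <- assistance_profile(th, rep(0, 300))
  expect_equal(fit$slope, 0)
  expect_false(fit$x_intercept_defined)
  expect_true(is.nan(fit$x_intercept_deg))
  expect_error(assistance_profile(rep(0.5, 100), rnorm(100)), "degenerate")
})

test_that("hysteresis of canonical loops matches closed forms", {
  # purely elastic loop: zero enclosed area
  th <- deg2rad(c(seq(5, 65, length.out = 100), seq(65, 5, length.out = 100)))
  expect_lt(workloop_hysteresis(15 * th, th, 200), 1e-12)

  # rectangle loop with explicit vertical segments at the corners:
  # load at M = 1 over theta 0 -> 1, drop to 0.5, unload back, rise again
  th_r <- c(seq(0, 1, length.out = 101), 1, seq(1, 0, length.out = 101))
  M_r <- c(rep(1, 101), 0.5, rep(0.5, 101))
  expect_equal(workloop_hysteresis(M_r, th_r, length(th_r)), 0.5,
               tolerance = 1e-12)

  # viscous ellipse: theta = A sin(wt), M = K theta + b dtheta/dt encloses
  # pi * b * w * A^2
  A <- 0.5; w <- 2 * pi; K <- 12; b <- 0.4
  tm <- seq(0, 3, by = 1e-3)
  th_e <- A * sin(w * tm)
  M_e <- K * th_e + b * A * w * cos(w * tm)
  spc <- 1000
  n_use <- 3 * spc
  ratio <- workloop_hysteresis(M_e[1:n_use], th_e[1:n_use], spc)
  dth <- diff(th_e[1:(n_use + 1)])
  mbar <- (M_e[2:(n_use + 1)] + M_e[1:n_use]) / 2
  positive <- sum(pmax(mbar * dth, 0))
  expect_equal(ratio, 3 * pi * b * w * A^2 / positive, tolerance = 1e-3)

  expect_error(workloop_hysteresis(rep(0, 100), seq(0, 1, length.out = 100),
                                   100), "positive work")
})

test_that("adjusted profile equals the knee profile for braceless data", {
  ana <- ana_braceless_ideal()
  expect_equal(ana$profile_spring$slope, ana$profile_knee$slope)
  expect_equal(ana$profile_spring$x_intercept_deg,
               ana$profile_knee$x_intercept_deg)
})

test_that("chain rule links spring- and knee-basis slopes through compliance", {
  ana <- ana_brace_ideal()
  expect_equal(ana$profile_knee$slope, ana$profile_spring$slope * 0.96,
               tolerance = 0.005)
  # engagement offset maps through the inverted compliance line
  expect_equal(ana$profile_knee$x_intercept_deg,
               (ana$profile_spring$x_intercept_deg + 7.4) / 0.96,
               tolerance = 0.05)
})

test_that("deflection regression recovers the configured compliance", {
  ana <- ana_brace_ideal()
  expect_equal(ana$deflection$slope, 0.96, tolerance = 1e-3)
  expect_equal(ana$deflection$offset_deg, -7.4, tolerance = 0.02)

  # noisy: estimates within 2 standard errors of the generator values
  simn <- fixture("sim_brace_noisy", function()
    simulate_phantom(phantom_params("brace"), default_gait(5), brace_exo(),
                     noise_spec(2e-4, 0.5, seed = 7)))
  anan <- analyze_phantom(simn$markers, simn$forces, phantom_params("brace"))
  d <- anan$deflection
  expect_lt(abs(d$slope - 0.96), 2 * pmax(d$slope_se, 2e-3))
})

test_that("spring characterization sums per-spring stiffness", {
  recs <- lapply(1:4, function(i) simulate_torsion_test(4.15))
  chr <- characterize_springs(recs)
  expect_equal(chr$cumulative, 16.6, tolerance = 1e-9)
  expect_equal(chr$springs$stiffness, rep(4.15, 4), tolerance = 1e-9)
  expect_equal(chr$cumulative, sum(chr$springs$stiffness))

  # zero-stiffness spring
  expect_equal(characterize_springs(simulate_torsion_test(0))$cumulative, 0,
               tolerance = 1e-12)

  # symmetric hysteretic offset does not bias the slope
  reco <- simulate_torsion_test(4.15, hysteresis_offset = 0.3)
  chro <- characterize_springs(reco, cutoff = NULL)
  ref <- ols_oracle(reco$angle, reco$moment)
  expect_equal(chro$cumulative, unname(ref["slope"]), tolerance = 1e-12)
  expect_equal(chro$cumulative, 4.15, tolerance = 5e-3)

  # constant angle is degenerate
  flat <- data.frame(time = seq(0, 1, by = 0.01), angle = 0.2, moment = 1)
  class(flat) <- c("torsion_recording", "data.frame")
  expect_error(characterize_springs(flat, cutoff = NULL), "degenerate")
})

test_that("hysteresis grows with interface damping, not with compliance", {
  base <- ana_brace_ideal()$profile_knee$auc_ratio
  sims <- lapply(c(0.05, 0.15), function(b)
    simulate_phantom(phantom_params("brace"), default_gait(5), brace_exo(b),
                     noise_spec(0, 0)))
  aucs <- vapply(sims, function(s)
    analyze_phantom(s$markers, s$forces,
                    phantom_params("brace"))$profile_knee$auc_ratio,
    numeric(1))
  expect_true(all(diff(c(base, aucs)) > 0))

  # compliance alone (b = 0): ground-truth loop stays purely elastic
  simb <- sim_brace_ideal()
  expect_lt(workloop_hysteresis(simb$truth$M, simb$truth$theta_s, 1000), 1e-9)
  # on the knee angle too: the moment is still a line in theta_k
  expect_lt(workloop_hysteresis(simb$truth$M, simb$truth$theta_k, 1000), 1e-9)
})

test_that("stiffness relative difference reproduces the bench comparison", {
  expect_equal(stiffness_relative_difference(15.9, 16.6),
               100 * (16.6 - 15.9) / 16.6, tolerance = 1e-12)
})

test_that("assistance_profile methods are coherent", {
  th <- deg2rad(seq(5, 65, length.out = 400))
  set.seed(2)
  M <- 15 * th - 0.2 + rnorm(400, 0, 0.1)
  fit <- assistance_profile(th, M, samples_per_cycle = 200)
  expect_equal(unname(coef(fit)), c(fit$intercept, fit$slope))
  expect_equal(predict(fit, 0.5), fit$intercept + fit$slope * 0.5)
  expect_equal(mean(residuals(fit)), 0, tolerance = 1e-12)
  expect_identical(fit$n_cycles, 2L)
  expect_output(print(fit), "stiffness")
  expect_output(print(summary(fit)), "per-cycle")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
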