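# shared fixtures, built lazily once per test run

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_gait <- function(n_cycles = 15) {
  generate_gait_waveform(gait_waveform_spec(n_cycles = n_cycles))
}

# noise-free braceless simulation with the bench-characterized spring pack
sim_braceless_ideal <- function() fixture("sim_braceless_ideal", function() {
  simulate_phantom(phantom_params("braceless"), default_gait(),
                   exo_model("braceless", Ks = 16.6), noise_spec(0, 0))
})

# same, but markers emitted at the force rate for filter-bypass validation
sim_braceless_bypass <- function() fixture("sim_braceless_bypass", function() {
  simulate_phantom(phantom_params("braceless"), default_gait(4),
                   exo_model("braceless", Ks = 16.6), noise_spec(0, 0),
                   marker_rate = 1000)
})

# noise-free brace simulation with the soft-tissue compliance line
brace_exo <- function(damping_b = 0) {
  exo_model("brace", Ks = 15.2, theta_free = deg2rad(-0.884),
            damping_b = damping_b, compliance_c = 0.96,
            compliance_d = deg2rad(-7.4))
}

sim_brace_ideal <- function() fixture("sim_brace_ideal", function() {
  simulate_phantom(phantom_params("brace"), default_gait(), brace_exo(),
                   noise_spec(0, 0))
})

ana_braceless_ideal <- function() fixture("ana_braceless_ideal", function() {
  s <- sim_braceless_ideal()
  analyze_phantom(s$markers, s$forces, phantom_params("braceless"))
})

ana_brace_ideal <- function() fixture("ana_brace_ideal", function() {
  s <- sim_brace_ideal()
  analyze_phantom(s$markers, s$forces, phantom_params("brace"))
})

# closed-form simple-regression oracle (normal equations)
ols_oracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}
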