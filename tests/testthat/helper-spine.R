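# shared fixtures: memoised default parameters and expensive runs reused
# across test files (all deterministic)

the_fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (is.null(the_fixture_cache[[key]])) the_fixture_cache[[key]] <- fn()
  the_fixture_cache[[key]]
}

p_default <- function() fixture("p_default", default_parameters)

# 100 s unstimulated ER+ trajectory (rest stability + conservation checks)
quiet_run_100s <- function() {
  fixture("quiet100", function() {
    run_protocol(quiet_protocol(100), p_default(), er = TRUE, dt_quiet = 0.5)
  })
}

# unitary-pulse ER+ trajectory at the calibrated NMDAR conductance
er_pulse_calibrated <- function() {
  fixture("er_pulse_cal", function() {
    g <- calibrate_gN(p_default(), 0.2)
    run_protocol(unitary_epsp(), attr(g, "params"), er = TRUE, active_window = 3)
  })
}

# random nonnegative full state for derivative-agreement and conservation tests
random_state <- function(seed) {
  set.seed(seed)
  y <- stats::setNames(
    abs(stats::rnorm(spinestore:::n_states(), 1, 0.6)),
    spinestore:::state_names()
  )
  y["u"] <- stats::runif(1, -80, 10)
  y["ud"] <- stats::runif(1, -80, 10)
  y["mu"] <- stats::runif(1); y["hu"] <- stats::runif(1)
  y["h"] <- stats::runif(1); y["w"] <- stats::runif(1, -0.5, 1)
  y
}
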