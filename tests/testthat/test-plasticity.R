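test_that("active calmodulin under lobe independence", {
  p <- p_default()
  expect_equal(active_cam(p$CaM_total, p$CaM_total, p), 0)
  expect_equal(active_cam(0, p$CaM_total, p), 50) # all C-lobes occupied
  expect_equal(active_cam(25, 25, p), 50 * 0.75) # p(C0) = p(N0) = 0.5 -> 37.5
})

test_that("attractor function: limits, quiescent zone, depression plateau", {
  p <- p_default() # theta_D = 2, theta_P = 4, slopes 60
  expect_equal(omega_w(1e3, p), 0.5, tolerance = 1e-12)
  expect_lt(abs(omega_w(0, p)), 1e-10)
  expect_equal(omega_w(3, p), -0.5, tolerance = 1e-10) # mid-band plateau
  # bounded in (-0.5, 1)
  a <- seq(0, 50, by = 0.25)
  expect_true(all(omega_w(a, p) >= -0.5 & omega_w(a, p) <= 1))
})

test_that("weight time constant spans hours at rest to seconds at induction", {
  p <- p_default()
  expect_equal(tau_w(0, p), 10001)
  expect_gte(tau_w(0, p), 3600) # hours-scale persistence
  mid <- (p$theta_D + p$theta_P) / 2
  expect_equal(tau_w(mid, p), 1 + 10 / 1.001, tolerance = 1e-12)
  expect_lte(tau_w(mid, p), 60) # seconds-scale induction
  a <- seq(0, 50, by = 0.5)
  expect_true(all(diff(tau_w(a, p)) < 0))
})

test_that("weight dynamics: fixed point and exact exponential relaxation", {
  p <- p_default()
  a <- 3.2
  expect_equal(weight_derivative(omega_w(a, p), a, p), 0)
  # constant aCaM: replay matches the closed-form relaxation
  tt <- seq(0, 30, by = 0.05)
  w <- replay_weight(tt, rep(a, length(tt)), p)
  w_exact <- omega_w(a, p) * (1 - exp(-tt / tau_w(a, p)))
  expect_equal(w, w_exact, tolerance = 1e-9)
})

test_that("replayed weight agrees with the jointly integrated weight", {
  p <- p_default()
  proto <- stdp_train(10, n_pairings = 4, n_bap = 2)
  q <- default_parameters(list(theta_D = 5, theta_P = 15))
  traj <- run_protocol(proto, q, er = FALSE, dt_active = 1e-3)
  w_replay <- replay_weight(traj$time, traj$acam, q)
  expect_equal(w_replay[length(w_replay)], traj$w[nrow(traj)], tolerance = 5e-3)
})

test_that("threshold calibration rejects degenerate or non-increasing targets", {
  p <- p_default()
  expect_error(calibrate_thresholds(p, "rate", targets = c(5, 5)), "degenerate")
  expect_error(calibrate_thresholds(p, "rate", targets = c(15, 1)), "degenerate")
})

test_that("calibrated rate thresholds produce the target sign pattern", {
  p <- p_default()
  pc <- fixture("rate_calibrated", function() {
    calibrate_thresholds(p, "rate", targets = c(1, 15), n_events = 20)
  })
  expect_gt(pc$theta_P, pc$theta_D)
  # theta_D close to the specific published operating point (~2 uM)
  expect_gt(pc$theta_D, 1)
  expect_lt(pc$theta_D, 3)
  cm <- fixture("rate_curve_minus", function() {
    plasticity_curve(pc, "rate", c(0.5, 4, 8, 12, 18), er = FALSE, n_events = 20)
  })
  # no plasticity below the LTD boundary, depression inside the window,
  # potentiation above the LTP boundary (scaled 20-input trains)
  expect_lt(abs(cm$dw[cm$x == 0.5]), 0.01)
  expect_lt(cm$dw[cm$x == 4], -0.001)
  expect_lt(cm$dw[cm$x == 12], -0.01)
  expect_gt(cm$dw[cm$x == 18], 0.01)
})

test_that("with the ER store the 1 Hz train depresses while the ER-less spine does not", {
  p <- p_default()
  pc <- fixture("rate_calibrated", function() {
    calibrate_thresholds(p, "rate", targets = c(1, 15), n_events = 20)
  })
  tm <- run_protocol(rate_train(1, n_spikes = 20), pc, er = FALSE, dt_active = 5e-3)
  tp <- run_protocol(rate_train(1, n_spikes = 20), pc, er = TRUE, dt_active = 5e-3)
  expect_lt(abs(tm$w[nrow(tm)]), 0.01)
  expect_lt(tp$w[nrow(tp)], tm$w[nrow(tm)] - 0.005)
})
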