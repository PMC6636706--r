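test_that("compiled and reference right-hand sides agree exactly", {
  p <- p_default()
  for (seed in 1:5) {
    y <- random_state(seed)
    for (flags in list(
      list(er = TRUE, vgcc = TRUE, co_input = FALSE, stdp_mode = FALSE),
      list(er = FALSE, vgcc = FALSE, co_input = TRUE, stdp_mode = FALSE),
      list(er = TRUE, vgcc = TRUE, co_input = FALSE, stdp_mode = TRUE)
    )) {
      ctx <- spinestore:::run_context(
        p,
        er = flags$er, vgcc = flags$vgcc, co_input = flags$co_input,
        stdp_mode = flags$stdp_mode, nu_ip3 = 0.05, glu_const = 1
      )
      dr <- spinestore:::spine_rhs_r(0, y, ctx)[[1]]
      dc <- spinestore:::spine_rhs_c(y, ctx)
      expect_lt(max(abs(dr - dc) / pmax(abs(dr), 1e-8)), 1e-12)
    }
  }
})

test_that("rest state: 50 nM calcium, resting IP3, h at its steady state", {
  p <- p_default()
  rest <- find_rest(p, er = TRUE)
  expect_equal(rest$state[["ca"]], 0.05, tolerance = 1e-4 / 0.05)
  expect_equal(rest$state[["ip3"]], 0.1, tolerance = 1e-3)
  expect_equal(rest$state[["h"]], 0.8, tolerance = 1e-6)
  expect_equal(rest$state[["u"]], p$u_rest)
  expect_equal(rest$state[["w"]], 0)
  expect_lt(rest$residual, 1e-9)
})

test_that("the rest state is stationary under integration", {
  p <- p_default()
  traj <- run_protocol(quiet_protocol(20), p, er = TRUE, dt_quiet = 0.5)
  rest <- find_rest(p, er = TRUE)
  for (nm in spinestore:::state_names()) {
    scale <- max(abs(rest$state[[nm]]), 1e-3)
    expect_lt(max(abs(traj[[nm]] - rest$state[[nm]])) / scale, 1e-6)
  }
})

test_that("an ER with no channels and no pump is identical to no ER", {
  p <- default_parameters(list(N_R = 0, V_S = 0))
  t_er <- run_protocol(unitary_epsp(1.5), p, er = TRUE)
  t_no <- run_protocol(unitary_epsp(1.5), p, er = FALSE)
  expect_lt(max(abs(t_er$ca - t_no$ca)), 1e-9)
  expect_lt(max(abs(t_er$u - t_no$u)), 1e-6)
  expect_true(all(t_er$J_ER == 0))
})

test_that("unitary EPSP: few-mV depolarization and sub-uM calcium transient", {
  p <- p_default()
  traj <- run_protocol(unitary_epsp(1.5), p, er = FALSE)
  depol <- max(traj$u) - p$u_rest
  expect_gt(depol, 1)
  expect_lt(depol, 8)
  dca <- max(traj$ca) - p$Ca_rest
  expect_gt(dca, 0.15)
  expect_lt(dca, 0.25)
  # free calcium nonnegative throughout
  expect_true(all(traj$ca >= 0))
})

test_that("solution is converged: halving tolerances barely moves the peak", {
  p <- p_default()
  t1 <- run_protocol(unitary_epsp(1.2), p, er = FALSE)
  t2 <- run_protocol(unitary_epsp(1.2), p, er = FALSE, rtol = 5e-7, atol = 5e-10)
  rel <- abs(max(t1$ca) - max(t2$ca)) / (max(t1$ca) - p$Ca_rest)
  expect_lt(rel, 0.005)
})

test_that("bAP-driven spine depolarization is monotone in the bAP amplitude", {
  depol <- vapply(c(30, 67, 100), function(v0) {
    q <- default_parameters(list(V_0 = v0))
    traj <- run_protocol(single_bap(0.5), q, er = FALSE, active_window = 0.3)
    max(traj$u) - q$u_rest
  }, numeric(1))
  expect_true(all(diff(depol) > 0))
})

test_that("trajectory flux channels are recomputed consistently from states", {
  p <- p_default()
  traj <- er_pulse_calibrated()
  ctx <- attr(traj, "ctx")
  i <- which.max(traj$ca) # spot-check at the release peak
  of <- ip3r_open_fraction(traj$ip3[i], traj$ca[i], traj$h[i], ctx$p)
  expect_equal(traj$J_ICCR[i], iccr_flux(of, traj$ca[i], ctx$p), tolerance = 1e-12)
  expect_equal(
    traj$J_ER[i],
    traj$J_ICCR[i] - traj$serca_uptake[i] + traj$serca_leak[i],
    tolerance = 1e-12
  )
})
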