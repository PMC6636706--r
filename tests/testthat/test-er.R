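test_that("IP3R activation variables take their half-activation values", {
  p <- p_default()
  # m1 = 0.5 at IP3 = d_1, m2 = 0.5 at Ca = d_5, h supplied
  expect_equal(ip3r_open_fraction(p$d_1, p$d_5, 1, p), (0.5 * 0.5)^3)
  expect_equal(ip3r_open_fraction(0, 0.3, 0.8, p), 0)
  # exponent conventions differ in the documented direction
  ph <- default_parameters(list())
  ph$open_fraction_exponent <- "h_only"
  of_g <- ip3r_open_fraction(0.5, 0.2, 0.7, p)
  of_h <- ip3r_open_fraction(0.5, 0.2, 0.7, ph)
  expect_gt(of_h, of_g)
})

test_that("inactivation gate: steady states and fixed point", {
  p <- p_default()
  expect_equal(h_derivative(0.5, 0.2, p), 0) # h_inf(K_inh) = 0.5
  h_inf <- p$K_inh / (p$K_inh + 0.05)
  expect_equal(h_inf, 0.8)
  expect_equal(h_derivative(h_inf, 0.05, p), 0)
  # interval preservation: dh > 0 at h = 0, dh < 0 at h = 1 for any Ca >= 0
  for (ca in c(0, 0.1, 1, 10)) {
    expect_gte(h_derivative(0, ca, p), 0)
    expect_lte(h_derivative(1, ca, p), 0)
  }
})

test_that("single-channel current and cluster flux scale as specified", {
  p <- p_default()
  # alpha corresponds to 0.15 pA per open channel at dCa = 0.5 mM
  expect_equal(ip3r_single_channel_current(500, p), 0.15, tolerance = 1e-12)
  # linearity in cluster size
  f1 <- iccr_flux(0.01, 0.05, p)
  p2 <- default_parameters(list(N_R = 60))
  expect_equal(iccr_flux(0.01, 0.05, p2), 2 * f1, tolerance = 1e-12)
  p0 <- default_parameters(list(N_R = 0))
  expect_equal(iccr_flux(1, 0.05, p0), 0)
})

test_that("SERCA: Hill midpoint, zero-calcium limits, rest balance", {
  p <- p_default()
  s <- serca_flux(p$K_S, p)
  expect_equal(s$uptake, p$V_S / 2)
  s0 <- serca_flux(0, p)
  expect_equal(s0$uptake, 0)
  expect_gt(s0$leak, 0)
  sr <- serca_flux(p$Ca_rest, p)
  expect_equal(sr$uptake - sr$leak, 0, tolerance = 1e-12)
})

test_that("steady-state open fraction is bell-shaped in calcium", {
  p <- p_default()
  ca <- exp(seq(log(0.02), log(5), length.out = 60))
  of <- vapply(ca, function(c0) {
    ip3r_open_fraction(0.5, c0, p$K_inh / (p$K_inh + c0), p)
  }, numeric(1))
  i_max <- which.max(of)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(ca))
  # rising then falling branches
  expect_true(all(diff(of[1:i_max]) > 0))
  expect_true(all(diff(of[i_max:length(of)]) < 0))
})

test_that("net ER flux vanishes at the trimmed rest state", {
  p <- p_default()
  rest <- find_rest(p, er = TRUE)
  y <- rest$state
  of <- ip3r_open_fraction(y[["ip3"]], y[["ca"]], y[["h"]], p)
  upt <- p$V_S * y[["ca"]]^2 / (y[["ca"]]^2 + p$K_S^2)
  leak <- rest$k_S_eff * (p$Ca_ER - y[["ca"]])
  expect_equal(iccr_flux(of, y[["ca"]], p) - upt + leak, 0, tolerance = 1e-12)
})

test_that("glutamate evokes delayed store release even with NMDAR blocked", {
  p <- default_parameters(list(g_N = 1e-9))
  traj <- run_protocol(unitary_epsp(), p, er = TRUE, active_window = 3)
  post <- traj[traj$time > 0.3, ]
  expect_gt(max(post$ca), p$Ca_rest + 0.5)
  # the release is delayed, not stimulus-locked
  expect_gt(post$time[which.max(post$ca)] - 0.1, 0.2)
})
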