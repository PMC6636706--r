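test_that("AMPAR waveform: boundary values and analytic peak", {
  p <- p_default()
  expect_equal(ampar_conductance(0, p), 0)
  expect_lt(ampar_conductance(0.5, p), 1e-10)
  # analytic maximum of g_A (e^(-t/tau_d) - e^(-t/tau_r))
  t_star <- log(p$tau_A_d / p$tau_A_r) / (1 / p$tau_A_r - 1 / p$tau_A_d)
  expect_equal(t_star, 0.5117e-3, tolerance = 1e-3)
  g_star <- p$g_A * (exp(-t_star / p$tau_A_d) - exp(-t_star / p$tau_A_r))
  expect_equal(g_star, 0.34842, tolerance = 1e-4)
  expect_equal(ampar_conductance(t_star, p), g_star, tolerance = 1e-12)
  # train responses sum over pulses
  expect_equal(
    ampar_conductance(0.015, p, pulse_times = c(0, 0.01)),
    ampar_conductance(0.015, p) + ampar_conductance(0.005, p),
    tolerance = 1e-12
  )
})

test_that("magnesium block takes its printed sigmoid values", {
  expect_equal(mg_block(0), 1 / 1.28, tolerance = 1e-12)
  expect_equal(mg_block(-70), 1 / (1 + 0.28 * exp(0.062 * 70)), tolerance = 1e-12)
  expect_equal(mg_block(-70), 0.04449, tolerance = 1e-3)
  p <- p_default()
  expect_equal(nmdar_conductance(0, -70, p), 0)
})

test_that("VGCC gates: sigmoid midpoints and fixed points", {
  p <- p_default()
  g <- vgcc_gate_derivatives(p$u_m, 0.2, 0.2, p)
  expect_equal(g$m_inf, 0.5)
  g2 <- vgcc_gate_derivatives(p$u_h, 0.2, 0.2, p)
  expect_equal(g2$h_inf, 0.5)
  g3 <- vgcc_gate_derivatives(-40, NA, NA, p)
  g4 <- vgcc_gate_derivatives(-40, g3$m_inf, g3$h_inf, p)
  expect_equal(g4$dm, 0)
  expect_equal(g4$dh, 0)
})

test_that("GHK drive is continuous at u = 0 and gives inward flux", {
  p <- p_default()
  d0 <- spinestore:::ghk_drive(0, 0.05, p$Ca_ext)
  dm <- spinestore:::ghk_drive(-1e-6, 0.05, p$Ca_ext)
  dp <- spinestore:::ghk_drive(1e-6, 0.05, p$Ca_ext)
  expect_equal(d0, 0.05 - p$Ca_ext, tolerance = 1e-9)
  expect_equal(dm, d0, tolerance = 1e-6)
  expect_equal(dp, d0, tolerance = 1e-6)
  # closed gate -> no current; open gate influx positive over 0..40 mV
  expect_equal(lvgcc_ca_flux(10, 0, 0.5, 0.05, p), 0)
  for (u in seq(0, 40, by = 10)) {
    expect_gt(lvgcc_ca_flux(u, 0.5, 0.5, 0.05, p), 0)
  }
  # NMDAR calcium flux: zero gating -> zero; influx at rest
  expect_equal(nmdar_ca_flux(-70, 0.05, 0, p), 0)
  expect_gt(nmdar_ca_flux(-70, 0.05, 0.5, p), 0)
})

test_that("bAP waveform: onset amplitude, causality, decay value", {
  p <- p_default()
  expect_equal(bap_waveform(0, p), 67)
  expect_equal(bap_waveform(-1e-3, p), 0)
  expect_equal(bap_waveform(3e-3, p), 35.901, tolerance = 1e-4)
  # two bAPs sum
  expect_equal(
    bap_waveform(0.012, p, bap_times = c(0, 0.01)),
    bap_waveform(0.012, p) + bap_waveform(0.002, p)
  )
})
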