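test_that("immobile-buffer equilibrium matches the first-order dissociation constant", {
  p <- p_default()
  eq <- buffer_equilibrium(0.05, p)
  kd <- p$kb_CBP / p$kf_CBP # 524/247 ~ 2.121 uM
  expect_equal(eq[["cbp_b"]] / p$CBP_total, 0.05 / (0.05 + kd), tolerance = 1e-12)
  expect_equal(eq[["cbp_b"]] / p$CBP_total, 0.02302, tolerance = 1e-3)
})

test_that("buffers at equilibrium have zero derivatives and zero net flux", {
  p <- p_default()
  for (ca in c(0.05, 0.3, 2)) {
    eq <- buffer_equilibrium(ca, p)
    bd <- buffer_derivatives(ca, eq, p)
    expect_lt(max(abs(bd$d)), 1e-9)
    expect_lt(abs(bd$J_B), 1e-9)
  }
})

test_that("buffering conserves total calcium and buffer totals", {
  p <- p_default()
  for (seed in 1:4) {
    y <- random_state(seed)
    buf <- y[names(buffer_equilibrium(0.05, p))]
    bd <- buffer_derivatives(0.7, buf, p)
    # bound-calcium stoichiometry per species
    cb_names <- paste0("cb_", c("00", "10", "20", "01", "11", "21", "02", "12", "22"))
    cb_stoich <- c(0, 1, 2, 1, 2, 3, 2, 3, 4)
    bound_rate <- sum(bd$d[cb_names] * cb_stoich) +
      bd$d[["cbp_b"]] + bd$d[["slow_b"]] +
      bd$d[["cam_c1"]] + 2 * bd$d[["cam_c2"]] +
      bd$d[["cam_n1"]] + 2 * bd$d[["cam_n2"]]
    expect_equal(bd$J_B, -bound_rate, tolerance = 1e-9)
    # molecule totals unchanged
    expect_equal(sum(bd$d[cb_names]), 0, tolerance = 1e-9)
    expect_equal(sum(bd$d[c("cam_c0", "cam_c1", "cam_c2")]), 0, tolerance = 1e-9)
    expect_equal(sum(bd$d[c("cam_n0", "cam_n1", "cam_n2")]), 0, tolerance = 1e-9)
  }
})

test_that("pump cycle: rest balance, saturation limit, zero density", {
  p <- p_default()
  eq <- buffer_equilibrium(0.05, p)
  expect_equal(pump_flux(0.05, eq[["pmca_b"]], eq[["ncx_b"]], p)$J_out, 0,
    tolerance = 1e-12
  )
  # strong calcium: efflux saturates at k3 * [pump] (steady-state cycle)
  ca <- 500
  b_p <- p$PMCA_total * p$kf_PMCA * ca / (p$kf_PMCA * ca + p$kb_PMCA + p$k3_PMCA)
  b_n <- p$NCX_total * p$kf_NCX * ca / (p$kf_NCX * ca + p$kb_NCX + p$k3_NCX)
  J <- pump_flux(ca, b_p, b_n, p)$J_out
  leak <- p$kL_PMCA * (p$PMCA_total - b_p) + p$kL_NCX * (p$NCX_total - b_n)
  expect_equal(J, p$k3_PMCA * b_p + p$k3_NCX * b_n - leak, tolerance = 1e-9)
  expect_equal(J / (p$k3_PMCA * p$PMCA_total + p$k3_NCX * p$NCX_total), 1,
    tolerance = 0.01
  )
  p0 <- p; p0$PMCA_total <- 0; p0$NCX_total <- 0
  expect_equal(pump_flux(0.5, 0, 0, p0)$J_out, 0)
})

test_that("calcium derivative is the algebraic flux sum", {
  expect_equal(calcium_derivative(), 0)
  expect_equal(calcium_derivative(J_N = 2, J_ER = 1, J_B = -0.5, J_out = 0.5), 2)
})

test_that("removing the buffers increases the unitary EPSP calcium peak", {
  p <- p_default()
  base <- run_protocol(unitary_epsp(1), p, er = FALSE, active_window = 0.6)
  p0 <- default_parameters(list(
    CB_total = 1e-9, CBP_total = 1e-9, slow_total = 1e-9, CaM_total = 1e-9
  ))
  free <- run_protocol(unitary_epsp(1), p0, er = FALSE, active_window = 0.6)
  expect_gt(max(free$ca), 2 * max(base$ca))
})
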