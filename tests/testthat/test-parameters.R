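test_that("default parameter set carries the tabulated constants and derived fields", {
  p <- p_default()
  expect_equal(p$g_N, 0.065) # 65 pS in nS
  expect_equal(p$alpha, 937.5)
  expect_equal(p$tau_glu, 1e-3)
  expect_equal(p$G_max, 300)
  expect_equal(p$CB_total, 45)
  expect_equal(p$Ca_ER, 250)
  expect_equal(p$d_1, 0.8)
  expect_equal(p$a_1b, 2) # scaled-down glutamate unbinding
  expect_equal(p$b_11, 2) # scaled-down GAP rate

  # spine area: sphere of volume V_spine (identity to 1e-10 relative)
  r <- (3 * p$V_spine / (4 * pi))^(1 / 3)
  expect_equal(p$A_spine, 4 * pi * r^2, tolerance = 1e-12)
  expect_equal(p$A_spine, 0.74117, tolerance = 1e-4)

  # pump concentrations from surface densities (hand-computed)
  expect_equal(p$PMCA_total, 20.5095, tolerance = 1e-4)
  expect_equal(p$NCX_total, 2.8713, tolerance = 1e-4)

  # derived pump leak rates agree with the printed values at their precision
  expect_equal(p$kL_PMCA, 3.33, tolerance = 2e-3)
  expect_equal(p$kL_NCX, 10, tolerance = 1e-12)
})

test_that("pump leak construction balances transport exactly at rest", {
  p <- p_default()
  eq <- buffer_equilibrium(p$Ca_rest, p)
  fl <- pump_flux(p$Ca_rest, eq[["pmca_b"]], eq[["ncx_b"]], p)
  expect_equal(fl$J_out, 0, tolerance = 1e-12)
  expect_equal(fl$d_pmca, 0, tolerance = 1e-10)
  expect_equal(fl$d_ncx, 0, tolerance = 1e-10)
})

test_that("SERCA leak derivation solves the stated rest balance", {
  p <- p_default()
  ks <- derive_serca_leak(p)
  expect_equal(ks, 2.3534e-4, tolerance = 1e-4)
  # exact balance: leak equals uptake at rest
  expect_equal(ks * (p$Ca_ER - p$Ca_rest),
    p$V_S * p$Ca_rest^2 / (p$Ca_rest^2 + p$K_S^2),
    tolerance = 1e-14
  )
  p0 <- p; p0$V_S <- 0
  expect_equal(derive_serca_leak(p0), 0)
  p2 <- p; p2$V_S <- 2 * p$V_S
  expect_equal(derive_serca_leak(p2), 2 * ks, tolerance = 1e-14)
  pbad <- p; pbad$Ca_ER <- 0.01
  expect_error(derive_serca_leak(pbad), "Ca_ER")
})

test_that("configuration loading: identity, overrides, validation", {
  expect_identical(load_config(list()), p_default())
  expect_equal(load_config(list(N_R = 50))$N_R, 50)
  expect_error(load_config(list(theta_P = 1.0, theta_D = 2.0)), "theta_P")
  expect_error(load_config(list(nonsense_key = 1)), "unknown parameter")
  expect_error(load_config(list(CB_total = -1)), "CB_total")
})

test_that("configuration round-trips through the YAML format bit-identically", {
  p <- default_parameters(list(N_R = 37, theta_D = 1.234567890123))
  f <- withr::local_tempfile(fileext = ".yaml")
  save_config(p, f)
  p2 <- load_config(f)
  expect_identical(unclass(p2), unclass(p))
})

test_that("every equation symbol resolves to exactly one registry field", {
  map <- spinestore:::equation_symbol_map()
  reg <- parameter_registry()
  expect_true(all(map %in% reg$name))
  expect_false(any(duplicated(map)))
  p <- p_default()
  for (nm in map) expect_false(is.null(p[[nm]]), info = nm)
})

test_that("registry units are consistent with reaction molecularity", {
  p <- p_default()
  reg <- parameter_registry()
  units <- stats::setNames(reg$unit, reg$name)
  for (r in spinestore:::cascade_reactions()) {
    n_react <- sum(r$from)
    u <- units[[r$rate]]
    expected <- switch(as.character(n_react),
      "1" = "s^-1", "2" = "uM^-1 s^-1", "3" = "uM^-2 s^-1"
    )
    expect_identical(u, expected, info = paste(r$rate, r$name))
  }
})
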