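test_that("glutamate pulse: alpha function normalised to its printed peak", {
  p <- p_default()
  expect_equal(glutamate_pulse(p$tau_glu, p), 300, tolerance = 1e-12)
  expect_equal(glutamate_pulse(0, p), 0)
  expect_equal(glutamate_pulse(10e-3, p), 300 * 10 * exp(-9), tolerance = 1e-9)
  expect_equal(glutamate_pulse(10e-3, p), 0.3702, tolerance = 1e-3)
  # pulses in a train sum
  expect_equal(
    glutamate_pulse(3e-3, p, pulse_times = c(0, 2e-3)),
    glutamate_pulse(3e-3, p) + glutamate_pulse(1e-3, p)
  )
})

test_that("reaction table is auditable: every rate symbol used once, mass action", {
  p <- p_default()
  tab <- cascade_reaction_table(p)
  expect_false(any(duplicated(tab$rate_symbol)))
  reg <- parameter_registry()
  expect_true(all(tab$rate_symbol %in% reg$name))
  expect_equal(tab$rate, vapply(tab$rate_symbol, function(s) p[[s]], numeric(1)),
    ignore_attr = TRUE
  )
  # the three rates the model slows down relative to its source are present
  slowed <- tab$rate[tab$rate_symbol %in% c("a_1b", "a_2b", "b_11")]
  expect_equal(slowed, c(2, 2, 2), ignore_attr = TRUE)
})

test_that("cascade derivatives conserve every molecular total on random states", {
  p <- p_default()
  sp <- cascade_species_names()
  grp <- spinestore:::conserved_groups()
  grp <- grp[c("mGluR", "Gq_alpha", "Gq_betagamma", "PLC", "IP3K", "IP5P")]
  for (seed in 1:5) {
    y <- random_state(seed)[sp]
    cd <- cascade_derivatives(y, glu = 50, ca = 0.4, p = p, nu_ip3 = 0.1)
    for (nm in names(grp)) {
      members <- intersect(grp[[nm]], sp)
      expect_lt(abs(sum(cd$d[members])), 1e-9)
    }
  }
})

test_that("constitutive source holds resting IP3; degradation-only state sits lower", {
  p <- p_default()
  nu <- basal_ip3_balance(p)
  expect_gt(nu, 0)
  ss <- spinestore:::cascade_steady_state(p, ca = p$Ca_rest, glu = 0, nu_ip3 = nu)
  expect_equal(ss[["ip3"]], 0.1, tolerance = 1e-3 / 0.1)
  ss0 <- spinestore:::cascade_steady_state(p, ca = p$Ca_rest, glu = 0, nu_ip3 = 0)
  expect_lt(ss0[["ip3"]], 0.1)
  # more 5-phosphatase lowers stationary IP3 at fixed source
  p2 <- default_parameters(list(IP5P_total = 2))
  ss2 <- spinestore:::cascade_steady_state(p2, ca = p2$Ca_rest, glu = 0, nu_ip3 = nu)
  expect_lt(ss2[["ip3"]], ss[["ip3"]])
})

test_that("sustained glutamate drives IP3 above its basal level within a second", {
  p <- p_default()
  nu <- basal_ip3_balance(p)
  after1s <- spinestore:::cascade_steady_state(
    p, ca = p$Ca_rest, glu = 300, nu_ip3 = nu, t_relax = 1
  )
  expect_gt(after1s[["ip3"]], 0.15)
})

test_that("IP3 production is monotone in the receptor level", {
  p <- p_default()
  nu <- basal_ip3_balance(p)
  lo <- spinestore:::cascade_steady_state(p, ca = 0.1, glu = 10, nu_ip3 = nu)
  p_hi <- default_parameters(list(mGluR_total = 0.45))
  hi <- spinestore:::cascade_steady_state(p_hi, ca = 0.1, glu = 10, nu_ip3 = nu)
  expect_gt(hi[["ip3"]], lo[["ip3"]])
})

test_that("IP3 transient peaks with a delay; faster source rates shorten or abolish it", {
  p <- p_default()
  lat <- ip3_timecourse_latency(p)
  expect_gt(lat, 0.1)
  expect_lt(lat, 2)
  # reverting the three slowed rates to their source-model values removes the
  # slow receptor/G-protein dwell: the IP3 response is earlier or too small to
  # register as an event
  pr <- default_parameters(list(a_1b = 100, a_2b = 100, b_11 = 8))
  latr <- ip3_timecourse_latency(pr)
  expect_true(is.na(latr) || latr < lat)
  # no glutamate -> no event
  expect_true(is.na(ip3_timecourse_latency(p, protocol = quiet_protocol(2))))
})
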