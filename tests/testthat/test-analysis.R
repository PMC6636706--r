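# synthetic trajectory with two Gaussian calcium bumps, as a constructed
# fixture for the peak metrics
synthetic_double_bump <- function(h1 = 0.3, h2 = 0.3, t2 = 0.5, rest = 0.05) {
  tt <- seq(0, 2, by = 1e-3)
  onset <- 0.1
  # first (stimulus-locked) bump 50 ms after onset, second t2 later
  ca <- rest + h1 * exp(-((tt - onset - 0.05) / 0.015)^2) +
    h2 * exp(-((tt - (onset + 0.05 + t2)) / 0.05)^2)
  traj <- tibble::tibble(time = tt, ca = ca)
  attr(traj, "onset") <- onset
  traj
}

test_that("release delay and peak ratio on constructed double-bump traces", {
  tr <- synthetic_double_bump(h1 = 0.3, h2 = 0.3, t2 = 0.4)
  expect_equal(iccr_delay(tr), 450, tolerance = 1e-2)
  expect_equal(peak_ratio(tr), 1.0, tolerance = 1e-2)
  tr2 <- synthetic_double_bump(h1 = 0.2, h2 = 0.5, t2 = 0.6)
  expect_equal(iccr_delay(tr2), 650, tolerance = 1e-2)
  expect_equal(peak_ratio(tr2), 2.5, tolerance = 2e-2)
  # moving the second peak by 200 ms moves the measured delay by 200 ms
  expect_equal(iccr_delay(tr2) - iccr_delay(tr), 200, tolerance = 1e-2)
  # single bump -> no event
  tr1 <- synthetic_double_bump(h2 = 0)
  expect_true(is.na(iccr_delay(tr1)))
  expect_true(is.na(peak_ratio(tr1)))
  # no stimulus-locked first peak -> error
  tr0 <- synthetic_double_bump(h1 = 0, h2 = 0.3)
  expect_error(iccr_delay(tr0), "first")
})

test_that("peak detection is robust to the output sampling density", {
  p <- p_default()
  traj <- er_pulse_calibrated()
  d1 <- iccr_delay(traj)
  coarse <- traj[seq(1, nrow(traj), by = 5), ] # 1 kHz -> 200 Hz
  attr(coarse, "protocol") <- attr(traj, "protocol")
  d2 <- iccr_delay(coarse)
  expect_lt(abs(d1 - d2), 5)
})

test_that("threshold shifts recover exact displacements of synthetic curves", {
  x <- seq(0, 20, by = 0.5)
  shape <- function(x, s) {
    # piecewise-linear: flat 0, LTD trough, zero crossing, LTP
    approx(
      c(0, 4, 10, 15, 20) + s, c(0, 0, -0.3, 0, 0.3),
      xout = x, rule = 2
    )$y
  }
  cm <- tibble::tibble(x = x, dw = shape(x, 0), er = FALSE)
  cp <- tibble::tibble(x = x, dw = shape(x, -0.5), er = TRUE)
  class(cm) <- class(cp) <- c("spine_plasticity_curve", class(cm))
  attr(cm, "family") <- attr(cp, "family") <- "rate"
  s0 <- threshold_shifts(cm, cm)
  expect_equal(s0$d_ltd, 0)
  expect_equal(s0$d_ltp, 0)
  s <- threshold_shifts(cm, cp)
  expect_equal(s$d_ltd, -0.5, tolerance = 1e-9)
  expect_equal(s$d_ltp, -0.5, tolerance = 1e-9)
})

test_that("STDP window widths measure the plasticity-inducing timing sets", {
  x <- seq(-50, 50, by = 5)
  dw <- ifelse(x >= -30 & x <= -10, -0.1, ifelse(x >= 5 & x <= 25, 0.1, 0))
  w <- spinestore:::window_widths(x, dw)
  # boundary half-intervals included at half weight
  expect_equal(w[["ltd"]], 25)
  expect_equal(w[["ltp"]], 25)
  w0 <- spinestore:::window_widths(x, rep(0, length(x)))
  expect_equal(w0[["ltd"]], 0)
})

test_that("open-probability map: basal column flat, inhibition branch monotone", {
  p <- p_default()
  map <- fixture("popen_map", function() steady_state_popen_map(p))
  expect_true(all(map$converged))
  # no-glutamate column: near-basal, small and flat
  base <- map[map$glu == 0, ]
  expect_lt(max(base$popen), 1e-4)
  expect_lt(diff(range(base$popen)) / max(base$popen), 1)
  # high-calcium branch: open probability decreasing (receptor inactivation)
  col <- map[map$glu == max(map$glu), ]
  hi <- col[col$ca > 1, ]
  expect_true(all(diff(hi$popen[order(hi$ca)]) < 0))
  # activation peaks at sub-micromolar calcium
  pk <- popen_peak_ca(map)
  expect_gt(pk, 0.1)
  expect_lt(pk, 0.6)
})

test_that("sensitivity sampling is reproducible and handles empty draws", {
  # synthetic trace cache: aCaM profiles shaped so LTD/LTP windows exist
  grid <- seq(-50, 50, by = 10)
  mk_trace <- function(x, amp) {
    tt <- seq(0, 10, by = 0.05)
    # asymmetric timing profile (stronger on the pre-before-post side)
    acam <- amp * exp(-(((x - 10)) / 40)^2) * rep(1, length(tt))
    list(x = x, time = tt, acam = acam, smax_acam = max(acam))
  }
  minus <- lapply(grid, mk_trace, amp = 10)
  plus <- lapply(
    stats::setNames(c(10, 30, 50), c(10, 30, 50)),
    function(nr) lapply(grid, mk_trace, amp = 10 + nr / 10)
  )
  cache <- structure(
    list(
      p = p_default(), family = "stdp", grid = grid,
      n_r_values = c(10, 30, 50), n_events = 1, n_bap = 2,
      minus = minus, plus = plus,
      smax_minus = vapply(minus, `[[`, numeric(1), "smax_acam")
    ),
    class = "spine_trace_cache"
  )
  s1 <- sensitivity_sample(cache, n_draws = 20, seed = 11)
  s2 <- sensitivity_sample(cache, n_draws = 20, seed = 11)
  expect_identical(s1, s2)
  s3 <- sensitivity_sample(cache, n_draws = 20, seed = 12)
  expect_false(identical(s1$target_D, s3$target_D))
  s0 <- sensitivity_sample(cache, n_draws = 0, seed = 1)
  expect_equal(nrow(s0), 0)
})

test_that("curve and map objects expose tidy/glance/autoplot interfaces", {
  x <- seq(0, 20, by = 1)
  cm <- tibble::tibble(x = x, dw = sin(x / 3) / 10, er = FALSE)
  class(cm) <- c("spine_plasticity_curve", class(cm))
  attr(cm, "family") <- "rate"
  td <- tidy(cm)
  expect_named(td, c("x", "dw", "er"))
  gl <- glance(cm)
  expect_true(all(c("ltd_width", "ltp_width") %in% names(gl)))
  expect_s3_class(autoplot(cm), "ggplot")
  rest <- find_rest(p_default(), er = TRUE)
  expect_equal(glance(rest)$ca_nM, 50, tolerance = 1e-3)
  traj <- er_pulse_calibrated()
  expect_s3_class(autoplot(traj), "ggplot")
})
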