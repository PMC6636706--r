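# Derived metrics and experiment orchestration: ICCR delay and peak ratio,
# steady-state IP3R open-probability maps, plasticity curves, differential
# ER+/ER- metrics and seeded sensitivity sampling.

#' @importFrom dplyr %>% mutate filter arrange bind_rows group_by summarise
NULL

# local maxima (strict) of a sampled series
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
}

ca_peaks <- function(traj, onset) {
  post <- traj[traj$time >= onset, c("time", "ca")]
  rest <- traj$ca[max(1, which.max(traj$time >= onset) - 1)]
  idx <- local_maxima(post$ca)
  tibble::tibble(
    time = post$time[idx], ca = post$ca[idx], height = post$ca[idx] - rest,
    rest = rest
  )
}

#' Delay of the ER calcium release peak
#'
#' Time from glutamate application to the second local maximum of free
#' calcium (the delayed IP3R-mediated release), requiring a prominence of at
#' least 5% of the first (NMDAR-mediated) peak.
#'
#' @param traj a `spine_trajectory` from a single-pulse protocol.
#' @return Delay in ms, or `NA` ("no event") if no second peak exists.
#' @export
iccr_delay <- function(traj) {
  pk <- split_double_peak(traj)
  if (is.null(pk)) rlang::abort("trace lacks a first (stimulus-locked) calcium peak")
  if (is.na(pk$t2)) return(NA_real_)
  (pk$t2 - pk$onset) * 1000
}

#' Second-to-first calcium peak ratio
#'
#' `(second peak - rest) / (first peak - rest)` for a single-pulse ER
#' trajectory.
#'
#' @param traj a `spine_trajectory`.
#' @return Dimensionless ratio, or `NA` if the second peak is absent.
#' @export
peak_ratio <- function(traj) {
  pk <- split_double_peak(traj)
  if (is.null(pk)) rlang::abort("trace lacks a first (stimulus-locked) calcium peak")
  if (is.na(pk$t2)) return(NA_real_)
  pk$h2 / pk$h1
}

# identify the stimulus-locked first peak (within 150 ms of glutamate) and
# the delayed second peak with >= 5% relative prominence
split_double_peak <- function(traj) {
  proto <- attr(traj, "protocol")
  onset <- if (!is.null(proto) && length(proto$glu_times) > 0) {
    proto$glu_times[1]
  } else attr(traj, "onset")
  if (is.null(onset)) rlang::abort("trajectory carries no glutamate onset time")
  pks <- ca_peaks(traj, onset)
  first <- pks[pks$time - onset <= 0.15, ]
  if (nrow(first) == 0) return(NULL)
  i1 <- which.max(first$height)
  t1 <- first$time[i1]; h1 <- first$height[i1]
  later <- pks[pks$time > t1, ]
  rest <- pks$rest[1]
  post <- traj[traj$time >= t1, c("time", "ca")]
  res <- list(onset = onset, t1 = t1, h1 = h1, t2 = NA_real_, h2 = NA_real_)
  for (k in seq_len(nrow(later))) {
    t2 <- later$time[k]; h2 <- later$height[k]
    trough <- min(post$ca[post$time >= t1 & post$time <= t2]) - rest
    prom <- h2 - max(trough, 0)
    if (h2 >= 0.05 * h1 && prom >= 0.05 * h1) {
      res$t2 <- t2; res$h2 <- h2
      break
    }
  }
  res
}

# maximum steady-state amplitude during a train: maximum over the last 20%
# of the stimulation period
#' Steady-state maxima during a stimulation train
#'
#' Maximum of a trajectory column over the last 20% of the stimulation
#' period (skipping the initial transient).
#'
#' @param traj a `spine_trajectory`.
#' @param var column name (default `"ca"`).
#' @return The steady-state maximum.
#' @export
steady_max <- function(traj, var = "ca") {
  proto <- attr(traj, "protocol")
  ev <- sort(c(proto$glu_times, proto$bap_times))
  t_lo <- ev[1] + 0.8 * (ev[length(ev)] - ev[1])
  sel <- traj$time >= t_lo & traj$time <= ev[length(ev)] + 0.5
  if (!any(sel)) sel <- rep(TRUE, nrow(traj))
  max(traj[[var]][sel])
}

#' Steady-state IP3R open-probability map
#'
#' For every combination of clamped glutamate and clamped cytosolic calcium,
#' relaxes the mGluR-PLC-IP3 cascade to stationarity, then evaluates the
#' steady-state IP3R open probability with the inactivation gate at its
#' calcium-dependent steady state.
#'
#' @param p a `spine_params` object.
#' @param glu_grid clamped glutamate values (uM).
#' @param ca_grid clamped calcium values (uM).
#' @param t_relax relaxation horizon per cell (s).
#' @return A tibble with columns `glu`, `ca`, `ip3`, `popen`, `converged`.
#' @export
steady_state_popen_map <- function(p,
                                   glu_grid = c(0, 1, 3, 10, 30, 100, 300),
                                   ca_grid = exp(seq(log(0.01), log(3), length.out = 48)),
                                   t_relax = 1500) {
  nu <- basal_ip3_balance(p)
  rows <- list()
  for (g in glu_grid) {
    init <- NULL
    for (ca in ca_grid) {
      ss <- cascade_steady_state(
        p, ca = ca, glu = g, nu_ip3 = nu, t_relax = t_relax, init = init
      )
      init <- ss # warm start along the Ca sweep
      cd <- cascade_derivatives(ss, glu = g, ca = ca, p = p, nu_ip3 = nu)
      converged <- max(abs(cd$d)) < 1e-7 * max(1, max(abs(ss)))
      h_inf <- p$K_inh / (p$K_inh + ca)
      rows[[length(rows) + 1]] <- tibble::tibble(
        glu = g, ca = ca, ip3 = ss[["ip3"]],
        popen = ip3r_open_fraction(ss[["ip3"]], ca, h_inf, p),
        converged = converged
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("spine_popen_map", class(out))
  out
}

#' Calcium level maximising the steady-state open probability
#'
#' Locates the grid maximum of a [steady_state_popen_map()] and refines the
#' calcium coordinate by quadratic interpolation in log-calcium within the
#' maximising glutamate column.
#'
#' @param map output of [steady_state_popen_map()].
#' @return Calcium concentration (uM) of the maximum.
#' @export
popen_peak_ca <- function(map) {
  i <- which.max(map$popen)
  col <- map[map$glu == map$glu[i], ]
  col <- col[order(col$ca), ]
  j <- which.max(col$popen)
  if (j == 1 || j == nrow(col)) return(col$ca[j])
  x <- log(col$ca[(j - 1):(j + 1)])
  y <- col$popen[(j - 1):(j + 1)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  if (a >= 0) return(col$ca[j])
  exp(-b / (2 * a))
}

#' Plasticity induction curve
#'
#' Total weight change at the end of a stimulation protocol, as a function
#' of the induction variable: input rate (Hz) for the rate family, spike
#' timing difference (ms) for the STDP family.
#'
#' @param p a `spine_params` object (thresholds as calibrated).
#' @param family `"rate"` or `"stdp"`.
#' @param grid induction-variable grid.
#' @param er simulate with (`TRUE`) or without the ER store.
#' @param n_events inputs per run (rate) or pairings (STDP).
#' @param n_bap bAPs per pairing (STDP family).
#' @param keep_traces keep the aCaM time courses (attribute `"traces"`) for
#'   later weight replay.
#' @param dt_active trajectory sampling interval (s).
#' @return A tibble of class `spine_plasticity_curve` with columns `x`,
#'   `dw`, `er`.
#' @export
plasticity_curve <- function(p, family = c("rate", "stdp"), grid,
                             er = TRUE, n_events = 100, n_bap = 2,
                             keep_traces = FALSE, dt_active = 2e-3) {
  family <- match.arg(family)
  traces <- vector("list", length(grid))
  dw <- numeric(length(grid))
  for (i in seq_along(grid)) {
    proto <- if (family == "rate") rate_train(grid[i], n_spikes = n_events)
      else stdp_train(grid[i], n_pairings = n_events, n_bap = n_bap)
    traj <- run_protocol(proto, p, er = er, dt_active = dt_active)
    dw[i] <- traj$w[nrow(traj)]
    if (keep_traces) {
      traces[[i]] <- list(
        x = grid[i], time = traj$time, acam = traj$acam,
        smax_acam = steady_max_acam(traj, proto)
      )
    }
  }
  out <- tibble::tibble(x = grid, dw = dw, er = er)
  class(out) <- c("spine_plasticity_curve", class(out))
  attr(out, "family") <- family
  if (keep_traces) attr(out, "traces") <- traces
  out
}

# linearly interpolated boundary where the curve enters the region dw < -tol
# (down = TRUE) or crosses zero upward (down = FALSE)
curve_crossing <- function(x, dw, tol = 0.01, kind = c("ltd_onset", "zero_up")) {
  kind <- match.arg(kind)
  if (kind == "ltd_onset") {
    below <- dw < -tol
    i <- which(below)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(x[1])
    stats::approx(dw[(i - 1):i], x[(i - 1):i], xout = -tol)$y
  } else {
    i_trough <- which.min(dw)
    cand <- which(dw[-length(dw)] <= 0 & dw[-1] > 0)
    cand <- cand[cand >= i_trough] # upward crossing after the LTD trough
    if (length(cand) == 0) return(NA_real_)
    i <- cand[1]
    stats::approx(dw[i:(i + 1)], x[i:(i + 1)], xout = 0)$y
  }
}

# widths (measure) of the LTD / LTP windows of a curve on its grid
window_widths <- function(x, dw, tol = 0.01) {
  measure <- function(mask) {
    if (!any(mask)) return(0)
    w <- 0
    for (i in seq_len(length(x) - 1)) {
      xm <- (mask[i] + mask[i + 1]) / 2 # 0, 0.5 or 1 of the subinterval
      w <- w + xm * (x[i + 1] - x[i])
    }
    w
  }
  c(ltd = measure(dw < -tol), ltp = measure(dw > tol))
}

#' Threshold shifts between ER- and ER+ plasticity curves
#'
#' For the rate family: differences of the interpolated LTD-onset and
#' LTP zero-crossing frequencies. For the STDP family: differences of the
#' LTD/LTP window widths (measure of the timing set with `|dw| > tol`).
#'
#' @param curve_minus,curve_plus curves on the same grid
#'   ([plasticity_curve()]).
#' @param tol weight-change tolerance defining induced plasticity.
#' @return A one-row tibble: `d_ltd`, `d_ltp` (plus the per-curve values).
#' @export
threshold_shifts <- function(curve_minus, curve_plus, tol = 0.01) {
  stopifnot(isTRUE(all.equal(curve_minus$x, curve_plus$x)))
  family <- attr(curve_minus, "family")
  if (is.null(family)) family <- "rate"
  if (family == "rate") {
    fD_m <- curve_crossing(curve_minus$x, curve_minus$dw, tol, "ltd_onset")
    fD_p <- curve_crossing(curve_plus$x, curve_plus$dw, tol, "ltd_onset")
    fP_m <- curve_crossing(curve_minus$x, curve_minus$dw, tol, "zero_up")
    fP_p <- curve_crossing(curve_plus$x, curve_plus$dw, tol, "zero_up")
    tibble::tibble(
      family = family,
      ltd_minus = fD_m, ltd_plus = fD_p, d_ltd = fD_p - fD_m,
      ltp_minus = fP_m, ltp_plus = fP_p, d_ltp = fP_p - fP_m
    )
  } else {
    wm <- window_widths(curve_minus$x, curve_minus$dw, tol)
    wp <- window_widths(curve_plus$x, curve_plus$dw, tol)
    tibble::tibble(
      family = family,
      ltd_minus = wm[["ltd"]], ltd_plus = wp[["ltd"]],
      d_ltd = wp[["ltd"]] - wm[["ltd"]],
      ltp_minus = wm[["ltp"]], ltp_plus = wp[["ltp"]],
      d_ltp = wp[["ltp"]] - wm[["ltp"]]
    )
  }
}

#' Precompute aCaM trajectories for sensitivity sampling
#'
#' Simulates the protocol family once per grid point for the ER-less spine
#' and per (grid point, N_R) for the ER-bearing spine, recording the aCaM
#' time courses. Threshold draws can then be evaluated by replaying the
#' weight equation only (exact, since the weight feeds back on nothing).
#'
#' @inheritParams plasticity_curve
#' @param n_r_values IP3R cluster sizes simulated for the ER+ spine.
#' @return A cache object for [sensitivity_sample()].
#' @export
precompute_traces <- function(p, family = c("stdp", "rate"),
                              grid = seq(-55, 55, by = 10),
                              n_r_values = c(10, 20, 30, 40, 50),
                              n_events = 10, n_bap = 2, dt_active = 2e-3) {
  family <- match.arg(family)
  minus <- plasticity_curve(
    p, family, grid, er = FALSE, n_events = n_events, n_bap = n_bap,
    keep_traces = TRUE, dt_active = dt_active
  )
  plus <- lapply(n_r_values, function(nr) {
    q <- p; q$N_R <- nr
    plasticity_curve(
      q, family, grid, er = TRUE, n_events = n_events, n_bap = n_bap,
      keep_traces = TRUE, dt_active = dt_active
    )
  })
  names(plus) <- as.character(n_r_values)
  structure(
    list(
      p = p, family = family, grid = grid, n_r_values = n_r_values,
      n_events = n_events, n_bap = n_bap,
      minus = attr(minus, "traces"), plus = lapply(plus, attr, "traces"),
      smax_minus = vapply(attr(minus, "traces"), `[[`, numeric(1), "smax_acam")
    ),
    class = "spine_trace_cache"
  )
}

replay_curve <- function(traces, grid, p) {
  vapply(traces, function(tr) {
    w <- replay_weight(tr$time, tr$acam, p)
    w[length(w)]
  }, numeric(1))
}

#' Seeded sensitivity sampling of the plasticity thresholds
#'
#' Draws plasticity-threshold targets (and IP3R cluster size) uniformly from
#' the given ranges, calibrates the ER-less thresholds for each draw from
#' the precomputed aCaM trajectories, evaluates the ER+ and ER- induction
#' curves by weight replay, and records the differential LTD/LTP metrics
#' (window-width changes for STDP, boundary shifts for the rate family).
#' Fully reproducible for a given seed.
#'
#' @param cache a [precompute_traces()] cache.
#' @param n_draws number of draws.
#' @param seed RNG seed.
#' @param ranges named list of sampling ranges; for the STDP family
#'   `dt_D`, `dt_P` (ms windows), for the rate family `f_D`, `f_P` (Hz);
#'   `N_R` in both.
#' @return A tibble with one row per draw: the sampled values, per-curve
#'   LTD/LTP measures and the differential metrics `delta_D`, `delta_P`.
#' @export
sensitivity_sample <- function(cache, n_draws, seed,
                               ranges = NULL) {
  stopifnot(inherits(cache, "spine_trace_cache"))
  if (is.null(ranges)) {
    ranges <- if (cache$family == "stdp") {
      list(dt_D = c(-45, -25), dt_P = c(25, 45), N_R = c(10, 50))
    } else {
      list(f_D = c(1, 6), f_P = c(10, 20), N_R = c(10, 50))
    }
  }
  if (n_draws == 0) {
    return(tibble::tibble(
      draw = integer(0), target_D = numeric(0), target_P = numeric(0),
      N_R = numeric(0), theta_D = numeric(0), theta_P = numeric(0),
      ltd_minus = numeric(0), ltp_minus = numeric(0),
      ltd_plus = numeric(0), ltp_plus = numeric(0),
      delta_D = numeric(0), delta_P = numeric(0), seed = integer(0)
    ))
  }
  set.seed(seed)
  nm <- if (cache$family == "stdp") c("dt_D", "dt_P") else c("f_D", "f_P")
  tD <- stats::runif(n_draws, ranges[[nm[1]]][1], ranges[[nm[1]]][2])
  tP <- stats::runif(n_draws, ranges[[nm[2]]][1], ranges[[nm[2]]][2])
  nr_draw <- stats::runif(n_draws, ranges$N_R[1], ranges$N_R[2])
  # snap to the precomputed cluster sizes (exact in full-scale mode where the
  # cache covers every integer)
  nr <- vapply(nr_draw, function(v) {
    cache$n_r_values[which.min(abs(cache$n_r_values - v))]
  }, numeric(1))

  smax <- cache$smax_minus
  grid <- cache$grid
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    thD <- stats::approx(grid, smax, xout = tD[i], rule = 2)$y
    thP <- stats::approx(grid, smax, xout = tP[i], rule = 2)$y
    if (!(thP > thD)) { # non-monotone region: record failure, keep going
      rows[[i]] <- NULL
      next
    }
    q <- cache$p; q$theta_D <- thD; q$theta_P <- thP
    dw_m <- replay_curve(cache$minus, grid, q)
    dw_p <- replay_curve(cache$plus[[as.character(nr[i])]], grid, q)
    if (cache$family == "stdp") {
      wm <- window_widths(grid, dw_m); wp <- window_widths(grid, dw_p)
      rows[[i]] <- tibble::tibble(
        draw = i, target_D = tD[i], target_P = tP[i], N_R = nr[i],
        theta_D = thD, theta_P = thP,
        ltd_minus = wm[["ltd"]], ltp_minus = wm[["ltp"]],
        ltd_plus = wp[["ltd"]], ltp_plus = wp[["ltp"]],
        delta_D = wp[["ltd"]] - wm[["ltd"]],
        delta_P = wp[["ltp"]] - wm[["ltp"]],
        seed = seed
      )
    } else {
      fD_m <- curve_crossing(grid, dw_m, kind = "ltd_onset")
      fP_m <- curve_crossing(grid, dw_m, kind = "zero_up")
      fD_p <- curve_crossing(grid, dw_p, kind = "ltd_onset")
      fP_p <- curve_crossing(grid, dw_p, kind = "zero_up")
      rows[[i]] <- tibble::tibble(
        draw = i, target_D = tD[i], target_P = tP[i], N_R = nr[i],
        theta_D = thD, theta_P = thP,
        ltd_minus = fD_m, ltp_minus = fP_m,
        ltd_plus = fD_p, ltp_plus = fP_p,
        delta_D = fD_p - fD_m, delta_P = fP_p - fP_m,
        seed = seed
      )
    }
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (mean(ok) < 0.95) {
    rlang::abort(paste0(
      "sensitivity sampling: ", sum(!ok), "/", n_draws, " draws failed ",
      "(non-monotone aCaM between the sampled targets)"
    ))
  }
  dplyr::bind_rows(rows[ok])
}
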