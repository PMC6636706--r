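# Conductance calibrations performed verbally in the model description:
# g_N against the unitary-EPSP calcium increment, g_LVGCC against the
# matched peak NMDAR/L-VGCC influx rates.

# short single-pulse protocol used inside calibrations (peak Ca occurs well
# within 0.5 s of the pulse)
calibration_pulse <- function(duration = 0.8) {
  new_protocol(
    glu_times = settle_window(), bap_times = numeric(0),
    co_input = FALSE, vgcc = FALSE, duration = duration,
    label = "calibration pulse"
  )
}

#' Single bAP protocol
#'
#' One backpropagating action potential, no glutamate, VGCC enabled; used
#' for the L-VGCC influx calibration.
#'
#' @param duration total simulated time (s).
#' @return A `spine_protocol`.
#' @export
single_bap <- function(duration = 0.8) {
  new_protocol(
    glu_times = numeric(0), bap_times = settle_window(),
    co_input = FALSE, vgcc = TRUE, duration = duration,
    label = "single bAP"
  )
}

# peak free-Ca increment over rest for a unitary pulse in the ER-less spine
epsp_ca_peak <- function(p, dt_active = 5e-4) {
  traj <- run_protocol(
    calibration_pulse(), p, er = FALSE,
    dt_active = dt_active, active_window = 0.7, channels = FALSE
  )
  max(traj$ca) - p$Ca_rest
}

#' Calibrate the NMDAR conductance to a target calcium increment
#'
#' Finds `g_N` such that the peak free-calcium increment over rest evoked by
#' a single glutamate pulse in the ER-less reference spine equals the target
#' (scalar root finding; the peak is monotone in `g_N`, which is asserted).
#'
#' @param p a `spine_params` object.
#' @param target_dCa target increment in uM (0.05-2).
#' @param tol relative tolerance on the target (default 1%).
#' @return The calibrated conductance in pS, with the updated parameter set
#'   in attribute `"params"`.
#' @export
calibrate_gN <- function(p, target_dCa, tol = 0.01) {
  if (!is.numeric(target_dCa) || target_dCa < 0.05 || target_dCa > 2) {
    rlang::abort("target_dCa must be in [0.05, 2] uM")
  }
  peak_at <- function(g) {
    q <- p; q$g_N <- g
    epsp_ca_peak(q)
  }
  f <- function(g) peak_at(g) - target_dCa
  # bracket around the current conductance scaled by the target ratio
  g0 <- p$g_N * target_dCa / max(epsp_ca_peak(p), 1e-6)
  lo <- g0 / 3; hi <- g0 * 3
  for (k in 1:3) {
    flo <- f(lo); fhi <- f(hi)
    if (flo < 0 && fhi > 0) break
    lo <- lo / 10; hi <- hi * 10
    if (k == 3) rlang::abort("calibration failed: no bracketing interval for g_N")
  }
  # monotonicity assertion over the bracket
  if (!(peak_at(hi) > peak_at(lo))) {
    rlang::abort("calibration failed: EPSP calcium peak is not monotone in g_N")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = g0 * 1e-3)
  g <- root$root
  achieved <- peak_at(g)
  if (abs(achieved - target_dCa) > tol * target_dCa) {
    rlang::abort(paste0(
      "calibration failed: achieved dCa ", format(achieved),
      " uM vs target ", target_dCa
    ))
  }
  q <- p; q$g_N <- g
  structure(g * 1e3, params = q, achieved_dCa = achieved)
}

#' Calibrate the L-VGCC flux coefficient against the NMDAR influx
#'
#' Sets `g_LVGCC` so that the peak L-VGCC calcium influx rate during a
#' single bAP (no glutamate) equals the peak NMDAR calcium influx rate
#' during a single EPSP (no bAP), within 1%.
#'
#' @param p a `spine_params` object (`g_N` already set).
#' @return The calibrated flux coefficient (s^-1), with the updated
#'   parameter set in attribute `"params"`.
#' @export
calibrate_gLVGCC <- function(p, tol = 0.01) {
  if (p$g_N <= 0) rlang::abort("calibration failed: g_N = 0 gives a zero target")
  epsp <- run_protocol(
    calibration_pulse(), p, er = FALSE, dt_active = 5e-4, active_window = 0.7
  )
  target <- max(epsp$J_N)
  if (target <= 0) rlang::abort("calibration failed: zero NMDAR influx target")
  peak_vgcc <- function(g) {
    q <- p; q$g_LVGCC <- g
    traj <- run_protocol(
      single_bap(), q, er = FALSE, dt_active = 2e-4, active_window = 0.7
    )
    max(traj$J_LVGCC)
  }
  g <- if (p$g_LVGCC > 0) p$g_LVGCC else 1
  # the influx is nearly linear in the coefficient: fixed-point iteration
  for (k in 1:6) {
    pk <- peak_vgcc(g)
    if (pk <= 0) rlang::abort("calibration failed: no VGCC influx during bAP")
    if (abs(pk - target) <= tol * target) break
    g <- g * target / pk
    if (k == 6) rlang::abort("calibration failed: VGCC influx match did not converge")
  }
  q <- p; q$g_LVGCC <- g
  structure(g, params = q, peak_ratio = peak_vgcc(g) / target)
}
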