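# Calcium/calmodulin-driven bidirectional plasticity: the active-calmodulin
# readout, the difference-of-sigmoids attractor function Omega_w, the
# activity-dependent time constant tau_w, and the weight dynamics
# tau_w(aCaM) dw/dt = -w + Omega_w(aCaM).

#' Active calmodulin concentration
#'
#' Concentration of calmodulin molecules carrying at least one bound calcium
#' ion, computed under lobe independence:
#' `aCaM = CaM_total (1 - p(C0) p(N0))` where `p(X0)` is the unbound fraction
#' of each lobe.
#'
#' @param cam_c0 concentration of molecules with empty C-lobe (uM).
#' @param cam_n0 concentration of molecules with empty N-lobe (uM).
#' @param p a `spine_params` object.
#' @return aCaM in uM.
#' @export
active_cam <- function(cam_c0, cam_n0, p) {
  p$CaM_total * (1 - (cam_c0 / p$CaM_total) * (cam_n0 / p$CaM_total))
}

#' Plasticity attractor function
#'
#' Difference of two sigmoids of active calmodulin:
#' `Omega_w = 1/(1 + exp(-beta_P (aCaM - theta_P))) -
#'  0.5/(1 + exp(-beta_D (aCaM - theta_D)))`.
#' Below `theta_D` no plasticity is induced; between the thresholds the
#' attractor sits near the depression plateau (-0.5); above `theta_P` it
#' approaches potentiation (+0.5 .. 1 depending on the overlap).
#'
#' @param acam active calmodulin (uM), vectorised.
#' @param p a `spine_params` object.
#' @return Dimensionless attractor value in (-0.5, 1).
#' @export
omega_w <- function(acam, p) {
  1 / (1 + exp(-p$beta_P * (acam - p$theta_P))) -
    0.5 / (1 + exp(-p$beta_D * (acam - p$theta_D)))
}

#' Weight relaxation time constant
#'
#' `tau_w(aCaM) = 1 + 10 / (0.001 + (2 aCaM / (theta_D + theta_P))^p)`
#' seconds, with exponent `p = tau_w_p` (default 2). At rest
#' (`aCaM ~ 0`) this gives ~10^4 s (hours-scale persistence); at mid-band
#' activation it drops to ~11 s (seconds-scale induction).
#'
#' @param acam active calmodulin (uM), vectorised.
#' @param p a `spine_params` object.
#' @return Time constant in seconds.
#' @export
tau_w <- function(acam, p) {
  1 + 10 / (0.001 + (2 * acam / (p$theta_D + p$theta_P))^p$tau_w_p)
}

#' Synaptic weight derivative
#'
#' `dw/dt = (-w + Omega_w(aCaM)) / tau_w(aCaM)`.
#'
#' @param w synaptic weight (dimensionless; initialised to 0 in all
#'   protocols).
#' @param acam active calmodulin (uM).
#' @param p a `spine_params` object.
#' @return dw/dt in s^-1.
#' @export
weight_derivative <- function(w, acam, p) {
  (-w + omega_w(acam, p)) / tau_w(acam, p)
}

#' Replay the weight equation over a recorded aCaM time course
#'
#' The weight does not feed back on any other state, so `w(t)` can be
#' recomputed exactly from an aCaM trajectory for any threshold pair without
#' re-running the full model. Integration uses the exact exponential update
#' of the locally-linear weight ODE over each sampling interval.
#'
#' @param time sample times (s), strictly increasing.
#' @param acam aCaM samples (uM).
#' @param p a `spine_params` object carrying `theta_D`, `theta_P`.
#' @param w0 initial weight (default 0).
#' @return Numeric vector `w(t)` at the sample times.
#' @export
replay_weight <- function(time, acam, p, w0 = 0) {
  n <- length(time)
  stopifnot(length(acam) == n, n >= 1)
  w <- numeric(n)
  w[1] <- w0
  if (n == 1) return(w)
  # midpoint aCaM on each interval; exact integration of dw/dt = (omega-w)/tau
  a_mid <- (acam[-1] + acam[-n]) / 2
  om <- omega_w(a_mid, p)
  tw <- tau_w(a_mid, p)
  dt <- diff(time)
  f <- exp(-dt / tw)
  for (i in seq_len(n - 1)) {
    w[i + 1] <- om[i] + (w[i] - om[i]) * f[i]
  }
  w
}

#' Calibrate the plasticity thresholds
#'
#' Sets `theta_D` (`theta_P`) to the maximal steady-state aCaM attained in
#' the ER-less spine at the target LTD (LTP) boundary stimulus, so the
#' resulting weight-change curve changes sign at the targets. For the rate
#' family the boundary stimuli are frequencies (Hz); for the STDP family they
#' are spike-timing differences (ms, paired with the triplet/doublet
#' convention of [stdp_train()]).
#'
#' "Maximal steady-state aCaM" is the maximum over the final 20% of the
#' stimulation period, skipping the initial transient.
#'
#' @param p a `spine_params` object (simulated with ER disabled).
#' @param family `"rate"` or `"stdp"`.
#' @param targets numeric length-2: `c(f_D, f_P)` in Hz or
#'   `c(dt_D, dt_P)` in ms.
#' @param n_events number of synaptic inputs (rate) or pairings (STDP) used
#'   for the calibration runs; the defaults follow the full protocols (900 /
#'   100) but can be scaled down.
#' @param n_bap bAPs per pairing for the STDP family.
#' @return A `spine_params` object with calibrated `theta_D`, `theta_P`,
#'   carrying the calibration details in attribute `"calibration"`.
#' @export
calibrate_thresholds <- function(p, family = c("rate", "stdp"), targets,
                                 n_events = if (family == "rate") 900 else 100,
                                 n_bap = 2) {
  family <- match.arg(family)
  stopifnot(length(targets) == 2)
  if (!(targets[2] > targets[1])) {
    rlang::abort("degenerate thresholds: the LTP boundary must exceed the LTD boundary")
  }
  peak <- vapply(targets, function(tg) {
    proto <- if (family == "rate") rate_train(tg, n_spikes = n_events)
      else stdp_train(tg, n_pairings = n_events, n_bap = n_bap)
    traj <- run_protocol(proto, p, er = FALSE)
    steady_max_acam(traj, proto)
  }, numeric(1))
  if (!(peak[2] > peak[1])) {
    rlang::abort(paste0(
      "aCaM is not increasing between the target stimuli (",
      format(peak[1]), " -> ", format(peak[2]), " uM); cannot calibrate"
    ))
  }
  p$theta_D <- peak[1]
  p$theta_P <- peak[2]
  validate_parameters(p)
  attr(p, "calibration") <- list(
    family = family, targets = targets, peaks = peak, n_events = n_events
  )
  p
}

# maximum aCaM over the last 20% of the stimulation period
steady_max_acam <- function(traj, protocol) {
  ev <- sort(c(protocol$glu_times, protocol$bap_times))
  t_lo <- ev[1] + 0.8 * (ev[length(ev)] - ev[1])
  t_hi <- ev[length(ev)] + 0.5 # allow the final transient to express
  sel <- traj$time >= t_lo & traj$time <= t_hi
  if (!any(sel)) sel <- rep(TRUE, nrow(traj))
  max(traj$acam[sel])
}
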