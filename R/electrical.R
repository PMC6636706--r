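# Membrane electrical components: receptor conductance waveforms, Mg2+ block,
# VGCC gating, GHK calcium drive, bAP waveform. All are closed-form functions
# of time/state used both by the ODE right-hand side and directly in tests.

#' AMPAR conductance waveform
#'
#' Difference-of-exponentials conductance for glutamate pulses:
#' `g_A (exp(-t/tau_d) - exp(-t/tau_r))` per pulse, summed over pulses.
#'
#' @param t time in seconds (vectorised), measured on the protocol clock.
#' @param p a `spine_params` object.
#' @param pulse_times glutamate pulse onset times (s); default a single pulse
#'   at `t = 0`.
#' @return Conductance in nS.
#' @export
ampar_conductance <- function(t, p, pulse_times = 0) {
  sum_two_exp(t, pulse_times, p$tau_A_d, p$tau_A_r) * p$g_A
}

#' NMDAR conductance waveform
#'
#' Difference-of-exponentials glutamate gating with the slower NMDAR time
#' constants, multiplied by the voltage-dependent magnesium block [mg_block()].
#'
#' @inheritParams ampar_conductance
#' @param u membrane potential (mV), scalar or same length as `t`.
#' @return Conductance in nS.
#' @export
nmdar_conductance <- function(t, u, p, pulse_times = 0) {
  sum_two_exp(t, pulse_times, p$tau_N_d, p$tau_N_r) * p$g_N * mg_block(u)
}

sum_two_exp <- function(t, pulse_times, tau_d, tau_r) {
  out <- numeric(length(t))
  for (t0 in pulse_times) {
    dt <- t - t0
    on <- dt >= 0
    out[on] <- out[on] + exp(-dt[on] / tau_d) - exp(-dt[on] / tau_r)
  }
  out
}

#' Magnesium block of the NMDAR
#'
#' Sigmoidal voltage dependence `B(u) = 1 / (1 + 0.28 exp(-0.062 u))`.
#'
#' @param u membrane potential in mV.
#' @return Unblocked fraction in (0, 1).
#' @export
mg_block <- function(u) 1 / (1 + 0.28 * exp(-0.062 * u))

#' L-VGCC gating steady states and derivatives
#'
#' First-order relaxation of the activation (`m_u`) and inactivation (`h_u`)
#' gates towards their voltage-dependent steady states
#' `x_inf(u) = 1/(1 + exp(-(u - u_x)/k_x))`.
#'
#' @param u membrane potential (mV).
#' @param m_u,h_u current gate values.
#' @param p a `spine_params` object.
#' @return A list with `dm`, `dh` (s^-1) and the steady states `m_inf`,
#'   `h_inf`.
#' @export
vgcc_gate_derivatives <- function(u, m_u, h_u, p) {
  m_inf <- 1 / (1 + exp(-(u - p$u_m) / p$k_m))
  h_inf <- 1 / (1 + exp(-(u - p$u_h) / p$k_h))
  list(
    dm = (m_inf - m_u) / p$tau_m,
    dh = (h_inf - h_u) / p$tau_h,
    m_inf = m_inf, h_inf = h_inf
  )
}

# Goldman-Hodgkin-Katz drive 0.078 u (Ca - Ca_ext exp(-0.078 u)) /
# (1 - exp(-0.078 u)) in uM, with the analytic u -> 0 limit substituted for
# |0.078 u| < 1e-4 to avoid 0/0. Negative values correspond to inward flux.
ghk_drive <- function(u, ca, ca_ext) {
  k <- 0.078
  x <- k * u
  small <- abs(x) < 1e-4
  out <- numeric(length(u))
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- xs * (ca - ca_ext * exp(-xs)) / (1 - exp(-xs))
  }
  if (any(small)) {
    xs <- x[small]
    # x/(1 - e^-x) = 1 + x/2 + x^2/12 + O(x^4)
    out[small] <- (ca - ca_ext * exp(-xs)) * (1 + xs / 2 + xs^2 / 12)
  }
  out
}

#' L-VGCC calcium influx
#'
#' Modified GHK flux through the L-type channel,
#' `J = -g_LVGCC m_u^2 h_u D(u, Ca)` with `D` the GHK drive
#' `0.078 u (Ca - Ca_ext e^(-0.078u)) / (1 - e^(-0.078u))`, continuous at
#' `u = 0` via the series limit. `g_LVGCC` is a flux coefficient in s^-1
#' calibrated against the NMDAR influx (see [calibrate_gLVGCC()]).
#'
#' @param u membrane potential (mV).
#' @param m_u,h_u gate values.
#' @param ca cytosolic free calcium (uM).
#' @param p a `spine_params` object.
#' @return Calcium influx into the cytosol in uM/s (positive = inward).
#' @export
lvgcc_ca_flux <- function(u, m_u, h_u, ca, p) {
  -p$g_LVGCC * m_u^2 * h_u * ghk_drive(u, ca, p$Ca_ext)
}

# volumetric NMDAR Ca permeability over spine volume, s^-1:
# 0.1 * (g_N / Ca_ext) * (RT / 4F^2) / V_spine in SI, converted to package units
nmdar_ca_factor <- function(p) {
  g_SI <- p$g_N * 1e-9 # nS -> S
  ca_ext_SI <- p$Ca_ext * 1e-3 # uM -> mol m^-3
  RT <- p$R_gas * (p$T_celsius + 273.15)
  vol_m3 <- p$V_spine * 1e-18 # um^3 -> m^3
  0.1 * (g_SI / ca_ext_SI) * RT / (4 * p$F_const^2) / vol_m3
}

#' NMDAR calcium influx
#'
#' GHK-type calcium flux through the NMDAR, taking the calcium current as 10%
#' of the total NMDAR current: the volumetric permeability is
#' `0.1 (g_N / Ca_ext) (RT / 4F^2)` and the flux is
#' `-(permeability / V_spine) * gating * B(u) * D(u, Ca)` in uM/s.
#'
#' @param u membrane potential (mV).
#' @param ca cytosolic free calcium (uM).
#' @param gating dimensionless glutamate gating waveform (the NMDAR
#'   difference-of-exponentials, peak ~0.55 for a unitary pulse).
#' @param p a `spine_params` object.
#' @return Calcium influx in uM/s (positive = inward).
#' @export
nmdar_ca_flux <- function(u, ca, gating, p) {
  -nmdar_ca_factor(p) * gating * mg_block(u) * ghk_drive(u, ca, p$Ca_ext)
}

#' Backpropagating action potential waveform
#'
#' Dendritic depolarization `V_0 (0.7 exp(-t/tau_f) + 0.3 exp(-t/tau_s))` for
#' `t >= 0` (zero before onset); multiple bAPs sum.
#'
#' @param t time (s), vectorised.
#' @param p a `spine_params` object.
#' @param bap_times bAP onset times (s); default one bAP at `t = 0`.
#' @return Depolarization above rest in mV.
#' @export
bap_waveform <- function(t, p, bap_times = 0) {
  out <- numeric(length(t))
  for (t0 in bap_times) {
    dt <- t - t0
    on <- dt >= 0
    out[on] <- out[on] +
      p$V_0 * (0.7 * exp(-dt[on] / p$tau_f) + 0.3 * exp(-dt[on] / p$tau_s))
  }
  out
}
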