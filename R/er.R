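# ER calcium store: IP3-receptor gating (reduced Li-Rinzel-type scheme with
# instantaneous IP3/Ca activation and a slow Ca-dependent inactivation gate),
# release flux through the channel cluster, SERCA uptake and the
# compensating ER leak.

#' IP3 receptor open fraction
#'
#' Combines the instantaneous activation variables
#' `m1 = IP3/(d_1 + IP3)`, `m2 = Ca/(d_5 + Ca)` and the slow inactivation
#' gate `h`. Two exponent conventions are supported via
#' `p$open_fraction_exponent`: `"grouped"` (default) computes `(m1 m2 h)^3`,
#' `"h_only"` computes `m1 m2 h^3`.
#'
#' @param ip3 IP3 concentration (uM).
#' @param ca free calcium (uM).
#' @param h inactivation gate in \[0, 1\].
#' @param p a `spine_params` object.
#' @return Open fraction in \[0, 1\].
#' @export
ip3r_open_fraction <- function(ip3, ca, h, p) {
  m1 <- ip3 / (p$d_1 + ip3)
  m2 <- ca / (p$d_5 + ca)
  if (identical(p$open_fraction_exponent, "h_only")) m1 * m2 * h^3
  else (m1 * m2 * h)^3
}

#' IP3 receptor inactivation gate derivative
#'
#' `dh/dt = a_2 (K_inh - (K_inh + Ca) h)`; the steady state
#' `h_inf = K_inh / (K_inh + Ca)` falls with calcium, capturing inactivation
#' of the receptor at high calcium.
#'
#' @param h gate value.
#' @param ca free calcium (uM).
#' @param p a `spine_params` object.
#' @return dh/dt in s^-1.
#' @export
h_derivative <- function(h, ca, p) {
  p$a_2 * (p$K_inh - (p$K_inh + ca) * h)
}

# uM of cytosolic concentration per ion in the spine volume
ion_to_uM <- function(p) 1e21 / (p$N_a * p$V_spine)

#' Calcium release flux through the IP3R cluster
#'
#' `J_ICCR = alpha * open_fraction * N_R * (Ca_ER - Ca) / (N_a V_spine)` in
#' uM/s: `alpha * dCa` is the single-channel ion flux (ions/s), scaled by the
#' cluster size and converted to a cytosolic concentration rate.
#'
#' @param open_fraction IP3R open fraction in \[0, 1\].
#' @param ca free calcium (uM).
#' @param p a `spine_params` object.
#' @return Release flux in uM/s.
#' @export
iccr_flux <- function(open_fraction, ca, p) {
  p$alpha * open_fraction * p$N_R * (p$Ca_ER - ca) * ion_to_uM(p)
}

#' Single-channel IP3R current
#'
#' The calcium current carried by one fully open channel at a given
#' luminal-cytosolic concentration difference: `alpha * dCa * q_Ca`, in pA.
#'
#' @param d_ca concentration difference across the ER membrane (uM).
#' @param p a `spine_params` object.
#' @return Current in pA (0.15 pA at `d_ca = 500` with defaults).
#' @export
ip3r_single_channel_current <- function(d_ca, p = default_parameters()) {
  p$alpha * d_ca * p$q_Ca * 1e12
}

#' SERCA uptake and compensating ER leak
#'
#' Hill-type uptake `V_S Ca^2 / (Ca^2 + K_S^2)` and linear leak
#' `k_S (Ca_ER - Ca)`.
#'
#' @param ca free calcium (uM).
#' @param p a `spine_params` object.
#' @return List with `uptake` and `leak`, both uM/s.
#' @export
serca_flux <- function(ca, p) {
  list(
    uptake = p$V_S * ca^2 / (ca^2 + p$K_S^2),
    leak = p$k_S * (p$Ca_ER - ca)
  )
}

#' Net ER calcium flux
#'
#' `J_ER = J_ICCR - uptake + leak`; callers must use zero for an ER-less
#' spine.
#'
#' @param ip3,ca,h as in [ip3r_open_fraction()].
#' @param p a `spine_params` object.
#' @return Net flux in uM/s.
#' @export
er_net_flux <- function(ip3, ca, h, p) {
  s <- serca_flux(ca, p)
  iccr_flux(ip3r_open_fraction(ip3, ca, h, p), ca, p) - s$uptake + s$leak
}
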