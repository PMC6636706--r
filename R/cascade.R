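# mGluR-Gq-PLCbeta-IP3 signalling cascade.
#
# The network couples: (i) glutamate binding to the Gq-coupled receptor and
# receptor-catalysed G-protein activation, (ii) PLCbeta activation by
# cytosolic Ca2+ and Galpha-GTP and hydrolysis of its bound PIP2 into IP3 and
# DAG, with fast reloading of PIP2 from the (buffered) membrane pool, and
# (iii) IP3 removal by the Ca2+-activated 3-kinase and the 5-phosphatase.
# Every reaction is an explicit mass-action step indexed by its rate symbol
# and defined once, in the declarative table below, from which the reference
# derivative is generated. In the species names, `plc*` forms carry bound
# PIP2; `bl*` forms are the bare enzyme immediately after hydrolysis, before
# PIP2 reloading.

#' Glutamate pulse waveform
#'
#' Alpha-function glutamate transient at the perisynaptic mGluR location,
#' `G_max (t/tau_glu) exp(1 - t/tau_glu)` for `t >= 0`, normalised so the
#' peak equals `G_max` at `t = tau_glu`. Pulses in a train sum.
#'
#' @param t time (s), vectorised.
#' @param p a `spine_params` object.
#' @param pulse_times pulse onset times (s); default one pulse at `t = 0`.
#' @return Glutamate concentration (uM).
#' @export
glutamate_pulse <- function(t, p, pulse_times = 0) {
  out <- numeric(length(t))
  for (t0 in pulse_times) {
    dt <- t - t0
    on <- dt >= 0
    out[on] <- out[on] + p$G_max * (dt[on] / p$tau_glu) * exp(1 - dt[on] / p$tau_glu)
  }
  out
}

#' Cascade reaction table
#'
#' The full mGluR-Gq-PLC-IP3 network as a human-readable list of mass-action
#' steps: one row per elementary reaction, with reactant/product species
#' (`+`-separated), the rate-constant symbol and its value. `glu` (the
#' glutamate input) and `pip2` are clamped species; `ca` is the free-calcium
#' pool shared with the buffering equations.
#'
#' @param p a `spine_params` object (for the rate values).
#' @return A tibble with columns `reaction`, `rate_symbol`, `rate`,
#'   `reactants`, `products`.
#' @export
cascade_reaction_table <- function(p = default_parameters()) {
  rx <- cascade_reactions()
  tibble::tibble(
    reaction = vapply(rx, `[[`, "", "name"),
    rate_symbol = vapply(rx, `[[`, "", "rate"),
    rate = vapply(rx, function(r) p[[r$rate]], numeric(1)),
    reactants = vapply(rx, function(r) fmt_side(r$from), character(1)),
    products = vapply(rx, function(r) fmt_side(r$to), character(1))
  )
}

fmt_side <- function(side) {
  if (length(side) == 0) return("(source)")
  paste(ifelse(side > 1, paste0(side, " ", names(side)), names(side)), collapse = " + ")
}

# internal reaction list; `from`/`to` are named stoichiometry vectors over
# cascade species plus the external pools "glu", "ca", "pip2"
cascade_reactions <- function() {
  rxn <- function(name, rate, from, to) list(name = name, rate = rate, from = from, to = to)
  list(
    rxn("glutamate binding to mGluR", "a_1f", c(r = 1, glu = 1), c(rglu = 1)),
    rxn("glutamate unbinding from mGluR", "a_1b", c(rglu = 1), c(r = 1)),
    rxn("glutamate binding to mGluR:Gq", "a_2f", c(rg = 1, glu = 1), c(rglug = 1)),
    rxn("glutamate unbinding from mGluR:Gq", "a_2b", c(rglug = 1), c(rg = 1)),
    rxn("Gq binding to mGluR", "a_3f", c(r = 1, g = 1), c(rg = 1)),
    rxn("Gq unbinding from mGluR", "a_3b", c(rg = 1), c(r = 1, g = 1)),
    rxn("Gq binding to Glu:mGluR", "a_4f", c(rglu = 1, g = 1), c(rglug = 1)),
    rxn("Gq unbinding from Glu:mGluR", "a_4b", c(rglug = 1), c(rglu = 1, g = 1)),
    rxn("receptor-catalysed Gq activation", "a_5", c(rglug = 1), c(rglu = 1, ga = 1, gbg = 1)),
    rxn("basal Gq activation", "a_6", c(g = 1), c(ga = 1, gbg = 1)),
    rxn("intrinsic GTPase of Ga-GTP", "a_7", c(ga = 1), c(gagdp = 1)),
    rxn("heterotrimer reformation", "a_8", c(gagdp = 1, gbg = 1), c(g = 1)),
    rxn("Ca binding to PLC", "b_1f", c(plc = 1, ca = 1), c(plca = 1)),
    rxn("Ca unbinding from PLC:Ca", "b_1b", c(plca = 1), c(plc = 1, ca = 1)),
    rxn("Ga binding to PLC:Ca", "b_2f", c(plca = 1, ga = 1), c(plcag = 1)),
    rxn("Ga unbinding from PLC:Ca:Ga", "b_2b", c(plcag = 1), c(plca = 1, ga = 1)),
    rxn("Ga binding to PLC", "b_3f", c(plc = 1, ga = 1), c(plg = 1)),
    rxn("Ga unbinding from PLC:Ga", "b_3b", c(plg = 1), c(plc = 1, ga = 1)),
    rxn("Ca binding to PLC:Ga", "b_4f", c(plg = 1, ca = 1), c(plcag = 1)),
    rxn("Ca unbinding from PLC:Ca:Ga", "b_4b", c(plcag = 1), c(plg = 1, ca = 1)),
    rxn("Ga binding to bare PLC:Ca", "b_5f", c(blca = 1, ga = 1), c(blcag = 1)),
    rxn("Ga unbinding from bare PLC:Ca:Ga", "b_5b", c(blcag = 1), c(blca = 1, ga = 1)),
    rxn("GAP hydrolysis on PLC:Ga", "b_6", c(plg = 1), c(plc = 1, gagdp = 1)),
    rxn("Gq-activated PIP2 hydrolysis", "b_7", c(plcag = 1), c(blcag = 1, ip3 = 1, dag = 1)),
    rxn("PIP2 reloading of bare PLC:Ca", "b_8f", c(blca = 1, pip2 = 1), c(plca = 1)),
    rxn("PIP2 unloading of PLC:Ca", "b_8b", c(plca = 1), c(blca = 1, pip2 = 1)),
    rxn("PIP2 reloading of bare PLC:Ca:Ga", "b_9f", c(blcag = 1, pip2 = 1), c(plcag = 1)),
    rxn("PIP2 unloading of PLC:Ca:Ga", "b_9b", c(plcag = 1), c(blcag = 1, pip2 = 1)),
    rxn("GAP hydrolysis on bare PLC:Ca:Ga", "b_10", c(blcag = 1), c(blca = 1, gagdp = 1)),
    rxn("GAP hydrolysis on PLC:Ca:Ga", "b_11", c(plcag = 1), c(plca = 1, gagdp = 1)),
    rxn("DAG clearance", "b_12", c(dag = 1), c()),
    rxn("Ca activation of IP3K", "c_1f", c(k3k = 1, ca = 2), c(kca2 = 1)),
    rxn("Ca deactivation of IP3K", "c_1b", c(kca2 = 1), c(k3k = 1, ca = 2)),
    rxn("IP3 binding to IP3K:Ca2", "c_2f", c(kca2 = 1, ip3 = 1), c(kca2i = 1)),
    rxn("IP3 unbinding from IP3K:Ca2", "c_2b", c(kca2i = 1), c(kca2 = 1, ip3 = 1)),
    rxn("IP3K catalysis", "c_3", c(kca2i = 1), c(kca2 = 1)),
    rxn("IP3 binding to IP5P", "c_4f", c(p5 = 1, ip3 = 1), c(p5i = 1)),
    rxn("IP3 unbinding from IP5P", "c_4b", c(p5i = 1), c(p5 = 1, ip3 = 1)),
    rxn("IP5P catalysis", "c_5", c(p5i = 1), c(p5 = 1))
  )
}

#' Cascade derivatives
#'
#' Mass-action derivatives of the full mGluR-Gq-PLC-IP3 network, generated
#' from [cascade_reaction_table()]. The glutamate input and PIP2 are clamped;
#' the derivative of the shared free-calcium pool induced by cascade
#' calcium-binding steps is returned separately as `d_ca`.
#'
#' @param state named vector over [cascade_species()] concentrations (uM).
#' @param glu glutamate concentration (uM).
#' @param ca free calcium (uM).
#' @param p a `spine_params` object.
#' @param nu_ip3 constitutive IP3 source (uM/s), see [basal_ip3_balance()].
#' @return List with `d` (named derivatives over the cascade species, uM/s)
#'   and `d_ca` (uM/s contribution to free calcium).
#' @export
cascade_derivatives <- function(state, glu, ca, p, nu_ip3 = 0) {
  pool <- c(as.list(state), list(glu = glu, ca = ca, pip2 = p$PIP2_total))
  d <- stats::setNames(numeric(length(state)), names(state))
  d_ca <- 0
  for (r in cascade_reactions()) {
    v <- p[[r$rate]]
    for (s in names(r$from)) v <- v * pool[[s]]^r$from[[s]]
    for (s in names(r$from)) {
      if (s == "ca") d_ca <- d_ca - r$from[[s]] * v
      else if (s %in% names(d)) d[[s]] <- d[[s]] - r$from[[s]] * v
    }
    for (s in names(r$to)) {
      if (s == "ca") d_ca <- d_ca + r$to[[s]] * v
      else if (s %in% names(d)) d[[s]] <- d[[s]] + r$to[[s]] * v
    }
  }
  d[["ip3"]] <- d[["ip3"]] + nu_ip3
  list(d = d, d_ca = d_ca)
}

#' @rdname cascade_reaction_table
#' @export
cascade_species_names <- function() cascade_species()

# basal cascade steady state with Ca clamped (and optionally IP3 clamped),
# by stiff relaxation with the compiled right-hand side: the full system is
# integrated with the calcium clamp engaged and the glutamate input held
# constant (the clamp feeds the cascade only; the ionotropic receptor
# waveform states stay at zero). Returns the stationary cascade species.
cascade_steady_state <- function(p, ca, glu = 0, nu_ip3 = 0,
                                 ip3_clamp = NA_real_, t_relax = 2000,
                                 init = NULL) {
  sp <- cascade_species()
  y <- stats::setNames(numeric(n_states()), state_names())
  y["u"] <- p$u_rest; y["ud"] <- p$u_rest
  gd <- vgcc_gate_derivatives(p$u_rest, 0, 0, p)
  y["mu"] <- gd$m_inf; y["hu"] <- gd$h_inf
  y["ca"] <- ca
  beq <- buffer_equilibrium(ca, p)
  y[names(beq)] <- beq
  y["h"] <- p$K_inh / (p$K_inh + ca)
  if (is.null(init)) {
    y["r"] <- p$mGluR_total; y["g"] <- p$Gq_total
    y["plc"] <- p$PLC_total
    y["ip3"] <- if (is.na(ip3_clamp)) p$IP3_rest else ip3_clamp
    y["k3k"] <- p$IP3K_total; y["p5"] <- p$IP5P_total
  } else {
    y[sp] <- init[sp]
    if (!is.na(ip3_clamp)) y["ip3"] <- ip3_clamp
  }
  ctx <- run_context(
    p,
    er = FALSE, clamp_ca = TRUE, clamp_ip3 = !is.na(ip3_clamp),
    glu_const = glu, nu_ip3 = nu_ip3
  )
  out <- deSolve::ode(
    y = y, times = c(0, t_relax / 4, t_relax),
    func = "spine_derivs", parms = build_parvec(ctx),
    dllname = "spinestore", initfunc = "spine_initmod",
    method = "lsoda", rtol = 1e-10, atol = 1e-12, maxsteps = 100000
  )
  fin <- out[nrow(out), -1]
  names(fin) <- state_names()
  fin[sp]
}

#' Constitutive IP3 source balancing basal turnover
#'
#' Computes the constant IP3 production rate that holds the cascade's
#' stationary IP3 at its resting value (0.1 uM) with no glutamate and
#' calcium clamped at rest, i.e. the excess of basal degradation (IP3K +
#' IP5P) over basal PLC production at that operating point.
#'
#' @param p a `spine_params` object.
#' @return The source rate in uM/s (error if no positive solution exists).
#' @export
basal_ip3_balance <- function(p) {
  ss <- cascade_steady_state(p, ca = p$Ca_rest, glu = 0, ip3_clamp = p$IP3_rest)
  cd <- cascade_derivatives(ss, glu = 0, ca = p$Ca_rest, p = p, nu_ip3 = 0)
  nu <- -cd$d[["ip3"]]
  if (nu <= 0) {
    rlang::abort(paste0(
      "no positive constitutive IP3 source balances the basal state ",
      "(net basal production already ", format(-nu), " uM/s)"
    ))
  }
  nu
}

#' Latency of the IP3 response to a glutamate pulse
#'
#' Runs the full model through a unitary glutamate pulse and measures the
#' time from pulse onset to the peak of the IP3 transient.
#'
#' @param p a `spine_params` object.
#' @param protocol a stimulus protocol (default [unitary_epsp()]).
#' @param er simulate the ER-bearing spine (default TRUE).
#' @return Latency in seconds, or `NA` ("no event") if IP3 never exceeds
#'   baseline by more than 1%.
#' @export
ip3_timecourse_latency <- function(p = default_parameters(),
                                   protocol = unitary_epsp(), er = TRUE) {
  traj <- run_protocol(protocol, p, er = er)
  if (length(protocol$glu_times) == 0) return(NA_real_)
  t0 <- protocol$glu_times[1]
  post <- traj[traj$time >= t0, ]
  base <- traj$ip3[which.max(traj$time >= t0) - 1]
  if (length(base) == 0 || is.na(base)) base <- p$IP3_rest
  i <- which.max(post$ip3)
  if (post$ip3[i] < base * 1.01) return(NA_real_)
  post$time[i] - t0
}
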