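# ODE engine: assemble the full system, solve for the resting state, and
# integrate stimulation protocols into trajectories. Integration proceeds in
# per-event segments with state handoff; stimulus onsets enter as jumps of
# the linear input-filter states, so event times are exact mesh points.

the_rest_cache <- new.env(parent = emptyenv())

#' Resting state of the full model
#'
#' Computes the stationary state with no stimulus: membrane at `u_rest`,
#' gates at steady state, free calcium at `Ca_rest` (50 nM), buffers and
#' pumps at equilibrium, the cascade at its basal steady state with the
#' constitutive IP3 source holding IP3 at its resting value, `h` at
#' `h_inf(Ca_rest)` and `w = 0`. For an ER-bearing spine the ER leak is
#' additionally trimmed so the full ER flux (including the small basal IP3R
#' flux) vanishes at rest; the trimmed value is reported in the diagnostics.
#'
#' @param p a `spine_params` object.
#' @param er logical; include the ER store.
#' @param tol maximum residual derivative norm accepted (uM/s and mV/s
#'   scales), default 1e-9.
#' @return A list of class `spine_rest` with elements `state` (named
#'   vector), `nu_ip3`, `k_S_eff`, `residual` (worst absolute derivative)
#'   and `p`.
#' @export
find_rest <- function(p, er = TRUE, tol = 1e-9) {
  key <- rlang::hash(list(unclass(p), er))
  if (!is.null(the_rest_cache[[key]])) return(the_rest_cache[[key]])

  ca <- p$Ca_rest
  y <- stats::setNames(numeric(n_states()), state_names())
  y["u"] <- p$u_rest
  y["ud"] <- p$u_rest
  gd <- vgcc_gate_derivatives(p$u_rest, 0, 0, p)
  y["mu"] <- gd$m_inf
  y["hu"] <- gd$h_inf
  y["ca"] <- ca
  beq <- buffer_equilibrium(ca, p)
  y[names(beq)] <- beq
  nu <- basal_ip3_balance(p)
  css <- cascade_steady_state(p, ca = ca, glu = 0, nu_ip3 = nu, t_relax = 4000)
  y[cascade_species()] <- css
  y["h"] <- p$K_inh / (p$K_inh + ca)
  y["w"] <- 0

  k_S_eff <- if (er) {
    of <- ip3r_open_fraction(y[["ip3"]], ca, y[["h"]], p)
    upt <- p$V_S * ca^2 / (ca^2 + p$K_S^2)
    (upt - iccr_flux(of, ca, p)) / (p$Ca_ER - ca)
  } else p$k_S

  ctx <- run_context(p, er = er, nu_ip3 = nu, k_S_eff = k_S_eff)
  resid <- max(abs(spine_rhs_r(0, y, ctx)[[1]]))
  if (resid > tol) {
    # polish by further relaxation of the cascade (the only non-analytic block)
    css <- cascade_steady_state(p, ca = ca, glu = 0, nu_ip3 = nu,
                                t_relax = 40000, init = css)
    y[cascade_species()] <- css
    if (er) {
      of <- ip3r_open_fraction(y[["ip3"]], ca, y[["h"]], p)
      upt <- p$V_S * ca^2 / (ca^2 + p$K_S^2)
      k_S_eff <- (upt - iccr_flux(of, ca, p)) / (p$Ca_ER - ca)
      ctx$k_S_eff <- k_S_eff
    }
    resid <- max(abs(spine_rhs_r(0, y, ctx)[[1]]))
  }
  if (resid > tol) {
    d <- spine_rhs_r(0, y, ctx)[[1]]
    worst <- state_names()[which.max(abs(d))]
    rlang::abort(paste0(
      "rest state residual ", format(max(abs(d))), " exceeds tolerance; ",
      "worst component: ", worst
    ))
  }
  out <- structure(
    list(state = y, nu_ip3 = nu, k_S_eff = k_S_eff, residual = resid, p = p),
    class = "spine_rest"
  )
  the_rest_cache[[key]] <- out
  out
}

#' @export
print.spine_rest <- function(x, ...) {
  cat(
    "<spine_rest> Ca = ", format(x$state[["ca"]] * 1000), " nM, IP3 = ",
    format(x$state[["ip3"]]), " uM, residual = ", format(x$residual),
    "\n  nu_ip3 = ", format(x$nu_ip3), " uM/s, trimmed ER leak k_S = ",
    format(x$k_S_eff), " s^-1\n",
    sep = ""
  )
  invisible(x)
}

# jump applied to the input-filter states at an event
event_jump <- function(y, kind, p) {
  if (kind == "glu") {
    y[c("ampa_r", "ampa_d", "nmda_r", "nmda_d")] <-
      y[c("ampa_r", "ampa_d", "nmda_r", "nmda_d")] + 1
    y["glu_y2"] <- y[["glu_y2"]] + p$G_max * exp(1) / p$tau_glu
  } else if (kind == "bap") {
    y[c("bap_f", "bap_s")] <- y[c("bap_f", "bap_s")] + 1
  }
  y
}

#' Integrate a stimulation protocol
#'
#' Runs the full model from the resting state through a protocol with a
#' stiff adaptive integrator (lsoda, compiled right-hand side), in
#' per-event segments. Output is sampled densely after each event and
#' coarsely in quiet stretches.
#'
#' @param protocol a `spine_protocol`.
#' @param p a `spine_params` object.
#' @param er logical; simulate the ER-bearing (`TRUE`) or ER-less spine.
#' @param dt_active output sampling interval (s) within `active_window`
#'   after each event.
#' @param active_window length (s) of the densely sampled window.
#' @param dt_quiet sampling interval elsewhere (s).
#' @param rtol,atol solver tolerances (atol is per-state: concentrations
#'   `atol`, voltages 1e3 x `atol`).
#' @param channels logical; append derived flux channels (conductances,
#'   calcium fluxes, aCaM), recomputed from the state samples.
#' @return A tibble of class `spine_trajectory`: `time` plus state columns
#'   (and flux channels), with the run context in attributes.
#' @export
run_protocol <- function(protocol, p, er = TRUE,
                         dt_active = 1e-3, active_window = 1,
                         dt_quiet = 0.02, rtol = 1e-6, atol = 1e-9,
                         channels = TRUE) {
  stopifnot(inherits(protocol, "spine_protocol"))
  rest <- find_rest(p, er = er)
  ctx <- run_context(
    p,
    er = er, vgcc = protocol$vgcc, co_input = protocol$co_input,
    stdp_mode = length(protocol$bap_times) > 0,
    nu_ip3 = rest$nu_ip3, k_S_eff = rest$k_S_eff
  )
  parvec <- build_parvec(ctx)
  atol_vec <- rep(atol, n_states())
  atol_vec[state_index(c("u", "ud"))] <- atol * 1e3

  ev <- rbind(
    data.frame(time = protocol$glu_times, kind = rep("glu", length(protocol$glu_times))),
    data.frame(time = protocol$bap_times, kind = rep("bap", length(protocol$bap_times)))
  )
  ev <- ev[order(ev$time), , drop = FALSE]
  bounds <- unique(c(0, ev$time, protocol$duration))
  bounds <- bounds[bounds <= protocol$duration]

  y <- rest$state
  pieces <- vector("list", length(bounds) - 1)
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    # apply jumps for events at t0
    here <- which(abs(ev$time - t0) < 1e-12)
    for (j in here) y <- event_jump(y, ev$kind[j], p)
    times <- segment_times(t0, t1, dt_active, active_window, dt_quiet)
    sol <- deSolve::ode(
      y = y, times = times, func = "spine_derivs", parms = parvec,
      dllname = "spinestore", initfunc = "spine_initmod",
      method = "lsoda", rtol = rtol, atol = atol_vec, maxsteps = 50000
    )
    if (attr(sol, "istate")[1] < 0) {
      rlang::abort(paste0(
        "solver failure in segment [", t0, ", ", t1, "] of '",
        protocol$label, "'"
      ))
    }
    y <- sol[nrow(sol), -1]
    names(y) <- state_names()
    pieces[[i]] <- sol[if (i == 1) TRUE else -1, , drop = FALSE]
  }
  m <- do.call(rbind, pieces)
  colnames(m) <- c("time", state_names())
  check_state_sanity(m, protocol)

  traj <- tibble::as_tibble(as.data.frame(m))
  if (channels) traj <- add_channels(traj, ctx)
  attr(traj, "protocol") <- protocol
  attr(traj, "ctx") <- ctx
  attr(traj, "er") <- er
  class(traj) <- c("spine_trajectory", class(traj))
  traj
}

segment_times <- function(t0, t1, dt_active, active_window, dt_quiet) {
  len <- t1 - t0
  if (len <= 0) return(c(t0, t1))
  act_end <- min(t1, t0 + active_window)
  times <- seq(t0, act_end, by = dt_active)
  if (act_end + dt_quiet < t1) {
    times <- c(times, seq(act_end + dt_quiet, t1, by = dt_quiet))
  }
  times <- unique(c(times, t1))
  times[times <= t1]
}

check_state_sanity <- function(m, protocol) {
  if (anyNA(m) || any(!is.finite(m))) {
    rlang::abort(paste0("non-finite state values in '", protocol$label, "'"))
  }
  conc_cols <- setdiff(
    state_names(),
    c("u", "ud", "w") # voltages and the weight may be negative
  )
  mn <- min(m[, conc_cols])
  if (mn < -1e-9) {
    rlang::abort(paste0(
      "negative concentration excursion (", format(mn), ") in '",
      protocol$label, "'"
    ))
  }
}

# derived flux channels, recomputed (vectorised) from the state samples so
# they are exactly consistent with the snapshots
add_channels <- function(traj, ctx) {
  p <- ctx$p
  wN <- traj$nmda_d - traj$nmda_r
  B_u <- mg_block(traj$u)
  traj$glu <- traj$glu_y1 + ctx$glu_const
  traj$g_ampa <- p$g_A * (traj$ampa_d - traj$ampa_r)
  traj$g_nmda <- p$g_N * wN * B_u
  traj$J_N <- -nmdar_ca_factor(p) * wN * B_u * ghk_drive(traj$u, traj$ca, p$Ca_ext)
  traj$J_LVGCC <- if (ctx$vgcc) {
    -p$g_LVGCC * traj$mu^2 * traj$hu * ghk_drive(traj$u, traj$ca, p$Ca_ext)
  } else 0
  if (ctx$er) {
    of <- ip3r_open_fraction(traj$ip3, traj$ca, traj$h, p)
    traj$open_fraction <- of
    traj$J_ICCR <- iccr_flux(of, traj$ca, p)
    traj$serca_uptake <- p$V_S * traj$ca^2 / (traj$ca^2 + p$K_S^2)
    traj$serca_leak <- ctx$k_S_eff * (p$Ca_ER - traj$ca)
    traj$J_ER <- traj$J_ICCR - traj$serca_uptake + traj$serca_leak
  } else {
    traj$open_fraction <- 0
    traj$J_ICCR <- 0
    traj$serca_uptake <- 0
    traj$serca_leak <- 0
    traj$J_ER <- 0
  }
  pm_f <- p$PMCA_total - traj$pmca_b
  nc_f <- p$NCX_total - traj$ncx_b
  traj$J_out <- (p$kf_PMCA * traj$ca * pm_f - p$kb_PMCA * traj$pmca_b -
    p$kL_PMCA * pm_f) +
    (p$kf_NCX * traj$ca * nc_f - p$kb_NCX * traj$ncx_b - p$kL_NCX * nc_f)
  traj$acam <- active_cam(traj$cam_c0, traj$cam_n0, p)
  traj
}

#' @export
print.spine_trajectory <- function(x, ...) {
  proto <- attr(x, "protocol")
  cat(
    "<spine_trajectory> ", nrow(x), " samples over ",
    signif(max(x$time), 4), " s (", proto$label, ", ",
    if (isTRUE(attr(x, "er"))) "ER+" else "ER-", ")\n",
    sep = ""
  )
  NextMethod()
}
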