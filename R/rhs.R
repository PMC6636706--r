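# Reference implementation of the full ODE right-hand side, assembled from
# the module functions. The production integrator uses the compiled
# translation in src/spine_deriv.c; a property test asserts exact agreement
# between the two on randomised states. Stimulus inputs enter through linear
# filter states (ampa_*, nmda_*, glu_y*, bap_*) that are jumped at event
# times by the engine, so the system between events is autonomous.

# context flags for one run
run_context <- function(p, er = TRUE, vgcc = FALSE, co_input = FALSE,
                        stdp_mode = FALSE, clamp_ca = FALSE,
                        clamp_ip3 = FALSE, glu_const = 0,
                        nu_ip3 = 0, k_S_eff = NULL) {
  list(
    p = p, er = er, vgcc = vgcc, co_input = co_input, stdp_mode = stdp_mode,
    clamp_ca = clamp_ca, clamp_ip3 = clamp_ip3, glu_const = glu_const,
    nu_ip3 = nu_ip3, k_S_eff = if (is.null(k_S_eff)) p$k_S else k_S_eff
  )
}

spine_rhs_r <- function(t, y, ctx) {
  p <- ctx$p
  names(y) <- state_names()
  u <- y[["u"]]; ud <- y[["ud"]]; mu <- y[["mu"]]; hu <- y[["hu"]]
  ca <- y[["ca"]]
  dy <- stats::setNames(numeric(length(y)), state_names())

  # ---- input filter states -------------------------------------------------
  dy[["ampa_r"]] <- -y[["ampa_r"]] / p$tau_A_r
  dy[["ampa_d"]] <- -y[["ampa_d"]] / p$tau_A_d
  dy[["nmda_r"]] <- -y[["nmda_r"]] / p$tau_N_r
  dy[["nmda_d"]] <- -y[["nmda_d"]] / p$tau_N_d
  dy[["glu_y2"]] <- -y[["glu_y2"]] / p$tau_glu
  dy[["glu_y1"]] <- -y[["glu_y1"]] / p$tau_glu + y[["glu_y2"]]
  dy[["bap_f"]] <- -y[["bap_f"]] / p$tau_f
  dy[["bap_s"]] <- -y[["bap_s"]] / p$tau_s

  glu <- y[["glu_y1"]] + ctx$glu_const
  gA <- p$g_A * (y[["ampa_d"]] - y[["ampa_r"]]) # nS
  wN <- y[["nmda_d"]] - y[["nmda_r"]] # dimensionless NMDAR gating

  # ---- dendritic compartment ----------------------------------------------
  if (ctx$stdp_mode) {
    ud_eff <- p$u_rest + p$V_0 * (0.7 * y[["bap_f"]] + 0.3 * y[["bap_s"]])
    dy[["ud"]] <- 0
  } else {
    ud_eff <- ud
    leak_rate <- p$g_L / (p$C_m * 1e-6) # s^-1
    dud <- -leak_rate * (ud - p$u_rest)
    if (ctx$co_input) {
      syn_nS <- gA + p$g_N * wN * mg_block(ud) # per synapse, nS
      g_dens_rate <- p$rho_S * syn_nS * 1e-9 / (p$C_m * 1e-6) # s^-1
      dud <- dud - g_dens_rate * (ud - 0)
    }
    dy[["ud"]] <- dud
  }

  # ---- spine voltage -------------------------------------------------------
  C_pF <- p$C_m * p$A_spine * 1e-2
  gL_nS <- p$g_L * p$A_spine * 10
  B_u <- mg_block(u)
  J_vgcc <- if (ctx$vgcc) lvgcc_ca_flux(u, mu, hu, ca, p) else 0
  i_per_flux <- p$V_spine * 1e-15 * p$q_Ca * p$N_a * 1e6 # pA per uM/s
  I_out <- gL_nS * (u - p$u_rest) +
    gA * (u - p$E_A) +
    p$g_N * wN * B_u * (u - p$E_N) +
    1000 * (u - ud_eff) / p$R_C -
    J_vgcc * i_per_flux
  dy[["u"]] <- -1000 * I_out / C_pF

  gd <- vgcc_gate_derivatives(u, mu, hu, p)
  dy[["mu"]] <- gd$dm
  dy[["hu"]] <- gd$dh

  # ---- calcium fluxes ------------------------------------------------------
  J_N <- nmdar_ca_flux(u, ca, wN, p)
  buf <- buffer_derivatives(ca, y[c(
    "cb_00", "cb_10", "cb_20", "cb_01", "cb_11", "cb_21", "cb_02", "cb_12",
    "cb_22", "cbp_b", "slow_b", "cam_c0", "cam_c1", "cam_c2", "cam_n0",
    "cam_n1", "cam_n2"
  )], p)
  for (nm in names(buf$d)) dy[[nm]] <- buf$d[[nm]]
  pm <- pump_flux(ca, y[["pmca_b"]], y[["ncx_b"]], p)
  dy[["pmca_b"]] <- pm$d_pmca
  dy[["ncx_b"]] <- pm$d_ncx

  casc <- cascade_derivatives(
    y[cascade_species()], glu = glu, ca = ca, p = p, nu_ip3 = ctx$nu_ip3
  )
  for (nm in names(casc$d)) dy[[nm]] <- casc$d[[nm]]
  if (ctx$clamp_ip3) dy[["ip3"]] <- 0

  J_ER <- 0
  if (ctx$er) {
    of <- ip3r_open_fraction(y[["ip3"]], ca, y[["h"]], p)
    upt <- p$V_S * ca^2 / (ca^2 + p$K_S^2)
    leak <- ctx$k_S_eff * (p$Ca_ER - ca)
    J_ER <- iccr_flux(of, ca, p) - upt + leak
  }
  dy[["h"]] <- h_derivative(y[["h"]], ca, p)

  dy[["ca"]] <- if (ctx$clamp_ca) 0 else {
    J_N + J_vgcc + J_ER + buf$J_B - pm$J_out + casc$d_ca
  }

  # ---- plasticity ----------------------------------------------------------
  acam <- active_cam(y[["cam_c0"]], y[["cam_n0"]], p)
  dy[["w"]] <- weight_derivative(y[["w"]], acam, p)

  list(dy)
}

# pack parameters + run flags into the flat vector consumed by the compiled
# RHS; order must match the #defines in src/spine_deriv.c
build_parvec <- function(ctx) {
  p <- ctx$p
  c(
    tau_A_r = p$tau_A_r, tau_A_d = p$tau_A_d,
    tau_N_r = p$tau_N_r, tau_N_d = p$tau_N_d,
    tau_glu = p$tau_glu, tau_f = p$tau_f, tau_s = p$tau_s,
    g_A = p$g_A, g_N = p$g_N, E_A = p$E_A, E_N = p$E_N,
    u_rest = p$u_rest, R_C = p$R_C,
    C_pF = p$C_m * p$A_spine * 1e-2,
    gL_nS = p$g_L * p$A_spine * 10,
    leak_rate = p$g_L / (p$C_m * 1e-6),
    rho_fac = p$rho_S * 1e-9 / (p$C_m * 1e-6),
    u_m = p$u_m, k_m = p$k_m, tau_m = p$tau_m,
    u_h = p$u_h, k_h = p$k_h, tau_h = p$tau_h,
    g_LVGCC = p$g_LVGCC, Ca_ext = p$Ca_ext,
    jn_fac = nmdar_ca_factor(p),
    i_per_flux = p$V_spine * 1e-15 * p$q_Ca * p$N_a * 1e6,
    V_0 = p$V_0,
    k_M0M1 = p$k_M0M1, k_M1M2 = p$k_M1M2, k_M1M0 = p$k_M1M0, k_M2M1 = p$k_M2M1,
    k_H0H1 = p$k_H0H1, k_H1H2 = p$k_H1H2, k_H1H0 = p$k_H1H0, k_H2H1 = p$k_H2H1,
    kf_CBP = p$kf_CBP, kb_CBP = p$kb_CBP, CBP_total = p$CBP_total,
    kf_slow = p$kf_slow, kb_slow = p$kb_slow, slow_total = p$slow_total,
    k_C0C1 = p$k_C0C1, k_C1C2 = p$k_C1C2, k_C1C0 = p$k_C1C0, k_C2C1 = p$k_C2C1,
    k_N0N1 = p$k_N0N1, k_N1N2 = p$k_N1N2, k_N1N0 = p$k_N1N0, k_N2N1 = p$k_N2N1,
    CaM_total = p$CaM_total,
    kf_PMCA = p$kf_PMCA, kb_PMCA = p$kb_PMCA, k3_PMCA = p$k3_PMCA,
    kL_PMCA = p$kL_PMCA, PMCA_total = p$PMCA_total,
    kf_NCX = p$kf_NCX, kb_NCX = p$kb_NCX, k3_NCX = p$k3_NCX,
    kL_NCX = p$kL_NCX, NCX_total = p$NCX_total,
    a_1f = p$a_1f, a_1b = p$a_1b, a_2f = p$a_2f, a_2b = p$a_2b,
    a_3f = p$a_3f, a_3b = p$a_3b, a_4f = p$a_4f, a_4b = p$a_4b,
    a_5 = p$a_5, a_6 = p$a_6, a_7 = p$a_7, a_8 = p$a_8,
    b_1f = p$b_1f, b_1b = p$b_1b, b_2f = p$b_2f, b_2b = p$b_2b,
    b_3f = p$b_3f, b_3b = p$b_3b, b_4f = p$b_4f, b_4b = p$b_4b,
    b_5f = p$b_5f, b_5b = p$b_5b,
    b_6 = p$b_6, b_7 = p$b_7, b_8f = p$b_8f, b_8b = p$b_8b,
    b_9f = p$b_9f, b_9b = p$b_9b, b_10 = p$b_10, b_11 = p$b_11, b_12 = p$b_12,
    PIP2_total = p$PIP2_total,
    c_1f = p$c_1f, c_1b = p$c_1b, c_2f = p$c_2f, c_2b = p$c_2b, c_3 = p$c_3,
    c_4f = p$c_4f, c_4b = p$c_4b, c_5 = p$c_5,
    nu_ip3 = ctx$nu_ip3,
    d_1 = p$d_1, d_5 = p$d_5, K_inh = p$K_inh, a_2_ip3r = p$a_2,
    iccr_fac = p$alpha * p$N_R * ion_to_uM(p),
    Ca_ER = p$Ca_ER, V_S = p$V_S, K_S = p$K_S, k_S_eff = ctx$k_S_eff,
    beta_P = p$beta_P, beta_D = p$beta_D,
    theta_P = p$theta_P, theta_D = p$theta_D, tau_w_p = p$tau_w_p,
    er_on = as.numeric(ctx$er), vgcc_on = as.numeric(ctx$vgcc),
    co_input = as.numeric(ctx$co_input), stdp_mode = as.numeric(ctx$stdp_mode),
    clamp_ca = as.numeric(ctx$clamp_ca), clamp_ip3 = as.numeric(ctx$clamp_ip3),
    glu_const = ctx$glu_const,
    exp_grouped = as.numeric(identical(p$open_fraction_exponent, "grouped"))
  )
}

# derivative via the compiled RHS (used by the R/C agreement test and the
# rest-state residual diagnostics)
spine_rhs_c <- function(y, ctx, t = 0) {
  parvec <- build_parvec(ctx)
  .C("spine_set_parms",
    as.double(parvec), as.integer(length(parvec)),
    PACKAGE = "spinestore"
  )
  n <- n_states()
  out <- .C("spine_derivs",
    as.integer(n), as.double(t), as.double(y),
    ydot = double(n), double(1), integer(1),
    PACKAGE = "spinestore"
  )
  stats::setNames(out$ydot, state_names())
}
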