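/* Compiled right-hand side of the spine model ODE system, for use through
 * deSolve's compiled-model interface. This is a line-by-line translation of
 * the reference implementation in R/rhs.R; the state ordering matches
 * R/state.R and the parameter ordering matches build_parvec() in R/rhs.R.
 * A test asserts exact agreement of the two implementations. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NP 124
static double parms[NP];

/* parameter indices, in build_parvec() order */
enum {
  P_tau_A_r, P_tau_A_d, P_tau_N_r, P_tau_N_d, P_tau_glu, P_tau_f, P_tau_s,
  P_g_A, P_g_N, P_E_A, P_E_N, P_u_rest, P_R_C,
  P_C_pF, P_gL_nS, P_leak_rate, P_rho_fac,
  P_u_m, P_k_m, P_tau_m, P_u_h, P_k_h, P_tau_h,
  P_g_LVGCC, P_Ca_ext, P_jn_fac, P_i_per_flux, P_V_0,
  P_k_M0M1, P_k_M1M2, P_k_M1M0, P_k_M2M1,
  P_k_H0H1, P_k_H1H2, P_k_H1H0, P_k_H2H1,
  P_kf_CBP, P_kb_CBP, P_CBP_total, P_kf_slow, P_kb_slow, P_slow_total,
  P_k_C0C1, P_k_C1C2, P_k_C1C0, P_k_C2C1,
  P_k_N0N1, P_k_N1N2, P_k_N1N0, P_k_N2N1,
  P_CaM_total,
  P_kf_PMCA, P_kb_PMCA, P_k3_PMCA, P_kL_PMCA, P_PMCA_total,
  P_kf_NCX, P_kb_NCX, P_k3_NCX, P_kL_NCX, P_NCX_total,
  P_a_1f, P_a_1b, P_a_2f, P_a_2b, P_a_3f, P_a_3b, P_a_4f, P_a_4b,
  P_a_5, P_a_6, P_a_7, P_a_8,
  P_b_1f, P_b_1b, P_b_2f, P_b_2b, P_b_3f, P_b_3b, P_b_4f, P_b_4b,
  P_b_5f, P_b_5b,
  P_b_6, P_b_7, P_b_8f, P_b_8b, P_b_9f, P_b_9b, P_b_10, P_b_11, P_b_12,
  P_PIP2_total,
  P_c_1f, P_c_1b, P_c_2f, P_c_2b, P_c_3, P_c_4f, P_c_4b, P_c_5,
  P_nu_ip3,
  P_d_1, P_d_5, P_K_inh, P_a_2_ip3r, P_iccr_fac,
  P_Ca_ER, P_V_S, P_K_S, P_k_S_eff,
  P_beta_P, P_beta_D, P_theta_P, P_theta_D, P_tau_w_p,
  P_er_on, P_vgcc_on, P_co_input, P_stdp_mode, P_clamp_ca, P_clamp_ip3,
  P_glu_const, P_exp_grouped
};

/* state indices, in state_names() order */
enum {
  S_u, S_ud, S_mu, S_hu, S_ca,
  S_cb00, S_cb10, S_cb20, S_cb01, S_cb11, S_cb21, S_cb02, S_cb12, S_cb22,
  S_cbp, S_slow,
  S_camc0, S_camc1, S_camc2, S_camn0, S_camn1, S_camn2,
  S_pmca, S_ncx,
  S_r, S_rglu, S_rg, S_rglug,
  S_g, S_ga, S_gagdp, S_gbg,
  S_plc, S_plca, S_plg, S_plcag, S_blca, S_blcag,
  S_ip3, S_dag,
  S_k3k, S_kca2, S_kca2i,
  S_p5, S_p5i,
  S_h, S_w,
  S_ampa_r, S_ampa_d, S_nmda_r, S_nmda_d,
  S_glu_y1, S_glu_y2, S_bap_f, S_bap_s,
  N_STATE
};

void spine_initmod(void (*odeparms)(int *, double *))
{
  int n = NP;
  odeparms(&n, parms);
}

/* direct parameter setter so tests can evaluate the derivative without an
 * integrator run */
void spine_set_parms(double *values, int *n)
{
  int i, m = (*n < NP) ? *n : NP;
  for (i = 0; i < m; i++) parms[i] = values[i];
}

static double mg_block(double u)
{
  return 1.0 / (1.0 + 0.28 * exp(-0.062 * u));
}

/* GHK drive in uM; series expansion of x/(1-e^-x) near 0 */
static double ghk_drive(double u, double ca, double ca_ext)
{
  double x = 0.078 * u;
  if (fabs(x) < 1e-4)
    return (ca - ca_ext * exp(-x)) * (1.0 + x / 2.0 + x * x / 12.0);
  return x * (ca - ca_ext * exp(-x)) / (1.0 - exp(-x));
}

void spine_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
  int i;
  for (i = 0; i < N_STATE; i++) ydot[i] = 0.0;

  const double u = y[S_u], ud = y[S_ud], mu = y[S_mu], hu = y[S_hu];
  const double ca = y[S_ca];

  /* ---- input filter states --------------------------------------------- */
  ydot[S_ampa_r] = -y[S_ampa_r] / parms[P_tau_A_r];
  ydot[S_ampa_d] = -y[S_ampa_d] / parms[P_tau_A_d];
  ydot[S_nmda_r] = -y[S_nmda_r] / parms[P_tau_N_r];
  ydot[S_nmda_d] = -y[S_nmda_d] / parms[P_tau_N_d];
  ydot[S_glu_y2] = -y[S_glu_y2] / parms[P_tau_glu];
  ydot[S_glu_y1] = -y[S_glu_y1] / parms[P_tau_glu] + y[S_glu_y2];
  ydot[S_bap_f] = -y[S_bap_f] / parms[P_tau_f];
  ydot[S_bap_s] = -y[S_bap_s] / parms[P_tau_s];

  const double glu = y[S_glu_y1] + parms[P_glu_const];
  const double gA = parms[P_g_A] * (y[S_ampa_d] - y[S_ampa_r]);
  const double wN = y[S_nmda_d] - y[S_nmda_r];

  /* ---- dendritic compartment ------------------------------------------- */
  double ud_eff;
  if (parms[P_stdp_mode] > 0.5) {
    ud_eff = parms[P_u_rest] +
      parms[P_V_0] * (0.7 * y[S_bap_f] + 0.3 * y[S_bap_s]);
    ydot[S_ud] = 0.0;
  } else {
    ud_eff = ud;
    double dud = -parms[P_leak_rate] * (ud - parms[P_u_rest]);
    if (parms[P_co_input] > 0.5) {
      double syn_nS = gA + parms[P_g_N] * wN * mg_block(ud);
      dud -= parms[P_rho_fac] * syn_nS * ud;
    }
    ydot[S_ud] = dud;
  }

  /* ---- spine voltage ---------------------------------------------------- */
  const double B_u = mg_block(u);
  double J_vgcc = 0.0;
  if (parms[P_vgcc_on] > 0.5)
    J_vgcc = -parms[P_g_LVGCC] * mu * mu * hu *
      ghk_drive(u, ca, parms[P_Ca_ext]);
  double I_out = parms[P_gL_nS] * (u - parms[P_u_rest]) +
    gA * (u - parms[P_E_A]) +
    parms[P_g_N] * wN * B_u * (u - parms[P_E_N]) +
    1000.0 * (u - ud_eff) / parms[P_R_C] -
    J_vgcc * parms[P_i_per_flux];
  ydot[S_u] = -1000.0 * I_out / parms[P_C_pF];

  const double m_inf = 1.0 / (1.0 + exp(-(u - parms[P_u_m]) / parms[P_k_m]));
  const double h_inf = 1.0 / (1.0 + exp(-(u - parms[P_u_h]) / parms[P_k_h]));
  ydot[S_mu] = (m_inf - mu) / parms[P_tau_m];
  ydot[S_hu] = (h_inf - hu) / parms[P_tau_h];

  /* ---- calcium buffering ------------------------------------------------ */
  double bind = 0.0; /* net Ca binding rate, uM/s */

  /* calbindin 3x3: cb[i][j], i = medium sites, j = high sites; column-major
   * order in the state vector: (i,j) -> S_cb00 + i + 3*j */
  {
    double kon_m[2] = { parms[P_k_M0M1] * ca, parms[P_k_M1M2] * ca };
    double koff_m[2] = { parms[P_k_M1M0], parms[P_k_M2M1] };
    double kon_h[2] = { parms[P_k_H0H1] * ca, parms[P_k_H1H2] * ca };
    double koff_h[2] = { parms[P_k_H1H0], parms[P_k_H2H1] };
    int ii, jj;
    for (jj = 0; jj < 3; jj++) {
      for (ii = 0; ii < 3; ii++) {
        int s = S_cb00 + ii + 3 * jj;
        if (ii < 2) {
          double f = kon_m[ii] * y[s];
          ydot[s] -= f; ydot[s + 1] += f; bind += f;
          double r = koff_m[ii] * y[s + 1];
          ydot[s + 1] -= r; ydot[s] += r; bind -= r;
        }
        if (jj < 2) {
          double f = kon_h[jj] * y[s];
          ydot[s] -= f; ydot[s + 3] += f; bind += f;
          double r = koff_h[jj] * y[s + 3];
          ydot[s + 3] -= r; ydot[s] += r; bind -= r;
        }
      }
    }
  }

  {
    double f = parms[P_kf_CBP] * ca * (parms[P_CBP_total] - y[S_cbp]) -
      parms[P_kb_CBP] * y[S_cbp];
    ydot[S_cbp] = f; bind += f;
    f = parms[P_kf_slow] * ca * (parms[P_slow_total] - y[S_slow]) -
      parms[P_kb_slow] * y[S_slow];
    ydot[S_slow] = f; bind += f;
  }

  /* calmodulin lobes: two independent 3-state chains */
  {
    double f01 = parms[P_k_C0C1] * ca * y[S_camc0] - parms[P_k_C1C0] * y[S_camc1];
    double f12 = parms[P_k_C1C2] * ca * y[S_camc1] - parms[P_k_C2C1] * y[S_camc2];
    ydot[S_camc0] = -f01; ydot[S_camc1] = f01 - f12; ydot[S_camc2] = f12;
    bind += f01 + f12;
    f01 = parms[P_k_N0N1] * ca * y[S_camn0] - parms[P_k_N1N0] * y[S_camn1];
    f12 = parms[P_k_N1N2] * ca * y[S_camn1] - parms[P_k_N2N1] * y[S_camn2];
    ydot[S_camn0] = -f01; ydot[S_camn1] = f01 - f12; ydot[S_camn2] = f12;
    bind += f01 + f12;
  }
  const double J_B = -bind;

  /* ---- plasma-membrane pumps -------------------------------------------- */
  double J_out;
  {
    double pmca_f = parms[P_PMCA_total] - y[S_pmca];
    double ncx_f = parms[P_NCX_total] - y[S_ncx];
    double bind_p = parms[P_kf_PMCA] * ca * pmca_f - parms[P_kb_PMCA] * y[S_pmca];
    double bind_n = parms[P_kf_NCX] * ca * ncx_f - parms[P_kb_NCX] * y[S_ncx];
    ydot[S_pmca] = bind_p - parms[P_k3_PMCA] * y[S_pmca];
    ydot[S_ncx] = bind_n - parms[P_k3_NCX] * y[S_ncx];
    J_out = (bind_p - parms[P_kL_PMCA] * pmca_f) +
      (bind_n - parms[P_kL_NCX] * ncx_f);
  }

  /* ---- mGluR-Gq-PLC-IP3 cascade ----------------------------------------- */
  double d_ca_casc = 0.0;
  {
    double v;
    /* a1: R + Glu <-> RGlu */
    v = parms[P_a_1f] * y[S_r] * glu;
    ydot[S_r] -= v; ydot[S_rglu] += v;
    v = parms[P_a_1b] * y[S_rglu];
    ydot[S_rglu] -= v; ydot[S_r] += v;
    /* a2: RG + Glu <-> RGluG */
    v = parms[P_a_2f] * y[S_rg] * glu;
    ydot[S_rg] -= v; ydot[S_rglug] += v;
    v = parms[P_a_2b] * y[S_rglug];
    ydot[S_rglug] -= v; ydot[S_rg] += v;
    /* a3: R + G <-> RG */
    v = parms[P_a_3f] * y[S_r] * y[S_g];
    ydot[S_r] -= v; ydot[S_g] -= v; ydot[S_rg] += v;
    v = parms[P_a_3b] * y[S_rg];
    ydot[S_rg] -= v; ydot[S_r] += v; ydot[S_g] += v;
    /* a4: RGlu + G <-> RGluG */
    v = parms[P_a_4f] * y[S_rglu] * y[S_g];
    ydot[S_rglu] -= v; ydot[S_g] -= v; ydot[S_rglug] += v;
    v = parms[P_a_4b] * y[S_rglug];
    ydot[S_rglug] -= v; ydot[S_rglu] += v; ydot[S_g] += v;
    /* a5: RGluG -> RGlu + Ga + Gbg */
    v = parms[P_a_5] * y[S_rglug];
    ydot[S_rglug] -= v; ydot[S_rglu] += v; ydot[S_ga] += v; ydot[S_gbg] += v;
    /* a6: G -> Ga + Gbg */
    v = parms[P_a_6] * y[S_g];
    ydot[S_g] -= v; ydot[S_ga] += v; ydot[S_gbg] += v;
    /* a7: Ga -> GaGDP */
    v = parms[P_a_7] * y[S_ga];
    ydot[S_ga] -= v; ydot[S_gagdp] += v;
    /* a8: GaGDP + Gbg -> G */
    v = parms[P_a_8] * y[S_gagdp] * y[S_gbg];
    ydot[S_gagdp] -= v; ydot[S_gbg] -= v; ydot[S_g] += v;
    /* b1: PLC + Ca <-> PLC:Ca */
    v = parms[P_b_1f] * y[S_plc] * ca;
    ydot[S_plc] -= v; d_ca_casc -= v; ydot[S_plca] += v;
    v = parms[P_b_1b] * y[S_plca];
    ydot[S_plca] -= v; ydot[S_plc] += v; d_ca_casc += v;
    /* b2: PLC:Ca + Ga <-> PLC:Ca:Ga */
    v = parms[P_b_2f] * y[S_plca] * y[S_ga];
    ydot[S_plca] -= v; ydot[S_ga] -= v; ydot[S_plcag] += v;
    v = parms[P_b_2b] * y[S_plcag];
    ydot[S_plcag] -= v; ydot[S_plca] += v; ydot[S_ga] += v;
    /* b3: PLC + Ga <-> PLC:Ga */
    v = parms[P_b_3f] * y[S_plc] * y[S_ga];
    ydot[S_plc] -= v; ydot[S_ga] -= v; ydot[S_plg] += v;
    v = parms[P_b_3b] * y[S_plg];
    ydot[S_plg] -= v; ydot[S_plc] += v; ydot[S_ga] += v;
    /* b4: PLC:Ga + Ca <-> PLC:Ca:Ga */
    v = parms[P_b_4f] * y[S_plg] * ca;
    ydot[S_plg] -= v; d_ca_casc -= v; ydot[S_plcag] += v;
    v = parms[P_b_4b] * y[S_plcag];
    ydot[S_plcag] -= v; ydot[S_plg] += v; d_ca_casc += v;
    /* b5: PLC*:Ca + Ga <-> PLC*:Ca:Ga */
    v = parms[P_b_5f] * y[S_blca] * y[S_ga];
    ydot[S_blca] -= v; ydot[S_ga] -= v; ydot[S_blcag] += v;
    v = parms[P_b_5b] * y[S_blcag];
    ydot[S_blcag] -= v; ydot[S_blca] += v; ydot[S_ga] += v;
    /* b6: PLC:Ga -> PLC + GaGDP (GAP on the Ca-free complex) */
    v = parms[P_b_6] * y[S_plg];
    ydot[S_plg] -= v; ydot[S_plc] += v; ydot[S_gagdp] += v;
    /* b7: PLC:Ca:Ga -> PLC*:Ca:Ga + IP3 + DAG */
    v = parms[P_b_7] * y[S_plcag];
    ydot[S_plcag] -= v; ydot[S_blcag] += v; ydot[S_ip3] += v; ydot[S_dag] += v;
    /* b8: PLC*:Ca + PIP2 <-> PLC:Ca */
    v = parms[P_b_8f] * y[S_blca] * parms[P_PIP2_total];
    ydot[S_blca] -= v; ydot[S_plca] += v;
    v = parms[P_b_8b] * y[S_plca];
    ydot[S_plca] -= v; ydot[S_blca] += v;
    /* b9: PLC*:Ca:Ga + PIP2 <-> PLC:Ca:Ga */
    v = parms[P_b_9f] * y[S_blcag] * parms[P_PIP2_total];
    ydot[S_blcag] -= v; ydot[S_plcag] += v;
    v = parms[P_b_9b] * y[S_plcag];
    ydot[S_plcag] -= v; ydot[S_blcag] += v;
    /* b10: PLC*:Ca:Ga -> PLC*:Ca + GaGDP */
    v = parms[P_b_10] * y[S_blcag];
    ydot[S_blcag] -= v; ydot[S_blca] += v; ydot[S_gagdp] += v;
    /* b11: PLC:Ca:Ga -> PLC:Ca + GaGDP */
    v = parms[P_b_11] * y[S_plcag];
    ydot[S_plcag] -= v; ydot[S_plca] += v; ydot[S_gagdp] += v;
    /* b12: DAG clearance */
    v = parms[P_b_12] * y[S_dag];
    ydot[S_dag] -= v;
    /* c1: IP3K + 2 Ca <-> IP3K:Ca2 */
    v = parms[P_c_1f] * y[S_k3k] * ca * ca;
    ydot[S_k3k] -= v; d_ca_casc -= 2.0 * v; ydot[S_kca2] += v;
    v = parms[P_c_1b] * y[S_kca2];
    ydot[S_kca2] -= v; ydot[S_k3k] += v; d_ca_casc += 2.0 * v;
    /* c2: IP3K:Ca2 + IP3 <-> IP3K:Ca2:IP3 */
    v = parms[P_c_2f] * y[S_kca2] * y[S_ip3];
    ydot[S_kca2] -= v; ydot[S_ip3] -= v; ydot[S_kca2i] += v;
    v = parms[P_c_2b] * y[S_kca2i];
    ydot[S_kca2i] -= v; ydot[S_kca2] += v; ydot[S_ip3] += v;
    /* c3: IP3K:Ca2:IP3 -> IP3K:Ca2 (+ IP4) */
    v = parms[P_c_3] * y[S_kca2i];
    ydot[S_kca2i] -= v; ydot[S_kca2] += v;
    /* c4: IP5P + IP3 <-> IP5P:IP3 */
    v = parms[P_c_4f] * y[S_p5] * y[S_ip3];
    ydot[S_p5] -= v; ydot[S_ip3] -= v; ydot[S_p5i] += v;
    v = parms[P_c_4b] * y[S_p5i];
    ydot[S_p5i] -= v; ydot[S_p5] += v; ydot[S_ip3] += v;
    /* c5: IP5P:IP3 -> IP5P (+ IP2) */
    v = parms[P_c_5] * y[S_p5i];
    ydot[S_p5i] -= v; ydot[S_p5] += v;

    ydot[S_ip3] += parms[P_nu_ip3];
  }
  if (parms[P_clamp_ip3] > 0.5) ydot[S_ip3] = 0.0;

  /* ---- ER store --------------------------------------------------------- */
  double J_ER = 0.0;
  if (parms[P_er_on] > 0.5) {
    double m1 = y[S_ip3] / (parms[P_d_1] + y[S_ip3]);
    double m2 = ca / (parms[P_d_5] + ca);
    double of;
    if (parms[P_exp_grouped] > 0.5) {
      double q = m1 * m2 * y[S_h];
      of = q * q * q;
    } else {
      of = m1 * m2 * y[S_h] * y[S_h] * y[S_h];
    }
    double upt = parms[P_V_S] * ca * ca / (ca * ca + parms[P_K_S] * parms[P_K_S]);
    double leak = parms[P_k_S_eff] * (parms[P_Ca_ER] - ca);
    J_ER = parms[P_iccr_fac] * of * (parms[P_Ca_ER] - ca) - upt + leak;
  }
  ydot[S_h] = parms[P_a_2_ip3r] *
    (parms[P_K_inh] - (parms[P_K_inh] + ca) * y[S_h]);

  /* ---- free calcium ------------------------------------------------------ */
  double J_N = -parms[P_jn_fac] * wN * B_u * ghk_drive(u, ca, parms[P_Ca_ext]);
  ydot[S_ca] = (parms[P_clamp_ca] > 0.5) ? 0.0 :
    (J_N + J_vgcc + J_ER + J_B - J_out + d_ca_casc);

  /* ---- plasticity -------------------------------------------------------- */
  {
    double ct = parms[P_CaM_total];
    double acam = ct * (1.0 - (y[S_camc0] / ct) * (y[S_camn0] / ct));
    double om = 1.0 / (1.0 + exp(-parms[P_beta_P] * (acam - parms[P_theta_P]))) -
      0.5 / (1.0 + exp(-parms[P_beta_D] * (acam - parms[P_theta_D])));
    double tw = 1.0 + 10.0 /
      (0.001 + pow(2.0 * acam / (parms[P_theta_D] + parms[P_theta_P]),
                   parms[P_tau_w_p]));
    ydot[S_w] = (-y[S_w] + om) / tw;
  }
}

/* registration ------------------------------------------------------------ */

static const R_CMethodDef CEntries[] = {
  {"spine_set_parms", (DL_FUNC) &spine_set_parms, 2},
  {"spine_derivs", (DL_FUNC) &spine_derivs, 6},
  {NULL, NULL, 0}
};

void R_init_spinestore(DllInfo *dll)
{
  R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
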