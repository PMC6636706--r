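# Cytosolic calcium handling: buffering by calbindin (9-state scheme),
# immobile (CBP) and slow first-order buffers, the two calmodulin lobes, and
# extrusion by PMCA/NCX two-state transport cycles with compensating leaks.

#' Equilibrium buffer occupancies at a clamped calcium level
#'
#' Computes the equilibrium state of every buffer and pump species at a fixed
#' free-calcium concentration. Used to initialise the resting state and in
#' equilibrium tests.
#'
#' @param ca free calcium (uM).
#' @param p a `spine_params` object.
#' @return Named numeric vector over the buffer/pump state names
#'   (`cb_00` ... `ncx_b`).
#' @export
buffer_equilibrium <- function(ca, p) {
  chain3 <- function(total, kon1, koff1, kon2, koff2) {
    w1 <- kon1 * ca / koff1
    w2 <- w1 * kon2 * ca / koff2
    z <- 1 + w1 + w2
    total * c(1, w1, w2) / z
  }
  m <- chain3(1, p$k_M0M1, p$k_M1M0, p$k_M1M2, p$k_M2M1)
  h <- chain3(1, p$k_H0H1, p$k_H1H0, p$k_H1H2, p$k_H2H1)
  cb <- as.vector(outer(m, h)) * p$CB_total # column-major: (m0h0,m1h0,m2h0,m0h1,...)
  camc <- chain3(p$CaM_total, p$k_C0C1, p$k_C1C0, p$k_C1C2, p$k_C2C1)
  camn <- chain3(p$CaM_total, p$k_N0N1, p$k_N1N0, p$k_N1N2, p$k_N2N1)
  cbp <- p$CBP_total * p$kf_CBP * ca / (p$kf_CBP * ca + p$kb_CBP)
  slow <- p$slow_total * p$kf_slow * ca / (p$kf_slow * ca + p$kb_slow)
  pmca <- p$PMCA_total * p$kf_PMCA * ca / (p$kf_PMCA * ca + p$kb_PMCA + p$k3_PMCA)
  ncx <- p$NCX_total * p$kf_NCX * ca / (p$kf_NCX * ca + p$kb_NCX + p$k3_NCX)
  out <- c(
    cb,
    cbp, slow,
    camc, camn,
    pmca, ncx
  )
  names(out) <- c(
    "cb_00", "cb_10", "cb_20", "cb_01", "cb_11", "cb_21",
    "cb_02", "cb_12", "cb_22", "cbp_b", "slow_b",
    "cam_c0", "cam_c1", "cam_c2", "cam_n0", "cam_n1", "cam_n2",
    "pmca_b", "ncx_b"
  )
  out
}

#' Buffer reaction derivatives and net buffering flux
#'
#' Mass-action derivatives for all cytosolic buffer species and the net flux
#' `J_B` they exert on free calcium (uM/s; negative while buffers are binding
#' calcium), so that free and bound calcium changes are exactly opposite.
#'
#' @param ca free calcium (uM).
#' @param buffers named vector as returned by [buffer_equilibrium()] (pump
#'   states ignored here).
#' @param p a `spine_params` object.
#' @return A list with `d` (named derivatives, uM/s) and `J_B` (uM/s).
#' @export
buffer_derivatives <- function(ca, buffers, p) {
  b <- as.list(buffers)
  d <- list()
  bind <- 0 # total rate of Ca binding minus unbinding (uM/s)

  # calbindin: 3x3 grid, transitions change one site-occupancy index at a time
  cb <- matrix(
    c(
      b$cb_00, b$cb_10, b$cb_20,
      b$cb_01, b$cb_11, b$cb_21,
      b$cb_02, b$cb_12, b$cb_22
    ),
    nrow = 3
  ) # cb[i+1, j+1] = CB(M_i, H_j)
  kon_m <- c(p$k_M0M1, p$k_M1M2) * ca
  koff_m <- c(p$k_M1M0, p$k_M2M1)
  kon_h <- c(p$k_H0H1, p$k_H1H2) * ca
  koff_h <- c(p$k_H1H0, p$k_H2H1)
  dcb <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      if (i < 3) { # M binding i-1 -> i
        f <- kon_m[i] * cb[i, j]
        dcb[i, j] <- dcb[i, j] - f
        dcb[i + 1, j] <- dcb[i + 1, j] + f
        bind <- bind + f
        r <- koff_m[i] * cb[i + 1, j]
        dcb[i + 1, j] <- dcb[i + 1, j] - r
        dcb[i, j] <- dcb[i, j] + r
        bind <- bind - r
      }
      if (j < 3) { # H binding j-1 -> j
        f <- kon_h[j] * cb[i, j]
        dcb[i, j] <- dcb[i, j] - f
        dcb[i, j + 1] <- dcb[i, j + 1] + f
        bind <- bind + f
        r <- koff_h[j] * cb[i, j + 1]
        dcb[i, j + 1] <- dcb[i, j + 1] - r
        dcb[i, j] <- dcb[i, j] + r
        bind <- bind - r
      }
    }
  }
  d$cb_00 <- dcb[1, 1]; d$cb_10 <- dcb[2, 1]; d$cb_20 <- dcb[3, 1]
  d$cb_01 <- dcb[1, 2]; d$cb_11 <- dcb[2, 2]; d$cb_21 <- dcb[3, 2]
  d$cb_02 <- dcb[1, 3]; d$cb_12 <- dcb[2, 3]; d$cb_22 <- dcb[3, 3]

  # first-order immobile and slow buffers
  f <- p$kf_CBP * ca * (p$CBP_total - b$cbp_b) - p$kb_CBP * b$cbp_b
  d$cbp_b <- f; bind <- bind + f
  f <- p$kf_slow * ca * (p$slow_total - b$slow_b) - p$kb_slow * b$slow_b
  d$slow_b <- f; bind <- bind + f

  # calmodulin lobes: two independent 3-state chains over the same molecules
  lobe <- function(x0, x1, x2, kon1, kon2, koff1, koff2) {
    f01 <- kon1 * ca * x0 - koff1 * x1
    f12 <- kon2 * ca * x1 - koff2 * x2
    list(d0 = -f01, d1 = f01 - f12, d2 = f12, bind = f01 + f12)
  }
  lc <- lobe(b$cam_c0, b$cam_c1, b$cam_c2, p$k_C0C1, p$k_C1C2, p$k_C1C0, p$k_C2C1)
  ln <- lobe(b$cam_n0, b$cam_n1, b$cam_n2, p$k_N0N1, p$k_N1N2, p$k_N1N0, p$k_N2N1)
  d$cam_c0 <- lc$d0; d$cam_c1 <- lc$d1; d$cam_c2 <- lc$d2
  d$cam_n0 <- ln$d0; d$cam_n1 <- ln$d1; d$cam_n2 <- ln$d2
  bind <- bind + lc$bind + ln$bind

  list(d = unlist(d), J_B = -bind)
}

#' Plasma-membrane pump fluxes
#'
#' Two-state transport cycle for each pump species: `P + Ca <-> PCa -> P`
#' (rates `kf`, `kb`, `k3`) with a constant inward leak `kL` per free pump
#' molecule, constructed to balance transport exactly at the resting calcium
#' level.
#'
#' @param ca free calcium (uM).
#' @param pmca_b,ncx_b calcium-bound pump concentrations (uM).
#' @param p a `spine_params` object.
#' @return A list with `d_pmca`, `d_ncx` (uM/s) and `J_out`, the net calcium
#'   removal from the cytosol (uM/s; zero at rest).
#' @export
pump_flux <- function(ca, pmca_b, ncx_b, p) {
  pmca_f <- p$PMCA_total - pmca_b
  ncx_f <- p$NCX_total - ncx_b
  bind_p <- p$kf_PMCA * ca * pmca_f - p$kb_PMCA * pmca_b
  bind_n <- p$kf_NCX * ca * ncx_f - p$kb_NCX * ncx_b
  list(
    d_pmca = bind_p - p$k3_PMCA * pmca_b,
    d_ncx = bind_n - p$k3_NCX * ncx_b,
    J_out = (bind_p - p$kL_PMCA * pmca_f) + (bind_n - p$kL_NCX * ncx_f)
  )
}

#' Free-calcium derivative
#'
#' Algebraic mass balance of Eq.-style flux terms:
#' `dCa/dt = J_N + J_LVGCC + J_ER + J_B - J_out`, where `J_ER` is zero in an
#' ER-less spine.
#'
#' @param J_N,J_LVGCC,J_ER,J_B,J_out component fluxes in uM/s (influx
#'   positive; `J_out` is net extrusion).
#' @return dCa/dt in uM/s.
#' @export
calcium_derivative <- function(J_N = 0, J_LVGCC = 0, J_ER = 0, J_B = 0, J_out = 0) {
  J_N + J_LVGCC + J_ER + J_B - J_out
}
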