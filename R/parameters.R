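#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
NULL

# Registry of every model constant. `default` values are in package units:
# time s, voltage mV, concentration uM, conductance nS, volume um^3,
# lengths/areas um, surface densities um^-2 (rho_S in cm^-2 as tabulated),
# bimolecular rates uM^-1 s^-1, unimolecular rates s^-1.
spine_parameter_table <- function() {
  tribble_ <- function(...) {
    m <- matrix(list(...), ncol = 5, byrow = TRUE)
    tibble(
      name = unlist(m[, 1]), group = unlist(m[, 2]), unit = unlist(m[, 3]),
      default = unlist(m[, 4]), description = unlist(m[, 5])
    )
  }
  tribble_(
    # -- physical constants ---------------------------------------------------
    "N_a", "physical", "mol^-1", 6.023e23, "Avogadro number",
    "q_Ca", "physical", "C", 3.2e-19, "electric charge per Ca2+ ion",
    "R_gas", "physical", "J mol^-1 K^-1", 8.314, "universal gas constant",
    "F_const", "physical", "C mol^-1", 96485, "Faraday constant",
    "T_celsius", "physical", "degC", 30, "temperature",
    # -- geometry -------------------------------------------------------------
    "V_spine", "geometry", "um^3", 0.06, "spine head volume (sphere)",
    "er_volume_ratio", "geometry", "1", 0.1, "ER-to-spine-head volume ratio",
    "A_spine", "geometry", "um^2", NA_real_, "spine surface area (derived from V_spine)",
    # -- electrical -----------------------------------------------------------
    "C_m", "electrical", "uF cm^-2", 1, "specific membrane capacitance",
    "g_L", "electrical", "S cm^-2", 2e-4, "leak conductance density",
    "u_rest", "electrical", "mV", -70, "resting potential (spine and dendrite)",
    "R_C", "electrical", "MOhm", 100, "spine neck coupling resistance",
    "g_A", "electrical", "nS", 0.5, "AMPAR conductance parameter",
    "tau_A_r", "electrical", "s", 0.2e-3, "AMPAR rise time constant",
    "tau_A_d", "electrical", "s", 2e-3, "AMPAR decay time constant",
    "E_A", "electrical", "mV", 0, "AMPAR reversal potential",
    "g_N", "electrical", "nS", 0.065, "NMDAR conductance parameter (65 pS)",
    "tau_N_r", "electrical", "s", 5e-3, "NMDAR rise time constant",
    "tau_N_d", "electrical", "s", 50e-3, "NMDAR decay time constant",
    "E_N", "electrical", "mV", 0, "NMDAR reversal potential",
    "u_m", "electrical", "mV", -20, "L-VGCC activation offset",
    "k_m", "electrical", "mV", 5, "L-VGCC activation slope",
    "tau_m", "electrical", "s", 0.08e-3, "L-VGCC activation time constant",
    "u_h", "electrical", "mV", -65, "L-VGCC inactivation offset",
    "k_h", "electrical", "mV", -7, "L-VGCC inactivation slope",
    "tau_h", "electrical", "s", 300e-3, "L-VGCC inactivation time constant",
    "g_LVGCC", "electrical", "s^-1 (flux factor)", 0.8052909, "L-VGCC flux coefficient; frozen calibration at g_N = 65 pS (see calibrate_gLVGCC)",
    "V_0", "electrical", "mV", 67, "peak bAP depolarization in dendrite",
    "tau_f", "electrical", "s", 3e-3, "fast bAP decay time constant",
    "tau_s", "electrical", "s", 40e-3, "slow bAP decay time constant",
    "rho_S", "electrical", "cm^-2", 5e5, "co-active synaptic input density on dendrite",
    # -- calcium buffering ----------------------------------------------------
    "k_M0M1", "buffering", "uM^-1 s^-1", 174, "calbindin medium site, first Ca on",
    "k_M1M2", "buffering", "uM^-1 s^-1", 87, "calbindin medium site, second Ca on",
    "k_M1M0", "buffering", "s^-1", 35.8, "calbindin medium site, first Ca off",
    "k_M2M1", "buffering", "s^-1", 71.6, "calbindin medium site, second Ca off",
    "k_H0H1", "buffering", "uM^-1 s^-1", 22, "calbindin high-affinity site, first Ca on",
    "k_H1H2", "buffering", "uM^-1 s^-1", 11, "calbindin high-affinity site, second Ca on",
    "k_H1H0", "buffering", "s^-1", 2.6, "calbindin high-affinity site, first Ca off",
    "k_H2H1", "buffering", "s^-1", 5.2, "calbindin high-affinity site, second Ca off",
    "kf_CBP", "buffering", "uM^-1 s^-1", 247, "immobile buffer (CBP) on-rate",
    "kb_CBP", "buffering", "s^-1", 524, "immobile buffer (CBP) off-rate",
    "kf_slow", "buffering", "uM^-1 s^-1", 24.7, "slow buffer on-rate",
    "kb_slow", "buffering", "s^-1", 52.4, "slow buffer off-rate",
    "k_C0C1", "buffering", "uM^-1 s^-1", 6.8, "CaM C-lobe, first Ca on",
    "k_C1C2", "buffering", "uM^-1 s^-1", 6.8, "CaM C-lobe, second Ca on",
    "k_C1C0", "buffering", "s^-1", 68, "CaM C-lobe, first Ca off",
    "k_C2C1", "buffering", "s^-1", 10, "CaM C-lobe, second Ca off",
    "k_N0N1", "buffering", "uM^-1 s^-1", 108, "CaM N-lobe, first Ca on",
    "k_N1N2", "buffering", "uM^-1 s^-1", 108, "CaM N-lobe, second Ca on",
    "k_N1N0", "buffering", "s^-1", 4150, "CaM N-lobe, first Ca off",
    "k_N2N1", "buffering", "s^-1", 800, "CaM N-lobe, second Ca off",
    "CB_total", "buffering", "uM", 45, "total calbindin",
    "CBP_total", "buffering", "uM", 80, "total immobile buffer",
    "slow_total", "buffering", "uM", 40, "total slow buffer",
    "CaM_total", "buffering", "uM", 50, "total calmodulin",
    # -- extrusion ------------------------------------------------------------
    "kf_PMCA", "extrusion", "uM^-1 s^-1", 150, "PMCA Ca binding",
    "kb_PMCA", "extrusion", "s^-1", 15, "PMCA Ca unbinding",
    "k3_PMCA", "extrusion", "s^-1", 12, "PMCA transport (efflux) step",
    "kL_PMCA", "extrusion", "s^-1", NA_real_, "PMCA leak per free pump (derived: balances efflux at rest)",
    "kf_NCX", "extrusion", "uM^-1 s^-1", 300, "NCX Ca binding",
    "kb_NCX", "extrusion", "s^-1", 300, "NCX Ca unbinding",
    "k3_NCX", "extrusion", "s^-1", 600, "NCX transport (efflux) step",
    "kL_NCX", "extrusion", "s^-1", NA_real_, "NCX leak per free exchanger (derived)",
    "rho_PMCA", "extrusion", "um^-2", 1000, "PMCA surface density",
    "rho_NCX", "extrusion", "um^-2", 140, "NCX surface density",
    "PMCA_total", "extrusion", "uM", NA_real_, "PMCA concentration (derived from density)",
    "NCX_total", "extrusion", "uM", NA_real_, "NCX concentration (derived from density)",
    # -- mGluR-Gq-PLC cascade -------------------------------------------------
    "tau_glu", "cascade", "s", 1e-3, "glutamate pulse (alpha function) time constant",
    "G_max", "cascade", "uM", 300, "peak glutamate concentration at mGluR",
    "a_1f", "cascade", "uM^-1 s^-1", 11.1, "Glu + mGluR binding",
    "a_1b", "cascade", "s^-1", 2, "Glu unbinding from mGluR (scaled down x50)",
    "a_2f", "cascade", "uM^-1 s^-1", 11.1, "Glu + mGluR:Gq binding",
    "a_2b", "cascade", "s^-1", 2, "Glu unbinding from mGluR:Gq (scaled down x50)",
    "a_3f", "cascade", "uM^-1 s^-1", 2, "mGluR + Gq-GDP binding",
    "a_3b", "cascade", "s^-1", 100, "Gq-GDP unbinding from mGluR",
    "a_4f", "cascade", "uM^-1 s^-1", 2, "Glu:mGluR + Gq-GDP binding",
    "a_4b", "cascade", "s^-1", 100, "Gq-GDP unbinding from Glu:mGluR",
    "a_5", "cascade", "s^-1", 116, "GDP/GTP exchange: Glu:mGluR:Gq -> Glu:mGluR + Ga-GTP + Gbg",
    "a_6", "cascade", "s^-1", 0.001, "basal Gq activation",
    "a_7", "cascade", "s^-1", 0.02, "intrinsic GTPase of free Ga-GTP",
    "a_8", "cascade", "uM^-1 s^-1", 6, "heterotrimer reformation Ga-GDP + Gbg -> Gq",
    "b_1f", "cascade", "uM^-1 s^-1", 300, "PLC + Ca binding",
    "b_1b", "cascade", "s^-1", 100, "Ca unbinding from PLC:Ca",
    "b_2f", "cascade", "uM^-1 s^-1", 900, "PLC:Ca + Ga binding",
    "b_2b", "cascade", "s^-1", 30, "Ga unbinding from PLC:Ca:Ga",
    "b_3f", "cascade", "uM^-1 s^-1", 800, "PLC + Ga binding",
    "b_3b", "cascade", "s^-1", 40, "Ga unbinding from PLC:Ga",
    "b_4f", "cascade", "uM^-1 s^-1", 1200, "PLC:Ga + Ca binding",
    "b_4b", "cascade", "s^-1", 6, "Ca unbinding from PLC:Ca:Ga",
    "b_5f", "cascade", "uM^-1 s^-1", 1200, "PLC*:Ca + Ga binding (PIP2-hydrolysed form)",
    "b_5b", "cascade", "s^-1", 6, "Ga unbinding from PLC*:Ca:Ga",
    "b_6", "cascade", "s^-1", 2, "GAP hydrolysis on PLC:Ga",
    "b_7", "cascade", "s^-1", 160, "activated hydrolysis PLC:Ca:Ga -> PLC*:Ca:Ga + IP3 + DAG",
    "b_8f", "cascade", "uM^-1 s^-1", 1, "PIP2 reloading of PLC*:Ca",
    "b_8b", "cascade", "s^-1", 170, "PIP2 unloading of PLC:Ca",
    "b_9f", "cascade", "uM^-1 s^-1", 1, "PIP2 reloading of PLC*:Ca:Ga",
    "b_9b", "cascade", "s^-1", 170, "PIP2 unloading of PLC:Ca:Ga",
    "b_10", "cascade", "s^-1", 8, "GAP hydrolysis on PLC*:Ca:Ga",
    "b_11", "cascade", "s^-1", 2, "GAP hydrolysis on PLC:Ca:Ga (scaled down x4)",
    "b_12", "cascade", "s^-1", 8, "DAG clearance",
    "c_1f", "cascade", "uM^-2 s^-1", 1111, "IP3K + 2 Ca activation",
    "c_1b", "cascade", "s^-1", 100, "IP3K:Ca2 deactivation",
    "c_2f", "cascade", "uM^-1 s^-1", 100, "IP3K:Ca2 + IP3 binding",
    "c_2b", "cascade", "s^-1", 80, "IP3 unbinding from IP3K:Ca2:IP3",
    "c_3", "cascade", "s^-1", 20, "IP3K catalysis (IP3 -> IP4)",
    "c_4f", "cascade", "uM^-1 s^-1", 9, "IP5P + IP3 binding",
    "c_4b", "cascade", "s^-1", 72, "IP3 unbinding from IP5P:IP3",
    "c_5", "cascade", "s^-1", 18, "IP5P catalysis (IP3 -> IP2)",
    "mGluR_total", "cascade", "uM", 0.3, "total mGluR",
    "Gq_total", "cascade", "uM", 1, "total Gq-GDP (G protein)",
    "PLC_total", "cascade", "uM", 0.8, "total PLC-PIP2",
    "PIP2_total", "cascade", "uM", 4000, "total PIP2 (buffered, constant)",
    "IP3K_total", "cascade", "uM", 0.9, "total IP3 3-kinase",
    "IP5P_total", "cascade", "uM", 1, "total IP3 5-phosphatase",
    # -- ER / IP3R / SERCA ----------------------------------------------------
    "d_1", "er", "uM", 0.8, "IP3R IP3 half-activation",
    "d_5", "er", "uM", 0.3, "IP3R Ca half-activation",
    "K_inh", "er", "uM", 0.2, "IP3R Ca inhibition dissociation constant",
    "a_2", "er", "uM^-1 s^-1", 2.7, "IP3R inactivation gate rate",
    "alpha", "er", "uM^-1 s^-1", 937.5, "per-channel flux coefficient (0.15 pA at dCa = 0.5 mM)",
    "N_R", "er", "1", 30, "IP3R channel cluster size",
    "V_S", "er", "uM s^-1", 1, "maximal SERCA uptake rate",
    "K_S", "er", "uM", 0.2, "SERCA Hill half-activation",
    "k_S", "er", "s^-1", NA_real_, "SERCA-compensating ER leak (derived)",
    "Ca_ER", "er", "uM", 250, "ER luminal Ca (fixed)",
    # -- concentrations -------------------------------------------------------
    "Ca_rest", "concentrations", "uM", 0.05, "resting cytosolic Ca",
    "IP3_rest", "concentrations", "uM", 0.1, "resting IP3",
    "Ca_ext", "concentrations", "uM", 2000, "extracellular Ca",
    # -- plasticity -----------------------------------------------------------
    "beta_P", "plasticity", "uM^-1", 60, "potentiation sigmoid slope",
    "beta_D", "plasticity", "uM^-1", 60, "depression sigmoid slope",
    "theta_P", "plasticity", "uM", 4, "LTP threshold on aCaM (calibratable)",
    "theta_D", "plasticity", "uM", 2, "LTD threshold on aCaM (calibratable)",
    "tau_w_p", "plasticity", "1", 2, "exponent in the weight time-constant function"
  )
}

#' Parameter registry
#'
#' Tabulates every constant of the model: name, parameter group, unit,
#' default value and a one-line description. Entries whose default is `NA`
#' are derived quantities filled in by [default_parameters()].
#'
#' @return A tibble with columns `name`, `group`, `unit`, `default`,
#'   `description`.
#' @export
parameter_registry <- function() spine_parameter_table()

# names that are legal in a configuration document
config_keys <- function() c(spine_parameter_table()$name, "open_fraction_exponent")

# derived fields recomputed by derive_parameters(); overriding them directly is
# allowed (they are re-derived only when NA)
derived_keys <- function() {
  c("A_spine", "kL_PMCA", "kL_NCX", "PMCA_total", "NCX_total", "k_S")
}

derive_parameters <- function(p) {
  # sphere surface area from volume
  r <- (3 * p$V_spine / (4 * pi))^(1 / 3)
  p$A_spine <- 4 * pi * r^2
  # pump molecule counts -> cytosolic concentrations (uM); 1e21 converts
  # molecules / (mol^-1 * um^3) to umol / L
  conc <- function(rho) rho * p$A_spine / (p$N_a * p$V_spine) * 1e21
  p$PMCA_total <- conc(p$rho_PMCA)
  p$NCX_total <- conc(p$rho_NCX)
  # leak per free pump balancing the transport step exactly at rest:
  # occupancy o = kf*Ca/(kf*Ca + kb + k3); k3*o = kL*(1-o)
  p$kL_PMCA <- p$k3_PMCA * p$kf_PMCA * p$Ca_rest / (p$kb_PMCA + p$k3_PMCA)
  p$kL_NCX <- p$k3_NCX * p$kf_NCX * p$Ca_rest / (p$kb_NCX + p$k3_NCX)
  p$k_S <- derive_serca_leak(p)
  p
}

#' Default model parameters
#'
#' Returns the full parameter set of the spine model with all tabulated
#' constants and the derived quantities (spine surface area, pump
#' concentrations, pump leak rates, SERCA-compensating ER leak) populated.
#'
#' @param overrides optional named list of parameter overrides, applied before
#'   derivation and validation (unknown names are an error).
#' @return An object of class `spine_params`: a named list of parameter
#'   values in package units (s, mV, uM, nS, um^3).
#' @examples
#' p <- default_parameters()
#' p$g_N * 1000 # NMDAR conductance in pS
#' @export
default_parameters <- function(overrides = NULL) {
  tab <- spine_parameter_table()
  p <- as.list(tab$default)
  names(p) <- tab$name
  # exponent grouping convention for the IP3R open fraction: "grouped" applies
  # the cube to the product m1*m2*h (source-model form), "h_only" cubes h alone
  # (the typeset form)
  p$open_fraction_exponent <- "grouped"
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), config_keys())
    if (length(bad) > 0) {
      abort(paste0("unknown parameter name(s): ", paste(bad, collapse = ", ")))
    }
    p[names(overrides)] <- overrides
  }
  # only re-derive fields the caller did not pin explicitly
  fixed <- intersect(names(overrides), derived_keys())
  keep <- p[fixed]
  p <- derive_parameters(p)
  p[fixed] <- keep
  p <- structure(p, class = "spine_params")
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks strict positivity of all rate constants, conductances,
#' concentrations and volumes, the threshold ordering `theta_P > theta_D`,
#' receptor time-constant ordering, the sphere surface-area identity, and the
#' ER luminal gradient `Ca_ER > Ca_rest`.
#'
#' @param p a `spine_params` object.
#' @return `p`, invisibly, or an error naming the offending field.
#' @export
validate_parameters <- function(p) {
  tab <- spine_parameter_table()
  # everything numeric except signed voltage offsets/slopes and the VGCC flux
  # coefficient (zero allowed: channel absent)
  signed <- c(
    "u_rest", "E_A", "E_N", "u_m", "k_m", "u_h", "k_h", "V_0",
    "g_LVGCC", "k_S", "V_S", "rho_S", "N_R", "a_6"
  )
  for (nm in setdiff(tab$name, signed)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(paste0("parameter '", nm, "' must be a single positive number"))
    }
  }
  for (nm in c("g_LVGCC", "V_S", "rho_S", "N_R", "a_6")) {
    if (p[[nm]] < 0) abort(paste0("parameter '", nm, "' must be >= 0"))
  }
  if (!(p$theta_P > p$theta_D)) {
    abort("invariant violated: theta_P must exceed theta_D")
  }
  if (!(p$tau_A_d > p$tau_A_r)) abort("invariant violated: tau_A_d must exceed tau_A_r")
  if (!(p$tau_N_d > p$tau_N_r)) abort("invariant violated: tau_N_d must exceed tau_N_r")
  if (!(p$Ca_ER > p$Ca_rest)) abort("invariant violated: Ca_ER must exceed Ca_rest")
  r <- (3 * p$V_spine / (4 * pi))^(1 / 3)
  if (abs(p$A_spine - 4 * pi * r^2) > 1e-10 * p$A_spine) {
    abort("invariant violated: A_spine is not the surface area of a sphere of volume V_spine")
  }
  if (!p$open_fraction_exponent %in% c("grouped", "h_only")) {
    abort("open_fraction_exponent must be 'grouped' or 'h_only'")
  }
  invisible(p)
}

#' Load a parameter configuration
#'
#' Reads a flat key-value configuration (YAML file or named list) whose keys
#' are the tabulated parameter symbols (`g_N`, `N_R`, `theta_D`, ...).
#' Missing keys fall back to the defaults; unknown keys are rejected; the
#' resulting set is validated.
#'
#' @param config a path to a YAML file, or a named list (possibly empty).
#' @return A validated `spine_params` object.
#' @examples
#' identical(load_config(list()), default_parameters())
#' load_config(list(N_R = 50))$N_R
#' @export
load_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) abort("config must be a file path or a named list")
  if (length(config) > 0 && (is.null(names(config)) || any(names(config) == ""))) {
    abort("config entries must all be named")
  }
  default_parameters(overrides = config)
}

#' Save a parameter configuration
#'
#' Writes the full parameter set as a flat YAML document that round-trips
#' bit-identically through [load_config()].
#'
#' @param p a `spine_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(p, path) {
  stopifnot(inherits(p, "spine_params"))
  vals <- unclass(p)
  txt <- vapply(names(vals), function(nm) {
    v <- vals[[nm]]
    if (is.character(v)) paste0(nm, ": ", v)
    else paste0(nm, ": ", sprintf("%.17e", v))
  }, character(1))
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.spine_params <- function(x, ...) {
  cat("<spine_params> ", length(unclass(x)), " parameters\n", sep = "")
  cat("  g_N = ", x$g_N * 1e3, " pS, N_R = ", x$N_R,
    ", theta_D/theta_P = ", x$theta_D, "/", x$theta_P, " uM\n",
    sep = ""
  )
  invisible(x)
}

#' SERCA-compensating ER leak rate
#'
#' Solves the rest balance `k_S (Ca_ER - Ca_rest) = V_S Ca_rest^2 /
#' (Ca_rest^2 + K_S^2)`, i.e. the linear ER leak that exactly offsets SERCA
#' uptake at the resting calcium concentration.
#'
#' @param p a `spine_params` object (or plain list with the required fields).
#' @return The leak rate constant in s^-1.
#' @examples
#' derive_serca_leak(default_parameters()) # ~2.35e-4
#' @export
derive_serca_leak <- function(p) {
  if (p$Ca_ER <= p$Ca_rest) abort("Ca_ER must exceed Ca_rest")
  uptake <- p$V_S * p$Ca_rest^2 / (p$Ca_rest^2 + p$K_S^2)
  uptake / (p$Ca_ER - p$Ca_rest)
}

# map from the symbols appearing in the model equations to registry fields;
# used by the symbol-inventory test
equation_symbol_map <- function() {
  c(
    # voltage equation and conductances
    C_m = "C_m", g_L = "g_L", u_rest = "u_rest", R_C = "R_C",
    g_A = "g_A", tau_A_r = "tau_A_r", tau_A_d = "tau_A_d", E_A = "E_A",
    g_N = "g_N", tau_N_r = "tau_N_r", tau_N_d = "tau_N_d", E_N = "E_N",
    # VGCC gating and GHK current
    u_m = "u_m", k_m = "k_m", tau_m = "tau_m",
    u_h = "u_h", k_h = "k_h", tau_h = "tau_h",
    q_Ca = "q_Ca", N_a = "N_a", g_LVGCC = "g_LVGCC", Ca_ext = "Ca_ext",
    # NMDAR calcium flux
    R_gas = "R_gas", F_const = "F_const", T_celsius = "T_celsius",
    V_spine = "V_spine",
    # bAP waveform and dendritic drive
    V_0 = "V_0", tau_f = "tau_f", tau_s = "tau_s", rho_S = "rho_S",
    # IP3R gating and flux
    d_1 = "d_1", d_5 = "d_5", K_inh = "K_inh", a_2 = "a_2",
    alpha = "alpha", N_R = "N_R", Ca_ER = "Ca_ER",
    # SERCA
    V_S = "V_S", K_S = "K_S", k_S = "k_S",
    # plasticity rule
    beta_P = "beta_P", beta_D = "beta_D", theta_P = "theta_P",
    theta_D = "theta_D"
  )
}
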