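# Canonical state-vector layout shared by the R reference RHS and the
# compiled RHS (src/spine_deriv.c). Order must not change without updating
# the C code; the test suite asserts exact R/C derivative agreement.

state_names <- function() {
  c(
    "u", "ud", "mu", "hu", "ca",
    # calbindin CB(M_i, H_j), i = medium-site occupancy, j = high-site occupancy
    "cb_00", "cb_10", "cb_20", "cb_01", "cb_11", "cb_21", "cb_02", "cb_12", "cb_22",
    "cbp_b", "slow_b",
    "cam_c0", "cam_c1", "cam_c2", "cam_n0", "cam_n1", "cam_n2",
    "pmca_b", "ncx_b",
    # mGluR-Gq-PLC cascade
    "r", "rglu", "rg", "rglug",
    "g", "ga", "gagdp", "gbg",
    "plc", "plca", "plg", "plcag", "blca", "blcag",
    "ip3", "dag",
    "k3k", "kca2", "kca2i",
    "p5", "p5i",
    # ER IP3R inactivation gate and synaptic weight
    "h", "w",
    # linear input filter states (jumped at stimulus events)
    "ampa_r", "ampa_d", "nmda_r", "nmda_d",
    "glu_y1", "glu_y2", "bap_f", "bap_s"
  )
}

n_states <- function() length(state_names())

state_index <- function(nm) match(nm, state_names())

cascade_species <- function() {
  c(
    "r", "rglu", "rg", "rglug", "g", "ga", "gagdp", "gbg",
    "plc", "plca", "plg", "plcag", "blca", "blcag",
    "ip3", "dag", "k3k", "kca2", "kca2i", "p5", "p5i"
  )
}

# conserved totals (species groups whose summed concentration is constant)
conserved_groups <- function() {
  list(
    mGluR = c("r", "rglu", "rg", "rglug"),
    Gq_alpha = c("g", "rg", "rglug", "ga", "gagdp", "plg", "plcag", "blcag"),
    Gq_betagamma = c("g", "rg", "rglug", "gbg"),
    PLC = c("plc", "plca", "plg", "plcag", "blca", "blcag"),
    IP3K = c("k3k", "kca2", "kca2i"),
    IP5P = c("p5", "p5i"),
    CB = c(
      "cb_00", "cb_10", "cb_20", "cb_01", "cb_11", "cb_21",
      "cb_02", "cb_12", "cb_22"
    ),
    CaM_C = c("cam_c0", "cam_c1", "cam_c2"),
    CaM_N = c("cam_n0", "cam_n1", "cam_n2")
  )
}
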