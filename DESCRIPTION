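Package: spinestore
Title: Calcium Dynamics and Metaplasticity in Dendritic Spines with ER Stores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic single-compartment model of a hippocampal CA1
    dendritic spine head bearing an endoplasmic-reticulum (ER) calcium store.
    Couples Hodgkin-Huxley-type membrane voltage dynamics (AMPAR, NMDAR with
    magnesium block, L-type VGCC, backpropagating action potentials), detailed
    cytosolic calcium buffering (calbindin, immobile and slow buffers,
    calmodulin) and extrusion (PMCA, NCX), a mass-action mGluR-Gq-PLCbeta
    cascade producing IP3, IP3-receptor-gated calcium-induced calcium release
    with SERCA reuptake, and a calcium/calmodulin-driven bidirectional
    synaptic plasticity rule. Provides stimulation protocols (unitary EPSPs,
    rate trains, spike-timing pairings), a stiff ODE engine with a compiled
    right-hand side, and analyses of rate- and timing-dependent plasticity
    with and without the ER store.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
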