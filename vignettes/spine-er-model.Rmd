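---
title: "A dendritic spine model with an ER calcium store: model, calibrations and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dendritic spine model with an ER calcium store}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinestore)
```

## The model

`spinestore` simulates a single hippocampal CA1 spine head as a
well-mixed compartment coupled to its parent dendrite. Five interacting
subsystems are integrated jointly as one stiff ODE system (55 state
variables):

1. **Membrane voltage.** The spine potential $u$ follows a
   Hodgkin–Huxley-type current balance
   $$C_m A\,\dot u = -g_L A (u - u_\mathrm{rest}) - I_A - I_N -
   I_\mathrm{L\text{-}VGCC} - (u - u_d)/R_C,$$
   with AMPAR and NMDAR conductances modelled as differences of
   exponentials gated by glutamate pulses, the NMDAR additionally scaled
   by the magnesium-block sigmoid $B(u) = 1/(1 + 0.28 e^{-0.062u})$, an
   L-type Ca²⁺ current with $m^2h$ gating and a
   Goldman–Hodgkin–Katz (GHK) voltage dependence, and resistive coupling
   ($R_C$ = 100 MΩ) to the dendritic compartment. The constant
   0.078 mV⁻¹ in the GHK factor is used verbatim for compatibility with
   the published equations rather than recomputed from $2F/RT$.

2. **Free calcium.** $\dot{[\mathrm{Ca}]} = J_N + J_\mathrm{L\text{-}VGCC} +
   J_\mathrm{ER} + J_B - J_\mathrm{out}$, with the NMDAR calcium current
   taken as 10% of the total NMDAR current via the volumetric
   permeability $0.1\,(g_N/[\mathrm{Ca}]_\mathrm{ext})(RT/4F^2)$ at 30 °C.

3. **Buffering and extrusion** ($J_B$, $J_\mathrm{out}$). Calbindin is a
   9-state scheme over two medium- and two high-affinity sites;
   transitions change one site-occupancy index at a time, with the
   printed first/second-step rates taken as already containing the
   two-identical-site statistical factors. The immobile (CBP) and slow
   buffers are first-order. Calmodulin is two independent cooperative
   two-site lobes (C and N) over the same 50 µM molecule population.
   PMCA and NCX are explicit two-state transport cycles
   ($P + \mathrm{Ca} \rightleftharpoons P\mathrm{Ca} \to P$), not
   quasi-steady-state approximations, each with a constant inward leak
   per *free* pump molecule, $k_L = k_3 k_f [\mathrm{Ca}]_\mathrm{rest}/
   (k_b + k_3)$, which balances transport exactly at 50 nM. This exact
   form reproduces the printed leak constants (3.33 s⁻¹ and 10 s⁻¹) and
   makes the rest state a true fixed point. Pump surface densities are
   converted to concentrations as $\rho A / (N_a V)$, with non-integer
   molecule counts allowed in this deterministic mean-field setting.

4. **mGluR–G$_q$–PLCβ–IP₃ cascade.** A mass-action network defined
   declaratively in `cascade_reaction_table()`: glutamate binding to the
   receptor and its G-protein precoupled form, receptor-catalysed
   GDP/GTP exchange, PLCβ activation by cytosolic Ca²⁺ and Gα-GTP,
   hydrolysis of PLC-bound PIP₂ into IP₃ and DAG with fast reloading
   from the 4 mM PIP₂ pool, GAP-accelerated Gα hydrolysis on the PLC
   complexes, and IP₃ removal by the Ca²⁺-activated 3-kinase (two Ca²⁺
   bound in one kinetic step, as the µM⁻²s⁻¹ rate units dictate) and the
   5-phosphatase. Glutamate pulses are α-functions
   ($\tau_\mathrm{glu}$ = 1 ms) normalised so the *peak* equals
   $G_\mathrm{max}$ = 300 µM (the published value specifies a peak
   amplitude, not an area). PIP₂ is treated as buffered: no resynthesis
   rates are given, so depletion is not modelled.

5. **ER store (ICCR).** IP₃ receptors follow a reduced gating scheme:
   instantaneous activation $m_1 = \mathrm{IP_3}/(d_1 + \mathrm{IP_3})$,
   $m_2 = \mathrm{Ca}/(d_5 + \mathrm{Ca})$ and a slow inactivation gate
   $\dot h = a_2(K_\mathrm{inh} - (K_\mathrm{inh} + \mathrm{Ca})h)$. The
   default open fraction is the *grouped* cube $(m_1 m_2 h)^3$
   (source-model convention); the typeset variant $m_1 m_2 h^3$ is
   available via `open_fraction_exponent = "h_only"`. Release scales
   with the cluster size $N_R$ and the per-channel coefficient
   $\alpha$ = 937.5 µM⁻¹s⁻¹ (0.15 pA per open channel at a 0.5 mM
   gradient). SERCA uptake is Hill-type with a linear compensating leak.
   Luminal Ca²⁺ is fixed at 250 µM.

6. **Plasticity.** The weight obeys
   $\tau_w(a)\,\dot w = -w + \Omega_w(a)$ driven by active calmodulin
   $a$ — the concentration of CaM molecules with at least one bound
   Ca²⁺, computed under lobe independence as
   $\mathrm{CaM}_T(1 - p_{C0}p_{N0})$ (molecules, not lobes, are
   counted). $\Omega_w$ is the difference of two steep sigmoids with
   thresholds $\theta_D < \theta_P$. The time-constant function is
   implemented as $\tau_w = 1 + 10/(0.001 + (2a/(\theta_D+\theta_P))^p)$
   with $p = 2$ (exposed as `tau_w_p`): the printed rendering of this
   expression is typographically ambiguous, so the reconstruction is
   validated against the three stated time scales — about 10⁴ s (hours)
   at rest, tens of seconds in the depression band, ~10 s at full
   activation — which the test suite asserts.

## Units

Package-wide convention: time in s, voltage in mV, concentrations in µM,
conductances in nS (pS values appear as 0.0xx nS; `calibrate_gN()`
reports pS), volumes in µm³, fluxes in µM s⁻¹. There is no unit-inference
machinery; configuration files (flat YAML, keys named after the model
symbols) are interpreted in these units.

## Reconstructed elements

Two parts of the model are reconstructions rather than transcriptions,
and both are confined to well-identified ambiguities:

* **Cascade topology.** The reaction network figure specifies species
  and rate symbols but not every arrow direction, and the upstream
  kinetic model it adopts was not available while this package was
  written. The network in `cascade_reaction_table()` was therefore
  selected, within the constraints of the printed rate symbols and their
  units, to satisfy the published behaviours: a basal state in which
  degradation alone would hold IP₃ *below* its 0.1 µM resting value
  (so a positive constitutive source, `basal_ip3_balance()`, tops it
  up); an IP₃ transient whose slow rise is controlled by the two
  deliberately slowed dwell times (glutamate on the receptor,
  $a_{1b} = a_{2b} = 2$ s⁻¹, and Gα on active PLC, $b_{11} = 2$ s⁻¹);
  and a delayed store-release calcium peak ~0.5 s after a unitary
  pulse. Hydrolysis is strictly Gα-dependent in this reconstruction;
  a first-order DAG clearance step keeps the terminal product bounded.
  One printed rate (the heterotrimer reformation, 6 s⁻¹) is necessarily
  bimolecular in any mass-action cycle and is used as 6 µM⁻¹s⁻¹.
  Note that the *IP₃* concentration itself peaks later (~1.4 s) than
  the release peak it drives; with both pinned 0.5 s dwell times this
  is a structural property of any mass-action realisation.

* **$\tau_w$.** As described above; the exponent is exposed and the
  time-scale constraints are the acceptance surface.

## Calibrations

Three quantities are calibrated rather than tabulated:

* `calibrate_gN(p, target)` root-finds the NMDAR conductance giving a
  target unitary-EPSP free-Ca²⁺ increment in the ER-less spine (1%
  relative tolerance; monotonicity asserted). The published operating
  point — 65 pS for 0.2 µM — is recovered to within ~3%.
* `calibrate_gLVGCC(p)` matches the peak L-VGCC Ca²⁺ influx during one
  bAP to the peak NMDAR influx during one EPSP (1%). The shipped default
  (0.805 s⁻¹ flux units) is this calibration at 65 pS, frozen so that
  parameter-set construction does not run simulations; the test suite
  re-derives it.
* `calibrate_thresholds()` sets $(\theta_D, \theta_P)$ to the maximal
  steady-state aCaM (maximum over the last 20% of the stimulation
  period — the model description does not define this window, so the
  late-window maximum is this package's convention, chosen to skip the
  initial transient) at the target boundary stimuli in the ER-less
  spine. Peak aCaM rather than a temporal average is used, matching the
  maximum-activation axes of the published analyses. With 1 Hz / 15 Hz
  targets the calibrated $\theta_D$ comes out near 2 µM, the published
  operating choice.

The engine's rest solver (`find_rest()`) additionally (i) computes the
constitutive IP₃ source and (ii) trims the ER leak $k_S$ so the *full*
ER flux — including the small basal IP₃R flux at resting IP₃ — vanishes
at rest. For cluster sizes in the published range the basal IP₃R flux
exceeds resting SERCA uptake, so the trimmed $k_S$ is negative (a net
compensating efflux); the value is reported in the `find_rest()`
diagnostics. `derive_serca_leak()` remains the pure SERCA-only balance
(~2.35×10⁻⁴ s⁻¹).

## Protocols and drives

* Unitary input: one glutamate pulse; VGCC disabled (its contribution to
  rate-protocol calcium is ignored, following the model description).
* Rate trains: regular pulses (exact $k/f$ spacing), with the dendrite
  modelled per unit area ($C_m$, $g_L$ as the spine) and driven by the
  co-active synaptic conductance density $\rho_S(g_A(t) + g_N(t)B(u_d))$
  toward 0 mV; the dendrite's own magnesium block voltage is used, and
  the spine's feedback current on the dendrite is neglected (the
  dendrite is much larger). This minimal circuit yields ~15 mV spine
  depolarization per input at the tabulated $\rho_S$.
* STDP pairings at 5 Hz: the dendritic potential is *prescribed* as the
  summed bAP waveform $V_0(0.7e^{-t/\tau_f} + 0.3e^{-t/\tau_s})$ (peak
  at onset, so "bAP peak" = waveform onset time); VGCC enabled. Timing
  $\Delta t$ is glutamate onset to the peak of the (second) bAP,
  positive when glutamate leads; bAPs in a triplet burst are 10 ms
  apart.
* Every protocol starts with a 0.1 s settling window.

Stimulus waveforms enter the ODE as linear filter states jumped at event
times, so the system between events is autonomous and event onsets are
exact mesh points.

## Numerics

Integration uses `deSolve::lsoda` on a compiled right-hand side
(`src/spine_deriv.c`), relative tolerance 10⁻⁶ and absolute tolerance
10⁻⁹ µM (10⁻⁶ mV for the voltages), in per-event segments with state
handoff. A reference R implementation of the same derivative
(`R/rhs.R`) is kept as the readable definition; a property test asserts
exact agreement between the two on randomised states, and the rest-state
residual (< 10⁻⁹) is evaluated with the reference version. The GHK
factor switches to a series expansion for $|0.078u| < 10^{-4}$ to avoid
0/0. Halving the solver tolerances moves the unitary-EPSP calcium peak
by < 0.5%; conserved totals drift by < 10⁻⁶ (relative) over 100 s.

Weight replay: because $w$ feeds back on nothing and aCaM does not
depend on $(\theta_D, \theta_P)$, `replay_weight()` recomputes $w(t)$
exactly from a recorded aCaM trace for any thresholds (piecewise
exponential update; agreement with the jointly integrated weight is
tested). `sensitivity_sample()` exploits this: trajectories are
precomputed once per (grid point, $N_R$) and each threshold draw costs
only a scalar-ODE replay. In scaled runs $N_R$ draws snap to the
precomputed grid; a full-scale cache over every integer $N_R$ makes the
factorisation exact.

## Problem sizes in the tests

The full study protocols (900 inputs per frequency at 0.1 Hz steps;
100 pairings at 1 ms steps; 5000 sensitivity draws) are available
through the exported functions. The shipped test and acceptance runs use
scaled versions chosen to preserve the qualitative invariants: 20-input
calibration trains, 150-input trains for the frequency-dependent
differential-calcium comparison, 10-pairing STDP runs on a 5 ms timing
grid over ±60 ms (5 ms resolves the few-ms window-boundary shifts that
the width measures quantify), 100 sensitivity draws over the published
ranges ($\Delta t_D \in [-45,-25]$ ms, $\Delta t_P \in [25,45]$ ms,
$N_R \in [10,50]$ snapped to {10,20,30,40,50}). Scaled trains
accumulate less weight change than 900-input trains (the weight ODE
integrates ~45× less time), so curve boundaries are asserted with
frequency margins of 1–2 Hz rather than the 0.1 Hz grid of a
full-scale run.

## What the simulations do and do not show

All results are properties of this deterministic single-compartment
model: no spatial Ca²⁺ gradients or spine–dendrite Ca²⁺ diffusion, no
luminal depletion (fixed ER Ca²⁺), no stochastic single-channel IP₃R
gating, no explicit CaMKII/phosphatase enzymology (abstracted in
$\Omega_w$), and no receptor desensitisation. Agreement of the scaled
test suite therefore demonstrates internal consistency and the model's
published operating points, not predictions about any particular
biological spine.

## A worked pass through the main result

```{r pipeline, eval = FALSE}
p <- default_parameters() # Tables of constants + derived quantities

# ER-bearing spine, one synaptic input: delayed store release
g <- calibrate_gN(p, 0.2) # ~65-67 pS
traj <- run_protocol(unitary_epsp(), attr(g, "params"), er = TRUE)
iccr_delay(traj) # ~490 ms
autoplot(traj)

# rate-dependent plasticity with and without the store
pc <- calibrate_thresholds(p, "rate", targets = c(1, 15), n_events = 20)
grid <- c(0.5, 1, 2, 4, 8, 12, 15, 17, 20)
cm <- plasticity_curve(pc, "rate", grid, er = FALSE, n_events = 20)
cp <- plasticity_curve(pc, "rate", grid, er = TRUE, n_events = 20)
threshold_shifts(cm, cp) # LTD boundary shifts far more than LTP
autoplot(cm, cp)
```
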