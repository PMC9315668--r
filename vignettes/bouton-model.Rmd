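---
title: "A hybrid stochastic model of calcium handling and release at a CA3 bouton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid stochastic model of calcium handling and release at a CA3 bouton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutonsim)
```

## The model

`boutonsim` simulates a single hippocampal CA3 presynaptic terminal as a
well-mixed sphere of 0.122 µm³ with two embedded microdomains: one around
a cluster of 10 IP₃-receptor (IP₃R) channels on the endoplasmic reticulum
(ER), one around a cluster of Cav2.1 (P/Q-type) voltage-gated Ca²⁺
channels (VGCCs) in the active zone (AZ). Four coupled balance equations
track Ca²⁺ in the cytosol, the two microdomains and the whole terminal;
the ER concentration is recovered algebraically from the conservation
expression `Ca_ER = δ₂(Ca_total − Ca_cyt + Ca_IPRn/δ₁ − Ca_AZ)` rather
than integrated. Fluxes comprise plasma-membrane leak plus an
IP₃-dependent store-operated component, PMCA extrusion and SERCA uptake
(Hill kinetics), an ER leak, release through the IP₃R cluster,
microdomain-to-cytosol diffusion, VGCC influx, and a bidirectional
ER–AZ transfer flux

    J_coupling = Vc (Ca_AZ² − k̄ Ca_IPRn²) / (Ca_AZ² + Kc²)

that stands in for buffered diffusion between the two microdomains. The
"high coupling" (HC) preset (`k̄ = 15, Kc = 10`) emulates the
down-regulation of Ca²⁺ buffering proteins reported in familial
Alzheimer's disease (FAD); "normal coupling" (NC) uses `k̄ = 5, Kc = 20`.
We use the additive (`+Kc²`) denominator of bidirectional SERCA-type
exchange models: the subtractive form creates a pole at `Ca_AZ = Kc`
inside the physiological range, which we judged to be a typographical
slip; it remains available behind
`params$coupling$printed_denominator = TRUE` with a guard band.

**IP₃R gating.** Each channel occupies Rest (0 Ca²⁺ bound), Active (2),
Open (2) or Inactive (5) states, with ligand-dependent rates built from
harmonic compositions of sequential Ca²⁺-binding steps and three
IP₃-occupancy factors `KO, KA, KI` (Hill functions of IP₃). The
inactivation factor uses the condition-dependent prefactor `a3`; the
source table prints `a2` there, but that assignment would orphan `a3`
and erase the wild-type/AD difference in inactivation. Because every
cycle of the chain balances, the stationary law is available in closed
form, `π ∝ (1, KA·Ca², KO·Ca², KI·Ca⁵)`, which the package uses for all
open-probability surfaces and which the test suite cross-checks against
an independent generator null-space solve and against long stochastic
simulations. With the wild-type (WT) fit the channel opens with
probability ≈ 0.065 at Ca²⁺ = 1 µM, IP₃ = 10 µM; the 3xTg-AD fit gives
≈ 0.42 at the same ligands, a ~6.5-fold gain of function:

```{r po}
ip3r_open_probability(1, 10, bouton_params("WT", "NC"))$po
ip3r_open_probability(1, 10, bouton_params("AD", "NC"))$po
```

A caveat worth recording: the published low-IP₃ open probabilities
(0.0056 and 0.0248 for WT at 110/250 nM Ca²⁺ and IP₃ = 0.3 µM, 0.2565
for AD at 250 nM) are mutually inconsistent with the printed rate
structure. Detailed balance forces `Po = KO·Ca²/Z` for *any* reading of
the transition table, and no non-negative choice of the occupancy
factors reproduces all three values together with the fixed ratio
`KO(AD)/KO(WT) = a1(AD)/a1(WT)`. The package implements the printed
model exactly and reports its own values (0.0112, 0.0354, 0.2012 at
those ligand points).

**Membrane and VGCCs.** A Hodgkin–Huxley membrane (instantaneous Na⁺
activation, φ-accelerated `n`/`h` gates, Ca²⁺-dependent AHP conductance)
drives a five-state Cav2.1 chain `C1↔C2↔C3↔C4↔O` with
`α_i = α_i0·exp(V/k_i)` and `β_i = β_i0·exp(−V/k_i)`. The source prints
the same sign in both exponents, which would make gating
voltage-independent; the deactivation sign follows the standard Cav2.1
formulation, and is required for the channel to be shut at −70 mV and to
activate during the spike. Open channels carry the ohmic current
`Is = g·Po·(V − E_Ca)` with the calibration defaults `g = 2.7 pS`,
`E_Ca = +50 mV` (cited to an external source but not printed).

**Release machinery.** Vesicles move from a reserve pool (R = 100)
through docking (U) and Ca²⁺-dependent priming into release sites
(N = 8), where they are either channel-detached (V, slow-releasing pool,
sensors driven by cytosolic Ca²⁺) or channel-attached (W,
fast-releasing pool, driven by AZ Ca²⁺). Each primed vesicle carries two
sensors acting in parallel: a synchronous sensor with five Ca²⁺ sites
(fusion at γ₂ ≈ 2 ms⁻¹ once saturated), an asynchronous sensor with two
sites (fusion at γ₃ = a·γ₂ ≈ 0.05 ms⁻¹), and a spontaneous pathway
(γ₁ = 9·10⁻⁶ ms⁻¹ from the unoccupied state). Unbinding is slowed by
the cooperativity factor `b^(m−1)`. A fused site is refractory and
recovers at `kRF = 0.01 ms⁻¹` (the table prints a garbled value; the
methods text states 0.01 ms⁻¹). Both a per-vesicle stochastic mode and
its mass-action expectation (an ODE over the 6×3 sensor-occupancy grid
per pool, integrated with `deSolve`) share the same rate definitions,
and the test suite verifies their agreement on fixed Ca²⁺ waveforms.

## Numerical scheme

Deterministic states advance by classical RK4 with a fixed 1 µs step;
channel clusters and (optionally) vesicles advance per step as
discrete-time Markov chains, the fixed-step equivalent of the Gillespie
algorithm. Transition probabilities use `1 − exp(−k_tot·dt)` with the
destination drawn proportionally to the individual rates, and any block
whose total propensity exceeds 0.05 per step is automatically
sub-stepped. This matters because IP₃R exit rates reach thousands per ms
during microdomain transients at low IP₃; a fixed `k·dt` product without
sub-stepping would either abort or bias open dwell times upward.
Channel clusters are simulated by their exchangeable state *counts*,
which is statistically identical to independent per-channel paths.
Integration guards clamp concentrations at zero and gate variables to
[0, 1]; a non-finite state aborts with a diagnostic. The RK4 order, the
exactness of closed-system Ca²⁺ conservation (relative drift < 10⁻⁶/s)
and bit-level reproducibility under a `(seed, trial)` pair are all under
test. Random numbers come from xoshiro256++ with splitmix64 seeding;
each trial index opens an independent substream, so enlarging a sweep
never reshuffles earlier trials.

## Calibrations and initial conditions

Three constants are deliberate calibrations rather than printed values,
each fixed once against a stated anchor:

* **`V_eff` = 4.2·10⁻¹⁷ L** — the volume converting cluster current to
  flux. The printed "terminal volume" (1.22·10⁻⁶ L) exceeds the
  stated bouton volume by ten orders of magnitude and cannot be meant
  literally. We anchor the single knob the flux pathway offers so that
  a wild-type synapse with 35 VGCCs releases with probability ≈ 0.14 on
  the first action potential of a 20 Hz train — the reference operating
  point the study reports for that configuration.
* **Tonic agonist/amyloid background `q₀` = 105.16 µg/mL** — with a zero
  background input the PLC→IP₃ production cascade is inert (the PLC
  activity fixed point is ~2·10⁻⁵ of its scaled total), the printed
  resting IP₃ of 0.1 µM is not a fixed point of the metabolism
  equations, and the condition-dependent production parameters
  (V₀, V_Q, K_R, V_R) can never act. `q₀` is fixed by one equation:
  the *wild-type* IP₃ fixed point at the reference resting Ca²⁺
  (0.1 µM) must equal the printed resting IP₃ (0.1 µM). The same
  background applied to the AD column then yields an elevated IP₃
  fixed point (≈ 0.65 µM) — the disease phenotype emerges from the
  printed parameter differences rather than from any AD-specific tuning.
* **`E_Cl` = −75 mV** — reversal potentials are not printed. With the
  printed leak conductances, a chloride reversal of −65 mV puts the leak
  balance above spike threshold and the terminal fires tonically at
  ~23 Hz; −75 mV restores a quiescent rest and exactly one spike per
  stimulus pulse, which the study's protocols presuppose.

Simulations start from the relaxed resting state of the selected
condition/coupling combination (means over seconds 5–8 of three long
unstimulated runs, stored as defaults and reproducible with
`simulate_bouton(params, NULL, t_end = 8000)`). Starting instead from
the printed reference values would contaminate short protocols with a
settling transient and would deny the AD terminal its elevated resting
Ca²⁺ — which is the phenotype under study (the relaxed states give
cytosolic Ca²⁺ ≈ 64 nM for WT and ≈ 112 nM for AD, the same ~2-fold
separation reported for cortical neurons from control and 3xTg-AD mice).
Release sites start fully primed with the V/W split at the resting
attach/detach equilibrium; `P_r` is always counted against this initial
pool of 8.

## Experiment drivers and read-outs

`run_single_ap()`, `run_paired_pulse()` (40 ms interval) and
`run_train()` (20 pulses at 20 Hz) stimulate with rectangular 20 µA/cm²,
1 ms current pulses after a 50 ms settling period, sweep the VGCC
cluster size, and average stochastic trials. Scoring windows run from
each pulse onset to the next (last pulse: +50 ms). Decay times use a
basal + 5%-of-peak return band, since exact equality never occurs in
floating point. `run_ca_clamp()` integrates the deterministic release
expectation under Ca²⁺ clamps. Stimulus–release synchrony transforms
each event time into its phase within the bracketing AP cycle and
reports the modulus of the mean complex phase vector; the literal
printed index-pairing of events to APs is available via
`pairing = "indexed"`.

## What the defaults do and do not show

Under the default conditions the model expresses: monotone growth of
`P_r` with VGCC count and its enhancement in AD; the inverse
PPR–`P_r1` relationship; train depression with faster RRP rundown in
AD; and stimulus–release synchrony near 1 at low `P_r` that degrades
with release probability. Two published qualitative features are weak
or absent under the printed constants, and we report them as such
rather than re-tuning: (i) asynchronous release stays near zero in
trains, because PMCA extrusion at its printed capacity (3.195 µM/ms)
clears the per-spike cytosolic load within a few ms, so the residual
Ca²⁺ that drives the two-site sensor never accumulates; (ii) for the
same reason, the late-train loss of synchrony is carried almost
entirely by depression rather than by a synchronous→asynchronous
shift. The synthetic experiments emulate a single, spatially lumped
terminal; they do not represent heterogeneity across boutons, VGCC
subtype mixtures, RyR-mediated release, mitochondria, or postsynaptic
responses, so agreement here speaks to the internal consistency of the
mechanism, not to quantitative prediction of any particular recorded
synapse.

## Problem sizes used in the test suite

The default test battery uses sweeps of 4–5 cluster sizes, 25–100
trials per configuration, and 3–60 s of simulated time per stochastic
channel check. These sizes keep Monte-Carlo standard errors a few times
smaller than the effects under test while keeping run times practical;
larger sweeps and trial counts only sharpen the same comparisons.
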