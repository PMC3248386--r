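---
title: "A receptor-trafficking model of PKC Apl II translocation desensitization under spaced and massed serotonin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A receptor-trafficking model of PKC Apl II translocation desensitization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkcdesens)
```

## The biological question

In *Aplysia* sensory neurons, serotonin (5HT) drives the novel protein kinase
C isoform PKC Apl II to the plasma membrane, where it is active. Repeated
5-min 5HT pulses separated by washes (spaced training) desensitize this
translocation far more strongly than one continuous (massed) application of
the same total duration — a paradox, since spaced training gives the neuron
time to recover between exposures. `pkcdesens` implements a dynamical model
of this phenomenon in which the difference between spaced and massed training
is read out by the synthesis and degradation kinetics of two short-lived
proteins, and provides everything needed to exercise the model without
external data: stimulation protocols, a solver, readouts, a synthetic
measurement generator, staged fitting and a sensitivity scan.

## Model structure

The unit of the model is the 5HT receptor signaling complex S, a conserved
pool distributed over seven states:

* `S_OFF` → `S_ON` under 5HT (rate `kA1·[5HT]`); `S_ON` produces
  diacylglycerol (DAG), and membrane DAG is the translocation readout:
  `dDAG/dt = kDAGp·(S_ON + S_ADON) − kDAGd·DAG`.
* Homologous desensitization: `S_ON → S_IN1` (`kA2`), then either fast
  recycling `S_IN1 → S_OFF` (`kA3`) or sorting into a deep inactive pool
  `S_IN1 → S_IN2` (`kA4`) with near-zero return (`kA5`).
* Heterologous (PKA-mediated) desensitization: `S_OFF → S_PKA` driven by PKA
  activity (`kB1·C`) and by the Desensitizer protein D (`kD1·D`), both gated
  by an inhibitory Hill function of the Anti-Desensitizer AD
  (`kD1a`, `kD1b`). Recycling `S_PKA → S_OFF` (`kB2`) is doubly inhibited,
  by PKA (`kB2a`, `kB2b`) and by D (`kD2a`, `kD2b`).
* AD protection: `S_OFF → S_AD` (`kC1·AD`) and `S_PKA → S_AD`
  (`kD3`, activating Hill in AD); `S_AD` is shielded from both
  desensitization routes but is activatable (`S_AD → S_ADON` with the same
  rates as `S_OFF → S_ON`) and recycles slowly (`kC2`, inhibited by AD).

PKA is a reduced cAMP module: cAMP is synthesized at
`Vm·[5HT]/(K5HT + [5HT])` and relaxes to `cAMP_basal` at rate `kcAMPd`;
cAMP dissociates the holoenzyme RC into R + C (`Kfpka`) against reassociation
(`Kbpka`), with no subunit synthesis or degradation; PKA activity is
identified with free C.

The two proteins carry the timing information:

* AD is synthesized at `kS1·hill(I_PKC; kS1a, kS1b)` where
  `I_PKC = ∫_{t−intPKC}^{t} DAG ds` — a 15-min running integral of PKC
  activity. Only sustained (massed) stimulation pushes `I_PKC` over the
  threshold `kS1a`, so AD accumulates under massed but not spaced training.
  AD degrades at `kS2 = 0.2`/min (half-life 3.5 min).
* D is synthesized at `kS3·hill(I_PKA; kS3a, kS3b)` where `I_PKA` integrates
  PKA activity over 15 min *delayed by 10 min* (`delayD`), and degrades at
  `kS4`. The delay reproduces the observation that depression of a second
  pulse appears only for washes of ~15 min and longer.

Total S is conserved: `dS_OFF/dt` is computed as minus the sum of the other
six receptor derivatives, so the conservation is exact by construction, and
the solver preserves it to machine precision.

Drugs are binary inputs: anisomycin zeroes the synthesis terms of AD and D
(degradation continues); KT5720 replaces PKA activity C by zero in every
receptor and synthesis term while the internal cAMP/R/C/RC dynamics keep
evolving.

## Parameters

The packaged preset `table1_primary` carries the published values; rates are
per minute, windows in minutes, concentrations molar (10 µM 5HT = `1e-5`).
Two values are the package's own reconstruction:

* `kcAMPd = 1`/min — the cAMP decay constant is not listed in the published
  table; 1/min lets PKA activity persist for a few minutes after washout,
  which is required for desensitization to continue into the wash, while
  decaying substantially within ~5 min.
* The cAMP-synthesis Hill coefficient is fixed at 1, the simplest form
  consistent with a single half-saturation `K5HT`.

Two published naming collisions (two rows named `k_D3b`, two named `k_B2a`)
are resolved by the roles the accompanying text assigns: the 0.3372 Hill
coefficient and the 5.33e-8 half-saturation form the AD-inhibition pair
(`kD1b`, `kD1a`) on `S_OFF → S_PKA`, and the 53.1 half-saturation is the
D-inhibition half-saturation (`kD2a`) on `S_PKA → S_OFF`.

`table1_alternate` swaps in the published alternate core set (`kA1 = 2e5`,
`kA2 = 2`, `kA3 = 2`, `kA4 = 0.08`, `kDAGp = 2`, `kDAGd = 200`). Note a
structural consequence: this set rescales absolute DAG by a factor of 200
while the AD-synthesis threshold `kS1a` is unchanged, so `I_PKC` never
reaches threshold and AD synthesis is effectively off. The orderings that do
not depend on the AD threshold (conservation, 1-min rise and washout,
monotone homologous desensitization, the faster recovery of PKA-mediated
desensitization, more desensitization with longer washes) are preserved and
tested under the alternate set; AD-dependent contrasts are not claimed for
it.

## Numerical scheme

The system is a delay integro-differential equation; the solver is classical
fixed-step RK4 with the two history integrals evaluated by the trapezoid
rule on the solver grid.

* Default `dt = 0.01` min. This is dictated by stability, not accuracy: the
  fastest rates are DAG turnover (`kDAGd = 100`/min) and holoenzyme
  dissociation (`Kfpka·cAMP ≈ 158`/min during 5HT), and RK4's real-axis
  stability limit (`|λ|·dt ≲ 2.78`) puts `dt ≤ ~0.017` min. A deliberately
  coarse step produces a divergence error naming the offending step rather
  than silent garbage.
* The integral terms change on the `intPKC`/`intPKA` timescale (15 min ≫
  `dt`), so each RK4 step reuses the integral values computed at its start
  for all four stages. This makes the step formally first-order in the
  integral pathway; in practice translocation traces at `dt = 0.01` and
  `dt = 0.005` differ by under 0.1% sup-norm on every packaged protocol
  (tested), and the scheme self-converges at order ≈ 4 on smooth
  sub-problems where the synthesis pathway is silent.
* Windowed integrals truncate at t = 0 (history before the simulation start
  is zero); off-grid window endpoints (needed when `delayD` or `intPKA` are
  being fitted) interpolate the cumulative integral linearly.
* Protocol transitions are snapped to grid points and applied on half-open
  intervals `[start, end)`; `dt` must divide all event times, which is
  validated up front.
* The initial state is the naive neuron: all S in `S_OFF`, no DAG/AD/D,
  cAMP at basal, and the PKA subunits at their basal fixed point, obtained
  in closed form from the quadratic subunit balance (residual < 1e-10).
* The RK4 inner loop is compiled (Rcpp); Hill-function arguments are clamped
  at zero so that transient solver undershoot (|x| ~ 1e-12) cannot reach a
  fractional power of a negative number.

## Readout conventions

Measurements are membrane/cytosol ratios normalized to "post 5HT #1" — the
first measurement after 5HT addition. In the model this is the translocation
value at the 5-min point of the first pulse (the pulse end for 5-min pulses,
the 5-min point of longer applications), so drug and no-drug conditions are
normalized at the same stimulus age. The default sampling schedule takes a
point every 5 min within each pulse, emulating the imaging cadence. The
wash-desensitization ratio for 15-min-pulse protocols is translocation at
the 5-min point of pulse k+1 over the 15-min point of pulse k.

## Synthetic data

`sample_measurements()` emulates the statistical structure of the imaging
data — per-cell normalized ratios, additive Gaussian noise truncated at
zero, summarized as mean ± SEM over n cells. Defaults are n = 8 cells (the
experiments report 5–10) and per-cell sd 0.4, which yields SEMs near 0.18 at
n = 5, the per-point variability reported for the imaging data. What the
generator does *not* emulate: pixel-level image quantification, cell-to-cell
kinetic heterogeneity (every pseudo-cell shares one latent trajectory), or
temporally correlated noise within a cell. Passing recovery tests on these
data therefore demonstrate identifiability under idealized i.i.d.
measurement noise, not robustness to biological variability.

## Staged fitting

`fit_stage()` reproduces the incremental construction: the core
translocation component (`base`), homologous desensitization
(`homologous`: `kA4`, `kA5`), the PKA pathway (`pka`), the AD pathway
(`ad`), and the D pathway (`d`). Each stage may free only its own
parameters; everything fitted earlier is held bit-identical.
`stage_protocols()` records which datasets each stage consumed. Residuals
are unweighted by default (SEM weighting is available as an option), and the
optimizer is bounded Levenberg–Marquardt from multiple seeded starts, with
an objective that treats a diverged simulation as a very bad fit rather than
an error.

The parameter-recovery study (see the acceptance tests and
`scripts/acceptance.R`) was designed after an identifiability analysis:

* `(kS1, kS2)` and `(kS3, kS4)` are ridge-degenerate — the normalized
  translocation constrains the synthesis/degradation *ratio* (the protein
  level), not the individual rates, and at imaging noise levels the joint
  fit wanders along the ridge. The recovery study therefore frees the
  degradation rates `kS2` and `kS4` with the synthesis rates held at their
  previously-fitted values.
* `kA5 ≈ 0.003`/min is identified almost entirely by the test-pulse height
  after a long wash, so the 140-min recovery protocol samples its 5-min test
  pulse at 1-min within-pulse frames, as the imaging experiment did.

With noise-free data the homologous stage recovers `(kA4, kA5)` to machine
precision from a 2× perturbed start, and fitting it to the massed protocol
drives `kA5` to (near) zero from any start — the model's signature
prediction that recovery from homologous desensitization is essentially
absent.

## Sensitivity classification

Each of the 39 table parameters is perturbed by ±5% and ±50% with the others
fixed, and the perturbed model re-simulated under the massed (90-min) and
spaced (5×5-min) reference protocols. Because the packaged reference data
are the *noise-free* readouts of the unperturbed model, a change measure of
the form |SSE − SSE₀|/SSE₀ is undefined (SSE₀ = 0). The package instead
measures the change in fit on the R² scale:

> change = SSE_perturbed / SStot_reference = 1 − R²(perturbed vs reference),

which is 0 for the unperturbed model, strictly increasing in every residual,
and classifies with the published rule: High if either ±5% change exceeds
0.25 (strictly), else Medium if either ±50% change does, else Low. The
published per-parameter classes were computed against the original imaging
data with an unstated metric, so per-parameter agreement is reported, not
asserted; what is asserted is the published table's own self-consistency
(5 High / 12 Medium / 6 Low parameters with protocol-independent class).

## Problem sizes

The test-suite and acceptance-script simulations use the study protocols at
full length (85–140 min) at `dt = 0.01` min (≈ 9,000–14,000 steps each); the
recovery study uses 5 replicate noise seeds at the reported noise level
(sd 0.1, n = 8). A full sensitivity scan is 314 simulations (≈ 10 s); the
complete acceptance script runs in well under a minute on one CPU.

## Known limitations

* The state equations are reconstructed from the network description and the
  parameter table, not transcribed from typeset equations; the conservation,
  drug-contract, closed-form and oracle tests pin the reconstruction down,
  but alternative algebraic readings (e.g. of the AD-synthesis integrand,
  taken here to be raw DAG) cannot be excluded.
* The published "~5 min" AD half-life and the printed `kS2 = 0.2`/min
  (half-life 3.47 min) disagree slightly; the printed value is used.
* The alternate core parameter set silences AD synthesis (above), so the
  published claim that "the rest of the model still worked" under that set
  is only partially reproducible here.
* No spatial compartments, no receptor synthesis or degradation, no
  persistent-PKA or transcriptional machinery: the model covers minutes to
  a few hours, not long-term facilitation.
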