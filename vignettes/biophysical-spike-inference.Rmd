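---
title: "Biophysical modelling of GCaMP fluorescence and spike inference"
author: "biospike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biophysical modelling of GCaMP fluorescence and spike inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biospike)
```

## The problem

Genetically encoded calcium indicators (GECIs) of the GCaMP family report
neuronal action potentials through calcium-dependent fluorescence, but their
intramolecular kinetics distort the mapping from spikes to signal. Fast
variants are not simply faster versions of a linear kernel: older sensors
(GCaMP6f, jGCaMP7f) amplify closely spaced spikes supralinearly, and the
newest fast sensor (jGCaMP8f) shows a *use-dependent slowing* — its
fluorescence decay after a burst is about three times slower than after a
single spike. Spike-inference algorithms built on linear convolution
misread that slow decay as extra spikes. This package implements a
mechanistic generative model of the sensor and the imaged compartment, and
two inference methods built on it: a sequential Monte Carlo sampler
(particle Gibbs with ancestor sampling, PGAS) and a supervised regressor
trained on synthetic data from the same generative model, together with a
complete spike-matching evaluation suite.

## The sensor model

GCaMP's calcium-sensing domain is calmodulin, which binds calcium
semi-independently at two lobes: the fast-binding N-lobe and the
slow-binding C-lobe. Each lobe is modelled as a three-state chain

    apo  <->  Ca-bound  <->  Ca+peptide-bound

where the second step is binding of the target peptide that switches the
chromophore into a bright configuration. All first-order rates are
lobe-local; the joint sensor state is tracked over the 9 combined
configurations so that quantities conditioned on C-lobe status (the
"slow fluorescent" states responsible for use-dependent slowing) are well
defined. Any configuration with at least one lobe in the Ca+peptide state
fluoresces, and all such states are equally bright. Calcium binding uses a
pseudo-first-order on-rate tied to the off-rate:

$$k_{on}(\mathrm{Ca}) = k_{off} \left(\frac{[\mathrm{Ca}]}{K_a}\right)^{H}$$

so that at equilibrium the bound fraction follows a Hill curve with
apparent dissociation constant $K_a$ and coefficient $H$. $H$ enters only
the rate law, not the state count; the calcium stoichiometry used for mass
balance is the separate integer `nCaPerLobe` (default 2, the two EF-hands
per lobe). Fluorescence is read out as
$F = 1 + (R_f - 1)\,(\varphi - \varphi_0)/(\varphi_{sat} - \varphi_0)$,
where $\varphi$ is the fluorescent-class occupancy and $R_f$ the dynamic
range; stopped-flow simulations normalize $\varphi$ between its
zero-calcium and saturating values instead.

Because each lobe is a birth–death chain, steady states factorize exactly
into per-lobe stationary distributions, and propagation under
piecewise-constant calcium uses per-lobe matrix exponentials (Kronecker
products of 3×3 propagators) — unconditionally stable at any rate
stiffness, which matters because fitted peptide and binding rates span
four orders of magnitude.

## The bouton model

The imaged compartment is a cerebellar granule-cell bouton. Each action
potential adds a fixed total calcium `aCa` (µM) that equilibrates
instantly with a fast, low-affinity endogenous buffer of capacity
$\kappa_B \approx 40$: the free pool receives $a_{Ca}/(1+\kappa_B)$, the
buffer the rest, and all continuous fluxes are likewise divided by
$1+\kappa_B$ (the standard linearized-buffer approximation, which
preserves calcium balance while keeping the system non-stiff). Calcium
then leaves through Michaelis–Menten extrusion
($V_{max}$, $K_m$), optionally exchanges with an intracellular store
(Michaelis–Menten in both directions), and equilibrates with a slow second
compartment (volume fraction `slowFrac`, rate `slowK`) that produces the
slow tail of measured transients. Resting calcium is an *exact* fixed
point: a constant leak influx balancing the basal pump and store fluxes is
computed at construction, and when the store exchanges both ways its
resting level is solved so the store is also at rest — otherwise traces
would drift before the first spike. Spike influx is instantaneous (a
delta) because ~1 kHz sampling cannot resolve sub-millisecond influx
shapes. Observation noise is additive white Gaussian on ΔF/F, matching the
SMC observation model.

The reference integrator is `deSolve::lsoda` on the coupled 13-state
system (4 calcium pools + 9 sensor states) with spike events.

## Parameters that matter

| parameter | units | default | meaning |
|---|---|---|---|
| `aCa` | µM | 20 | total calcium per action potential (≈0.49 µM free after buffering) |
| `kappaB` | – | 40 | endogenous buffer capacity |
| `gTotal` | µM | 20 | sensor concentration (the sensor is itself a buffer) |
| `pumpVmax`, `pumpKm` | µM/s, µM | 1500, 0.5 | extrusion |
| `slowFrac`, `slowK` | –, 1/s | 0.1, 2 | slow compartment |
| `caBasal` | µM | 0.05 | resting free calcium |
| `Rf` | – | per variant | dynamic range |

Store exchange is disabled in the standard set: at these statistics it is
degenerate with the pump plus slow compartment, and fitting it freely only
inflates parameter variance. The machinery remains available and tested.

## Calibration of the shipped variant parameters

`scripts/calibrate_defaults.R` produces
`inst/extdata/sensors/{jgcamp8f,gcamp6f,jgcamp7f}.json`. For each variant
the ten lobe rate constants and $R_f$ are fitted (Nelder–Mead on a
squared-log-ratio loss, from fixed hand-chosen starting points, hence
deterministic) so that a *single* parameter set reproduces, under the
*single* shared bouton model above, all of that variant's measured
transient statistics simultaneously: single-spike 10–90% rise time,
single- and 10-spike half-decay times, single-spike peak ΔF/F,
paired-pulse ratio at 10 ms, and the 10:1-pulse amplitude ratio. That
simultaneous satisfiability is the model's central claim — fast rise with
slow post-burst decay (jGCaMP8f) falls out of N-lobe/C-lobe kinetics
rather than separate time constants per protocol. The fit is joint with a
stopped-flow constraint: the simulated saturating calcium step must show
the biphasic (two-exponential) rise that purified-protein kinetics
exhibit, enforced as a penalty on the one- versus two-component residual
ratio. Soft penalties also keep the fit in the physically meaningful
regime (the N-lobe binds faster than the C-lobe at matched calcium; Hill
exponents above 0.1; $R_f \lesssim 100$).
Only the product of $R_f$ and basal-occupancy terms is constrained by
ΔF/F data, so $R_f$ itself should be read as a phenomenological scale, not
an in-vitro dynamic range. Each JSON embeds its fit loss and achieved
statistics.

The multistart stopped-flow fitter (`globalFitSensor`) draws its starting
points from a maximin Latin hypercube over log-scaled bounds — a
low-discrepancy design; the characterization-scale setting would use
thousands of starts, the default (64) is sized for interactive use.

## Spike inference

The state-space model has, per time bin: a Bernoulli spike indicator (rate
`rateHz`·dt, at most one spike per bin, bin = sample interval), the
deterministic advance of the bouton/sensor state, a Gaussian-random-walk
baseline (scale `driftScale` per √s), and Gaussian observation noise
`sigma`. `pgasInfer` alternates:

1. a **conditional SMC sweep** in which particle 0 replays the reference
   trajectory and its ancestor index is redrawn by ancestor-sampling
   weights (transition density × one-step-lookahead likelihood under the
   reference continuation — the standard practical choice when most of the
   state advances deterministically);
2. **Metropolis-within-Gibbs** log-scale random-walk updates of
   (`aCa`, `gTotal`, `pumpVmax`, `Rf`, `sigma`, `rateHz`, `driftScale`)
   given the sampled trajectory, with log-normal priors.

Burn-in is the first 25% of iterations; per-bin spike probabilities are
means of the post-burn-in indicators; MAP spikes threshold at 0.5 and
merge adjacent supra-threshold bins at their probability-weighted centre.
The default desk-scale budget is 64 particles × 40 iterations, which
processes a 60 s, 500 Hz trace in a few minutes; all randomness flows
through R's RNG, so runs are bit-reproducible given the seed.

Inside the sweep the bouton state advances with Strang-split substeps:
exact per-lobe matrix-exponential propagators, linearly interpolated on a
log-calcium table (zero plus 399 log-spaced points), alternated with midpoint steps for the
calcium scalars — 62.5 µs substeps for the 10 ms after each spike, 1 ms
substeps elsewhere. Against the reference integrator this is accurate to
better than 1×10⁻³ ΔF/F except in the spike bin itself (≈4×10⁻³ there,
where the intra-bin rise is unresolved by construction); the tests pin
these tolerances.

A linear AR(2) generative model with fixed per-spike amplitude
(`generativeModel = "linear_ar"`) plugs into the same sampler. Its kernel
is fitted to the sensor's single-spike response; it exists to demonstrate
the characteristic failure mode of linear models on use-dependent-slowing
sensors — false positives during the slowed decay of spike trains. The
acceptance suite checks this on ten seeds by counting false positives on
the post-burn-in sampled trajectories (the single-trajectory spike
rasters used to compare generative models), where the effect is visible
even when bin-wise posterior averaging would dilute it below the MAP
threshold.

## Synthetic data and the supervised route

`generateTrace` composes the noiseless simulation, an Ornstein–Uhlenbeck
baseline drift (the simplest stationary process with an amplitude and a
timescale; the data regime being emulated specifies only "baseline
drift"), and white Gaussian noise, with the seed split deterministically
into spike/drift/noise streams. The excitatory preset is 10 Hz Poisson
spiking (3 ms refractory) at 500 Hz sampling with σ = 0.12 ΔF/F — chosen
so the calibrated jGCaMP8f single-spike peak (0.59) gives SNR ≈ 5; the
inhibitory preset is 30 Hz Poisson with `aCa` halved and $R_f - 1$ halved.
What these synthetics do *not* emulate: shot noise, scan artefacts,
neuropil contamination, or movement — so green tests here bound model- and
algorithm-correctness, not robustness to imaging artefacts.

`trainSupervised` fits a windowed gradient-boosted tree regressor (±64 ms
window) from fluorescence to the 10 ms-Gaussian-smoothed spike density;
it is deliberately small and CPU-trainable in minutes, and its manifest
(corpus manifest, seeds, settings, loss curve) suffices to retrain it
bit-identically. `discretizeDensity` converts density to spike times by
greedy matching pursuit with unit-mass Gaussian kernels, stopping when the
residual mass falls below half a kernel.

## Evaluation suite

`matchSpikes` computes the minimum-total-|offset| one-to-one assignment
within a 10 ms window, with cost of unassignment `maxDt/2` (the unique
choice that makes the window binding); since both trains are sorted and
the cost is convex, an optimal non-crossing matching exists and dynamic
programming finds it exactly — verified against brute-force enumeration.
Precision, recall, F-score, and Jaccard-style accuracy
TP/(TP+FP+FN) follow, with 0/0 cases reported as undefined rather than 0.
Timing bias is the median signed offset (positive = imputed late),
uncertainty the median absolute offset; robust SD is MAD/0.6745
throughout. `filteredCorrelation` smooths both the continuous spike
probability and the binned truth with matched Gaussian kernels
(edge-replicated padding so constant signals stay constant) and reports
Pearson r per width.

## Numerical choices and degenerate inputs

* Tie-breaks: assignment backtracking prefers matched pairs at equal
  cost; `mapSpikes` merges *adjacent* supra-threshold bins only.
* Degenerate sensors (equal zero-calcium and saturating fluorescence)
  raise a configuration error rather than dividing by zero.
* Negative concentrations during integration are clipped at zero with one
  warning per simulation; occupancies are renormalized only at
  construction, never silently during propagation.
* `fitHill` refuses flat data; `fitMultiExponential` is deterministic
  (log-spaced tau grid + Levenberg–Marquardt polish) and returns taus
  ascending.

## Problem sizes used by the tests

The suite exercises the full pipeline at sizes chosen for a single CPU:
the calibration-coherence checks run noise-free 1 kHz simulations; the
SMC recovery check uses one 60 s excitatory trace at 500 Hz with 64
particles × 40 iterations; the linear-vs-biophysical comparison uses ten
15 s seeds at 48 particles × 24 iterations; supervised training uses four
15 s traces. The same code scales to longer recordings and larger budgets
by changing the corresponding arguments.

## Known limitations

* The sensor model is phenomenological at the state-count level: real
  GCaMPs have more conformational states (magnesium competition, pH
  dependence, chromophore maturation are all out of scope).
* $R_f$ and basal occupancy are jointly, not separately, identified from
  ΔF/F statistics.
* The per-bin advance inside SMC does not resolve the intra-bin rise
  (see above); spike *times* are therefore quantized to bins before MAP
  refinement.
* The "accessible slowing" index (`accessibleSlowing`) is a documented
  surrogate — a ratio of slow- to fast-pathway entry-rate × dwell-time —
  not a published formula.
* Performance numbers on the external jGCaMP8f ground-truth benchmark are
  intentionally not reproduced here; `readGroundTruthEpochs` adapts such
  data if present, and the acceptance suite substitutes property-based
  checks on synthetic ground truth.

## A worked example

```{r example, eval = FALSE}
sensor <- defaultSensor("jGCaMP8f")
cell <- defaultCellParams()

## what the calibrated sensor does
unlist(sliceStats(sensor, cell))

## simulate a synthetic excitatory cell and infer its spikes
pre <- tracePreset("excitatory", duration = 20, sampleRate = 500)
gen <- generateTrace(pre, sensor, cell, seed = 7)
cfg <- inferenceConfig(nParticles = 64, nIterations = 30, seed = 11)
post <- pgasInfer(gen$trace, sensor, cfg, cell)
classificationMetrics(matchSpikes(post@mapSpikes, gen$spikes, 0.010))
```
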