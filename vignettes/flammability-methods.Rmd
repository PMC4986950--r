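---
title: "Mechanistic flame propagation from leaf traits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic flame propagation from leaf traits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffmr)
```

## The model

`ffmr` simulates flame propagation through a multi-strata forest stand as a
chain of convective ignition events, escalating from single leaves to
foliage clumps, plants and whole vegetation strata. The state advances in
one-second steps; everything is deterministic.

The mechanism in one sentence: a burning **donor** (first the surface
litter bed, later any burning stratum) produces a flame whose convective
plume follows the wind-tilted flame angle; air temperature in the plume
decays with distance from the donor; an unburnt **receiver** leaf ignites
if the heating time the donor can supply exceeds the receiver's time to
ignition at the local plume temperature.

Three leaf-scale properties drive this:

* **Ignitability** — the ignitability coefficient
  `IC = moisture (%ODW) × thickness (mm) / number of leaf sides` (a flat
  lamina has two sides, a terete leaf one). Higher IC means more water per
  unit heated surface, so slower ignition. Below the leaf's minimum piloted
  ignition temperature (the *endotherm*, set by leaf chemistry) no heating
  time suffices. Foliage moisture entering IC is the live moisture mixed
  with the dead-fuel moisture content (DFMC), weighted by the proportion of
  dead material in the plant — DFMC affects suspended dead fuel, not only
  litter.
* **Combustibility** — the flame length a burning leaf produces, driven by
  leaf length, width and moisture.
* **Sustainability** — how long the leaf flames, driven by leaf
  cross-section area (width × thickness) and moisture.

At each step the model computes, for every stratum, the **depth of
ignition** (the largest plume-axis distance at which the ignition condition
still holds) and intersects the plume axis with the crown cross-section to
get the **plume pathway** — the depth of foliage the plume can reach. The
crown is the symmetric hexagon implied by five envelope parameters (base
centre and edge heights, top edge height, crown top, width). Leaves inside
the reachable pathway ignite, counted through the periodic clump pattern
(clump diameter + separation, leaves per clump). The leaves burning in a
step are those from the previous step, plus newly ignited, minus those
whose flame duration has elapsed; this ledger is asserted at every step.
The merged flame of `n` burning leaves scales the per-leaf flame length by
`n^0.5` (sublinear: mutual air entrainment), and stand flame height is the
maximum over strata of `origin + length × sin(angle)`.

Wind couples the strata: foliage in non-burning strata above a height
attenuates the wind exponentially in cumulative leaf area index (LAI), so
overstorey **sheltering** keeps low flames upright, while open stands let
wind flatten the plume — which can lengthen the pathway through a
neighbouring crown or tilt the plume under a receiver entirely. The wind
reduction factor (WRF = open wind / wind at 1.5 m) summarises the profile.
As strata ignite they stop sheltering.

The run is piloted by an empirical surface litter flame (power law in fuel
load, exponential damping in DFMC, linear enhancement in wind), constrained
to the approximate domain of the laboratory data behind it: out-of-domain
inputs are clamped to the boundary and flagged.

## Sub-model coefficients

The fitted relations behind time-to-ignition, leaf flame duration and
length, plume decay, flame tilt, merging, canopy wind attenuation and the
litter model are deliberately configuration, not code: each block of
`inst/extdata/submodels.yaml` records the functional form, coefficients,
validity range and a provenance note, and `ffm_config()` loads and merges
overrides. The shipped defaults are standard physical forms calibrated once
to realistic eucalypt-forest magnitudes:

| Block | Form | Key defaults |
|---|---|---|
| `time_to_ignition` | `a·IC/(T − t_ref)` | a = 60 s·°C per IC unit, t_ref = 100 °C |
| `flame_duration` | `a·(w·t mm²)^0.6·e^{0.002 m}` | ~5 s for a eucalypt leaf |
| `leaf_flame_length` | `a·L^0.8·W^0.4·e^{−0.003 m}` | ~0.14 m per eucalypt leaf |
| `plume` | `(L/d)^{5/3}` far-field decay | classic buoyant-plume exponent |
| `flame_angle` | `atan(gL/(c U²))` | Froude-number balance, c = 1 |
| `flame_merge` | `n^0.5` | sublinear entrainment |
| `microclimate` | `e^{−k·LAI}` | k = 0.6 per unit LAI |
| `surface_fire` | `a·load^0.75·e^{−5·dfmc}·(1+0.3u)` | 0.5–1.5 m litter flames |
| `flame.temperature_c` | constant | 950 °C |

Replacing any block with laboratory refits requires no code change. The
litter-model domain box is marked provisional in the file.

## Units and conventions

Lengths are metres internally; leaf thickness is accepted in millimetres in
input files (signalled by the `leaf_thickness_mm` column). Wind is recorded
in km/h (signed relative to the spread direction: flanks get zero,
opposing wind is negative) and converted to m/s at the module boundary.
Slope is signed degrees, negative for downslope spread; a negative slope
steepens the effective plume angle toward the overhead fuel column.
Moisture is %ODW; the dead fraction is stored as a proportion in [0, 1]
(avoids repeated division by 100); DFMC is a fraction of oven-dry weight.
Crown heights are absolute metres above ground.

## The three treatments

* **F** — surface fuel only: the litter flame under the sheltered wind.
  Standing plants influence F only through LAI sheltering.
* **FS** — plus stand structure: the full engine, but leaf traits averaged
  into the monocotyledon and dicotyledon groups (unweighted means by
  default; a config switch enables composition weighting) and internal
  crown structure collapsed to a single clump filling the crown depth with
  zero separation. This keeps the crown envelope — the only structure FS
  retains — while removing within-crown gappiness. The crown-envelope LAI
  is used for FS sheltering.
* **FSL** — plus leaf traits: species-specific traits and clump structure.

These nest: with no strata all three coincide; a single-species stand whose
clump already fills the crown makes FS and FSL identical. Both nestings are
tested exactly.

Validation scores predictions against observed flame-height intervals
(bounded below by the height of combustion and above by the lowest of
scorch height or the next unconsumed stratum base): signed and absolute
errors are measured against the interval **median**, while the proportion
of correct predictions (PCP, and PCP₁ for observed flames ≥ 1 m) uses the
full interval with inclusive bounds. The median convention reconciles the
two uses of the observations and is switchable in principle to a
nearest-bound distance; we record it prominently because the field
convention does not fix it.

## Sensitivity analysis

The response is predicted flame height under FS minus that under FSL; the
twelve predictors cover donor flammability (donor flame height below the
highest receiver, and its treatment delta), receiver ignitability (mean
IC), overstorey shelter (sum and canopy LAI and their deltas), weather
(wind, DFMC, slope) and structure (vertical continuity, surface fine
fuel). All **delta predictors are FSL − FS**; with the FS − FSL response
this makes a *negative* coefficient mean "the trait-driven increase raises
FSL flames relative to FS". Published analyses of this design mix both
delta directions between tables; we use one convention throughout and note
that only coefficient signs, not magnitudes or inclusion frequencies,
depend on it. Vertical continuity — named but never defined in the
published predictor tables — is defined here, provisionally, as the negated
sum of vertical gaps between successive occupied strata.

Fitting uses `glmnet::cv.glmnet` (L1 path, k = 10 folds, 100-value
log-scale penalty path) under either the `min` or `1se` rule. Because
secondary predictors enter or leave with the random fold allocation, the
ensemble repeats the fit (default 1000 runs, seeds derived from a base
seed, bit-reproducible) and reports per-predictor inclusion counts and
coefficient statistics on the original predictor scale.

```{r lasso-demo}
set.seed(3)
x <- matrix(rnorm(60 * 12), 60, 12,
            dimnames = list(NULL, c("signal", paste0("n", 1:11))))
m <- list(x = x, y = 2 * x[, 1] + rnorm(60, 0, 0.1))
head(summary(ffm_ensemble(m, n_runs = 20, base_seed = 1)), 3)
```

## The synthetic-stand generator

`ffm_synthetic_sites()` draws sites, species tables and weather uniformly
and independently within the structural and exogenous ranges the model is
parameterised for (surface fuel 9.6–24.3 t/ha; wind −21 to 30 km/h; slope
−28° to 21°; DFMC 3.6–13.7%; per-stratum crown geometry and spacing
ranges), with species traits jittered ±20% around shipped synthetic
archetypes (tussock grass, forb, sclerophyll and mesic shrubs, wattle and
tea-tree midstorey, eucalypt canopy). Crown geometry invariants hold by
construction; every generated site passes the validator battery (tested in
bulk). Observed intervals are manufactured by running the full model and
widening its prediction (`half-width = 0.3 × prediction + 0.2 m`, median
jittered within the interval, a fifth of sites capped near the next
unburnt stratum base), so truth is recoverable by construction: with all
noise at zero the full treatment scores PCP = 1 and MAE = 0 exactly.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: correlated trait–structure–weather distributions
(real stands are not independent uniforms), measured per-site abundances
(composition weights default to equal because per-stratum abundance is
rarely recorded), real floristics, and observation error that is not
centred on the model's own prediction. Recovery results on synthetic data
demonstrate internal consistency of the pipeline, not field accuracy.

## Numerical choices

* Time step 1 s; step cap 600 with a logged truncation warning.
* Escalation order within a step is ground-up (surface → near-surface →
  elevated → midstorey → canopy), so a stratum ignited in a step can act as
  a donor for strata above it in the same step — upward convective transfer
  is the modelled mechanism.
* The plume axis originates at the flame *origin* and distances are
  measured along it; inside the flame envelope the plume holds the flame
  temperature. For inter-stratum transfer the reachable pathway is the
  part of the crown chord within the depth of ignition. (The alternative —
  anchoring the transfer plume at the flame mid-point — is flagged in
  config.)
* Depth of ignition is found by bisection on the monotone ignition
  condition (50 iterations after bracketing); tests pin it to an
  exhaustive 1 mm scan.
* A plume grazing a crown edge counts as intersecting (inclusive
  tie-break). Leaf counts are floored to whole leaves.
* Donor flames for stratum-to-stratum ignition are the merged stratum
  flames; the receiver test uses the composition-weighted mean leaf
  flammability of the receiver stratum. A stratum's fuel is bounded by the
  leaves on its centreline chord; extinguished leaves do not re-ignite.
* Leaf-scale outputs are clamped at zero so extrapolation outside fitted
  trait ranges cannot produce negative durations or flame lengths.
* Negative (opposing) winds attenuate and tilt by magnitude; sign is
  preserved in the profile.

## Problem sizes

The test suite runs stands of 1–4 strata with 1–3 species per stratum,
bulk-validates 500 generated sites structurally, and uses a 1000-member
ensemble at n = 200 for the LASSO recovery check; the acceptance script
scores a 40-site synthetic study and two 1000-run ensembles. These sizes
exercise every mechanism while keeping a full run in the low minutes on a
single core.

## Known limitations

* Heat transfer is convective only; radiation and ember transport are out
  of scope, as are rate of spread, perimeter growth and smouldering.
* Leaf chemistry enters only through the endotherm; phosphate content and
  tissue density effects are excluded.
* The published sub-model coefficient tables and the deposited per-site
  observed/predicted dataset are external supplementary material; the
  shipped coefficients are the package's own documented calibration, and
  the headline field statistics of the original 58-site study can only be
  recomputed once that per-site file is supplied (see
  `tests/testthat/test-acceptance.R`).
* "Branch" as an intermediate scale is represented by the foliage clump
  (the clump parameters are the branch-scale structure); the two are
  conflated deliberately.
* Within-crown versus between-crown wind averaging at a height is not
  distinguished; the profile is horizontally averaged.
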