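---
title: "Estimating infinite-dilution diffusivities: models, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating infinite-dilution diffusivities: models, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracerdiff)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the limitations a user should know about.

## The quantity and its units

D12 is the binary (tracer) diffusion coefficient of a solute (subscript 2)
at infinite dilution in a solvent (subscript 1) — the limit of vanishing
solute concentration, where solute–solute interactions are negligible. All
functions use one frozen unit dialect: temperature in K, solvent viscosity
mu1 in cP, density in g cm^-3, molar mass in g mol^-1, critical pressure in
bar, critical volume in cm^3 mol^-1, Lennard-Jones diameter in Angstrom,
Lennard-Jones energy as eps/kB in K, and D12 in cm^2 s^-1. Conversions to
SI/CGS (bar to Pa, Angstrom to cm, Avogadro and Boltzmann constants) happen
inside the functions, never at call sites, so a user can feed tabulated
values directly.

## Classic models

**Hydrodynamic correlations.** `wilke_chang()` and `tyn_calus()` descend
from the Stokes–Einstein relation: D12 proportional to T/mu1, with
empirical molecular-size corrections through the molar volume at the normal
boiling point (`vbp_from_vc()`, the Tyn–Calus power law 0.285 Vc^1.048).
Their assumptions — a large spherical solute in a continuum solvent — are
crude, which is why both are homogeneous of degree +1 in T and −1 in mu1
(a property the tests check on randomized inputs). The Wilke–Chang
association factor phi (1.9 methanol, 1.5 ethanol, 1.0 otherwise) is
resolved from the solvent identity by `association_factor()` and can be
overridden per call.

**Two-parameter correlation.** `magalhaes_fit()` fits D12 = a T/mu1 + b per
system by ordinary least squares. It interpolates excellently but needs
existing data for the very system of interest: it is a correlation, not a
prediction. The minimum fit size is 3 distinct T/mu1 values — two
parameters plus one residual degree of freedom; sparser systems raise an
error, and `fit_magalhaes_per_system()` skips them with a warning naming
the system. Extreme extrapolation can produce a negative D12; the value is
returned as-is with a warning rather than clipped, so the caller sees the
failure instead of a silently censored number.

**Hybrid Lennard-Jones model.** `zhu_state()` + `zhu_d12()` implement a
free-volume/energy hybrid for nonpolar fluids. The state object carries the
binary parameters from the combining rules (arithmetic-mean diameter with
interaction correction k12d, geometric-mean energy) and the reduced
coordinates T12* and rho12*. The diffusivity is a Chapman–Enskog dilute-gas
prefactor times three corrections; at rho12* = 0 it reduces *exactly* to
the kinetic prefactor, which is both a physical sanity check and the
anchor that fixes the equation's grouping where typesetting of the source
material is ambiguous. Every constant and grouping choice of this model is
isolated in one internal table (`R/constants.R`), so correcting a reading
against the original source changes one definition. Two grouping decisions
are worth stating:

* the solvent-energy bracket *multiplies* Tc1/1.313;
* the temperature term inside the dense-fluid correction F2 is a *power*
  of T12*; and the cube roots on both diameter estimators, lost in
  typesetting, are restored on dimensional grounds (volume to length).

With these readings the model gives 5.9e-5 cm^2 s^-1 for benzene in
n-hexane at 298 K — the right decade and within ~30% of the hydrodynamic
estimates, and the solvent self-diffusion analogue lands at the well-known
~4e-5 cm^2 s^-1 scale, which supports the reconstruction. The reduced
density fed to the solvent-parameter estimator is a mass-density ratio,
rho_r1 = rho1/(M1/Vc1): the alternative reading through pressure is
dimensionally untenable for these equations.

One empirical caveat, found numerically and encoded in the tests: the
dense-fluid correction F2 is only constrained where such correlations are
fitted (liquid-like reduced densities). Below rho12* of about 0.4 at
T12* at or below 1 the product of corrections is not monotone in density;
the model should not be trusted there, and the monotonicity test is
asserted on rho12* in [0.4, 1]. Likewise F1 turns negative (free volume
exhausted) at high density/low temperature; `zhu_d12()` then warns and
returns the value rather than failing, so batch evaluations can filter
after the fact.

## Dataset handling

Records follow a versioned CSV schema (`solvent_cas, solute_cas, T_K,
rho1_g_cm3, mu1_cP, D12_cm2_s, polarity, source`, plus optional per-record
property columns) with a header comment line freezing the unit dialect.
Pure-compound properties absent from a file are resolved by joining against
the packaged compound table on CAS or name. The polarity label is a column,
taken as ground truth, never inferred from chemistry.

The train/test split (`split_train_test()`, default 70/30) is at the
*record* level, not the system level: one system may contribute points to
both sets, which matches how per-system accuracy tables can show the same
system in train and test. The seed is a required, recorded input. The same
split should feed the ML models and the classic benchmarks so that all
models see identical data.

## The machine-learning pipeline

**Variable selection.** `select_variables()` removes collinear variables:
while any kept pair has |Pearson| above the threshold (default 0.50), the
currently worst-offending pair is processed and its member with the lower
absolute correlation with D12 is dropped; ties fall back to a preference
order encoding how easy a variable is to obtain for a new system.
Processing pairs in descending |r| makes the outcome deterministic — the
result is independent of the order in which variables happen to be listed.

**Scaling.** Inputs are min-max scaled to [0, 1] with bounds learned on the
training rows only (`fit_scaler()`/`apply_scaler()`). Test rows falling
outside the training range are *not* clipped: the affine map is extended,
preserving the models' ability to extrapolate moderately.

**Algorithms and tuning.** Five regressors sit behind one contract:
multilinear regression (`stats::lm`), k-nearest neighbours
(`caret::knnreg`), decision tree (`rpart`), random forest (`ranger`) and
gradient boosting (`xgboost`). `grid_search_train()` searches a declared
grid exhaustively, scoring each candidate by the mean validation
coefficient of determination over 4 cross-validation folds (contiguous
blocks after one seeded shuffle; the fold protocol is a choice, recorded
here, since block assignment conventions differ), refits the winner on the
full training set, and breaks ties by first-in-grid order. The grids ship
as data (`inst/extdata/hyper_grids.json`) — grids are configuration, not
code — with 0 encoding "unlimited" depth. They are declared defaults, not
reconstructions of any particular published tuning table.

Two numerical choices inside the contract:

* a zero-variance validation fold makes R^2 undefined; such folds are
  scored by negative squared error so perfect predictions still rank
  first;
* the boosted regressor is fit on the *standardized* target and its
  predictions unscaled on the way out, because split-gain evaluation in
  gradient-boosting implementations underflows at the 1e-5 cm^2 s^-1
  magnitude of liquid-phase diffusivities and the booster otherwise never
  splits. The other algorithms are scale-invariant and take D12 raw.

**Determinism.** Given a seed, the entire path — fold assignment, forest
and booster randomness, the split — is reproducible; the tests assert
bit-identical predictions across runs. Seeded internals save and restore
the caller's RNG state, so package calls do not perturb user scripts.

**Validation metrics.** `aard()` (average absolute relative deviation, %)
is the headline metric because diffusivities span decades; `rmse()`
complements it in absolute units. `r_squared()` is 1 − SSres/SStot about
the mean *of the evaluated set*: on training data it reports R^2, on
held-out data Q^2. Centring Q^2 on the test mean is the conventional
external-validation choice (the alternative, centring on the training
mean, differs only when the two means drift apart; the choice is recorded
here). `evaluate()` reports the point-pooled ("global") AARD and the
unweighted per-system mean separately; the global value equals the
NDP-weighted mean of per-system AARDs as an algebraic identity, which the
tests verify to 1e-12 relative tolerance.

**y-randomization.** `y_randomization()` rebuilds the identical pipeline
on training sets whose D12 vector has been permuted and scores each rebuilt
model on the untouched test set. A real model's Q^2 should sit far above
the permuted distribution; on targets that are pure noise it should sit
*inside* it — both behaviours are tested. The reference protocol uses 200
permutations.

## The synthetic-data generator

`generate_dataset()` emulates the *schema and statistical shape* of
experimental compilations so that every pipeline stage is testable without
the experimental data, which live in primary literature sources and are not
redistributable here. Design, chosen once and recorded:

* Per system, one solvent/solute property vector held constant across the
  system's records — as in real databases, where only T, rho1, mu1, D12
  vary within a system. Scale-type properties are drawn log-uniformly
  within ranges defaulting to the applicability domain of polar-solvent
  diffusivity models (T 268–554 K, M2 17–674 g mol^-1, Pc2 4.1–221.2 bar,
  M1 20–113 g mol^-1, eps1/kB 208–2121 K).
* Per record, temperature is uniform in a per-system window of half-width
  40–80 K (typical of well-studied systems), and *fluidity* 1/mu1 is
  uniform within a per-system band spanning a 5–10-fold viscosity ratio
  centred log-uniformly on 0.2–2.5 cP. Uniform fluidity is the
  free-volume-theory behaviour of liquids over wide temperature ranges;
  density decreases mildly and linearly with T.
* D12 comes from one of three mechanisms — the Wilke–Chang equation itself
  (for generator/model identity tests), a per-system affine law in T/mu1
  (for parameter-recovery tests; the truth is attached to the output), or
  a smooth nonlinear function of T, mu1, M2, Pc2 and M1 (for exercising
  the nonlinear learners) — times multiplicative lognormal noise.
  Multiplicative (not additive) noise is deliberate: AARD is a relative
  metric, so relative noise of coefficient of variation c makes the true
  mechanism's expected AARD approximately 100 c, giving interpretable
  benchmarks. Default ranges keep every generated D12 inside
  1e-7–1e-3 cm^2 s^-1, the physical span of liquid-phase diffusivities.
* `inject_collinearity()` plants derived columns with known correlation
  structure to exercise the selection step.

What the generator does *not* emulate, hence what passing tests do and do
not show: the marginal distributions and inter-property correlations of
real compounds (properties are drawn independently, so e.g. a heavy solute
can carry a small critical volume); the thermodynamic consistency between
rho1, T and the critical constants (so the hybrid LJ model evaluated on
synthetic states can fall outside its validity domain); measurement-error
structure beyond i.i.d. relative noise; and the long tail of systems with
one or two points. Pipeline results on synthetic data demonstrate that the
machinery is correct and that algorithm orderings hold under a known
signal-to-noise ratio — they are not estimates of accuracy on real
diffusivity data.

With the default sampling design, 5% relative noise and at least 10 points
per system, ordinary least squares recovers the affine mechanism's slope
within 5% for about 93% of systems (a 20-seed property test asserts at
least 90%); this rate is limited by the interaction of multiplicative
noise with unweighted least squares, not by the generator's spread.

## Problem sizes used in the tests

The property and pipeline tests run on databases of 20–60 systems
(roughly 500–1700 records), 20-seed replications for the stochastic
orderings, and 200 permutations for the y-randomization check; these sizes
were chosen so the full suite exercises every claim at statistically
meaningful scale while remaining quick to run routinely.

## Known limitations

* The hybrid LJ model is restricted to nonpolar systems (the CLI refuses
  polar rows) and to liquid-like reduced densities, as discussed above.
* The Klincewicz estimator is implemented only in its two-input (M, Tb)
  correlation form; group-contribution variants for Tc, Pc and Vc are out
  of scope, and the packaged table's Pc/Vc entries are data, not
  recomputed. One tabulated critical temperature (ferrocene) is known not
  to obey the M–Tb correlation that the other organometallic entries
  follow; it is packaged as tabulated.
* The packaged compound table preserves its source's quirks verbatim
  (a synonym pair sharing one CAS number; one zero Lennard-Jones energy;
  one molar mass that disagrees with the formula), and the validator is
  written to tolerate exactly those: synonym rows must agree on every
  property, and eps/kB must be non-negative rather than positive.
* Hyper-parameter grids are modest by design; users with more compute can
  pass wider grids through `grid_search_train(grid = ...)` or a JSON file
  to the CLI.
* No uncertainty quantification is attached to predictions; AARD/RMSE/Q^2
  on held-out data are the package's accuracy statements.
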