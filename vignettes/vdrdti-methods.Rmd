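---
title: "Models and methods behind vdrdti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vdrdti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vdrdti` chains five scientific components: behavioral scoring of
value-directed remembering lists, a latent-trait cohort simulator, digital
diffusion phantoms, tensor/FA estimation with ROI statistics, and a
probabilistic-tractography-plus-correlation battery. This vignette explains
each model, its assumptions, the tunable parameters, and the numerical and
design choices that were genuinely open.

## Behavioral scoring

A study list carries a multiset of point values; the default design is five
lists of 24 words, half valued {10, 11, 12} and half {1, 2, 3}, each value
four times, so the mean list value is exactly 6.5. For a recall record the
package computes `actual` (points earned), `chance` (mean value × number
recalled — the score expected had values been assigned at random), `ideal`
(the top-`n` value sum), and the Selectivity Index
`(actual − chance)/(ideal − chance)`.

Two edge cases are not defined by the index itself and required a decision:

* **Zero or full recall** makes `ideal = chance` and the index undefined.
  `score_list()` records `NA` and `selectivity_index()` errors rather than
  returning a silent number.
* **Averaging across lists**: lists with an undefined index are excluded
  from the subject's selectivity mean but retained for the high/low recall
  means. Dropping preserves the defined-score semantics; imputing any
  value (e.g. 0) would bias subjects toward value-insensitivity precisely
  when their behavior is uninformative.

Ties in the ideal score are irrelevant by construction — values, not word
identities, are summed — and word identities are plain indices; no lexical
content is modeled. Scoring is invariant to word order, which the tests
check by permutation.

The group-level `paired_t()`/`one_sample_t()` helpers compute the standard
statistics by explicit formula rather than `t.test()` so that zero-variance
input yields a signed-infinite t with a warning instead of an error;
simulation sweeps over extreme configurations must not abort on degenerate
draws.

## Cohort simulator

Each subject carries three latent standard-normal traits: general memory
ability, semantic-pathway integrity, and reward sensitivity (uncorrelated
by default; the trait correlation matrix is a config field because the
behavioral data alone cannot constrain it). Word recall is
independent-Bernoulli logistic,

```
P(recall) = plogis(a_i + g_i * z(v)),
a_i = alpha0 + w_ability * ability_i + w_semantic * semantic_i,
g_i = gamma0 + w_reward * reward_i,
```

with `z(v)` the word value standardized over the list's value distribution.
This is the simplest generative model that produces both overall-recall and
selectivity variation with interpretable knobs; list-level capacity
constraints and across-list strategy learning are deliberately not modeled
(a static per-subject slope stands in for acquired selectivity).

Defaults (`alpha0 = -0.04`, `w_ability = 0.3`, `w_semantic = 0.8`,
`gamma0 = 1.2`, `w_reward = 0.45`, `fa_noise_sd = 0.5`,
`ts_noise_sd = 1.35`, n = 19 subjects) were calibrated once, by large-n
simulation, so that the population reproduces the group profile typical of
this paradigm — mean high-value recall near 8.6/12, low-value recall near
3.2/12, mean Selectivity Index near 0.6 — and so that the analytic imaging
surrogates attain population correlations of about 0.7 (bundle-FA surrogate
vs high-value recall) and 0.5 (tract-strength surrogate vs selectivity),
with the control tract exactly null by construction. These are qualitative
targets: correlations observed in any single 19-subject sample are sample
statistics with wide sampling error, and the simulator makes no claim to
reproduce specific published point estimates.

One property of this model is worth flagging because it is easy to get
backwards: increasing `w_reward` spreads the value-sensitivity slope
symmetrically across subjects, and since expected selectivity is *concave*
in the slope around the calibrated baseline, the cohort's **mean**
selectivity slightly decreases while its **variance** and its coupling to
the reward trait increase. The monotone facts are that expected selectivity
rises with `gamma0`, and the trait–selectivity correlation rises with
`w_reward`; the tests assert exactly these.

All randomness flows from one master seed through `child_seeds()`, so every
stage is reproducible in isolation and in composition.

## Diffusion phantoms

The phantom is a 24×24×24 grid of 2 mm isotropic voxels (geometry scales
with the grid; 16³ is used for fast tests). Coordinates are 0-based voxel
units with a diagonal RAS affine. Four bundles are laid out as tubes around
parametric paths:

* an anterior–posterior **corridor** (IFOF-like, radius 2.4 voxels);
* a **hook** (UF-like, radius 1.6) whose anterior limb runs *inside* the
  corridor — so the two smoothed atlas masks overlap, reproducing the
  threshold-sensitivity that motivates exclusive masking — and whose
  descending turn crosses the corridor's edge, creating genuine two-fiber
  voxels;
* a **control** bundle far from both, whose coherence never loads on any
  trait;
* a short **seed–target** bundle (radius 1.8) joining two compact spherical
  ROIs. The radius leaves one voxel of fiber-bearing buffer around the
  seed/target cross-section; with a tighter tube the walkable voxel set
  equals the seed footprint and streamlines die on the first lateral voxel
  crossing — a voxelization artifact, not connectivity.

Single-bundle voxels hold one pure axially-symmetric tensor
(λ∥ = 1.7×10⁻³ mm²/s; λ⊥ = λ∥(1 − coherence)), so noise-free tensor fits
recover ground truth exactly; crossing voxels hold an equal-fraction
two-tensor mixture; background diffuses isotropically at 0.8×10⁻³ mm²/s.
Subject traits map to physics via `phantom_params_from_traits()`: semantic
integrity raises the hook's coherence, reward sensitivity lowers the
seed–target bundle's angular dispersion (a tangent-plane Gaussian jitter of
the fiber axes — a small-angle model that grows coarse above ~1 rad but
remains monotone), and out-of-range values are clamped with a warning.

Signals follow the multi-tensor Stejskal–Tanner forward model on a
64-direction b = 1000 s/mm² shell (directions placed by electrostatic
repulsion of antipodal pairs) plus one b0. Noise is Rician — the magnitude
noise model of MR — with default SD S0/30; Rician rather than Gaussian both
for realism and because it stresses the fit's positivity handling. Atlas
probability maps are bundle indicators smoothed with a σ = 1 voxel Gaussian
(separable truncated kernel, replicate-padded edges).

The phantom intentionally omits realistic head geometry, susceptibility and
eddy artifacts, multi-shell schemes, and partial-volume anatomy. Passing
tests therefore demonstrate the *pipeline's* correctness and the
statistics' calibration, not robustness to real-data artifacts such as
motion, distortion or registration error.

## Tensor fitting and ROI statistics

`fit_tensor()` solves `ln S = ln S0 − b gᵀDg` by ordinary (unweighted)
linear least squares over the six tensor elements plus `ln S0` — the
classic default of standard tensor tools; a one-pass weighted variant
(weights S²) sits behind `wls = TRUE` since the field's tools differ in
their weighting default. Numerical guards: signals are floored at
1e-6 × max(signal) before the log (Rician noise produces near-zero
magnitudes); negative eigenvalues are clamped to zero for FA only, leaving
the raw tensor untouched so fit pathology stays visible; voxels whose mean
b0 falls below a floor are treated as background and assigned FA 0. A
rank-deficient design (fewer than six non-collinear directions) is an
error, not a warning.

Mask thresholding is inclusive (`prob >= threshold`, default 0.10) so
behavior at the conventional 10% boundary is deterministic;
`exclusive_mask()` is a literal set difference; `mean_fa()` on an empty
mask errors, signalling over-thresholding rather than silently producing
NaN.

## Probabilistic tractography

Full Bayesian posterior estimation of fiber orientations (the MCMC
machinery of standard crossing-fiber trackers) is replaced by a parametric
stand-in: each voxel holds up to two mean directions with a concentration
mapped from FA, `kappa = 30·FA/(1 − FA + 0.01)` capped at 1000, so coherent
voxels sample tight von Mises–Fisher distributions and near-isotropic
voxels sample almost uniformly. **This is a simplification**: the
downstream analysis consumes only the seed-normalized hit fraction, whose
semantics the stand-in preserves, but posterior dispersion estimated from
data would additionally reflect SNR and fitting uncertainty.

Sampling is axial (a direction and its negation are equivalent): a vMF
draw is folded to the previous step's hemisphere, the first step's sign is
random for a single sampled path, and `count_hits()` propagates every
sample in both directions from its start, as standard probabilistic
trackers do — without this, half the samples leave the seed away from the
target and the zero-dispersion strength limit of 1 is unreachable. Start
points are uniform continuous positions within each seed voxel (voxel
centers create lattice artifacts). Paths terminate on grid exit, max steps
(200), a turn sharper than 80° (cosine threshold 0.1736), or background
(concentration below 1e-3, emulating anisotropy-threshold stopping).
Defaults — step 0.5 voxel, 5000 samples per seed voxel — follow common
practice; the pipeline's `run_config()` default lowers samples to 500 to
keep a 19-subject end-to-end run at desk scale, and the tests use 50–500.
The tracker is compiled (Rcpp) and draws from R's RNG, so results are
bit-reproducible under `set.seed()`.

Tract strength is `hits / (samples_per_voxel × seed voxels)`; the target
ROI is jittered by up to one voxel per subject in `run_full()` so the
target-size covariate of the partial correlation is non-degenerate, echoing
the subject-to-subject variability of probabilistic anatomical targets.

## The correlation battery

All brain–behavior correlations are tested one-tailed for a *positive*
association, fixed a priori (more coherent pathway → better performance);
tract-strength tests are first-order partial correlations controlling
target-ROI size (df = n − 3). The FDR family is every correlation test in
the battery run — simple and partial together — adjusted by
Benjamini–Hochberg via `stats::p.adjust`; since the family's exact
boundaries are a judgment call, the family definition is part of
`battery_spec()` and is recorded in the report. Dependent-correlation
comparisons (each tract's high- vs low-value correlation; left vs right
hemisphere against the same behavior) use Steiger's Z1* with the pooled
Dunn–Clark covariance, are two-tailed, and are reported unadjusted, as is
conventional for such follow-up contrasts; Williams' t is available behind
a flag. The implied 3×3 correlation matrix must be positive semidefinite or
the comparison errors.

Two statistical facts observed while validating the battery are documented
here because they affect interpretation:

* With ~12 near-independent one-tailed tests, the null battery sits
  essentially *at* the Benjamini–Hochberg bound (false discovery rate ≈ q),
  so empirical-FDR checks must allow Monte-Carlo error around q rather
  than expect strict undershoot.
* When a battery contains several strong true effects, the step-up rule
  becomes lenient for the remaining tests: each null (control-tract) entry
  is rejected at a rate near q, so "the control tract is clean" is a
  per-entry statement, not a guarantee that no control entry in a battery
  ever crosses the threshold.

## Problem sizes and runtime choices

The test suite exercises: exhaustive subset enumeration on a 6-word list;
2×10⁴-draw Monte-Carlo for the chance-score property; 10⁵ replicates for
the Steiger type-I check (n = 19); 1000 null-cohort batteries for FDR
control; n = 500 cohorts against n = 50 000 population references for
parameter recovery (±0.08); 24³ phantoms with 500 samples/voxel for
tract-strength properties and 16³ phantoms elsewhere. These sizes were
chosen so each stochastic check has comfortable Monte-Carlo resolution
while the full suite stays in the minutes range on one CPU.

## Known limitations

* The recall model has no list-capacity constraint, no serial-position or
  output-order structure, and no across-list learning.
* The orientation model is not estimated from the diffusion signal's
  uncertainty; concentration is a deterministic function of FA.
* Partial correlations support a single covariate; multi-covariate
  adjustment is out of scope.
* The phantom's "hemispheres" are surrogate columns in the cohort table
  (left/right bundles sharing a trait), not spatially distinct structures.
* NIfTI I/O assumes the package's own diagonal RAS affine; arbitrary
  external affines are not resampled.
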