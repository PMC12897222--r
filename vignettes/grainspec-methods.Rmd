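---
title: "Detecting hidden kernel infestation from NIR hyperspectral images: methods and design"
author: "grainspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hidden kernel infestation from NIR hyperspectral images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainspec)
```

## The problem

Immature stages of stored-grain weevils (such as the rice weevil,
*Sitophilus oryzae*) develop hidden inside cereal kernels, where visual
inspection cannot find them. Near-infrared hyperspectral imaging offers a
nondestructive route: an infested kernel's internal changes in moisture,
starch and protein shift its reflectance in chemically informative regions
of the 850--1700 nm range, and a push-broom camera measures a full spectrum
at every pixel. `grainspec` implements the complete single-kernel analysis
chain for this setting:

1. **Hypercube handling** — ENVI raster input/output, black-and-white
   reflectance correction, kernel segmentation, per-kernel mean spectra.
2. **Spectral preprocessing** — Savitzky–Golay smoothing and derivatives,
   multiplicative scatter correction (MSC), standard normal variate (SNV),
   detrending, asymmetric least-squares baseline correction.
3. **PLS-driven wavelength selection** — CARS, SPA, UVE and IRIV, plus
   SPA-chained combinations (CARS–SPA, UVE–SPA, IRIV–SPA).
4. **Classification and evaluation** — Kennard–Stone partitioning, four
   classifier families, confusion-matrix metrics including Cohen's kappa.
5. **A synthetic-data generator** that emulates the statistical structure
   of single-kernel NIR data, so every stage is testable end to end
   without proprietary instrument data.

## Reflectance correction and spectrum extraction

Raw counts are converted to reflectance pixelwise with white/dark
references, `I = (I0 - B) / (W - B)`. The denominator is floored at
`1e-6` of the white cube's dynamic range; affected pixels are counted and
reported. Reflectance is not clipped by default (an optional flag clamps
to [0, 1.2]), since clipping discards information that preprocessing can
still use.

Kernels are segmented from the band-mean image by Otsu's threshold,
followed by 4-connected component labelling; components below a minimum
area are dropped, and survivors are renumbered row-major by centroid so
labels are deterministic. Touching kernels are *not* split — the workflow
assumes kernels are placed with spacing on the imaging plate, which is
how single-kernel studies are imaged. The per-kernel spectrum is the
arithmetic mean over the kernel's pixels at every band.

Band indices are 1-based everywhere, the native convention of R's matrix
and array APIs; wavelengths are reported in nm to one decimal.

## Preprocessing

All seven transforms operate row-wise on a spectra matrix:

| method | parameters (default) | what it removes |
|---|---|---|
| `sg` | window 11, polyorder 2 | high-frequency noise |
| `sg_fd`, `sg_sd` | window 11, polyorder 2 | baseline (1st), slope (2nd), per nm |
| `msc` | reference = training column mean | per-sample gain and offset |
| `snv` | — | per-sample gain and offset |
| `detrend` | polyorder 2 | smooth polynomial baseline |
| `baseline` | lambda 1e5, p 0.01, 10 iterations | slowly varying baseline |

The Savitzky–Golay window and order are not dictated by any instrument
convention; window 11 / order 2 are common NIR practice and both are
configurable and serialized with results. Edge points use truncated
one-sided least-squares windows rather than reflection padding, so exact
polynomial reproduction holds at interior points only. Derivatives are
scaled by the mean grid step (per nm); a non-uniform grid triggers a
warning.

MSC fits each spectrum to a reference by ordinary least squares and
inverts the fitted affine map. The reference is computed on the
*training* rows only and frozen for test-set transformation — the
pipeline never lets test rows influence preprocessing statistics.
Standard deviations are sample standard deviations (denominator n−1)
throughout.

Baseline correction is asymmetric least squares (penalized second
differences with asymmetric weights): the method label "baseline
correction" underdetermines the algorithm, and AsLS is the standard
modern choice; a linear endpoint-to-endpoint baseline is available behind
a flag. One property worth stating precisely: the asymmetry weight `p`
pushes the baseline under the noise cloud, but an O(10%) fraction of
points still falls marginally below the smooth curve at the fixed point —
`p` is a weight, not a quantile. The tests assert the directional
property (far more points above the baseline than with symmetric
weights, overshoot below the noise scale) rather than a literal
`1 - p` coverage.

## The PLS engine

All four selectors are driven by a PLS1 regression of the class code
(healthy = 0, infested = 1) on the spectra. The implementation is NIPALS
on column-centered data; with a single response the weight vector per
component is the normalized covariance `X'y`, so no inner iteration is
needed. Coefficients are returned on the original variable scale with an
explicit intercept. Model selection uses RMSECV: out-of-fold residuals
are pooled over all folds into a single RMSE per component count (not a
mean of per-fold RMSEs). Folds are stratified by class and dealt
round-robin after a seeded shuffle, so a `(N, n_folds, seed)` triple
fully determines the assignment. The caps of 8 latent variables (CARS)
and 40 (IRIV) are upper bounds; the component count actually used is the
RMSECV minimizer under the cap.

## Wavelength selection

**CARS** runs 50 Monte-Carlo iterations. Each iteration fits a PLS model
on a random 80% of the samples, weights every surviving band by its
normalized absolute coefficient, enforces the exponentially decreasing
retention schedule `r_i = a·exp(-k·i)` calibrated so `r_1 = 1` and
`r_N = 2/B` (enforced count `⌈B·r_i⌉`), and then applies adaptive
reweighted sampling: weighted draws with replacement (5× the enforced
count), unique survivors, truncated to the enforced count by descending
weight. Each iteration's surviving set is scored by 10-fold RMSECV on the
full calibration set, and the best-scoring set over all iterations wins.
The per-iteration minimum (rather than a post-hoc refit) is the selection
rule; ties go to the earliest iteration.

**SPA** builds, from every candidate start column, a forward chain that
repeatedly picks the band with the largest norm orthogonal to the span of
the chain so far (ties to the lowest band index, within a 1e-9 relative
tolerance). Every (start, length) candidate with length in `n_min..n_max`
(default 5..min(30, N−2)) is scored by PLS RMSECV — consistent with the
RMSECV stopping rule the method family uses — and the global minimizer is
returned; an MLR-CV scorer is available behind a flag.

**UVE** augments the spectra with B artificial uniform-noise columns
scaled to 1e-10 of the data magnitude, refits the PLS coefficient vector
once per deletion group (default: the 10 CV folds; leave-one-out via
`n_folds = N`), and scores each variable's stability `c = mean(b)/sd(b)`
across refits. The cutoff is the 0.99 quantile of `|c|` over the noise
columns; real bands above it survive. A caveat the synthetic experiments
expose: when per-sample scatter (gain/offset/baseline) correlates all
real bands, their coefficients are systematically more stable than those
of independent noise columns, and UVE retains a substantial fraction of
non-informative bands (tens of percent) — the same order as published
UVE band counts on real kernel spectra. With uncorrelated bands the
retention of uninformative variables drops to the ~1% the threshold
implies.

**IRIV** iterates on the current variable set: draw a 500-row binary
inclusion matrix (inclusion probability 0.5), compute each row's RMSECV
(11-fold), and classify every variable by comparing the RMSECV
distributions of rows excluding vs including it — difference of means
DMEAN and a Wilcoxon rank-sum p-value at alpha 0.05. Variables with
DMEAN > 0 (strongly or weakly informative) are retained; iterations stop
when nothing is dropped, and a final backward elimination removes any
variable whose removal lowers RMSECV. Row count, test and alpha are not
fixed by convention anywhere; 500/rank-sum/0.05 are recorded in every
result.

Chained selection (`cars_spa`, `uve_spa`, `iriv_spa`) runs SPA on the
column subset retained by the first stage and maps indices back to the
original grid; the chained output is a subset of the first stage by
construction.

All selectors are deterministic given `(X, y, params, seed)`; re-running
bit-reproduces the `selection_result`, which carries the selected
indices, wavelengths, a per-iteration trace, the seed and the frozen
parameters.

## Splitting, classifiers, evaluation

Kennard–Stone splits 70/30 by maximin Euclidean distance with
lowest-index tie-breaks, giving 412/177 on the default 589-kernel design.
The split is computed on the raw spectra so that preprocessing statistics
can be fitted on training rows only (the split is label-free, so this
ordering is the leakage-safe one).

The four classifiers use fixed, published-style hyperparameters: an
RBF-kernel SVM with cost 2.5 and automatic kernel scale, a Gini decision
tree capped at 20 splits (grown deep, then pruned to the largest subtree
within the cap), KNN with Minkowski p = 2 distance and equal weights and
K tuned over {3, 5, 7, 9, 11, 15, 20}, and a 200-tree random forest with
minimum leaf size 5. The automatic kernel scale is the median pairwise
distance heuristic (`gamma = 1/(2·median²)` on a deterministic subsample);
a fixed `gamma = 1/B` makes the RBF kernel nearly constant on
small-amplitude reflectance data and degenerates to the majority class.
SVM cost and KNN K are tuned by seeded 5-fold grid search on the training
set; K is chosen by maximum CV accuracy with Cohen's kappa as the first
tie-break and the smaller K as the second (one concrete reading of
"jointly considering accuracy and kappa").

Evaluation treats infested as the positive class: accuracy, precision,
recall, F1 (positive class) and Cohen's kappa
`(p_o − p_e)/(1 − p_e)` with expected agreement from the confusion
marginals.

## The synthetic generator

Each spectrum is built as

```
x = gain · (base + label · effect + baseline) + offset + noise
```

* `base` — a smooth wheat-like reflectance profile: a gentle upward slope
  with Gaussian absorption dips near the water features (970 and 1450 nm)
  and a C–H feature (1200 nm).
* `effect` — raised-cosine bumps (smooth, band-limited, mimicking NIR
  absorption features rather than boxcars) inside the discriminative
  windows 980--1100, 1200--1300 and 1400--1600 nm, amplitude 0.02
  reflectance units by default. Only infested samples (`label = 1`)
  receive it.
* scatter — lognormal gain (sdlog 0.05) and additive offset (sd 0.01),
  the multiplicative/additive distortion MSC and SNV are designed to
  remove.
* `baseline` — a random degree-2 polynomial (coefficient sds 0.01) that
  exercises detrending and baseline correction.
* `noise` — white noise, sd 0.005 reflectance units, a realistic
  single-kernel noise floor for line-scan NIR instruments.

Defaults mirror the target study design: 256 bands over 850--1700 nm and
220 healthy vs 369 infested kernels, so the Kennard–Stone 412/177 split
is exercised at the study's scale. The ground-truth object records
labels, per-sample gain/offset, the noiseless class means and the set of
informative bands (bands with nonzero class-mean difference), which gives
every selector an unambiguous recovery score.

The cube generator plants per-kernel spectra into disjoint ellipses on a
dark plate, converts reflectance to counts with known white/dark levels
and optional pixel noise, and returns the matching reference cubes, the
true mask and the true spectra — so correction → segmentation →
extraction can be validated exactly (to 1e-10 without noise, to the
`3·σ/√n_pixels` averaging bound with noise).

What the generator does *not* emulate: instrument-specific stray light,
wavelength-dependent noise, kernel orientation and shading effects, or
developmental-stage spectral signatures (stages are represented only by
the effect amplitude, with larger amplitudes reproducing the qualitative
finding that later stages separate more easily). Passing tests therefore
demonstrate algorithmic correctness and the expected statistical
behaviour under this model, not instrument-level performance on real
kernels.

### Problem sizes in the test-suite experiments

Recovery experiments use 10 seeds each: CARS and UVE on the full
589 × 256 design with ten single-band planted windows; IRIV on a
30-band, 200-sample balanced design with five planted bands (IRIV's
binary-matrix resampling is the most expensive selector, and 30 bands is
where its per-variable statistics are well resolved). The null-amplitude
check uses balanced 150/150 classes, since chance level is 50% only for
balanced designs. The amplitude-monotonicity check uses amplitudes
0.002/0.006/0.02, spanning sub-noise to well-separated regimes.

## Known limitations

* Touching kernels are not split; a watershed stage would be needed for
  clustered layouts.
* UVE's noise-threshold calibration assumes uninformative variables
  behave like independent noise; under strong inter-band correlation it
  over-retains (see above), and the chained UVE–SPA stage is the
  practical remedy.
* `class::knn` offers Euclidean distance only (Minkowski p = 2); other
  Minkowski exponents are not available.
* PLS is single-response (class-code regression); multi-response PLS and
  posterior-based PLS-DA decisions are out of scope.
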