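---
title: "Steric pocket descriptors and nonlinear selectivity modeling"
author: "stericsel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steric pocket descriptors and nonlinear selectivity modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stericsel)
```

## Scope and model

`stericsel` supports a common workflow in asymmetric-catalysis
informatics: quantify the steric environment of the axial reactive
pockets of paddlewheel dirhodium catalysts (and the shapes of substrates
and products) from conformer ensembles, convert screened diastereomeric
ratios into activation free-energy differences, and regress the two
against each other with a sparse nonlinear model whose terms are
algebraic combinations of the physical descriptors. The fitted model is
then deconvoluted with chemical-space maps, clustering and regression
trees to expose which descriptor regimes produce selective catalysis.

Three modeling layers are involved, each with its own assumptions.

### 1. Ensemble-weighted steric descriptors

A catalyst is represented as a `ConformerEnsemble`: conformers sharing
atom order, each with an energy in kcal/mol. Per-conformer descriptors
are aggregated with Boltzmann weights
$w_i \propto \exp(-E_i/RT)$ at the ensemble temperature (default
298.15 K, $R = 1.98720425\times10^{-3}$ kcal mol⁻¹ K⁻¹). Weighting
assumes the supplied energies rank conformers correctly (electronic
energies and free energies give different weights; the package uses
whatever energies the file carries, and the choice should be stated
when reporting results). Aggregates are MIN, MAX, the weighted mean,
and the weighted *population* standard deviation
$\sigma = \sqrt{\sum_i w_i (v_i - \bar v)^2}$; MIN/MAX ignore weights
except that zero-weight conformers are excluded, because extreme
conformers matter for accessibility arguments even when rarely
populated.

The pocket descriptors live in a `PocketFrame`: the binding Rh with a
unit axis pointing away from the second Rh into the axial pocket. For a
`CavitySpec` with probe offset $d$ (default 2.0 Å, a typical
metal–substrate approach distance), probe radius $R$ (4.0 Å), proximal
cutoff $p$ (2.0 Å) and grid spacing $h$ (0.2 Å):

* **V_CAVITY** — volume of the probe sphere centered at
  $\mathbf{c} + d\,\hat{\mathbf{a}}$ not occupied by any atom's van der
  Waals sphere. Estimated as the analytic sphere volume times the
  open-voxel fraction, which makes the unobstructed case exact, cancels
  the sphere-boundary discretization error, and guarantees
  proxV + distV = V exactly. The proximal part collects voxels whose
  axial distance from the binding Rh is at most $p$;
  **distV_CAVITY %** is the distal percentage of the cavity.
* **ESA / proxESA** — open area of the disc of radius $R$ perpendicular
  to the axis at axial distance $d$ (entry window) or $p$ (proximal
  window), after removing the cross-sections of atom spheres cutting
  that plane. The window is a flat disc rather than a spherical cap: the
  flat form has simple analytic test cases and the two differ only by a
  smooth monotone factor at fixed spec. Percentage forms divide by the
  unobstructed window $\pi R^2$, so catalysts of different sizes are
  comparable.
* Per-conformer, per-site values are reduced across the two axial sites
  first (min for the MIN aggregate, max for MAX, the across-site mean
  for MEAN and SIGMA), then the Boltzmann statistic is taken. Metal
  atoms themselves count as occluders — they are real matter.

Absolute values are meaningful only at a fixed `CavitySpec`; the spec
is therefore part of every reported row.

Shadow descriptors use a deterministic Fibonacci sphere (default 20 000
directions, reproducible without a seed): **G%** is the percentage of
directions from the center atom whose ray hits another atom's van der
Waals sphere, and **G% surface** re-expresses openness as an absolute
area, $(1 - G\%/100)\,4\pi R_s^2$, on the sphere that encompasses the
whole conformer ($R_s = \max_i(\lVert\mathbf{r}_i-\mathbf{c}\rVert +
r_i^{vdW})$). Its ensemble sigma, **G% surface σ**, is a flexibility
proxy: it is zero for a rigid catalyst and grows when conformers differ
in how much reactive space they leave open. All non-center atoms shield
by default; an exclusion list is available when a scaffold should not
count.

**Sterimol** L/B1/B5 follow the convention: L is measured from the
attachment atom's center along the attachment axis including the far
atom's radius, with no legacy +0.40 Å correction; B5 is the largest
perpendicular extent; B1 is the minimum over in-plane directions of the
maximum signed half-width, found by a dense angular scan (0.2°
steps — the scan, not an analytic minimum, because atom unions make the
width function piecewise smooth). **Sphericity**
$\Psi = \pi^{1/3}(6V)^{2/3}/A$ uses the van der Waals union: $V$ by
voxel counting (default 0.1 Å) and $A$ by sampling each sphere's
surface with deterministic Fibonacci points and counting the exposed
fraction. Surface sampling is used instead of voxel-face counting
because face counting systematically overestimates curved areas (a
sphere's voxel surface is ~50% too large at any resolution), while
per-sphere exposed-fraction sampling converges to the true union area.

### 2. Reaction thermodynamics

Diastereomeric ratios convert through transition-state arithmetic,
$\Delta\Delta G^\ddagger = -RT\,\ln(\mathrm{syn}/\mathrm{anti})$, with
the convention that syn-major ratios are negative. The reaction
temperature matters (|ΔΔG‡| grows with T at fixed ratio), so strict
mode refuses tables without a temperature column; the default fills in
298.15 K. Fully selective ratios (`syn = 0` or `anti = 0`) are bounds,
not measurements: they become signed infinities flagged `censored` and
are excluded from regression by default. Electronic descriptors such as
carbene NBO charges or NMR shifts are *ingested* from external quantum
chemistry — the package never computes electronic structure — and
carry a provenance tag so tables remain auditable.

### 3. Sparse nonlinear regression

`fitSisso()` implements screening-plus-exhaustive-search regression in
the SISSO family. Base descriptors are z-scored (their units are
incomparable: Å³ next to elementary charges), then expanded rung by
rung with the operator set $\{+, -, \times, \div, x^2, x^{-1},
\sqrt{x}, |x|\}$; a feature's rung is its operator nesting depth.
Exponentials and logarithms are deliberately excluded by default — the
expansion is purely algebraic. Deduplication is by canonical string
(commutative operands sorted) plus exact-collinearity hashing at any
pool size; the full $|r| > 0.9999$ near-duplicate sweep runs when the
pool is small enough for a quadratic pass (≤ 3000 columns) and is
otherwise applied within the screened pools where the exhaustive search
operates.

Operator domains are guarded. Beyond the obvious rules (no square roots
of negatives, no division by zero), **division and inverse require a
one-signed denominator column**. The reciprocal of a quantity that
crosses zero is unbounded and discontinuous, so on z-scored descriptors
— which all cross zero — such features are leverage artifacts: they can
look informative on the training rows while exploding on new data. With
the guard, reciprocal features are formed of intrinsically one-signed
quantities (squares, absolute values, and their combinations), which is
also the physically interpretable case.

Model search proceeds in rounds: round $i$ ranks all features by
absolute Pearson correlation with the residual of the best
$(i-1)$-term model (ties: lower complexity, then lexicographic string)
and adds the top $k$ (default 50) to a candidate union; the best
$d$-term model is then found by *exhaustive* ordinary least squares
over all $d$-subsets of the union (Gram-matrix form, vectorized
closed-form solves for $d \le 3$), best by training RMSE. The search is
fully deterministic — rerunning a fit yields byte-identical model JSON.
The exhaustive stage is capped at $5\times10^6$ subsets and fails
loudly rather than silently switching to a heuristic. Coefficients are
reported on the feature scale with the scaling records stored in the
model, so prediction on raw descriptor values is exact.

No dimensional bookkeeping is enforced: descriptor products across
units (a shape index times a charge) are intentionally allowed, because
cross-component interaction terms are the point of the exercise.

## Validation utilities

* **Response-equidistant split** — training points are picked nearest
  to equally spaced response targets spanning the observed range
  (ties: smaller response, then smaller index), so training always
  contains the extremes and the model never extrapolates on its own
  test set. Note the flip side: the held-out rows concentrate in the
  interior of the response range, which *lowers* attainable test R² —
  a property worth remembering when comparing split strategies.
* **Kennard–Stone split** — classic maximin coverage design on z-scored
  features; deterministic, ties to the smaller index.
* **Q²** — leave-one-out PRESS over a *fixed* feature set
  ($Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$). Re-running feature
  selection inside each fold is statistically stricter but expensive;
  the fixed-set convention matches how these statistics are usually
  reported alongside multivariate linear models in this literature.
* **Fivefold R²** — one seeded shuffle, out-of-fold predictions pooled,
  $1 - \mathrm{SSE}/\mathrm{SST}$; at $k = n$ it reproduces Q².
* **External validation** — squared Pearson correlation between
  predicted and observed (the convention of external-validation plots),
  with the $1-\mathrm{SSE}/\mathrm{SST}$ alternative reported
  alongside as `r2_test_alt`.

## Chemical-space deconvolution

`pcaMap()` is PCA on z-scored columns with a deterministic sign
convention (the dominant element of each loading is positive).
`kmeansCluster()` is Lloyd's algorithm, best of 10 seeded starts by
inertia, with an explicit empty-cluster rule (re-seed at the farthest
point); it is hand-rolled because the reference implementation errors
out on empty clusters instead of recovering, and tests cross-check its
inertia against `stats::kmeans` on separable data. Cluster labels are
1-based, the R convention. Per-cluster response ranges reproduce the
min–max annotations used on selectivity maps. `regressionTree()` is
CART with the variance-reduction criterion, midpoint thresholds, and
deterministic tie-breaking (first column, then smaller threshold); a
classification mode thresholds the response at a selectivity cutoff
first. By default K-means runs on the full set of (scaled) model
parameters rather than on the first two PCs; both modes are available,
and the 2-PC map is for visualization.

## The synthetic generators, and what the tests do and do not show

No experimental dataset ships with the package, so two generators make
every module testable end to end.

`makeToyCatalyst()` emulates the geometry that matters for the pocket
code: a Rh–Rh core at ±1.2 Å with four bulky arms whose tilt
(`cone_angle`) moves them over the axial pocket, whose wobble generates
conformer diversity, and whose energies grow with angular deviation.
It produces structures whose descriptor responses are monotone by
construction (equatorial arms leave the entry window more open than
crown-like arms; zero wobble gives zero ensemble sigma), which is what
the property tests exercise. It makes no attempt to reproduce real
dirhodium bond lengths, ligand chemistry, or DFT energetics.

`makePlantedBenchmark()` emulates the statistics of a combinatorial
screening campaign: 18 catalysts × 5 substrates minus 4 withheld rows =
86 reactions; 4 catalyst-role and 3 substrate-role descriptors, i.i.d.
standard normal per entity and exactly standardized across the final
rows (an affine per-column adjustment, so each catalyst still carries a
single value per descriptor); response = one linear catalyst term plus
two catalyst × substrate products plus Gaussian noise. Coefficients are
set so 95% of the response variance is systematic with the linear term
carrying 35% and each interaction 30%. Products of independent
standard normals are uncorrelated with the linear columns, so the best
purely linear model can explain only about the linear share — this is
the analytic mechanism behind the linear-vs-nonlinear performance gap
the benchmark exhibits, and it is a *favourable* setting for screening:
real descriptor sets are correlated, have heavier tails, and their true
response surface is not exactly expressible at rung 2. Passing the
benchmark therefore shows the machinery is correct and well-behaved,
not that comparable statistics will be reached on any experimental
dataset.

One property of the response-equidistant split deserves emphasis
because it shapes the held-out numbers: with the extremes banked into
training, the test rows cluster in the interior, and their response
variance is a small fraction of the training variance on this
benchmark.
Held-out R² is therefore structurally lower than training R² even for
the *true* generating model refit by least squares, independent of any
overfitting. The replicated study (`plantedBenchmarkStudy()`) reports
exactly what it computes — per-seed training R², leave-one-out Q²,
held-out R² and the linear baseline — and the acceptance script prints
their medians.

## Numerical choices

* Grids are expressed in the pocket frame; volumes/areas are analytic
  references times open fractions (exact in the unobstructed limit).
* Boltzmann weighting shifts energies by their minimum before
  exponentiation (shift-invariant, overflow-safe).
* Singular leave-one-out designs fall back to the Moore–Penrose
  pseudoinverse with a message; singular candidate subsets in the
  exhaustive search are skipped via a determinant guard.
* Near-singular subset fits are rejected when their explained sum of
  squares exceeds the total (a numerical impossibility).
* A constant response yields a 0-term model with R² defined as 0.
* All stochastic steps (fold shuffles, K-means starts, generators) take
  explicit integer seeds and restore the caller's RNG state.

Problem sizes used by the shipped tests were chosen to keep the suite
fast while leaving the estimators in their asymptotic regime: 20
benchmark replicates for the study medians, 10⁶ Monte-Carlo samples for
the cavity oracle, 20 000 shadow directions, grid spacings of
0.05–0.25 Å depending on the tolerance under test.

## Known limitations

* The cavity probe is user-placed; there is no flood-fill pocket
  detection, and descriptor values are comparable only at a fixed spec.
* ESA uses a flat measurement window (documented dialect), not a
  spherical cap.
* G% treats all non-center atoms as shielding unless excluded; no
  automatic ligand/scaffold perception.
* No conformer generation, geometry optimization, or electronic
  structure: ensembles and electronic descriptors are inputs.
* The expansion implements the canonical screening-plus-exhaustive
  search dialect described above; published "modified" variants differ
  in unstated details, so coefficients and selected features should be
  compared across implementations only at matched configuration.
* No L1/compressed-sensing selection, no symbolic simplification beyond
  commutative canonicalization, no bootstrap confidence intervals.
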