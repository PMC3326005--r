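---
title: "Methods: twin modeling of white matter development with verifiable synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin modeling of white matter development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinfiber)
```

`twinfiber` re-implements a longitudinal twin imaging analysis — diffusion
tensor metrics, FACT tractography with group average fibers,
deformation-based morphometry, and twin variance-component models — with a
synthetic-data module supplying ground truth for every stage. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, what the synthetic data do and do not emulate, and the
design decisions taken where the procedure left room.

## The twin variance-component model

The classical twin design decomposes a trait's variance into additive
genetic (A), common-environment (C) and unique-environment (E) parts.
Monozygotic (MZ) co-twins share essentially all segregating genes, dizygotic
(DZ) co-twins half on average, so the implied covariance of the stacked
(twin 1, twin 2) trait vector is

- diagonal blocks `A + C + E`,
- cross-twin blocks `A + C` (MZ) and `0.5 A + C` (DZ).

Heritability is h² = A/(A + C + E) per trait; for two traits, the genetic
and unique-environment correlations r_g and r_e are the correlations of the
A and E matrices. Key assumptions inherited from the design: equal
environments across zygosities, random mating, and no dominance (no ADE
variant is provided).

`fit_model()` maximizes the full-information likelihood: each family
contributes the multivariate-normal density of its *observed* values, so an
incomplete pair enters through the observed co-twin's marginal rather than
being dropped. Families are grouped by zygosity and missingness pattern and
each group is evaluated with a single Cholesky factorization, which is what
makes 10,000-family fits take seconds. Sex and handedness enter as fixed
effects on the means (reference: female, right-handed). A and E (and C for
ACE) are parameterized by their Cholesky factors, so estimates are positive
semidefinite by construction and standardized quantities stay in range; the
price is a sign-unidentified factor, which is harmless because only A = LLᵀ
is interpreted. A singular implied covariance returns a large finite
penalty rather than an error so the simplex search can back away from the
boundary.

Optimization runs Nelder-Mead (up to 2000 iterations, relative tolerance
1e-10) followed by a BFGS polish, from a moment-based start (observed
variance split evenly across components) plus jittered restarts
(`n_starts`, default 5; jitter is seed-controlled and the RNG state is
restored). AIC = −2lnL + 2·(free parameters).

### Profile-likelihood confidence intervals

Bounds are the points where the profiled −2lnL rises `delta` above its
minimum, found by root bisection with all nuisance parameters re-optimized
at every evaluation. The default `delta = 2.71` is the χ²₁ 90th percentile —
the convention used by twin-modeling software for variance components,
where the boundary at zero makes the one-sided 95% and two-sided 90%
interval coincide; `delta = 3.84` is available for the strict two-sided 95%
reading, since published tables label such intervals "95%" while stating
the 2.71 rule. Profiling of standardized quantities uses dedicated
reparameterizations: univariate fits profile a² with total variance and
means free; bivariate AE fits re-express the model as per-trait total
standard deviations and a² proportions plus r_g and r_e (same dimension as
the Cholesky form), so any of those four can be held fixed. Bounds are
clipped to [0, 1] (or [−1, 1] for correlations) and flagged when the
profile never crosses, which is the expected outcome at a boundary
estimate.

A calibration property checked by the test suite: over 500 simulated
cohorts of 150 + 150 pairs with a² = 0.5, the event "profiled −2lnL at the
true value ≤ minimum + 2.71" — precisely the event that the CI contains the
truth — occurs ≈ 90% of the time.

### Model comparison and descriptive correlations

`compare_models()` gives the likelihood-ratio χ² (re-fitting the full model
with extra starts if the nested model paradoxically wins) and the AIC
difference; under simulation with c² = 0 the AE model is preferred by AIC
in well over 80% of replicates, matching the practice of dropping C when
neither criterion supports it. `twin_correlations()` reports double-entry
Pearson correlations per zygosity (each pair entered in both orders),
cross-twin cross-trait matrices, and Falconer's 2(rMZ − rDZ) for
orientation.

## The synthetic twin cohort

`generate_twin_cohort()` draws one vector per family from the implied
2-twin × n-trait covariance via an eigenvalue-based PSD factor (exact even
for singular models such as a² = 1). Choices fixed once:

- Total variance per trait is 1 — the generator takes variance
  *proportions* (a² + c² + e² = 1 to 1e-12), so `trait_means` shifts
  location only and all effect sizes are in SD units.
- Sex is assigned per pair (co-twins share sex in the emulated sample
  design); handedness per individual with P(right) = 0.84, the rate typical
  of a childhood cohort. Mean offsets are added for males and
  non-right-handers.
- Incomplete pairs arise by independent Bernoulli thinning
  (`incomplete_fraction`), blanking one random co-twin's traits while
  keeping the row — emulating longitudinal drop-out and exercising the FIML
  path.

What it deliberately does **not** emulate: non-normal trait distributions,
age/scanner covariates, assortative mating, dominance, sibling interaction,
or more than two children per family. Passing parameter-recovery tests
therefore show the estimator is correct under the model's own assumptions,
not that real data meet them.

## The diffusion phantom and tensor fitting

`generate_dwi_phantom()` builds a bundle of prolate tensors (default
eigenvalues (1.6, 0.5, 0.5)·10⁻³ mm²/s, white-matter-like) following a
straight, arc or helix center line inside an isotropic background
(0.7·10⁻³ mm²/s), on a 2.5-mm grid, imaged with 32 spherical-Fibonacci
directions at b = 1000 s/mm² plus 8 b0 volumes. The noise-free signal is
exactly `S = s0 exp(−b gᵀDg)`; log-signal is therefore exactly linear in
the six tensor components, which pins the no-noise recovery tests at
machine precision. The white-matter fraction is 1 inside the bundle radius
with a 1-voxel linear falloff (switchable to a hard edge), so the ≥ 90%
pure-WM mask rule has partial-volume voxels to reject; partial-volume
signal is the fraction-weighted mix of bundle and background signals.
Rician noise is the magnitude of a complex Gaussian — the standard MR
magnitude model — and visibly biases the b0 mean upward, shrinking as σ
does. Not emulated: crossing fibers, eddy-current/susceptibility artifacts,
motion.

`fit_tensor()` solves `log S = log S0 − b gᵀDg` per voxel: an OLS pass, one
reweighting with weights equal to the squared predicted signal (the
standard WLS linearization), and for `method = "robust"` an IRLS loop with
Geman–McClure weights `1/(1 + (r/s)²)²` on log-residuals, scale `s` set to
the MAD each iteration, at most 50 iterations, stopping when the largest
weight change is below 1e-6. The underlying study cites a robust
M-estimator without parameters; this is a documented standard choice in its
spirit, and the tests require only its qualitative property (strictly
smaller error than OLS under an injected outlier, agreement to 1e-8 without
noise). Negative eigenvalues are clamped to zero for FA/RD only, the raw
tensor is kept and the voxel flagged; an all-zero tensor yields an
undefined-flagged FA, never a silent 0.

## FACT tractography

Tracking is the canonical voxel-hopping FACT: advance from the current
point to the exit of the current voxel along that voxel's principal
eigenvector, then adopt the next voxel's eigenvector, sign-aligned with the
incoming direction (the eigenvector sign is otherwise arbitrary).
Termination: leaving the grid, FA below 0.1, or a turn exceeding 45°
(inclusive continuation *at* 45°, since the rule names a maximal angle).
Both directions from the seed are tracked and concatenated. Eight seeds per
voxel sit at ±0.25-voxel offsets from the center — corners of a cube half
the voxel size, forming a regular grid across neighboring voxels. Scalar
superimposition samples by containing voxel (nearest-neighbor), matching
the voxel-wise logic; minimum streamline length is 2 points. These step
details are not specified by the named algorithm's users beyond the
parameter values, so they are fixed here and covered by determinism,
reversal-symmetry and threshold-monotonicity tests.

## Average fibers and projection

Along-tract averaging anchors node 0 at the mean of per-streamline
arc-length midpoints, and node n at the mean of points at signed arc
distance 2n mm from each streamline's own midpoint — arc length, not
Euclidean distance, as the only reading that keeps nodes ordered on curved
bundles. Streamlines are pre-resampled at 0.5-mm arc steps to bound the
discretization of that rule, and oriented by flipping any streamline whose
end-to-end vector opposes the bundle's dominant direction (leading
eigenvector of the midpoint-to-endpoint scatter, sign fixed
deterministically). Node coordinates are smoothed by a 5-node moving
average whose window shrinks symmetrically at the ends (endpoints stay
fixed, straight fibers are exactly invariant), then re-spaced at 2-mm arc
steps keeping node 0 fixed.

Group averaging matches nodes by signed index after the same orientation
alignment, and trims end nodes to which strictly less than 25% of the
sample contributes — the boundary case (exactly 25%) is retained, and node
0 never trimmed. Projection assigns each individual node to its nearest
group node; the distance summary is the mean (switchable to max) of those
distances, and a summary above 10 mm marks the measurement unreliable, a
result state that withholds scalar summaries rather than an error.
Per-subject bundle means weight nodes equally. Bundle masks flag every
voxel a fiber segment passes through (dense sub-voxel sampling at a quarter
voxel); the group-weighted Jacobian average weights a subject's mask voxels
by the group count map.

## Morphometry

`jacobian_determinant()` uses central differences in mm (one-sided at
borders) on the displacement field and evaluates det(I + ∂u/∂x) in closed
form; against warps with analytic determinants the error is second order in
the voxel size, and exactly zero for affine warps. The voxelwise test is a
one-sample two-sided t of |J| − 1 against 0 — the literal reading of
"expansion or contraction, |J| ≠ 1" — with a log-|J| variant behind a flag;
zero-variance voxels are flagged degenerate with p forced to 0 or 1 by the
mean. FDR control is Benjamini–Hochberg at q = 0.05 via `p.adjust`,
returning the step-up threshold and mask. The analysis grid default is
2 × 2 × 2.4 mm. Registration itself is out of scope: deformation fields are
inputs, and the synthetic warps (identity, uniform scale, shear, radial
Gaussian bump, composites) exist to make the Jacobian stage verifiable.

## Cohort statistics, masks and histograms

`relative_change()` is 100·(x12 − x9)/x9. Group change is reported as the
change of group means (matching how printed cohort tables are laid out)
alongside the mean of individual changes — published tables do not say
which was used, so both are exported. Paired t-tests keep per-child degrees
of freedom; the family adjustment — using the number of families instead of
the number of children — applies to correlation p-values (df = families −
2) as in the emulated analysis, with a family-adjusted paired-t variant
behind a flag. The pure-WM mask keeps voxels with fraction ≥ 0.90
(inclusive). Extreme-growth groups use strict mean ± 1 SD cutoffs with the
n−1 standard deviation. FA histograms pool voxels across subjects within
group (per-subject averaging available), with 64 equal bins on [0, 1] and a
low-FA tail mass below 0.25 — bin settings are unspecified in the emulated
figures, so these defaults are explicit parameters.

## Problem sizes and runtime

The test suite and analysis drivers choose sizes that keep every stage's
statistical claim sharp while running on a single CPU in minutes:
parameter-recovery fits use 5000 + 5000 pairs (sampling error on h² well
under the ±2-point tolerance), the CI-coverage and AIC-preference
simulations use 500 and 200 replicates of 150–300-family cohorts, the BH
null control 200 replicates of 1000 voxels, and phantoms are 10–30 voxels
per side. Larger volumes change nothing structurally: all grid code is
shape-agnostic.

## Known limitations

- No dominance or sex-limitation models; at most two siblings per family.
- Profiling supports univariate a²/c² and bivariate-AE a², r_g, r_e; other
  targets would need further reparameterizations.
- FACT is deterministic single-tensor tracking; crossing-fiber geometry is
  outside the phantom family, so tractography tests certify the algorithm,
  not its behavior in crossing regions.
- The anatomical ROI definitions of the 14 human tracts are not shipped;
  ROI recipes exist for phantom geometries only.
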