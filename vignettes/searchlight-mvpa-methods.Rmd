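---
title: "Methods: searchlight decoding, pattern dissimilarity and permutation inference"
author: "SearchlightMVPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: searchlight decoding, pattern dissimilarity and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the data model, each analysis stage with its assumptions and
tunable parameters, what the synthetic-cohort generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## Data model

All volumes live on one `VolumeGrid`: a 3D lattice with a physical voxel
size and a boolean brain mask. Voxel indexing is 0-based in the on-disk
(x, y, z) array order; world-space coordinates come from the stored
affine. Multi-sample collections (`ConditionMaps`, `DissimilarityMaps`)
extend `SummarizedExperiment` with one column per volume and one row per
in-mask voxel, so grid geometry is stored once and all samples are
guaranteed to share it. Per-subject inputs are one z-statistic volume per
condition (`pain`, `touch`, `control`), plus a trait table with the four
empathy subscale sums (FS, EC, PT, PD), each the sum of six items scored
0–5 and therefore bounded by [0, 30].

## Searchlight geometry

A searchlight sphere is the set of integer offsets with
dx² + dy² + dz² ≤ r² (centre-to-centre distance in voxel units,
*inclusive*): 1, 7, 33, 123 voxels at r = 0, 1, 2, 3. The default r = 3
gives the 123-voxel neighbourhood used throughout. At mask or grid edges
spheres are **clipped** — out-of-mask voxels are dropped rather than the
sphere discarded — so every mask voxel receives a value and the member set
at a fixed centre is identical across all maps on the grid. The
alternative (discarding edge spheres) was considered and rejected because
it leaves holes in the output maps; clipping is the choice that keeps "a
value mapped to every centre voxel". Its cost is that heavily clipped
spheres (down to 1 voxel at mask corners) have high-variance statistics;
see the note on degenerate spheres below.

## Cross-participant decoding

Within each sphere, each subject-condition pattern is one sample. Three
binary linear SVMs (pain/touch, pain/control, touch/control) are trained
one-against-one and combined by majority vote; ties are broken
deterministically in the fixed label order pain < touch < control.
Scoring is leave-one-subject-out: train on all other subjects' samples,
predict the held-out subject's three maps; accuracy = correct / (3·n).
Chance is exactly 1/3 because every sample enters exactly one test fold.

The SVM cost parameter defaults to the norm-adaptive heuristic
C = 1 / mean(‖x‖²) over the training samples, which makes decisions
exactly invariant to a common rescaling of all features (the dual problem
is scaled by a constant). Whether the reference front end divides by the
mean norm or the mean squared norm is not recoverable; both are available
(`costHeuristic = "squared-norm"` (default) or `"norm"`), and an explicit
`cost` overrides the heuristic. No within-fold feature scaling is applied:
the inputs are already normalised z-statistics.

## Significance thresholds for accuracy maps

Voxelwise significance uses a resel-wise Bonferroni correction: the
effective number of independent tests is the number of non-overlapping
searchlight spheres fitting in the mask. The default estimator is
floor(mask voxels / sphere voxels); a cube-packing alternative
floor(mask voxels / (2⌊r⌋+1)³) is selectable. Neither exactly reproduces
the reference count of ~725 on the standard MNI mask (the original
packing rule is unspecified), so the resel count is always a reportable,
overridable input, 725 being the documented reference value.

The critical accuracy comes from the exact binomial null at chance 1/3.
Two conventions are implemented because they differ by one count at the
reference design:

* `"invcdf"` (default): the binomial inverse-CDF value — the smallest k
  with P(X ≤ k) ≥ 1 − α, equivalently P(X > k) ≤ α. At n = 210,
  α = 0.05/725 = 6.89×10⁻⁵ this gives k = 97 (46%), matching the
  reference threshold, which was derived via an inverse-CDF routine.
* `"tail"`: the smallest k whose own upper tail P(X ≥ k) ≤ α, which gives
  k = 98 at the same design (P(X ≥ 97) = 7.48×10⁻⁵ slightly exceeds α).

Tail probabilities are computed via `pbinom` on the log scale, so alphas
of 10⁻⁵ and far smaller pose no underflow risk. Map thresholding is
inclusive (accuracy ≥ k/n is significant), consistent with the critical
count itself being called significant.

## Pattern dissimilarity

Within each subject and sphere, the three condition patterns are scaled to
unit Euclidean norm and pairwise distances d = √(2 − 2·cos θ) are mapped
to the centre, giving three contrast maps per subject with values in
[0, 2]: 0 for identical patterns, √2 for orthogonal, 2 for antipodal.
**Normalisation is the single most consequential design inference in the
package**: the [0, 2] range that defines this analysis is only guaranteed
for unit-norm vectors (z-scoring per sphere would give a different, also
bounded, statistic). It is exposed as a flag (`normalize`), on by default;
with it off the raw Euclidean distance is returned.

Degenerate all-zero patterns cannot be normalised; they produce `NaN`
(not 0), so downstream summaries and inference can exclude them
explicitly. Note that 1-voxel clipped spheres at mask corners yield
patterns of dimension 1 whose normalised distance is exactly 0 or 2; peak
tables of group-mean dissimilarity near the mask edge should be read with
this in mind (restricting the peak search to a region of interest, as the
tests do, avoids the artefact). Group summaries are voxelwise means across
subjects, conventionally displayed thresholded at 1.5; `reportPeaks`
lists local maxima (26-neighbourhood, plateaus tie) above that threshold.

## Brain–behaviour inference

The per-voxel statistic is the slope t-statistic of the regression of
per-subject map values on the demeaned trait (a monotone transform of
Pearson r; demeaning does not change it, and is kept for fidelity to the
modelled design). Voxels with zero map variance — including `NaN`
dissimilarity voxels — get statistic 0; |t| is capped at 10⁴ so perfect
correlations remain finite.

TFCE integrates cluster extent and height over all thresholds:
TFCE(v) = Σ_h e(h,v)^E · h^H · dh for h = dh, 2dh, … ≤ stat(v), with
e(h,v) the size of the connected supra-threshold component containing v.
Defaults are E = 0.5, H = 2 — the standard published exponents for 3D
volumetric data, which the reference tooling also uses — with
26-connectivity (6/18 selectable) and an adaptive step
dh = (max statistic)/100, floored at 0.01 (configurable). Only the
positive part is enhanced; the negative contrast is the enhancement of
the negated map. The reference analysis names TFCE but not its
parameters, the permutation count for the dissimilarity correlations, or
the statistic's sidedness; the defaults above are documented assumptions.

The null is Fisher–Pitman design-row shuffling: the trait covariate is
permuted across subjects (there are no nuisance covariates, so simple
permutation is exact). For each permutation the statistic map is
recomputed and TFCE-enhanced and its volume-wide maximum recorded; the
FWE-corrected p at voxel v is (1 + #{maxima ≥ TFCE(v)}) / (nPerm + 1) —
the include-observed convention, so p is never 0 and the inverse p-value
1 − p never exceeds nPerm/(nPerm+1). Null covariates are drawn as
arrangements of the sorted trait assigned in trait-rank order, which
makes the p-values exactly invariant to consistent relabelling of
subjects. When nPerm ≥ n! the n! distinct permutations are enumerated
exhaustively (with a warning), giving the exact permutation p. nPerm
defaults to 1000, a desk-scale compromise; the reference large-scale
setting of 30000 is a config value away. The full battery is 3 contrasts
× 4 subscales × 2 directions = 24 independently seeded tests, and the
same machinery accepts raw per-subject condition or contrast volumes,
providing the analogous univariate analysis with identical inference.

## Synthetic cohorts: what they emulate, and what they do not

`generateCohort` emulates the *statistical structure* of first-level
z-statistic maps, not their physiology:

* **Noise** is i.i.d. Gaussian, smoothed with a separable Gaussian kernel
  (FWHM in voxels, default 3 — i.e. 6 mm on a 2 mm grid), rescaled to
  unit variance, times `noiseSD` (default 1, z units). Spatial
  correlation is what makes searchlight and TFCE behaviour realistic, so
  it is the one noise property modelled.
* **Signal regions** carry per-condition multivoxel templates built from
  a random orthonormal basis over the region's voxels. By default the
  noise-free separation of each region's variable condition pair is
  `baseSep` = √2 (orthogonal templates); per subject it becomes
  baseSep + slope·(trait − mean) + N(0, subjectSD), realised by rotating
  *both* templates of the pair symmetrically (by half the angle each) so
  that the designed normalised distance holds exactly at zero noise,
  while the third condition's template stays on an orthogonal basis
  vector. `signalScale` sets the template's per-voxel RMS amplitude in
  noise-SD units — an effective voxelwise SNR (default 1).

  Coupling selectivity has a known second-order limit: a searchlight
  sphere sees *sub-vectors* of the region templates, whose cross products
  are only O(1/√nROI) from orthogonal, so a subject-varying rotation
  leaks weakly into the other two contrasts' measured distances. The
  symmetric rotation halves this leakage and splits it across both other
  contrasts, and at realistic SNR (signalScale ≈ 1–1.5) with
  subject-level separation noise (subjectSD ≈ 0.1) the leaked
  correlation stays far below the coupled contrast's; an almost
  noise-free regime (signalScale ≳ 3, subjectSD ≲ 0.02) makes even this
  second-order term detectable and should not be read as a selectivity
  failure of the inference.
* **Traits** are truncated normals per subscale on [0, 30]; the defaults
  (means 16/20/17/11, SDs 5/4/4.5/4.5 for FS/EC/PT/PD) are typical adult
  norms for this questionnaire. Subscale sums are simulated directly;
  item-level structure and its reliability are not modelled.

Not emulated: hemodynamics and time-series structure, motion and
physiological artefacts, inter-subject anatomical misalignment,
condition-dependent noise, and real anatomy (the default test mask is an
ellipsoid "brain" on a 24³ desk-scale grid; the full 91×109×91 standard
grid is supported but not the default). Passing tests on these cohorts
therefore validate the *estimators and their calibration* (chance levels,
FWER control, selective recovery), not claims about real tissue.

The designed per-subject separations are returned alongside the maps, so
calibration checks can compare the realised trait correlation with the
closed-form attenuated value r = b·sd(trait) / √(b²·sd(trait)² +
subjectSD²).

## Numerical choices and degenerate inputs

* Sphere membership uses ≤ (inclusive) Euclidean distance; offsets are
  enumerated in lexicographic order, so patterns align element-wise
  across maps.
* The searchlight engine is statistic-agnostic and serial; traversal
  order cannot affect results, and the same engine serves decoding and
  dissimilarity (same spheres, same clipping).
* OVO vote ties break by fixed label order (pain < touch < control);
  documented, deterministic.
* Distances are clamped at 2 against floating-point overshoot of the
  bound; exact zeros in normalisation produce `NaN`, never silent zeros.
* TFCE integration is a fixed-step Riemann sum; halving dh changes
  results by O(dh). The step is frozen across observed and permuted maps
  within one test so enhanced values are comparable.
* Binomial tails are computed in log space; the two threshold conventions
  are both exposed because the reference design sits exactly on their
  one-count disagreement.
* Cohort generation, permutation draws and the CLI are seeded; identical
  config + seed reproduces outputs byte-identically, and every pipeline
  output carries a JSON sidecar with the config hash and seed.

## Problem sizes used by the shipped tests

The test suite validates calibration at desk scale, chosen to exercise
every code path with meaningful statistics: null decoding on a 24³ grid
with 20 subjects and 200 sampled spheres; signal recovery with a 7³
seeded block at SNR 1 against the resel-corrected binomial threshold for
that design; FWER control over 100 replicate 20-subject cohorts on a 20³
grid at 500 permutations; and selective trait-coupling recovery with the
full 24-test battery at 500 permutations. The full-scale design (70
subjects, 91×109×91, 30000 permutations) runs through the identical code
paths via configuration.

## Known limitations

* The resel count is an approximation of the effective number of tests;
  random-field-theory estimates from map smoothness are out of scope.
* Only Euclidean distance on unit-norm patterns is implemented;
  correlation- and Mahalanobis-distance variants are documented extension
  points, as is full RDM-based representational analysis.
* Surface-based and anatomically constrained searchlights are not
  supported; spheres are defined in voxel space.
* Permutation inference assumes full exchangeability of subjects (no
  exchangeability blocks, no variance smoothing).
* Heavily clipped edge spheres produce high-variance statistics rather
  than being excluded; users wanting exclusion can erode the mask.
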