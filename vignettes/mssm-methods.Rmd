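---
title: "Multiscale structural surface mapping: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale structural surface mapping: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

Cortical atrophy is conventionally quantified by cortical thickness — the
distance between the modeled gray/white interface (the *white* surface) and
the gray/CSF interface (the *pial* surface). Neurodegeneration, however, also
changes tissue microstructure before it measurably thins the cortex: the
T1-weighted intensity of deep gray matter drifts toward that of the adjacent
white matter. This package implements multiscale structural surface mapping
(MSSM), which augments thickness with gray/white contrast ratios sampled at
several laminar depths.

At every vertex $i$ with white position $w_i$ and pial position $p_i$:

* **Depth surfaces** at fractions $g \in \{0.2, 0.4, 0.6, 0.8\}$ of the
  cortical ribbon, $x_i(g) = (1-g)\,w_i + g\,p_i$. Straight-segment
  correspondence is used rather than Laplace streamlines: the phantom's
  white/pial pairs are in exact vertex correspondence, which is what a
  deformable-surface reconstruction provides.
* **Subjacent white-matter surfaces** at offsets $o \in \{0.5, 1.0\}$ mm
  below the gray/white border along the inward vertex normal (angle-weighted
  average of incident face normals — deterministic and standard).
* **Contrast features** $R_i(g, o) = I(x_i(g)) / I(w_i - o\,n_i)$, eight
  ratios per vertex, plus thickness $t_i = \lVert p_i - w_i \rVert$ as the
  ninth feature. Intensities are trilinearly interpolated through the
  voxel-to-world affine (nearest-neighbour available for ablation). Samples
  that leave the grid, or non-positive denominators, are flagged undefined
  and propagate as missing — never silently imputed.

The ratio is taken gray-over-white, so T1-like contrast gives values below 1
and disease-related contrast loss moves them *up* toward 1. The direction is
a convention (it only flips the sign of effects) and is configurable.

Because numerator and denominator are millimetres apart, any multiplicative
intensity field that is smooth at that scale — B0/B1 inhomogeneity, scanner
scaling — cancels to first order: the ratio is locally normalized. The
phantom tests quantify this: under a ±10% bias field the raw gray-matter
intensities move by several percent while the ratios move by less than 0.01
(asserted < 0.03).

### Surface smoothing

Feature maps are smoothed on the mesh with iterated neighbour averaging,
$v_i \leftarrow \mathrm{mean}(v_i \cup N(v_i))$, self included with the
weight of one neighbour. The iteration count is calibrated once per mesh (and
cached) so that the empirical standard deviation of a smoothed point impulse
matches the target $\sigma = \mathrm{FWHM}/2.3548$ for the default 5 mm FWHM;
a warning is raised when the mesh is too coarse or too small to realize the
kernel within 15%. All nine features are smoothed identically by default
(`smooth_thickness = FALSE` exempts thickness) — whether thickness should
share the kernel is genuinely open; sharing it is the simpler default.

### Vertex-wise PLS reduction

Per vertex, the nine features are min-max normalized to $[0,1]$ using
*training-split* bounds, centred, and reduced to a single component by PLS1
against the centred binary label: $w \propto X_c^\top y_c$, normalized to
unit length. This closed form is the first NIPALS component for a single
response; the test suite asserts equality with an independent NIPALS
implementation to $10^{-8}$. PLS weights are sign-ambiguous, so the sign is
fixed per vertex to correlate non-negatively with the label in training —
without this, vertex maps would not be comparable across vertices.
Zero-variance features receive weight zero; all-zero covariance flags the
vertex undefined. One component per vertex exactly; multi-component PLS is
out of scope. The final model is fitted on the training split only
(`refit_train_val = TRUE` pools training and validation instead); for
group-level statistical maps, where no held-out inference is made, the
reduction is fitted on the full cohort.

### Group statistics

Vertex-wise pooled-variance two-sample t-tests (the cohort generator matches
groups by construction, so no covariate adjustment is applied by default;
`vertex_ttest(..., covariates = )` residualizes every vertex on nuisance
covariates first, for unmatched cohorts),
Cohen's d, and Benjamini–Hochberg FDR at $q = 0.05$ pooled over all defined
vertices in a single family — the conservative single-family reading when
hemispheres are analysed together. The "extra region" analysis averages the
reduced map over vertices significant for MSSM but not thickness, and
correlates it (Pearson and Spearman) with a cognitive score, raw and
partialled on mean thickness over the whole cortex or over the
thickness-significant set. Partial correlation residualizes both variables
on the control; Spearman partials operate on ranks first.

### Classification

Subjects are split 60/20/20 (train/validation/test), stratified by label,
*before* any fitted object sees the data; each subject's assignment derives
deterministically from the seed and its ID. Class imbalance is handled with
inverse-prevalence weights $w_c = n/(K n_c)$: per-sample loss weights for
loss-based learners, split-criterion reweighting for the forest (kNN has no
weighting mechanism and runs unweighted). Nine families are considered: SVMs
with linear/sigmoid/polynomial/RBF kernels, a small (size-2) feed-forward network,
a random forest, ridge logistic regression, kNN, and a Gaussian-process
classifier. Each is trained with 5 random initializations × 4 stratified CV
folds over the train+validation pool (20 AUROCs averaged per family);
deterministic families realize their "initializations" through the fold
shuffling. The top 3 are refit and ensembled by averaging their class-1
probabilities. The decision threshold minimizes FP + FN on the validation
split (ties resolve to the lower threshold, favouring sensitivity); AUROC is
trapezoidal, AUPRC uses non-interpolated step integration to avoid the
optimistic trapezoid bias. Transfer evaluation applies every fitted object —
normalization bounds, PLS weights, ensemble, threshold — unchanged to a
second cohort.

SVM probabilities come from our own weighted Platt calibration of the
decision values on the training fold: it is deterministic and satisfies the
"calibrated score in [0, 1]" contract for every family. Ridge (rather than
plain) logistic regression is used because the vertex-wise inputs have far
more features than subjects. The classifier input is the vectorized reduced
map; an optional `top_k` cap (by training-split effect size) exists for
larger meshes, with all vertices used by default at phantom scale.

## The phantom

The synthetic subject is a spherical cortical ribbon: white surface = an
icosphere (level 4, 2562 vertices, radius 40 mm by default), pial surface =
white + local thickness along the outward normal, thickness 2.5 mm plus a
per-subject global offset $\mathcal N(0, 0.15\,\mathrm{mm})$ emulating normal
between-subject variation. The volume (1 × 1 × 1.2 mm voxels) is piecewise
constant — WM 110, GM 75, CSF 20, T1-like ordering — with each voxel assigned
to the innermost region containing its centre, then multiplied by a smooth
bias field (three cosine modes of ~100 mm wavelength with random directions
and phases, ±10% peak) and degraded with additive Gaussian noise (sd 5,
about 7% of the GM mean). The bias field is deliberately *injected* rather
than removed: the claim under test is that ratio features are locally
normalized against exactly this kind of nuisance.

Disease-like effects are spherical-cap "signatures": thinning
(−0.6 mm) in a 25° cap and contrast loss (GM shifted 25% of the way toward
WM intensity) in a 50° cap containing it, so the contrast effect extends
beyond the thinning region — the situation in which multiscale mapping
should add sensitivity. Thinning and contrast loss are modelled as distinct
but related processes: per-subject severities share a common factor
(correlation 0.5), and the synthetic FAQ-like functional score is generated
from the contrast severity; a hippocampal-volume-like scalar (with an
eTIV-like normalizer) tracks the mean burden. These synthetic clinical
columns exist so the extra-region correlation and scalar-baseline analyses
have a recoverable ground truth. Effect magnitudes are chosen for test
power, not biological fidelity — the source of real effect sizes is group
maps, not printed deltas.

What the phantom does *not* emulate: folded sulcal geometry, partial-volume
mixing within voxels (voxels are pure tissue before interpolation), Rician
noise, lesions, registration error across subjects (meshes share vertex
correspondence by construction). Passing tests therefore demonstrate the
correctness and internal sensitivity of the procedure, not its accuracy on
real MRI.

## Study conditions and problem sizes

The reference experiment (`run_study()`) uses an icosphere at subdivision
level 3 (642 vertices) with a 30 mm white radius, 40 affected vs 40 control
subjects, and the full nine-family zoo — a problem size chosen so the whole
study runs in about a minute while every stage operates above its degeneracy
thresholds. Ground-truth recovery tests use a dedicated thick-ribbon
phantom (3 mm cortex, 0.4 mm isotropic voxels, 12 mm radius): with the
default 2.5 mm cortex and 1 mm voxels, *no* sample point lies two voxels
clear of a tissue boundary, so exact recovery is only a well-posed check on
a geometry where the interpolation support stays within one tissue class.
The transfer cohort halves both effect deltas ("MCI-like"). Null
calibration trains on a 40/40 zero-effect cohort and evaluates on an
independent 60/60 zero-effect cohort: a 16-subject test split would carry a
±0.29 null band at 95%, so the independent-cohort design is what makes the
[0.35, 0.65] calibration band meaningful.

## Numerical and degenerate-input choices

* Sampling points exactly on the upper grid face use the last full cell;
  anything outside the interpolation support is undefined, counted, and
  propagated.
* Voxelization assigns voxel centres radially using the nearest mesh vertex
  direction; the mapping is cached per (grid, mesh).
* Smoothing calibration searches iterations 0–200 and picks the closest
  sigma; fwhm 0 is the exact identity.
* `choose_threshold` scans midpoints of adjacent unique scores plus
  sentinels; `which.min` returns the first (lowest) optimum.
* Family ranking ties break alphabetically for determinism.
* Content hashes (MD5 of serialized objects) verify train/test hygiene:
  permuting test labels or corrupting test features must not change any
  fitted object.
* Provenance records contain the config hash, seed and versions but no
  timestamps, so fixed-seed pipeline reruns are byte-identical.

## Known limitations

* The white-matter offset convention (0.5/1.0 mm) follows the figure-level
  description of the sampling scheme; offsets are configurable.
* The spherical phantom cannot probe gyral/sulcal bias of the normal-based
  white-matter sampling.
* kNN and the Gaussian process ignore class weights; with the matched
  default cohorts this is moot, but heavily imbalanced data would favour the
  weighted families.
* The iteration-count smoothing kernel is isotropic in the graph metric;
  strongly anisotropic meshes would need geodesic weights, which are out of
  scope.
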