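---
title: "Radiomic analysis of pancreatic tumor heterogeneity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic analysis of pancreatic tumor heterogeneity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Pancreatic ductal adenocarcinoma (PDAC) behaves differently depending on
where in the pancreas it arises: head tumors and body/tail tumors differ in
symptoms, treatment response and prognosis. `pancradiomics` asks whether
that heterogeneity is visible in routine contrast-enhanced CT: it extracts a
large engineered feature set (intensity, texture, shape) from the tumor
region of interest, screens the features for head vs body/tail differences,
and validates the discriminative ones by training classifiers to predict a
tumor's subregion from its imaging features alone.

Because the underlying patient CT cohort is not publicly deposited, the
package carries a first-class synthetic phantom generator that reproduces
the *statistical structure* of the cohort — class balance, size and
intensity contrasts, and a planted texture difference — so every stage of
the pipeline runs and is validated end to end without patient data.

# Pipeline and models

## Preprocessing and subregions

Volumes are min–max normalized to [0, 1] over the whole scan; no other
preprocessing (no resampling, no windowing) is applied, and masks must share
the volume's grid exactly. The pancreas is split into head, body and tail by
a transparent proportional rule: voxels are ordered by projection onto the
organ's first principal axis, sliced into slabs one in-plane voxel pitch
wide, and cut at cumulative voxel fractions 0.40 and 0.73 — the approximate
head/body/tail volume shares of the organ (head 40%, body 33%, tail 27%,
with the neck counted as head). The head end is identified as the end whose
terminal 10% of slabs has the larger mean cross-section (the head is the
bulkiest part, seated in the duodenal curve); an exact tie falls back to the
patient-right convention. This replaces anatomically exact
landmark-based subregion segmentation, which is out of scope; the partition
is reproducible, rotation-stable, and matches the stated proportions to
within one slab.

A tumor is assigned to `head` or `body_tail` by plurality vote of the
subregion labels under its voxels (body and tail are pooled, which is the
clinically used grouping). A tumor that touches no labeled voxel is resolved
from labels within 10 mm; an exact 50/50 tie goes to head (the majority
class) — tumors straddling the head–body boundary are a known ambiguity and
the tie rule makes the behavior deterministic and documented.

## Discretization and texture features

Texture matrices are built on integer grey levels obtained by equal-width,
fixed-bin-count binning of the in-ROI intensities over the ROI's own min–max
range. Fixed bin *count* (2, 4, …, 256) rather than fixed bin width is used
because the analysis sweeps bin counts as a parameter axis; the per-tumor
range makes texture reflect intra-tumor contrast. A constant ROI maps to
level 1 everywhere — any single level is texture-free and the lowest is the
conventional choice.

Five matrix families are computed, with fixed cardinalities:

| family | features | parameter axes |
|---|---|---|
| grey-level co-occurrence (GLCM) | 20 | bins × offset distance × angle |
| grey-level run length (GLRLM) | 15 | bins × angle |
| grey-level size zone (GLSZM) | 14 | bins |
| grey-level dependence (GLDM) | 12 | bins × kernel |
| neighbourhood grey-tone difference (NGTDM) | 5 | bins × kernel |

Accumulation is 2D in-plane (four quadrant directions 0°/45°/90°/135°)
summed over axial slices; the size-zone matrix alone is 3D (26-connected),
being direction-free. The *kernel* parameter is the in-plane neighborhood
radius (1–5 voxels): co-occurrence offsets are generated at distances up to
the kernel (one matrix per distance and angle), and dependence/grey-tone
statistics count neighbors within the kernel's Chebyshev radius. Features
are kept per angle rather than angle-averaged, which is what makes the
full default grid

$$20{\times}8{\times}5{\times}4 \;+\; 15{\times}8{\times}4 \;+\; 14{\times}8
\;+\; 12{\times}8{\times}5 \;+\; 5{\times}8{\times}5 \;+\; 15 \;+\; 20
\;=\; 4507$$

feature columns per tumor. First-order statistics (15) and 2D/3D shape
features (20) complete the set; both are computed once, being independent of
the texture sweep (the first-order entropy histogram uses a fixed 32-bin
discretization).

Four co-occurrence features — *inverse cluster shade*, *inverse cluster
tendency*, *Gaussian left polar* and *inverse Gaussian left polar* — have no
published formula in the field; this package defines them explicitly (see
`?glcm_features`): the "inverse" cluster moments are the usual cluster
moments computed on the normalized complement distribution
$p'(i,j) \propto \max(p) - p(i,j)$, and the (inverse) Gaussian left polar
features weight the lower-triangular joint mass with a Gaussian kernel in
$|i-j|$ with scale $\sigma = B/4$. They are deliberate, testable
definitions, not reconstructions of anyone else's.

Two counting conventions worth noting: the run-length family keeps the
normalized run-length non-uniformity but not the normalized grey-level
non-uniformity, and the dependence family omits grey-level non-uniformity —
these choices pin the families at exactly 15 and 12 features. GLDM
dependence uses exact level equality (tolerance 0) by default, exposed as a
parameter.

## Numerical conventions and degenerate inputs

* Percentiles use the empirical-CDF-with-linear-interpolation rule
  (`quantile(type = 4)`), so the 25th percentile of $\{1..100\}/100$ is
  exactly 0.25.
* Kurtosis is non-excess: a normal sample gives 3. This avoids a silent
  3-offset against either convention.
* Degenerate denominators (correlation of a zero-variance matrix, skewness
  of a constant ROI) return `NaN` sentinels; NGTDM coarseness of a
  texture-free ROI is capped at $10^6$. The screening filter removes any
  column containing a non-finite value or with zero variance, mirroring the
  filtering of unusable or infinite values a feature screen requires.
* Mesh surface area and volume come from a marching-tetrahedra iso-surface
  (6-tet cube split, linear edge interpolation) of the Gaussian-smoothed
  (σ = 1 voxel) mask indicator at level 0.5. Meshing the raw binary mask
  overestimates curved surfaces badly (a digital ball's staircase surface
  carries ~25% excess area); on the smoothed field a radius-20 digital ball
  measures sphericity 0.995. Masks so thin that the smoothed peak falls
  below 0.5 fall back to a binary/smoothed blend whose surface always
  exists. Axis lengths are $4\sqrt{\lambda}$ of the physical-coordinate
  covariance eigenvalues; a mask that is flat along an axis returns a `NaN`
  flatness sentinel.

## Screening

Each feature is compared between head and body/tail cases with a two-sided
Welch t-test; Welch rather than Student because the groups are unbalanced
(58/42) and variance equality is unverifiable. Significance is declared at
raw p < 0.05 with **no** multiplicity correction — the screening stage is
deliberately liberal and feeds the classifier stage, which provides the
external check; an optional Benjamini–Hochberg flag exists but is off by
default. The Manhattan export writes per-feature −log10 p grouped by family
as CSV plus a plot.

## Classification

Seven classifiers are trained: Gaussian naive Bayes, k-nearest neighbours,
K-means, linear-kernel SVM, linear regression, ensembled bagged trees, and
linear discriminant analysis. Where a method is not natively a binary
classifier the standard adaptation is used and exposed in configuration:
K-means acts as a supervised nearest-class-centroid rule; linear regression
fits a 0/1 response and thresholds at 0.5; bagged trees are a 50-tree forest
with every predictor offered at each split; KNN uses k = 5 on z-scored
features. Features are z-scored inside every pipeline with training-set
statistics only, so no test-set information leaks into the scaling.

Recursive feature elimination caps every model at five features — an
overfitting guard for ~100-case cohorts. Ranking is the absolute model
coefficient where the model has one (SVM weight vector, regression
coefficient, LDA scaling), impurity importance for the forest, and the
absolute univariate Welch t statistic for the coefficient-free methods. The
default elimination step is one feature per round; a fractional step (e.g.
0.5 = halve the surplus each round) is available for tables with thousands
of columns, where one-at-a-time refits would be needlessly slow without
changing the retained set's cap. If a method cannot be fit on the current
working set (LDA while more features than cases remain), that round ranks
by the univariate statistic; the final refit always uses the actual method.

Evaluation reports the 2×2 confusion matrix with head as the positive
class, accuracy / sensitivity / specificity as percentages (full precision
retained; integer reporting rounds half up), an ROC curve from a
score-threshold sweep, and the trapezoid AUC. Scores of exactly 0.5
classify as head, deterministically.

# The phantom generator

`generate_cohort()` defines the study conditions the tests run under:

* 58 head and 42 body/tail cases per cohort (the cohort split per
  100-scan subset);
* head tumor equivalent-sphere diameters uniform on 2.4–3.1 cm, body/tail
  on 5.6–6.1 cm. The source size summaries are reported in cm, which reads
  as a diameter range; the generator treats them as equivalent-sphere
  diameters — a flagged interpretation, not an assertion;
* head tumors +0.15 brighter on the normalized scale (head tumors present
  hyperintense, plausibly from duct compression altering contrast);
* intra-tumor texture drawn from Gaussian-correlated noise whose
  correlation length differs by class (1.2 vs 2.5 voxels, SD 0.08). The
  real texture differences are attributed to cellular arrangement without
  an imaging model, so correlated noise is the minimal stand-in that
  texture matrices can detect;
* an elongated, curved, head-heavy tubular pancreas (length 12–15 cm,
  anteroposterior radius tapering ~15 mm to ~6 mm) on an 88×56×32 grid at
  2×2×3 mm spacing — large enough that a 6.1 cm tumor fits with margin,
  small enough that a 100-case cohort extracts in about two minutes.

The intensity offset of 0.15 was chosen once so planted effects are
detectable at n = 100 but not trivially separable in intensity alone; the
grid and spacing are the package's choice of a desk-scale problem size. The
real effect sizes of the cohort are not published, so the phantom effect
sizes are free parameters of the generator, not calibrations to the study.

`generate_null_cohort()` runs the identical generative process for both
classes (zero offset, common correlation length, common size range), so
label-feature dependence is absent by construction; it is the type-I-error
and chance-AUC control.

What the phantoms deliberately do **not** emulate: CT physics (beam
hardening, contrast phase), anatomy beyond a tapering tube, duct dilation,
tumor infiltration beyond a perturbed ellipsoid, and inter-scanner
variation. Passing tests therefore demonstrate that the pipeline recovers
planted effects of the stated kind and size — not that the headline
real-data accuracies would reproduce on patient CT.

# Validation strategy

Every texture-matrix constructor is checked against naive brute-force
enumeration (voxel-pair, run, zone and neighborhood loops written
independently in R) on hundreds of randomized small level maps, along with
the conservation identities each matrix must satisfy (run lengths, zone
sizes and dependence counts each tally back to the ROI voxel count).
Feature formulas are frozen against hand-computed values on tiny matrices.
The screening stage is calibrated on null simulations (significant fraction
≈ α) and the evaluation stage cross-checked against an independent ROC/AUC
implementation. End-to-end, a planted-contrast cohort must yield the size
and intensity features among the significant set and a held-out best-method
accuracy above 70% — a property target for the synthetic conditions, not a
claim about patient data.

# Known limitations

* The subregion partition is proportional, not anatomical; boundary-zone
  tumors inherit the plurality rule's arbitrariness.
* Texture accumulation is in-plane; through-plane texture (beyond GLSZM) is
  not measured, consistent with quadrant-angle parameterization.
* Whether intensity normalization preceded or followed any windowing in the
  source protocol is unstated; the package normalizes the stored voxel
  values as given.
* The feature screen is uncorrected for multiplicity by design; its output
  is a candidate set, not an inference.
* NRRD support covers the common attached-header raw/gzip dialect only.
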