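---
title: "Peri-stent FAI: measurement model and statistical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-stent FAI: measurement model and statistical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stentfai)
```

`stentfai` measures the fat attenuation index (FAI) of the perivascular
adipose tissue (PVAT) surrounding a coronary stent on CT angiography, and
analyses its association with in-stent restenosis (ISR). This vignette is
the package's own account of the underlying model, the design decisions
that were genuinely open, and what the simulation-based validation does
and does not establish.

## The measurement model

### Geometry

All geometry lives in world millimetres with a voxel-center convention: a
`voxel_grid` stores a 3D HU array, the isotropic or anisotropic spacing,
and the world position of the first voxel center. A `centerline` is an
ordered polyline from the vessel ostium (arc length 0) with unit tangents;
cross-sections are resampled in planes orthogonal to the tangent, with
in-plane axes carried along the vessel by parallel transport (the
double-reflection method), so consecutive sections do not twist. The
initial in-plane axis is the first canonical axis not parallel to the
first tangent, orthogonalised — a fixed, reproducible tie-break.

The peri-stent PVAT shell follows the convention that perivascular fat
extends a radial distance equal to the vessel diameter from the outer
vessel wall. For a stent of diameter $d$ the shell is

$$\mathcal{S} = \{v : s(v) \in [a, b],\; d/2 < r(v) \le d/2 + m\,d\}$$

where $s(v)$ is the arc position of the voxel center's orthogonal
projection onto the centerline, $r(v)$ its distance to it, $[a, b]$ the
annotated stent extent, and $m$ the thickness multiplier (default 1).
Two readings of "radial distance equal to the stent diameter" are
possible: shell *thickness* $d$ measured outward from the outer stent
surface, or shell *outer radius* $d$ from the centerline. The package
uses the first: it matches the definition of PVAT as fat within one
vessel diameter of the outer wall, whereas the second would make the
shell thinner than that definition whenever the wall has any thickness.

The longitudinal extent defaults to the stented segment only
(`fai_config(extent = "stent")`); the `"stent_edges"` option adds the
5 mm edge segments, mirroring the ISR definition, for sensitivity
analyses.

### The index

$$\mathrm{FAI} = \operatorname{mean}\{ \mathrm{HU}(v) : v \in \mathcal{S},\;
-190 \le \mathrm{HU}(v) \le -30 \}$$

The adipose window is inclusive at both ends ("within the range" read
conventionally). Whether platform implementations use a plain mean or a
histogram-weighted statistic is not public; the package implements the
plain windowed mean and documents that choice. Lumen, stent-strut and
wall voxels that intrude on the shell geometrically are excluded by the
window itself (contrast ≈ 350 HU, struts ≈ 800 HU, soft tissue ≈ 40 HU),
and no voxel within $d/2$ of the centerline is ever in the shell. A shell
with zero in-window voxels raises a `no_adipose_voxels` error rather than
returning a number — mirroring the practice of excluding
artifact-corrupted stents instead of reporting an unusable measurement.

Voxel membership is decided by the voxel center, with no partial-volume
weighting. This makes the measurement exactly reproducible by a
brute-force loop over all voxels, which the test suite runs on 32³ grids;
partial-volume effects are emulated only through additive noise.

### Centerline extraction

No 3D thinning implementation exists in the package's dependency set, so
`extract_centerline()` uses a medial-path algorithm suited to the
single-tube masks in scope: (1) build the 6-connected voxel graph of the
mask (single-component enforced); (2) find an endpoint pair by double BFS
eccentricity; (3) route the path through the tube interior by weighting
edges inversely with an erosion-depth distance transform; (4) refine each
node to sub-voxel accuracy by moving it *perpendicular to the local
tangent* onto the center of mass of the mask voxels in its perpendicular
slab — the lateral-only update cannot shorten the curve or destabilise
the ends, and tangents within 2 mm of an endpoint are borrowed from the
curve interior because the raw graph endpoints sit on the rim of the
tube's end face; (5) smooth with an endpoint-preserving moving average
(window 5 points) and resample at a fixed 0.5 mm step. The endpoint
nearest the volume boundary is labelled the ostium. On phantoms this
recovers a straight axis to well under half a voxel and a helical axis to
a mean error below one voxel.

### Lumen profile and the degree of ISR

Lumen diameters are measured on resampled cross-sections by thresholding
at the contrast attenuation (default 180 HU, roughly midway between
soft tissue/fat and the 350 HU lumen), keeping the 4-connected component
containing the centerline pixel, and reporting the equivalent-circle
diameter $2\sqrt{A/\pi}$. The equivalent-circle rule was chosen over a
caliper diameter because it is far more robust to pixelation at small
lumina; an occluded center pixel yields diameter 0, not an error.

The profile samples the stent segment plus 5 mm edges; the proximal
reference is the *median* diameter over the window 10–5 mm proximal to
the stent (the median resists edge artifacts, and where exactly a
"normal proximal lumen" should be read is not standardised — the window
is configurable). The degree of ISR is
$100\,(d_\mathrm{ref} - d_\mathrm{min})/d_\mathrm{ref}$, clipped to 0 when
$d_\mathrm{min} > d_\mathrm{ref}$, and the binary ISR flag defaults to
degree ≥ 50 % — the conventional angiographic cutoff; the threshold is
exposed because the clinical read-out may differ. Stents whose proximal
reference window would start before the ostium raise a
`proximal_exclusion` error, mirroring the exclusion of stents within
10 mm of the ostium.

## The synthetic data

### Phantoms

`generate_phantom()` voxelises a straight or helical contrast-filled
vessel: lumen (350 HU), soft-tissue wall (40 HU), an annular strut layer
(800 HU) over the stent extent, a perivascular fat compartment, and a
soft-tissue background. Fat voxels are drawn i.i.d.
$N(\mu_\mathrm{fat}, \sigma_\mathrm{fat}^2)$ — spatially white, matching
the histogram-based definition of the FAI, which is insensitive to
spatial texture; a `fat_fraction` below 1 mixes in contaminant voxels
from the background distribution. An in-stent stenosis is modelled as a
squared-cosine narrowing of the lumen radius with soft-tissue neointima
filling the displaced lumen. Additive Gaussian image noise is applied
last; truth masks (lumen, struts, shell) are noise-free and mutually
disjoint by construction.

Default spacing is 0.5 mm isotropic — near the 0.625 mm detector
collimation of the scanners in view but rounder for analytic checks. The
default stent (diameter 3.5 mm, length 12 mm) is smaller than the
published cohort average (4.2 mm, 28 mm) so that the default grid stays
at 54 × 54 × 60 voxels and a full generate–extract–measure cycle runs in
under a second; the FAI measurement is scale-free in this range, and the
cohort generator, not the phantom, carries the published stent-size
distributions. Stenosis-recovery tests use 0.25 mm phantoms because a
50 %-narrowed 3 mm lumen is at the resolution limit of 0.5 mm voxels —
exactly as it is on real CT.

What phantoms do *not* emulate: beam hardening, blooming from struts and
calcium, cardiac motion, ECG-phase misregistration, spatially correlated
noise, bifurcations. Passing phantom tests therefore validates the
geometry and arithmetic of the measurement, not its robustness to scanner
physics — the latter was handled in the clinical workflow by excluding
artifact-corrupted cases.

### Cohorts

`generate_cohort()` draws a two-group cohort calibrated to the published
summaries: group sizes 52 (ISR) and 65 (non-ISR); peri-stent FAI
$N(-78.1, 6.2^2)$ vs $N(-87.2, 7.3^2)$ HU; ~30 demographic, laboratory
and stent covariates with the published per-group proportions or
means/SDs (`default_covariates()`); vessel and segment locations at the
published frequencies. Within the ISR group the degree of ISR is
$N(50.3, 21.5^2)$ % coupled to FAI through a Gaussian copula (bivariate
normal, degree clipped to [0, 100] %) at a target Pearson correlation of
0.579 — the simplest structure that reproduces a stated product-moment
correlation. No distributional form for the degree is published;
truncated normal is an assumption. Covariates are generated independently
of one another because no cross-covariate associations are published; a
LASSO run on such a cohort therefore sees weaker collinearity than real
laboratory panels exhibit, which flatters selection stability.

The clipping of the degree slightly attenuates the realised correlation
(about 2 % of the mass is clipped at the configured parameters), which is
visible as a small downward bias in correlation-recovery simulations —
within the tolerance of all checks, and intrinsic to bounding a
percentage.

## The statistical chain

* **Group comparisons** — Welch's t by default (no test is named in the
  source analyses; Student's pooled variant is available for replication
  attempts). Two samples that are each constant with equal means return
  p = 1 by convention. Categorical tables use chi-square without
  continuity correction, switching to Fisher's exact test for 2×2 tables
  with any expected cell below 5.
* **LASSO selection** (`lasso_select()`, glmnet backend) — binomial
  deviance over a 100-point log-spaced grid spanning four decades down
  from the smallest all-zero-coefficient penalty; 10-fold
  class-stratified, seeded folds; model 1 at `lambda.min`, model 2 at
  `lambda.1se` (largest penalty within one SE of the minimum CV
  deviance). Features are standardised internally, coefficients reported
  on the original scale, and failure to converge at the smallest
  penalties is surfaced as a flag, never silently.
* **Adjusted logistic regression** — maximum-likelihood `glm` with Wald
  95 % intervals $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$. FAI enters per
  +1 HU, so OR > 1 means less-negative (more inflamed) fat raises the
  odds of ISR. Quasi-separation is flagged; the pipeline caps the number
  of LASSO-chosen predictors entering this model (default 4, matching
  the size of a typical selected panel) and falls back to the
  primary-exposure model when the multi-predictor fit degenerates on a
  small cohort, so reported intervals stay finite.
* **ROC analysis** — AUC by the Mann–Whitney identity with half-credit
  ties (pROC backend, validated in-suite against an exhaustive pairwise
  oracle), DeLong 95 % intervals, orientation fixed so that higher FAI
  predicts ISR. The published cutoff criterion is not stated; Youden's
  J is assumed, with ties broken toward higher specificity.
* **Correlation** — Pearson's r with Fisher-z interval
  (SE $1/\sqrt{n-3}$) and a t-based p-value on $n-2$ df; constant input
  is an error.
* **ICC** — ICC(2,1): two-way random effects, absolute agreement, single
  measures, computed from the mean-squares decomposition with the
  F-based interval, implemented directly (no suitable dependency);
  constant ratings degenerate to `NA` with a warning.
* **Multiple testing** — none is applied across the descriptive tables,
  matching the source analyses.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
analytic cylinder geometry for shells and diameters, exhaustive
voxel/pairwise enumeration for FAI and AUC, closed-form variance ratios
for the ICC, and parameter-recovery simulations for the logistic,
correlation and LASSO estimators. Replicate counts (500 seeds for group
separation and AUC recovery, 1000 for the small LCx subgroup, 200 for
estimator-bias checks, 100 phantoms for the end-to-end FAI mean, 25 for
LASSO stability) were sized so the full suite completes in about a
minute on one CPU while keeping Monte-Carlo error well inside each
check's tolerance.

Note what the binormal cohort checks can and cannot show: the expected
AUC of the calibrated generator is the closed-form
$\Phi(\Delta/\sqrt{\sigma_1^2+\sigma_0^2}) \approx 0.83$, slightly below
a published 0.849 — consistent, since the published value is an
empirical AUC of one finite sample, not a binormal population value. The
acceptance comparisons use tolerances wide enough to cover exactly this
sampling gap and no wider.

## Known limitations

* Single-vessel, single-stent geometry: no bifurcations, overlapping or
  ostial stents (all excluded clinically as well).
* The FAI is unweighted; corrections for technical, anatomical and
  biological covariates of attenuation are out of scope.
* Phantom realism stops at Gaussian noise; scanner physics are not
  modelled.
* The cohort generator reproduces published margins, not joint
  distributions; estimates that depend on covariate correlation
  structure (e.g., adjusted ORs) are exercised for correctness, not for
  clinical fidelity.
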