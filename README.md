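# stentfai

Quantifying peri-stent perivascular fat attenuation on coronary CT
angiography, and testing its association with in-stent restenosis.

## The problem

After percutaneous coronary intervention, in-stent restenosis (ISR) —
recurrent diameter stenosis within the stent segment or its 5 mm edge
segments — remains a common failure mode, and vascular inflammation is a
central driver. Perivascular adipose tissue (PVAT) senses that
inflammation: inflamed vessels shift the composition of the surrounding
fat from the lipid phase (CT attenuation near −190 HU) toward the aqueous
phase (near −30 HU). The **fat attenuation index (FAI)** captures this as
the mean attenuation of PVAT voxels inside the adipose Hounsfield window
\[−190, −30\] HU: a *higher* (less negative) FAI means more inflamed fat.

Around a stent, PVAT is taken as the annular shell whose inner boundary is
the outer stent surface (radius *d*/2 from the vessel centerline for stent
diameter *d*) and whose radial thickness equals one stent diameter:

```
shell = { voxel : s(voxel) in [stent start, stent end],  d/2 < r(voxel) <= 3d/2 }
FAI   = mean { HU(voxel) : voxel in shell, -190 <= HU <= -30 }
```

where `s` is the arc-length position of the voxel's orthogonal projection
onto the centerline and `r` its radial distance from it. The severity of
restenosis is the diameter-stenosis degree

```
degree = 100 * (d_proximal_reference - d_minimal_in_stent) / d_proximal_reference   (%)
```

`stentfai` implements this measurement chain end to end — centerline
extraction from a lumen mask, perpendicular cross-section resampling,
lumen diameter profiling, PVAT shell construction, windowed attenuation
averaging — together with the downstream statistics used to evaluate FAI
as an ISR biomarker: Welch/Student group tests, chi-square/Fisher
categorical tests, LASSO feature selection with 10-fold cross-validated
`lambda.min` (model 1) and `lambda.1se` (model 2), adjusted logistic
regression, ROC/AUC with DeLong intervals and Youden cutoffs, per-vessel
subgroup ROC, Pearson correlation with Fisher-z intervals, and ICC(2,1)
inter-rater agreement.

Because no patient images are distributed, the package ships two
calibrated simulators that make every stage testable:

* `generate_phantom()` — CT phantoms (straight or helical vessels, stent,
  wall, fat compartment, noise) with exact voxel-level ground truth;
* `generate_cohort()` — synthetic patient cohorts whose FAI, covariate and
  restenosis-degree distributions are calibrated to published group
  summaries (ISR FAI −78.1 ± 6.2 HU at n = 52 vs non-ISR −87.2 ± 7.3 HU at
  n = 65, degree 50.3 ± 21.5 %, degree–FAI correlation 0.579).

## Worked example

```r
library(stentfai)

# simulate an ISR-condition phantom and measure its peri-stent FAI
ph <- generate_phantom(phantom_config(fat_mean_hu = -78.1, fat_sd_hu = 6.2,
                                      seed = 7))
cl <- extract_centerline(voxel_grid(ph$truth$lumen_mask, ph$volume$spacing))
measure_peristent_fai(ph$volume, cl, ph$truth$annotation)
#> <fai_measurement> FAI -78.3 HU (window [-190, -30] HU)
#>   7200 shell voxels (900 mm^3), 6720 in window (93.3%)

# simulate a calibrated cohort and run the core statistics
coh <- generate_cohort(cohort_config(seed = 7))
roc <- roc_curve_auc(coh$peri_stent_fai_hu, coh$isr)
roc
#> <roc_result> AUC 0.772 (95% CI 0.688-0.863), 52 positive / 65 negative
youden_cutoff(roc)$cutoff
#> [1] -81.66  # HU

isr <- subset(coh, isr == 1)
pearson_with_ci(isr$degree_of_isr, isr$peri_stent_fai_hu)$r
#> [1] 0.426
```

The measured phantom FAI (−78.3 HU) recovers the configured fat mean
(−78.1 HU) through the full geometric pipeline; the cohort ROC and the
Youden cutoff (≈ −82 HU) show FAI discriminating ISR from non-ISR as the
calibration implies; the single-seed correlation (0.426) scatters around
the configured 0.579 at n = 52.

The full pipeline — phantom pairs, cohort, group tables, LASSO models,
adjusted odds ratios, subgroup ROC, correlation, simulated two-reader
ICC — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "out/")
# writes out/cohort.csv and out/report.json
```

A thin command-line wrapper with `simulate-phantom`, `simulate-cohort`,
`measure`, `stats` and `run` subcommands is installed at
`inst/cli/stentfai.R`.

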