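---
title: "Grey-matter texture and volumetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-matter texture and volumetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graytex)
```

## The scientific problem

In behavioural-variant frontotemporal dementia and related
neurodegenerative conditions, regional grey-matter *volume* is the
standard structural MRI marker, but microstructural disruption of tissue
may precede or outpace measurable volume loss. Texture analysis
quantifies the *spatial regularity* of grey-matter intensity rather than
its amount: a homogeneous cortical region keeps high local intensity
similarity, while neuronal loss scattered below voxel resolution breaks
it up. graytex implements both measurement channels on co-registered
T1-like volumes and atlas parcellations, the group-level statistics that
compare them across disease stages, and a biomarker-style classification
comparison — together with a synthetic brain phantom that makes the
whole pipeline testable without patient data.

## The texture channel

For each region of interest (ROI) the pipeline runs four steps, each
within the ROI's own mask:

1. **Dynamic limited normalisation.** The ROI mean $\mu$ and standard
   deviation $\sigma$ are computed over in-mask voxels and intensities
   are clipped to $[\mu - k\sigma,\; \mu + k\sigma]$ (default
   $k = 3$). This bounds the influence of extreme voxels on the
   quantisation range.
2. **Uniform quantisation.** Clipped intensities are binned into $L$
   equal-width levels over the post-clip range ($L = 32$ by default,
   the conventional grey-level count for T1 radiomics):
   $\mathrm{level}(v) = \min\!\big(L,\; 1 + \lfloor L\,(v -
   v_{\min})/(v_{\max} - v_{\min})\rfloor\big)$, so $v_{\max}$ maps to
   level $L$ exactly. A constant ROI maps entirely to level 1 (with a
   warning) and yields feature value 1.
3. **Masked 3D GLCM.** For every offset $\mathbf{o}$ in the offset set
   and every in-mask voxel $\mathbf{v}$ with $\mathbf{v} + \mathbf{o}$
   also in-mask, the pair $(\mathrm{level}(\mathbf{v}),
   \mathrm{level}(\mathbf{v}+\mathbf{o}))$ is counted; symmetric
   accumulation also counts the reversed pair. Counts from all offsets
   are pooled into one matrix *before* normalising to probabilities
   $p(i,j)$ — a single documented choice; per-offset feature averaging
   differs negligibly for symmetric sets.
4. **Autocorrelation.** $A = \sum_i \sum_j i\, j\, p(i,j)$, bounded in
   $[1, L^2]$. High values mean co-occurring high levels (homogeneous
   tissue); hypointense microlesions move probability mass toward low
   levels and lower $A$.

The default offset set is the 13 unique direction vectors of the 3D
26-neighbourhood at distance $d = 1$ voxel, symmetric — rotation-robust
standard radiomics practice. The classic 2D illustration (horizontal +
vertical, $d = 1$) is available as `offsetSet("axial2")`.

Because normalisation and quantisation are per-ROI, the feature is
exactly invariant to shifting or positively rescaling all in-ROI
intensities (tested). Regions with fewer than 27 voxels, or whose GLCM
collects no valid pair, are reported missing rather than estimated.
Normalisation statistics are computed per region, including separately
for the composite region (the union of all flagged parcels), which is
analysed as its own ROI.

## The volume channel

Tissue-probability maps (GM/WM/CSF, playing the role of modulated
segmentation output) give intracranial volume
$\mathrm{ICV} = \sum_{\mathrm{voxels}} (\mathrm{GM} + \mathrm{WM} +
\mathrm{CSF}) \times v_{\mathrm{voxel}}$ in mm³. The GM map is smoothed
with a separable Gaussian kernel ($\sigma = \mathrm{FWHM} / (2.355
\cdot \mathrm{voxel\ size})$ per axis, default FWHM 8 mm,
nearest-neighbour boundary replication so constants are preserved), and
regional volume is the smoothed in-region GM sum divided by ICV —
applied to the scalar sum, which by linearity equals voxel-wise division
followed by summation. The result is a dimensionless fraction of ICV;
group contrasts on it are invariant to any global rescaling of the
maps, so no particular cm³ convention is imposed. With FWHM 0 the
composite volume is exactly additive over a partition (tested).

## Group statistics

Per region and measure, a single three-group linear model
`value ~ group + age + sex` is fitted; the three pairwise adjusted-mean
differences (HC−mild, HC−moderate, mild−moderate) come from contrasts of
that one fit, with t-based 95% CIs and two-sided p-values on the model's
residual degrees of freedom. Using one model (rather than three
two-group fits) guarantees the structural identity
$(\mathrm{HC}-\mathrm{moderate}) = (\mathrm{HC}-\mathrm{mild}) +
(\mathrm{mild}-\mathrm{moderate})$ exactly in every region. Constant
covariates are dropped from the design (the contrast then reduces to the
two-sample case); genuinely rank-deficient regions are skipped with a
warning.

Multiplicity is controlled with Benjamini–Hochberg FDR *across regions*,
one family per (measure × contrast); no correction is applied across the
three contrasts within a region. Effect sizes are the adjusted mean
difference divided by the model residual SD — a covariate-adjusted
Cohen's d (the effect-size metric was a genuinely open choice; d was
preferred over partial eta-squared because signed per-contrast maps and
their volume-minus-texture differences are needed). Z-scoring against
the control group's mean and SD is provided for visualisation only; all
inference runs on raw values.

Texture–volume association is a per-region OLS of volume on
autocorrelation with age and sex (optionally group) as covariates, with
FDR across regions. Demographic comparisons use the Wilcoxon rank-sum
test (normal approximation with tie correction) for continuous
variables, Fisher's exact test for 2×2 tables and chi-squared for
larger ones — both categorical tests are available since either
convention is common.

## Classification

The classifier is logistic regression — the minimal model for which a
two-feature "combined" model is well defined; with a single feature its
score is a monotone transform of that feature, so the AUC coincides with
simple thresholding. Scores are produced by leave-one-out
cross-validation and pooled into one ROC. Two numerical choices matter:

* **Per-fold standardisation.** Features are z-scored using the
  training fold's statistics (applied to the held-out subject), keeping
  fits scale-free regardless of the feature's units.
* **Class-balanced fold weights.** Pooled LOOCV-ROC is known to be
  pessimistically biased under the null: removing a positive subject
  lowers the training prior, which lowers the held-out positive's
  predicted probability, anti-correlating scores with labels. Balancing
  class weights in each fold removes the prior term of this bias; the
  permutation-null mean AUC is then within sampling error of 0.5
  (tested over 100 permutations).

Perfect separation in a fold triggers a small ridge-penalised IRLS
fallback (penalty on non-intercept coefficients only); a fold that loses
a class entirely scores by the fold prior, with a warning. AUC is the
trapezoid/Mann–Whitney value with ties counted ½. The operating point
maximises Youden's $J = \mathrm{sens} + \mathrm{spec} - 1$ on the pooled
out-of-fold scores, ties broken toward higher sensitivity. Paired AUCs
are compared with DeLong's structural-components test; identical score
vectors have zero variance and return $p = 1$ by convention.

## The phantom generator

`syntheticConfig()` / `simulateCohort()` draw a three-group cohort on a
shared deterministic atlas (ellipsoidal parcels on a lattice inside an
ellipsoidal brain mask; label 0 background; every parcel also
contributes to the composite region). Per subject:

* age ~ Normal(group mean, group SD), sex ~ Bernoulli(group female
  proportion); defaults encode a 33/21/11 cohort aged 63.1 ± 7.9,
  61.5 ± 8.5 and 64.4 ± 9.3 years with female proportions
  0.363/0.047/0.181;
* GM density inside regions = baseline (default 0.8) × (1 − α_g) +
  subject offset + age slope × (age − cohort mean) + smooth random
  field + white noise, clipped to [0, 1]. The smooth field is
  Gaussian-filtered white noise (FWHM default 4 mm,
  σ = FWHM/2.355) rescaled to the white-noise SD, so the noise-free
  limit is exactly constant;
* tissue maps: GM = density; WM/CSF fill the remaining brain fraction
  80/20, so ICV equals brain volume;
* the T1-like image is 300 + 700 × density (arbitrary units; texture is
  shift/scale invariant), after which hypointense voxels are implanted:
  a partial-volume fraction (`pvFraction`, default 0.05, identical in
  all groups) plus the group's microlesion fraction ρ_g (with
  subject-level jitter), each multiplied by `lesionIntensityFactor`
  (default 0.3).

Three design points deserve emphasis:

* **Lesions are intensity-only.** Tissue maps carry the pre-lesion
  density, so disruption degrades texture without changing measured
  volume — the dissociation the pipeline is designed to detect, and a
  model of sub-voxel microstructural damage below volumetric
  resolution. Atrophy (α) conversely lowers volume while texture,
  being shift-invariant, is largely unaffected.
* **The partial-volume floor is essential to the mechanism.** With
  per-ROI equal-width quantisation, a low-intensity tail anchors
  $v_{\min}$; healthy tissue then occupies the *upper* grey levels, and
  each additional lesion voxel moves co-occurrence mass toward low
  levels, lowering autocorrelation monotonically in ρ (tested at
  ρ ∈ {0, 0.15, 0.3} over 20 seeds). Without such a floor, lesions
  would instead stretch the quantisation range and push normal tissue
  into top bins, *raising* the statistic.
* **Between-subject heterogeneity** (`subjectGmSd` = 0.06 density
  units, `subjectRhoSd` = 0.05) makes group distributions overlap the
  way clinical cohorts do; without it every contrast saturates
  (AUC = 1) and calibration properties become untestable. Density
  saturation at 1.0 also couples texture weakly to a subject's overall
  GM level, a small within-group texture–volume association the model
  shares with real data.

Default disease effects are α = (0, 0.15, 0.18) and
ρ = (0, 0.10, 0.30) for HC/mild/moderate: both patient groups atrophy
to a similar degree while disruption clearly progresses, so disease
*stage* separates on texture more than on volume. What the phantom does
**not** emulate: cortical folding and anatomy, scanner protocols, bias
fields, skull, registration error, and any region-specific disease
topography — passing tests therefore validate the measurement and
inference machinery, not anatomical fidelity on real scans.

## Numerical choices and degenerate inputs

* FWHM↔σ conversion uses the 2.355 constant throughout; kernels are
  truncated at 4σ and renormalised to unit mass.
* Degenerate ROIs (σ = 0) quantise to level 1 and score exactly 1.
* Empty GLCMs, sub-minimal regions (< 27 voxels) and zero-SD control
  references propagate as explicit `NA` with warnings, never silently.
* Missing feature values are excluded pairwise per region with a logged
  count.
* Atlas placement is a deterministic function of the configuration;
  cohort draws are governed entirely by the config seed, and the
  pipeline re-run with the same configuration is bit-identical.

## Problem sizes

The shipped test-suite and acceptance script sizes are the package's
own validation conditions: GLCM oracle equivalence on 1000 random
masked grids up to 6³ voxels at up to 8 levels; FDR equivalence on 1000
random p-vectors plus a 160-region null at 200 replicates; ANCOVA
coverage/size at group sizes 33/21/11 over 500 replicates; DeLong
calibration at n = 60 over 500 replicates; LOOCV permutation null over
100 draws; generator monotonicity over 20 seeds per parameter level;
and the texture/volume dissociation on twenty 28³-voxel cohorts of 65
subjects. The acceptance script runs the full default conditions
(48³ grid, 8 parcels + composite, 65 subjects).

## Known limitations

Cross-sectional only; no voxel-wise inference; autocorrelation is the
only texture feature (the GLCM machinery is generic, but other Haralick
statistics are deliberately out of scope); registration, segmentation
and bias correction are assumed done upstream — the package requires
pre-aligned image/atlas pairs and never resamples. The phantom's effect
sizes are free parameters, not calibrated to any particular cohort's
printed tables.
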