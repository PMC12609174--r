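# graytex

Region-wise grey-matter **texture** and **volumetry** analysis for
staging neurodegeneration from structural MRI, with a synthetic
brain-phantom generator for end-to-end validation.

In dementias such as behavioural-variant frontotemporal dementia,
regional grey-matter volume is the standard structural marker, but
microstructural disruption may progress even where volume appears
stable. graytex measures both channels on co-registered T1-like volumes
and integer label atlases and compares them statistically, for
researchers who want a tested, reproducible region-of-interest pipeline
rather than ad-hoc scripts:

* **Texture**: per-ROI grey-level co-occurrence matrix (GLCM)
  autocorrelation. Within each region's mask, intensities are clipped
  to μ ± 3σ (dynamic limited normalisation), binned uniformly into
  L = 32 levels, co-occurrences accumulated over the 13 symmetric 3D
  neighbour directions at distance 1, and the feature computed as

  A = Σᵢ Σⱼ i · j · p(i, j),   bounded in [1, L²],

  where p(i, j) is the pooled pair-probability matrix. High A =
  spatially homogeneous tissue; scattered hypointense microlesions
  lower it.
* **Volume**: intracranial-volume-normalised regional grey matter from
  GM/WM/CSF tissue-probability maps, after 8-mm FWHM Gaussian
  smoothing.
* **Group statistics**: per-region three-group ANCOVA
  (`value ~ group + age + sex`) with all pairwise adjusted-mean
  differences, t-based 95% CIs, Benjamini–Hochberg FDR across regions,
  covariate-adjusted Cohen's d effect sizes and volume-minus-texture
  effect maps, z-scoring against controls, texture–volume regressions,
  and demographic tests (Wilcoxon, Fisher, chi-squared).
* **Classification**: leave-one-out cross-validated logistic scores for
  volume-only, texture-only and combined models; pooled ROC with
  Youden-optimal operating point; DeLong test for paired AUCs.
* **Phantom cohorts**: a seeded generator producing NIfTI images,
  tissue maps, atlases and manifests with controllable atrophy (volume
  channel) and microlesion disruption (texture channel), so every
  downstream stage is testable without patient data.

## Worked example

Simulate a small three-group cohort, extract both measures, and compare
groups:

```r
library(graytex)

cfg <- syntheticConfig(gridShape = c(28L, 28L, 28L), nRegions = 4L,
                       groupSizes = c(HC = 12L, mild = 10L, moderate = 8L),
                       seed = 11L)
cohort <- simulateCohort(cfg)
cohort
#> SyntheticCohort: 30 subjects (HC=12, mild=10, moderate=8)
#>   shared atlas with 4 parcels on 28x28x28 grid

features <- extractCohortFeatures(cohort, fwhmMm = 8)
ctr <- ancovaContrasts(features, cohort@manifest, "autocorrelation")
subset(ctr, region_id == compositeId(cohort@atlas))
#>    region_id         measure group_i  group_j difference     ci_low   ci_high            p        p_fdr
#> 13         5 autocorrelation      HC     mild   32.66272  -3.890369  69.21581 7.761964e-02 2.075097e-01
#> 14         5 autocorrelation      HC moderate  210.10774 171.179813 249.03567 3.636394e-11 9.090985e-11
#> 15         5 autocorrelation    mild moderate  177.44502 136.806747 218.08329 2.610776e-09 4.351294e-09
```

Each row is one pairwise contrast in the composite region (id 5, the
union of the 4 parcels): the adjusted mean difference I − J, its 95% CI
and the raw and FDR-adjusted p-values. Here texture separates moderate
from mild dementia decisively (difference 177, p_FDR ≈ 4e-9) while the
HC-vs-mild difference is smaller and, in this small cohort, not
significant after correction.

```r
cls <- classifyGroups(features, cohort@manifest,
                      regionId = compositeId(cohort@atlas),
                      groups = c("HC", "mild"))
cls$volume
#> RocResult [volume]: AUC 0.850, sens 0.70 / spec 0.83 at 0.6729 (n = 22)
cls$autocorrelation
#> RocResult [autocorrelation]: AUC 0.683, sens 0.70 / spec 0.75 at 0.5188 (n = 22)
cls$delong
#> DeLong: AUC 0.850 vs 0.683, z = 1.575, p = 0.1153
```

The AUCs are leave-one-out out-of-fold, with sensitivity/specificity at
the Youden-optimal threshold; the DeLong test finds no significant
difference between the two markers at this sample size.

A whole configured run (simulate → extract → statistics → classify,
with CSV outputs and a hashed run manifest) is one call:
`runPipeline("config.yaml")` — see `?readPipelineConfig` for the schema
and `vignettes/graytex-methods.Rmd` for the models, parameter defaults
and design choices.

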