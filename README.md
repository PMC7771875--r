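# aptwquant

Quantification of amide proton transfer weighted (APTw) CEST MRI and
statistical evaluation of APTw summary statistics as presurgical markers of
glioma grade.

APTw imaging saturates amide protons of mobile proteins at +3.5 ppm
downfield of water and reads the transferred saturation off the water
signal. From the sampled Z-spectrum Z(δ) = S(δ)/S₀ the package computes the
asymmetry score

    APTw = (1/Δ) ∫ [Z(−δ) − Z(δ)] dδ   over δ ∈ 3.5 ± 0.4 ppm,  Δ = 0.8 ppm

per voxel, after B0 correction from the bottom of the Z-spectrum. Because
high-grade gliomas (WHO 3–4) overexpress mobile proteins relative to
low-grade (WHO 2) tumors, ROI summary statistics of this score (mean, max,
min, range) discriminate grade; the package implements the full evaluation:
Mann-Whitney U with tie handling and exact enumeration, empirical ROC with
Youden-midpoint cutoffs and DeLong intervals, fixed-threshold classifiers,
a combined logistic model with Nagelkerke / Hosmer-Lemeshow / omnibus
diagnostics, and molecular-subgroup (IDH, MGMT) descriptives.

It ships two data sources:

* a packaged 26-subject clinical cohort (histology, IDH/MGMT status,
  initial radiological read, APTw mean/max/min in percent), and
* a seeded multi-pool Lorentzian phantom generator whose tissue classes are
  calibrated so the full pipeline recovers nominal APTw values (NAWM 0%,
  LGG 1.49%, HGG 2.60%, MET 2.49%), for end-to-end testing of the image
  stages without any download.

## Worked example

```r
library(aptwquant)

cohort <- load_table1_fixture()          # 26 subjects
final  <- apply_exclusions(cohort)       # 22: 16 HGG, 6 LGG
table(final$group)
#> HGG LGG
#>  16   6

roc_curve(final$aptw_max, final$group)
#> <roc_result> AUC 0.948 (95% CI 0.844-1.000, DeLong), p = 0.001522
#>   optimal cutoff 2.480: sensitivity 93.8%, specificity 100.0%

classify_cohort(final, threshold_rule("max", 2.48))
#> <cohort_classification> max > 2.48%: 21/22 gliomas correct (sens 93.8%, spec 100.0%)

model <- fit_combined_model(final)       # grade ~ mean + max + range
round(roc_curve(model$fitted, model$groups)$auc, 3)
#> [1] 0.958
round(nagelkerke_r2(model), 3)
#> [1] 0.72
```

The ROC cutoff 2.48% is the Youden-optimal midpoint between the highest LGG
max (2.35%) and the lowest HGG max above it (2.61%): a maximal APTw above
2.48% calls the tumor high grade, and on this cohort that rule misses a
single glioblastoma with atypically low APTw. The combined logistic model
raises the AUC to 0.958.

The image side works the same way from a synthetic acquisition:

```r
spec <- phantom_spec(c(16, 16, 3), noise_sd = 0.002, seed = 7,
                     lesions = list(list(center = c(8, 8, 2),
                                         radius = c(4, 4, 1), class = "HGG")))
ph  <- build_lesion_phantom(spec)
map <- compute_aptw_map(ph$offset_stack, ph$s0_volume)
roi_stats(map, find_max_roi(map, ph$lesion_mask, ph$exclusion_mask))
#> <roi_stats> n = 10: mean 2.89%, max 3.67%, min 2.20%, range 1.47%
```

A thin CLI over the same functions lives at `inst/cli/aptw.R`
(subcommands `simulate-phantom`, `compute-aptw`, `roi-stats`,
`simulate-cohort`, `cohort-stats`, `classify`, `report`), e.g.

```sh
Rscript inst/cli/aptw.R report --table fixture
```

## Layout

```
R/                  implementation (Z-spectrum engine, codec, maps, ROI,
                    phantom generator, cohort, classifiers, statistics,
                    pipeline)
inst/extdata/       packaged cohort table (CSV)
inst/cli/aptw.R     command-line front end
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (models, calibration, conventions)
```
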