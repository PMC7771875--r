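---
title: "APTw quantification and glioma grading: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{APTw quantification and glioma grading: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptwquant)
```

## The contrast and the quantity being computed

Amide proton transfer weighted (APTw) imaging is a chemical exchange
saturation transfer (CEST) technique: off-resonance radio-frequency
saturation applied at the amide proton frequency (+3.5 ppm downfield of
water) is transferred to the water pool by chemical exchange, attenuating the
water signal in proportion to the mobile protein and peptide content of the
tissue. Sampling the normalized water signal $Z(\delta) = S(\delta)/S_0$
across saturation offsets $\delta$ yields the Z-spectrum; the APTw score is
the asymmetry of that spectrum about water, averaged over a window around
the amide resonance:

$$\mathrm{APTw} \;=\; \frac{1}{\Delta}\int_{3.5 - \Delta/2}^{3.5 + \Delta/2}
\left[ Z(-\delta) - Z(\delta) \right]\, d\delta, \qquad \Delta = 0.8\ \mathrm{ppm}.$$

The asymmetry reference subtracts direct water saturation and the symmetric
part of the semisolid magnetization transfer (MT) background, so in healthy
white matter the score sits near zero while proliferative tumor tissue, with
elevated mobile protein content, scores positive. The score is dimensionless
(a fraction of $S_0$) and is reported throughout in percent.

Because gliomas of WHO grades 3–4 overexpress mobile proteins relative to
grade 2 tumors, summary statistics of APTw inside the lesion (mean, maximum,
minimum, and range = max − min over a region of interest) carry grading
information, and the package evaluates them as presurgical classifiers of
low-grade (LGG) versus high-grade (HGG) glioma.

## The per-voxel pipeline

`normalize_zspectrum()` divides the saturated acquisitions by the reference
$S_0$ and converts offsets from Hz to ppm (42.576 MHz/T; positive ppm
downfield of water). The default protocol is a 3 T acquisition with
$B_1 = 2\,\mu$T, five 100 ms saturation pulses with 61 ms gaps, and 21
offsets from −610 to +610 Hz (±4.78 ppm).

**The $S_0$ convention.** The reference acquisition uses far off-resonant
pre-saturation at −150 ppm. Strictly this is not an unsaturated image — it
retains a trace of direct and semisolid saturation — but the package treats
it as the normalization denominator without further correction, because the
asymmetry analysis removes symmetric background by construction. The
`s0_offset_ppm` field of `saturation_protocol()` records the convention; no
MT-background subtraction beyond the asymmetry itself is attempted.

**B0 correction** (`correct_b0()`). Field inhomogeneity shifts each voxel's
spectrum; the water center is relocated from the bottom of the Z-spectrum.
The 21 samples are interpolated with a natural cubic spline, evaluated on a
0.01 ppm grid over ±1.5 ppm, and the grid argmin is refined by a single
three-point parabolic fit before the spectrum is re-centered and resampled
on the nominal grid. The parabolic refinement matters: the asymmetry windows
sit on the steep flanks of the water line, where the score changes by
roughly 0.1–0.15 percentage points per 0.01 ppm of center error, so leaving
the minimum quantized to the search grid would make the score visibly depend
on the (physically meaningless) phase of the B0 offset relative to the grid.
With refinement the score is stable to better than 0.05 percentage points
for shifts up to ±0.5 ppm, which the suite property-tests. Spectra without
an interior minimum near water (no dip, or a minimum on the search-interval
boundary) are rejected as uncorrectable rather than silently shifted.

**The window integral** (`mtr_asym_integral()`). The 21-offset grid spaces
samples ~0.48 ppm apart, so at most two samples fall inside each 0.8 ppm
window; the integral is therefore evaluated on the spline interpolant with a
0.01 ppm trapezoid rule and divided by the window width. This makes the
result a window *average* in units of $S_0$, independent of how the sampling
grid happens to align with the window — the interpretation used everywhere
in the package. Windows that are not fully covered by the sampled offsets on
both sides raise a coverage error.

**The stored-intensity codec** (`encode_aptw_intensity()`). Scanner
pipelines store APTw as 12-bit integers $C$ with
$\mathrm{APTw} = (C - 2048)/(10 \cdot 2000)$: code 2048 is zero, one code
unit is 0.005 percentage points, and the representable range is ±10.24
percent, clamped with a saturation warning. The round trip over all 4096
codes is exact and is tested exhaustively.

`compute_aptw_map()` runs this pipeline per voxel over a 4D offset stack,
counts non-positive references and uncorrectable spectra in a QC summary,
and marks those voxels missing rather than zero.

## ROI quantification

Clinical practice places one circular ROI "of 10 pixels" at the point of
highest APTw signal inside the lesion, avoiding hemorrhagic, cystic and
necrotic tissue. Two readings of "10 pixels" exist (member count versus
diameter); the package reads it as a **10-member digital disc** — the ten
pixels nearest the center, ties broken by row then column — and exposes the
count as a parameter. The search (`find_max_roi()`) is two-dimensional per
slice, mirroring how ROIs are drawn on slices, and maximizes the ROI mean
over all admissible centers with deterministic tie-breaks (lowest slice,
then row, then column). Admissibility requires every member voxel to be
inside the lesion mask, outside the exclusion mask and quantified; a missing
member disqualifies the center rather than being skipped. The exclusion mask
is an input: the package does not attempt to detect necrosis automatically.
Because the clinical placement was manual, the automated maximal-mean search
is a reproducible surrogate, and outputs are labelled as such. A whole-lesion
single-slice variant (`whole_lesion_stats()`) summarizes every admissible
lesion voxel on one slice. The search is verified against brute-force
exhaustive placement on random instances up to 64×64×8.

## The synthetic generator

No raw images accompany the clinical table, so the image stages are
exercised on synthetic multi-pool phantoms. Each tissue class is a sum of
Lorentzian saturation lines on the normalized scale:
$Z(\delta) = 1 - \sum_i A_i / (1 + ((\delta - c_i)/(w_i/2))^2)$, with pools
for direct water saturation (0 ppm), a broad semisolid MT pool (−2.4 ppm,
amplitude 0.10, width 25 ppm), a relayed-NOE pool (−3.5 ppm, amplitude
0.03, width 4 ppm) and the amide pool (+3.5 ppm, width 3 ppm) whose
amplitude carries the class contrast. A Lorentzian line model was chosen
over Bloch-McConnell pulse-train simulation deliberately: the package's
claims concern the asymmetry statistic and the downstream analysis, not
saturation physics, and a closed-form generator admits exact oracles
(window averages of Lorentzians have an antiderivative), seeded
determinism, and transparent calibration.

The water line width (5.6 ppm full width at half maximum, giving
$Z(\pm 3.5\,\mathrm{ppm}) \approx 0.5$) reflects the broad direct +
residual-MT water dip of continuous-equivalent 2 µT saturation at 3 T. It
is also the numerically safe regime: much narrower water lines are
undersampled by the 21-offset grid and the resulting spline ringing leaks
into the asymmetry windows.

**Calibration.** Class amide amplitudes are solved so that a clean spectrum
pushed through the *actual* pipeline returns the class's nominal APTw —
0% for normal-appearing white matter, 1.49% (LGG), 2.60% (HGG), 2.49%
(metastasis); the CSF-like class is a bare water line scoring 0 by symmetry.
The solver seeds from the closed-form window averages and refines by secant
iteration through the engine, so the calibration absorbs the pipeline's
small interpolation bias; generator→engine closure within 0.2 percentage
points is tested for every class. Amide amplitudes order NAWM < LGG < HGG
by construction.

Phantoms (`build_lesion_phantom()`) place ellipsoidal lesions (semi-axes in
voxels, matching anisotropic 2×2×4 mm voxels) with optional necrotic cores
that populate the exclusion mask, a linear-in-space B0 offset field, and
i.i.d. Gaussian noise on the normalized signal (default sd 0.005; a Rician
option exists for the low-SNR magnitude regime, but at the SNR of interest
Gaussian noise is adequate and analytically checkable). All randomness
flows from one integer seed, and the caller's RNG state is preserved.

Cohorts (`simulate_cohort_table()`) draw per-subject (mean, max, min)
triples from group-level trivariate normals with equicorrelation 0.8 —
the three statistics of one subject are strongly concordant in practice —
rejection-sampled to satisfy min ≤ mean ≤ max. Group means and SDs default
to the clinical cohort's values (HGG 2.60±0.97, LGG 1.49±0.50 for the mean,
and correspondingly for max and min; the metastasis SDs are computed from
its two subjects).

What the generator does *not* emulate: anatomy (no brain template, no
partial-volume mixing), scanner reconstruction, motion, multi-pool exchange
dynamics, or Gd-enhancement. Passing tests on these phantoms demonstrates
the correctness of the quantification and statistics, not the clinical
performance of APTw on real scanners.

## Cohort assembly and classifiers

The packaged 26-subject table carries histology, grade group (grade 2 →
LGG; grades 3–4 → HGG; the one grade-3 anaplastic astrocytoma is grouped
with HGG), IDH/MGMT status, the initial conventional-MRI radiological read,
and the APTw summary statistics. `apply_exclusions()` removes the two
low-grade subjects with radiological progression after histological
sampling and then any group below the minimum analyzable size (4), which
removes the two metastases; the result is the 22-subject analysis cohort
(16 HGG, 6 LGG). The operation records reasons and is idempotent.

Threshold rules are **strictly greater-than** (a value exactly at the
cutoff predicts LGG), matching how the clinical cutoffs are stated; the
boundary convention is config-exposed. Metastases pass through threshold
rules for reporting but never enter sensitivity or specificity, which are
computed over gliomas only; an empty group leaves its rate missing, not
zero.

The combined model is a maximum-likelihood logistic regression of grade on
mean, max and range (range derived as max − min). Fitting delegates to
IRLS (`stats::glm`, epsilon 1e-8, maxit 25) wrapped with explicit
degeneracy and separation detection — an aliased design errors, diverging
coefficients warn and set a flag, never silently. On the packaged cohort
the fitted probabilities have AUC 0.958 and Nagelkerke R² 0.72.

**Classification cutoffs for the combined model.** Two conventions coexist:
the conventional 0.5 classification cutoff, under which exactly subjects 3
and 17 are upgraded to HGG and subject 7 (a glioblastoma with unusually low
APTw) downgraded to LGG; and a reported probabilistic cutoff of 0.38, under
which subject 11 (fitted probability 0.41, a histological LGG with
atypically high APTw) crosses the boundary as well. `predict_combined()`
defaults to 0.38 and takes the cutoff as an argument; the audit tables make
the consequences of either choice explicit. The Youden-optimal cutoff of
the fitted probabilities (~0.62) reproduces the 93.8%/100%
sensitivity/specificity pair.

## The statistical battery

* **Mann-Whitney U** (`mann_whitney()`): midranks for ties; U reported from
  the smaller rank-sum side (the convention of common clinical software);
  the asymptotic p is the tie-corrected normal approximation *without*
  continuity correction, which is what reproduces the printed two-sided
  p-values (.005/.002/.055/.032). An exact two-sided p (probability of a
  rank sum at least as far from its null mean) is additionally computed —
  from the closed-form tie-free null when there are no ties, otherwise by
  full enumeration of group assignments when at most 2×10⁵ exist. The
  asymptotic p targets the mid-p of the discrete null (exact p minus half
  the observed point mass); the suite tests that correspondence, and the
  exact test's size at the cohort's group sizes (16 vs 6) is 0.049.
* **ROC** (`roc_curve()`): empirical curve under the strictly-greater rule;
  candidate cutoffs are midpoints between adjacent distinct observed scores
  — the convention that reproduces the printed cutoffs 1.90 / 2.48 / 0.91 —
  AUC as the concordance probability with half-credit ties (equal to the
  trapezoidal area, and to the U-statistic identity
  $\mathrm{AUC} = U_{\mathrm{pos}}/(n_1 n_2)$ on tie-free data, which is
  property-tested); the optimal cutoff maximizes Youden's J with ties broken
  toward higher specificity. Confidence intervals use the DeLong variance;
  they are reported but not used as pass/fail anchors, since other software
  may use a different standard error.
* **Model diagnostics**: Nagelkerke R² (Cox-Snell rescaled by its
  maximum), the omnibus likelihood-ratio test, and Hosmer-Lemeshow over
  deciles of fitted probability with ties kept together. The
  Hosmer-Lemeshow statistic is binning-sensitive; its p-value is
  descriptive only and is not asserted against any external value.
* **Shapiro-Wilk** wraps the Royston algorithm (`stats::shapiro.test`).
* **Subgroup descriptives** (`subgroup_means()`) stratify by MGMT promoter
  methylation or IDH mutation status, drop unknown-status subjects with a
  reported count, and flag strata below n = 4 as insufficient for testing
  (on the packaged cohort: MGMT-methylated 2.38% vs non-methylated 1.92%;
  IDH wildtype 2.26% vs mutant 2.30% — descriptive only).

One documented inconsistency: the printed U for the mean column (9.0)
disagrees with the mean ranks printed alongside it (13.88/5.17, which give
rank sum 31 and U = 10) and with the printed AUC (.896 = 1 − 10/96). The
package computes U = 10; the mean-column U is therefore not used as an
anchor anywhere, while max/min/range (5/22/19) reproduce exactly.

## Numerical and display choices

* Natural cubic splines (`stats::splinefun`) everywhere a spectrum is
  interpolated; 0.01 ppm fine grids for both the minimum search and the
  window quadrature.
* Normalized signals are clamped to [0, 1.1] with a warning (noise
  headroom); negative raw intensities are rejected.
* Display rounding in rendered tables is half-away-from-zero with a 1e-9
  fuzz (so 0.935 renders 0.94, as clinical tables print), at 2 dp for
  descriptives, 3 dp for AUC, 1 dp for sensitivity/specificity. All CSV and
  JSON artifacts keep full precision.
* `run_pipeline()` is deterministic under its seed and writes a manifest
  with MD5 content hashes; two runs with the same config produce identical
  manifests.

## Problem sizes

The suite exercises phantoms up to 32×32×8 voxels (the ROI-search oracle
equivalence), 200-replicate noise calibrations, 500-replicate power checks
of the cohort simulator, and a 10,000-replicate null calibration of the
exact Mann-Whitney test; the full suite runs in well under a minute on one
CPU. Larger volumes change nothing structurally — the per-voxel pipeline is
embarrassingly parallel — and were not needed to validate correctness.

## Known limitations

* The Lorentzian generator cannot probe saturation-physics questions
  (B1 dependence, exchange rates, duty cycle); its realism is anchored only
  at the level of the asymmetry statistic.
* The asymmetry analysis itself mixes APT with relayed-NOE and residual MT
  asymmetry; the package computes the conventional mixed score and does not
  attempt multi-pool decomposition.
* The automated maximal-mean ROI is a surrogate for expert placement; on
  real data the two can differ wherever image artifacts survive the
  exclusion mask.
* With 22 subjects the clinical statistics are fragile: confidence
  intervals are wide, the Hosmer-Lemeshow test is near-powerless, and the
  molecular subgroup strata (n = 3 non-methylated) are descriptive only.
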