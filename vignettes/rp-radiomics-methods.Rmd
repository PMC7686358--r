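---
title: "Radiomic prediction of radiation pneumonitis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic prediction of radiation pneumonitis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Grade >= 2 radiation pneumonitis (RP) is the most common symptomatic
toxicity after stereotactic body radiation therapy (SBRT) for early-stage
lung cancer. Classical predictors are dose-volume histogram (DVH) summaries
of the lung — the percentage of lung receiving more than x Gy (Vx) and the
mean lung dose (MLD). `rpradiomics` implements an alternative: quantify the
*texture* of the irradiated lung on the pretreatment planning CT, on the
hypothesis that lungs whose parenchyma already shows a particular spatial
structure react differently to dose. The pipeline is:

1. **Dose-threshold ROIs.** From co-registered CT, dose, lung and GTV
   grids, build four regions LV0, LV5, LV10, LV20 — the lung volume
   excluding the gross tumor volume (GTV) receiving *strictly more than*
   0, 5, 10 and 20 Gy. The strict inequality makes the masks nested.
2. **486 radiomic features per (patient, ROI).** 54 features — 14
   histogram statistics and 40 texture features from four gray-level
   matrices (GLCM, GLRLM, GLSZM, NGTDM) — computed on the original volume
   and on each of 8 single-level 3-D wavelet subbands: 54 x 9 = 486.
3. **Selection-frequency signatures.** Per balanced subset, repeated
   LASSO logistic regression on bootstrap resamples; the four features
   most frequently assigned nonzero coefficients form the signature.
4. **Balanced-subset ensemble.** The training cohort is imbalanced
   (roughly 9% RP). All positives plus a disjoint tenth of the negatives
   form each of 10 balanced subsets; one logistic model is fitted per
   subset and the ensemble prediction is the arithmetic mean of the 10
   member probabilities.
5. **Evaluation.** AUC (rank formulation), sensitivity, specificity and
   accuracy; the operating threshold is Youden-optimal on training and
   frozen when applied to the test cohort.

A DVH baseline ensemble (candidates V5, V10, V20, MLD; the most frequently
LASSO-selected parameter combination per subset) is fitted with the same
subset structure for comparison.

## The synthetic cohort generator

No patient volumes ship with the package; `cohort_spec()` /
`generate_cohort()` produce seeded synthetic cohorts with the statistical
structure the analysis needs, so every stage is testable end to end.

Each patient is an ellipsoidal "lung" (semi-axes ~0.38 of the grid, mildly
jittered per patient) with a spherical GTV (radius 3–5 voxels) placed
randomly inside it. Defaults mimic a planning CT: 48^3 grid at (2.0, 1.0,
1.0) mm spacing, lung baseline intensity −800 with texture amplitude 50
(HU-like). Dose is a radial Gaussian centred on the GTV centroid,
`dose_peak * exp(-d^2 / (2 * dose_falloff^2))` with a 48 Gy peak (a typical
SBRT prescription) and a 10-voxel falloff; because dose decays
monotonically with distance, the LVx masks are nested by construction, and
the random GTV position makes V5/V10/V20/MLD vary across patients.

The **planted effect** follows the direction reported for this kind of
analysis: RP-positive lungs have *higher voxel-neighbour spatial
correlation*. Lung texture is white Gaussian noise smoothed with a
separable Gaussian kernel whose standard deviation is
`correlation_length_pos` (default 2.0 voxels) for positives and
`correlation_length_neg` (default 1.0) for negatives. The smoothed field
is renormalised to unit marginal variance, so the *histogram* of
intensities is matched between classes and the class difference lives in
the spatial autocorrelation — which GLCM correlation measures directly.
The 2:1 kernel ratio was chosen once as a clearly-expressed but not
caricatured effect: it yields GLCM correlation values around 0.87 vs 0.60,
standardised mean difference ~2, comparable to a strong imaging biomarker.

What the generator does *not* emulate: real bronchovascular anatomy,
respiratory motion, scanner-specific noise and reconstruction kernels, or
any dose–outcome association (the labels are independent of the dose
field, so the DVH baseline has no true signal — the synthetic study only
tests that the radiomic model recovers the planted texture effect and
outperforms the baseline *here*, not that it would on real patients).
Passing tests therefore demonstrate correctness of the machinery and
recoverability of a known effect, nothing about clinical validity.

## Feature definitions and numerical conventions

* **Quantization**: uniform (equal-width) binning of in-mask intensities
  into `Ng = 32` levels, recomputed per (ROI, domain); min -> 1,
  max -> `Ng`. Equal-width binning is monotone and affine-invariant, so
  features are unchanged by linear intensity rescaling.
* **GLCM**: distance 1, the 13 unique 3-D directions merged into one
  symmetric matrix (each pair counted in both orders), probability
  normalised. Nine features: energy, contrast, correlation, homogeneity,
  variance, sum average, entropy, dissimilarity, autocorrelation.
  Correlation is `sum p(i,j)(i - mu)(j - mu) / sigma^2` on the symmetric
  matrix's marginal moments.
* **GLRLM**: maximal same-level in-mask collinear runs, 13 directions
  accumulated into one matrix; 13 classical features (SRE ... RLV). Run
  percentage uses `13 x` the voxel count as its denominator so the merged
  matrix keeps it in (0, 1].
* **GLSZM**: 26-connected equal-level zones (a small union-find kernel in
  C++, cross-checked against an R flood-fill oracle in the tests); 13
  features mirroring the run-length set.
* **NGTDM**: 26-neighbourhood Amadasun–King features (coarseness,
  contrast, busyness, complexity, strength) restricted to in-mask
  neighbours.
* **Degenerate rules** (all deterministic): skewness/kurtosis of
  zero-variance data are 0; GLCM correlation with zero marginal variance
  is 0; NGTDM coarseness with a zero denominator is capped at 1e6; any
  remaining non-finite feature is mapped to 0 with a warning. Constant
  in-mask regions quantize to a single level and are flagged.
* **Out-of-mask locality**: out-of-mask voxels never enter a pair, run,
  zone or neighbourhood. Features on the *original* domain depend only on
  in-mask intensities; wavelet-domain features additionally see in-mask
  structure through the filter support, as any convolution-based domain
  must.

## The wavelet transform

The eight subbands come from applying the low-pass (L) or high-pass (H)
analysis filter along each of x, y, z — labels are written x-major
(`"LHH"` = L in x, H in y, H in z). The transform is *undecimated*
(stationary), so each subband lives on the original grid and the ROI mask
applies unchanged — no resampling step, no interpolation choice. Filters
are the orthonormal Coiflet-1 pair (configurable; Haar available) scaled
by `1/sqrt(2)` per axis, making the analysis a tight frame: under periodic
extension the summed energy of the eight subbands equals the input energy
exactly, which the test suite asserts to 1e-10. Feature extraction uses
symmetric (reflection) boundary handling, the conventional choice for
images, where the identity is approximate near edges. For speed the
extractor crops each volume to the ROI bounding box padded by the filter
length before transforming; in-mask feature values are unaffected.

## Signature construction and the ensemble

Within each balanced subset the features are z-standardised, constant
columns dropped, and `n_repeats` LASSO fits run. Each repeat draws a
*stratified bootstrap* (within-class resampling with replacement,
preserving class sizes) and picks the penalty by 3-fold stratified
cross-validation (`lambda.min`); features with nonzero coefficients are
recorded. Features are ranked by selection count with deterministic
tie-breaks — higher mean absolute coefficient, then lexicographic name —
and the top 4 form the signature. The repeat loop, fold assignment and
bootstrap all run inside a single seeded RNG scope, so results are
bit-reproducible.

Design points that were genuinely open, and the choices made:

* *What varies across the repeats*: the resample and the CV-chosen
  penalty jointly. Resampling is what makes selection frequency a
  stability measure; re-choosing the penalty per resample avoids fixing a
  single regularisation path as "the" model.
* *Repeats per subset vs per cohort*: per subset, matching the
  subset-wise signature construction of the ensemble design; the pooled
  alternative would let the majority class dominate selection.
* *Negatives across subsets*: a disjoint partition (sizes `n_pos` or
  `n_pos + 1`; 22/223 gives 7 groups of 22 and 3 of 23), so every
  negative is used exactly once and members are maximally decorrelated.
* *Final member fit*: L1-penalised logistic regression on the signature
  columns (penalty by the same CV), which also keeps coefficients finite
  under perfect separation; a single-feature member falls back to an
  unpenalised fit with a separation warning.
* *Collinearity* between original-domain and LLL features is deliberately
  left to LASSO — linear dependence does not imply dispensability, and no
  correlation pre-filter is applied.

The default `n_repeats` is 1000 for a full-scale analysis; the shipped
tests and the acceptance script use 100 (and 5–50 in unit tests), which
the selection frequencies plateau well before on the synthetic effect.

## Evaluation conventions

AUC uses the midrank Mann–Whitney formulation (equal to the trapezoidal
ROC area with tie handling), verified against a brute-force pairwise count
in the tests. A probability exactly at the operating threshold classifies
positive. The default threshold rule is Youden's J maximised on the
training ROC — taking the smallest threshold among ties — then frozen for
the test cohort; a fixed 0.5 rule is available. AUC never depends on the
rule, which the tests assert.

## Problem sizes

The acceptance-level checks run the study at its full cohort structure —
245 training patients (22 RP-positive) and 30 test patients (8 positive)
on 48^3 grids, 10 subsets, 100 LASSO repeats — in about 6 minutes on one
CPU. Unit and property tests use 16^3–32^3 grids and cohorts of up to 60.
Oracle-equivalence tests enumerate volumes up to 5^3 where brute force is
exact.

## Known limitations

* The feature list follows the classical MATLAB-lineage radiomics sets
  (9 GLCM + 13 GLRLM + 13 GLSZM + 5 NGTDM + 14 histogram); other toolkits
  differ in normalisation details (e.g. per-direction averaging instead of
  merged matrices), so absolute feature values are not interchangeable
  across toolkits.
* Dose grids are assumed co-registered to the CT; DICOM-RT parsing,
  contour rasterisation and dose resampling are out of scope.
* Whether DVH denominators should include the GTV is not standardised;
  this package uses lung-minus-GTV everywhere, consistent with the ROI
  definition.
* The synthetic DVH baseline carries no real dose–outcome signal (see
  above); its AUC hovers near chance by construction.
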