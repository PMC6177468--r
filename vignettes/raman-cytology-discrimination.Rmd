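---
title: "Discriminating cervical cytology classes from single-cell Raman spectra: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating cervical cytology classes from single-cell Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Liquid-based cervical cytology (ThinPrep) slides carry exfoliated squamous
cells from the uppermost epithelial layers — intermediate and superficial
cells. In specimens from patients with a high-grade squamous intraepithelial
lesion (HSIL), most of these cells still *look* morphologically normal, yet
their biochemistry is altered ("field change"): glycogen stores drop while
nucleic-acid and some protein band intensities rise. Raman microspectroscopy
of single cells over the 400–1800 cm⁻¹ fingerprint region can read this
signature, and a supervised classifier can call a spectrum negative or HSIL
without any morphological assessment.

`ramancyto` implements the full analysis chain for this design — spectral
data model and I/O, glass-background removal, baseline correction and
normalization, PCA-LDA and PLS-DA classifiers with random-subsets
cross-validation, band-level statistics — plus a hierarchical synthetic-data
generator, because no public single-cell dataset of this kind exists. All
statistical machinery is exercised and calibrated against the generator.

## The generative model

A spectrum is simulated as

$$ y(w) \;=\; \sum_b a_b\, \phi_b(w) \;+\; g\, G(w) \;+\; P(w) \;+\;
\varepsilon(w), $$

where $\phi_b$ are unit-height Gaussian or Lorentzian band profiles at the
22 positions of the band table (`default_peak_table()`), $G$ is a smooth
glass-slide background (no feature narrower than 200 cm⁻¹ FWHM) with a
per-spectrum coefficient $g \sim U(0.8, 1.2)$ on a dominant scale, $P$ is a
random degree-3 polynomial baseline, and $\varepsilon \sim N(0,
\sigma^2)$ i.i.d. with $\sigma = 0.01$ against base peak heights of 0.2–0.9.

The band amplitudes are hierarchical:

$$ a_b \;=\; h_b \cdot u_{p(i),b} \cdot c_b^{[\mathrm{HSIL}]} \cdot
s_b^{[\mathrm{superficial}]}, $$

with $h_b$ the base height, $u_{p,b}$ a lognormal per-patient multiplier
(SD 0.10 on the log scale) shared by all of a patient's cells — this induces
the within-patient correlation that makes spectrum-level versus patient-level
cross-validation a meaningful comparison — and multiplicative class and
cell-type effects. Defaults follow the biology: in HSIL spectra, glycogen
bands (482, 855, 936 cm⁻¹) shrink by 30–40% and nucleic-acid/protein bands
(728, 1092, 1578, 1669 cm⁻¹, among 16 in total) grow by 30–40%; superficial
cells differ from intermediate cells only weakly (±5–10%, mostly glycogen).
Multiplicative (not additive) effects were chosen because Raman band
intensity scales with analyte concentration.

The default study design is 18 negative and 17 HSIL patients with strata of
176/252 intermediate and 174/153 superficial spectra (755 in total) on a
1 cm⁻¹ grid. The grid spacing is configurable; nothing in the pipeline
assumes a specific detector geometry.

**What the generator does not emulate:** Pap-stain contributions,
cosmic-ray spikes, instrument drift and wavelength-calibration error,
substrate etalon fringes, intensity-response curvature, and any nonlinearity
between concentration and signal. Effect *sizes* are calibration choices —
the emulated study reports which bands differ but not by how much — so
passing tests demonstrate that the machinery recovers what was seeded at
realistic noise, not that real clinical data are this separable. Indeed the
default regime should be expected to be *more* separable than real cytology:
on it, cross-validation reaches zero error with a single latent variable
(see `analysis/04_classification.R`). Users studying borderline regimes
should weaken `class_effects` and/or raise `patient_sd` and `noise_sd`.

## Preprocessing

Per spectrum, in order:

1. **Glass removal.** Non-negative least squares against a reference library
   of one glass spectrum plus six biochemical components (glycogen, DNA,
   RNA, protein, collagen, lipid). Only the background-flagged (glass)
   contribution is subtracted; the biochemical components are there to
   stabilise the glass coefficient, not to denoise. The solver is
   Lawson–Hanson active-set, deterministic (smallest index enters on ties),
   with KKT optimality asserted in tests against an exhaustive
   subset-enumeration oracle.
2. **Baseline.** Default is the rubberband: subtract the linear interpolant
   of the lower convex hull, which maps any affine spectrum to zero. The
   alternative `polynomial` method is a modified polynomial fit with
   automatic peak suppression: iteratively refit and clip the working
   spectrum at fit + residual RMS until the RMS stabilises (tolerance 1e-6,
   at most 50 iterations). On constructed fixtures (three bands on a
   degree-5 background) it recovers peaks to well under 2% of peak height.
   The choice of baseline algorithm is genuinely open in this design; the
   rubberband is the default because it is parameter-free.
3. **Vector normalization** to unit L2 norm. A zero spectrum is an error
   (an empty or failed measurement should fail loudly).

Mean-centering is deliberately *not* part of this chain. The classifiers
centre internally on the data they are fitted to, so during cross-validation
each training fold is centred on its own mean and test folds are centred with
the stored training mean — leakage of test-fold information into centring is
structurally impossible. Global pre-centring (centre once, then split), the
order used with a single fixed dataset, is available via
`cv_config(center_before_cv = TRUE)`.

Pipeline order (glass → baseline → normalize, all on the already-cropped
fingerprint region) is a design choice; cropping uses a closed interval, so
"400 to 1800" keeps both endpoints.

## Classifiers

**PCA-LDA.** PCA is computed from the smaller of the two symmetric
eigenproblems (the n×n Gram matrix when spectra are long), with a fixed sign
convention (largest-|loading| element positive) so fits are bit-reproducible.
Fisher LDA on the leading PC scores uses pooled within-class scatter with a
ridge of `1e-8 · trace/k` for near-singular small folds; the decision value is
the projection minus the midpoint of the projected class means, oriented so
HSIL is positive.

**PLS-DA.** SIMPLS with a 0/1 class coding (negative = 0, HSIL = 1): latent
variables maximise covariance with the class label under orthonormal-score
constraints. SIMPLS was chosen over NIPALS because it is deterministic (no
iteration tolerance) and its truncation property lets one fit at the largest
candidate count and read off predictions for every smaller count — the
regression vector for k latent variables is built from the first k weight
vectors. Training squared error is non-increasing in the number of latent
variables (a deflation theorem, asserted in tests); thresholded 0/1 error is
not guaranteed monotone and is not asserted. At full rank PLS-DA reproduces
ordinary least squares, and the first weight vector is collinear with
$X^\top y$ — both checked against closed forms.

The classification threshold is the midpoint of the coding: 0.5 on the PLS-DA
predicted value, 0 on the signed PCA-LDA decision value; exact ties count as
positive calls. The number of PCs for PCA-LDA and the probability threshold
are not fixed by the emulated design, so both are explicit configuration.

## Cross-validation and component selection

Random-subsets cross-validation: per iteration the units are randomly
partitioned into 20 disjoint test sets whose sizes differ by at most one, so
every unit is tested exactly once per iteration; 10 iterations by default.
Units are spectra by default — matching a samples/20 split of 755 spectra —
but `grouping = "patient"` partitions patients instead, keeping all of a
patient's spectra on one side of every fold. Spectrum-level splitting leaks
patient identity through the shared lognormal multipliers and therefore
flatters accuracy; patient-level grouping is recommended whenever
patient-level generalisation is the question. Reports record which grouping
was used.

Per fold, the model is fitted on the training rows only and the held-out rows
are predicted at every candidate component count; the count with minimum mean
CV misclassification is chosen, ties broken toward fewer components.
Per-spectrum predictions are averaged across iterations before thresholding,
giving one predicted value per spectrum. Partitions are derived from
`seed` and the iteration index, so iteration k is invariant to the total
number of iterations, and the entire report is a deterministic function of
(dataset, model specification, CV configuration).

If a random partition leaves a training fold with only one class it is
redrawn (at most 100 attempts); imbalanced-but-nonempty folds are allowed.

## Band-level statistics

Group summaries use the sample SD (denominator n−1); a singleton group
reports SD 0 with a warning. The difference spectrum is the difference of
group means with a root-sum-of-squares band $\sqrt{SD_A^2 + SD_B^2}$ — one
of several defensible definitions of a "difference ± SD" display, recorded
explicitly here.

`differential_bands()` runs an unpaired two-sided pooled-variance t-test at
every grid point at α = 0.001 with *no* multiple-testing correction,
reducing contiguous significant runs to their maximum-|t| wavenumber. A
Bonferroni-adjusted p value is carried alongside for transparency. Zero
pooled variance at a point is flagged and given p = 1. Note two caveats
demonstrated by the calibration tests: (i) the nominal type-I rate holds for
i.i.d. spectra — patient-level correlation inflates it, so band lists from
spectrum-level tests on hierarchical data are optimistic; (ii) at 1401 grid
points and α = 0.001, about 1.4 false-positive points per dataset are
*expected* — a detected band list should never be read as exactly the set of
true effects. Vector normalization also couples bands: raising one band
necessarily lowers normalized intensity elsewhere, so strong seeded effects
produce genuine compensatory differences at unseeded bands.

## Calibration and test design

Three problem-size choices keep the statistical checks honest and fast:

* **Null calibration** uses *balanced* zero-effect studies (equal strata,
  no patient effects). With unbalanced classes a 0.5 threshold on 0/1-coded
  predictions centres at the class prevalence rather than 0.5, and patient
  correlation would invalidate the binomial reference; the balanced i.i.d.
  null is the regime where "sensitivity ≈ specificity ≈ 50%" is the correct
  expectation. Pooled over 10 studies, both rates are required to sit inside
  the 99% binomial interval around 50%.
* **Type-I calibration** of the per-wavenumber t-test runs on i.i.d. null
  spectra (20 seeds × 1401 points) because the pooled-variance t-test
  assumes independence; the observed rate must match α = 0.001 within 3
  standard errors.
* **Structural checks** (mixing cell types costs ≤ 5 accuracy points when
  cell-type effects are ≤ ⅓ of class effects; supervised PLS-DA does at
  least as well as PCA-LDA) run on a scaled default regime — 16 patients,
  ~200 spectra, 4 cm⁻¹ grid, 5 seeds — chosen so the full suite completes in
  well under a minute per property while preserving the hierarchy the
  properties concern. The PLS-DA ≥ PCA-LDA ordering is a property of this
  regime (class-correlated directions dominate), not a universal theorem.

## Numerical choices

* NNLS: gradient tolerance 1e-10 relative, ties to the smallest index,
  duplicated basis columns warn and resolve to the smallest index.
* PCA/PLS sign conventions: largest-|element| of each loading/weight made
  positive.
* LDA ridge: `1e-8 · trace(S_w)/k`.
* Rubberband: lower convex hull via monotone chain; collinear hull points are
  dropped (interpolation unchanged).
* Degenerate inputs: zero spectra fail normalization; single-class inputs
  fail LDA/PLS/metrics; empty crop windows, extrapolating grids and unknown
  metadata labels are errors, not warnings.
* I/O round-trips are bit-exact: wide CSV numbers are written with 17
  significant digits.

## Known limitations

* JCAMP-DX support is read-only and covers the plain AFFN
  `(X++(Y..Y))` dialect only (no SQZ/DIF/DUP compression).
* The generator's effect sizes are not estimates of clinical effect sizes;
  absolute sensitivities/specificities on synthetic data say nothing about
  clinical performance.
* No cosmic-ray despiking, smoothing or instrument calibration: inputs are
  assumed to be quality-controlled spectra.
* Two-class only (negative vs HSIL); no multiclass grading, no ROC/AUC.
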