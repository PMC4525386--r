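---
title: "Dual-range Raman diagnostics of esophageal tissue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-range Raman diagnostics of esophageal tissue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanfphw)
```

## The problem

Fiber-optic Raman endoscopy acquires vibrational spectra of esophageal
mucosa *in vivo* in two ranges at once: the fingerprint range (FP,
800–1800 cm⁻¹), rich in narrow protein/lipid/nucleic-acid bands but
dominated by tissue autofluorescence, and the high-wavenumber range (HW,
2800–3600 cm⁻¹), with strong CH/NH/OH stretching bands and little
autofluorescence. Esophageal squamous cell carcinoma (ESCC) changes the
relative band intensities — lipid bands (1078, 2850, 2885 cm⁻¹) fall,
DNA and protein bands (1335, 1618, 2940 cm⁻¹) rise, the amide I band at
1655 cm⁻¹ broadens, and the asymmetric-to-symmetric OH-stretching ratio
(3400 vs 3250 cm⁻¹) increases with tissue water content. This package
implements the complete analysis that turns raw dual-range spectra into
a spectrum-level ESCC/normal diagnosis: preprocessing, univariate
channel statistics, and a patient-aware PLS-DA classifier — together
with a synthetic cohort generator that provides ground truth for every
step, since no clinical spectra are distributed with the package.

## The synthetic cohort: what it emulates and what it does not

Every spectrum is simulated as

$$ S(\nu) = B(\nu) + m_{\text{patient}} \sum_k A_k\, \phi_k(\nu) +
\varepsilon(\nu), \qquad \varepsilon(\nu) \sim
\mathcal N\!\big(0,\; \sigma^2 (S_0(\nu)+1)\big), $$

where $B$ is a random polynomial autofluorescence baseline (order 5 in
FP with coefficient scale 8 a.u., i.e. roughly 5–20× the Raman peak
amplitudes; order 1 in HW with scale 0.3), $\phi_k$ are Lorentzian lines
(Gaussian for the broad water envelopes at 3250/3400 cm⁻¹, FWHM
150 cm⁻¹), $m_{\text{patient}}$ is a log-normal patient amplitude
multiplier (log-SD 0.15), and the noise is shot-like with scale
$\sigma = 0.02$ on the noiseless signal $S_0$. Class effects enter as
per-peak amplitude multipliers (and a width multiplier for the 1655
band) on ESCC-labelled sites; labels live at the *site* level and ESCC
sites occur only in ESCC-designated patients (40% of patients, 2/3 of
their sites), so replicate spectra are clustered exactly the way the
cross-validation assumes. The default cohort shape — 48 patients, 2–3
sites each, 8–12 replicates per site, ≈1200 spectra with roughly a
quarter ESCC — mirrors the clinical study design this analysis targets.
Where that design gives no value (per-patient site counts, the ESCC
site fraction), the defaults are uniform draws chosen once as plausible
for an endoscopic screening cohort; they are inventions of the
generator, not measurements.

The generator's default class effects are deliberately strong (≥ 4
noise-SD separation on the informative channels after normalization).
Passing tests therefore demonstrate that the pipeline *recovers a known
signal through realistic nuisance structure* (dominant FP baseline,
patient amplitude variation, shot noise); they do not demonstrate
clinical-grade performance on real tissue, where class effects are far
subtler and histology itself is imperfect. The generator also omits
cosmic-ray spikes, detector etaloning, wavelength drift, and any
radiometric calibration error.

## Preprocessing

The chain follows the order used by online clinical Raman software:
smooth, fit/subtract the autofluorescence, quality-check, normalize.

* **Savitzky–Golay smoothing.** Local polynomial least squares per
  segment. The classical clinical setting of a 3-pixel, third-order
  filter is mathematically inconsistent (the order must be below the
  window; a 3-point quadratic is an exact interpolation and smooths
  nothing), so the default is the nearest valid neighborhood, window 5
  / order 3; `preprocess_config(sg_window = 3, sg_order = 2)` gives the
  literal (identity) setting. Edges are handled by refitting on the
  truncated window.
* **Autofluorescence removal.** A fifth-order polynomial models the FP
  baseline and a first-order polynomial the HW baseline. The default
  mode is the iterative modified polyfit: refit on
  $\min(\text{input}, \text{previous fit})$ until the fit changes by
  less than `iterative_tol` everywhere. A single least-squares pass is
  retained (`baseline_mode = "single_pass"`) as the literal
  fit-and-subtract reading, but it bites into the peaks — the iterative
  fit converges onto the fluorescence floor beneath them, and after
  convergence never exceeds the input by more than the tolerance.
  Convergence on the default cohort typically needs several hundred
  refits, hence the defaults `iterative_tol = 1e-5`,
  `iterative_max_iter = 2000` (an active-set update makes this cheap);
  non-convergent spectra return the last iterate with a warning.
* **Quality control.** The clinical protocol discards probe-off-tissue
  acquisitions automatically but does not state the rule. The rule
  implemented here is invented and documented as such: accept iff the
  background-removed intensity at the channel nearest 2940 cm⁻¹ (the
  protein CH₃ band, present in any in-contact tissue spectrum) divided
  by a robust noise estimate (median absolute second difference of the
  HW segment / 1.048) reaches `qc_min_snr = 3`.
* **Normalization.** Both segments are divided by the *joint* FP+HW
  trapezoidal area of the absolute intensity, so the combined area is
  exactly 1. Joint (rather than per-range) normalization preserves the
  FP:HW intensity balance as a feature; per-range normalization is
  exposed as a non-default option. The trapezoidal rule is used rather
  than a channel sum for exactness at segment edges.

Wavenumber calibration against reference lamp/standard lines and flat
spectral-response division are provided as standalone operations
(`fit_wavenumber_calibration`, `apply_response_correction`); the
generator emits already-calibrated axes, so they sit outside the
default chain.

## Univariate statistics

Per-channel comparison uses the classic pooled-variance two-sided
Student's t (not Welch — equal variances are assumed deliberately,
matching standard practice in this literature), with raw p-values
floored at the smallest positive double. Significant regions are
maximal runs of channels with p below a hard screen of 1e-10 — a
deliberately conservative threshold in lieu of multiple-testing
correction across ~900 channels — with single-channel gaps bridged and
runs never crossing the 1800–2800 cm⁻¹ acquisition gap. Peak intensities
are means over ±5 cm⁻¹ windows (robust at ~9 cm⁻¹ optical resolution),
and single-ratio classifiers (e.g. I2940/I2850) select their threshold
by maximizing Youden's J over all midpoints in both orientations, ties
resolved toward higher sensitivity then lower threshold. The Youden rule
is an explicit design choice: published ratio sensitivities in this
field rarely state a threshold rule, so the package's in-sample
Youden-optimal counts are a transparent, reproducible convention rather
than a reproduction of any particular printed figure. One caveat worth
stating: joint area normalization couples channels, so even bands whose
generator multiplier is 1 can show class differences after
normalization — the significant-region tests therefore check that the
configured effects are *recovered*, not that untouched channels stay
silent.

## PLS-DA with leave-one-patient-out cross-validation

The classifier is PLS1 on the mean-centered spectra with the 0/1 class
vector (ESCC = 1): NIPALS iterations $w \propto X^\top y$ (unit norm),
$t = Xw$, $p = X^\top t / t^\top t$, $q = y^\top t / t^\top t$, with
deflation of both $X$ and $y$; coefficients are assembled as
$\beta = W (P^\top W)^{-1} q$. PLS1 on a scalar response was chosen over
a two-column PLS2 because the problem is strictly binary and the
rankings are equivalent. The continuous PLS score is mapped to a
posterior probability by a logistic calibration fitted on the training
scores (with a steep-sigmoid fallback through the class-mean midpoint
when the classes are perfectly separated and the GLM diverges); the
decision threshold is fixed at 0.5.

Model complexity (the number of latent variables, up to
`max_components = 8` by default) is chosen by leave-one-patient-out
cross-validation: all replicate spectra of one patient are held out per
fold, so site/patient replicates can never leak between training and
testing. One NIPALS run per fold supplies every nested component count.
The selected count maximizes pooled cross-validated accuracy, ties going
to fewer components. The ROC curve and AUC are computed on the pooled
cross-validated posteriors (not on resubstitution predictions), and the
independent 80/20 evaluation splits *patients*, sized by spectra: a
greedy randomized search accepts a partition when the training spectra
fraction is within ±3 points of 80% and both classes appear on both
sides.

## Numerical choices and degenerate inputs

* Channels where both groups have identical values get $t = 0$, $p = 1$
  (0/0 resolved by definition, keeping the invariant $t = 0$ iff equal
  means).
* A spectrum with zero combined area cannot be normalized and raises an
  error; QC rejects all-zero spectra (SNR 0) and accepts noiseless ones
  (SNR ∞).
* NIPALS stops early if a weight or score norm underflows (rank
  exhaustion) and reports the achieved component count.
* The ROC uses ±∞ threshold sentinels so the curve always spans (0,0)
  to (1,1); its trapezoidal AUC equals the Mann–Whitney pairwise
  concordance, which the tests verify by enumeration.
* All randomness (generator, splits, pipeline stages) flows from
  integer seeds; `run_pipeline` derives per-stage seeds from one master
  seed via a counter scheme so stages can be rerun in isolation.

## Problem sizes used by the tests and the acceptance script

Unit tests run on miniature axes (16 channels per range) and small
cohorts (3–12 patients) where brute-force oracles are feasible; the
acceptance suite and `scripts/acceptance.R` run the full default cohort
(48 patients, ≈1200 spectra, all three views) once, plus three
shuffled-label cross-validations. The shuffled-label null AUC is
reported as the mean over three label permutations because held-out
posteriors are correlated within a patient, making a single
permutation's AUC a noisy estimate of the chance level 0.5.

## Known limitations

* The generator's class effects are parametric and strong; no attempt
  is made to emulate the subtle, overlapping biochemical gradients of
  real dysplastic progression, and "dysplasia" as a third class is out
  of scope.
* The QC rule, the Youden threshold convention, and the logistic
  posterior mapping are package conventions for behaviors that clinical
  systems implement but do not specify.
* Baseline removal assumes the autofluorescence is polynomial of known
  order per range; structured non-polynomial backgrounds (etaloning,
  probe fluorescence) are not modelled.

## A minimal run

```{r pipeline, eval = FALSE}
report <- run_pipeline(pipeline_config(seed = 1))
compare_views(report)          # CV + holdout metrics per view
report$regions                 # significant spectral sub-regions
```

The four scripts under `analysis/` execute the same steps one stage at
a time, writing intermediate spectra under `scratch/` and summary
tables under `results/`.
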