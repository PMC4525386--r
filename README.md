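# ramanfphw

Analysis of simultaneous fingerprint (FP, 800–1800 cm⁻¹) and
high-wavenumber (HW, 2800–3600 cm⁻¹) fiber-optic Raman spectra of
esophageal tissue, for discriminating esophageal squamous cell
carcinoma (ESCC) from normal mucosa. The package is aimed at
biomedical-spectroscopy researchers who want a fully reproducible,
tested implementation of this diagnostic workflow — from raw dual-range
spectra to cross-validated posterior probabilities — exercisable end to
end on synthetic cohorts, since clinical in vivo spectra are not
publicly distributed.

## What it implements

* **Synthetic cohort generator** with ground truth: spectra are
  `baseline + Σ peaks × patient multiplier + shot-like noise`, with 16
  esophageal Raman bands (Lorentzian lines; Gaussian water envelopes at
  3250/3400 cm⁻¹), a dominant order-5 polynomial autofluorescence
  background in FP and a weak order-1 background in HW, site-level ESCC
  labels nested in patients.
* **Preprocessing**: Savitzky–Golay smoothing; iterative
  (modified-polyfit) or single-pass polynomial autofluorescence removal
  (order 5 in FP, order 1 in HW); SNR quality control at the
  2940 cm⁻¹ band; joint FP+HW unit-area normalization; pixel→wavenumber
  calibration and spectral-response correction.
* **Univariate statistics**: per-channel pooled two-sided Student's t
  and p maps; contiguous significant sub-regions (p < 1e-10); peak
  panels; Youden-optimal single-ratio classifiers; Cohen's kappa.
* **PLS-DA classification**: mean-centered NIPALS PLS1 on the 0/1 class
  vector, with the score

  `β = W (PᵀW)⁻¹ q`,   `posterior = logistic(a + b·(x − x̄)ᵀβ)`,

  leave-one-patient-out cross-validation (LOPCV) for latent-variable
  selection, patient-level 80/20 train/test splitting, confusion
  metrics (sensitivity = TP/(TP+FN), specificity = TN/(TN+FP)) and
  trapezoidal ROC/AUC — for the FP, HW and integrated FP+HW views.

## Worked example

```r
library(ramanfphw)
cohort <- generate_cohort(synthetic_config(seed = 101))
print(cohort$set)
#> spectra_set: 1169 spectra (48 patients, 116 sites), stage 'raw'
#>   FP: 501 channels [800, 1800] cm^-1; HW: 401 channels [2800, 3600] cm^-1
#>   labels: normal=848, ESCC=321, unknown=0
```

1169 dual-range spectra from 48 patients, with ESCC sites confined to
ESCC-designated patients. Preprocess, split by patient, cross-validate
and evaluate:

```r
pre <- preprocess_set(cohort$set)            # 0 rejections at default noise
sp  <- split_by_patient(pre$set, 0.8, seed = 101)
cv  <- lopcv(sp$train, "FP+HW", max_components = 8)
confusion_from_predictions(cv)
#> confusion: TP=267 FN=0 TN=658 FP=0
#>   sensitivity 100.0% (267/267), specificity 100.0% (658/658), accuracy 100.0% (925/925)
roc_curve(cv)$auc
#> [1] 1
```

At the generator's default (deliberately strong) class effects, the
integrated FP+HW model separates the classes completely in
cross-validation and on the held-out patients — the point being that
the pipeline recovers a known signal through the dominant FP baseline,
patient amplitude variation and shot noise, not that real tissue is
this easy. Diagnostic-metric arithmetic matches the conventional
count-derived reporting style:

```r
confusion_metrics(tp = 196, fn = 6, tn = 717, fp = 19)
#> confusion: TP=196 FN=6 TN=717 FP=19
#>   sensitivity 97.0% (196/202), specificity 97.4% (717/736), accuracy 97.3% (913/938)
```

The scripts `analysis/01_simulate.R` … `analysis/04_classify.R` run the
same workflow one stage at a time from the shell, writing intermediate
spectra under `scratch/` and summary tables (cohort composition,
rejection log, channel statistics, significant regions, ratio
classifiers, per-view metrics, ROC points) under `results/`.

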