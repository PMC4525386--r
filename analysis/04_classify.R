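#!/usr/bin/env Rscript
# Step 4: PLS-DA classification.
#
# Patient-level 80/20 split, leave-one-patient-out cross-validation on
# the training partition for the FP, HW and integrated FP+HW views
# (latent-variable count chosen by pooled CV accuracy), refit and
# evaluation on the held-out patients, confusion metrics and ROC.

library(ramanfphw)

SEED <- 101

set <- read_spectra("scratch/processed/spectra.csv",
                    "scratch/processed/manifest.csv",
                    stage = "normalized")
sp <- split_by_patient(set, train_fraction = 0.8, seed = SEED)
cat(sprintf("split: %d training / %d testing spectra (%d / %d patients)\n",
            n_spectra(sp$train), n_spectra(sp$test),
            length(unique(sp$train$manifest$patient_id)),
            length(unique(sp$test$manifest$patient_id))))

dir.create("results", showWarnings = FALSE)
rows <- list()
for (view in c("FP", "HW", "FP+HW")) {
  cv <- lopcv(sp$train, view, max_components = 8)
  hold <- evaluate_holdout(sp$train, sp$test, view, max_components = 8)
  cvm <- confusion_from_predictions(cv)
  cvr <- roc_curve(cv)
  cat(sprintf("%-6s LVs=%d  CV acc %.1f%% (AUC %.3f)  holdout acc %.1f%% (AUC %.3f)\n",
              view, cv$n_components, cvm$accuracy_pct, cvr$auc,
              hold$metrics$accuracy_pct, hold$roc$auc))
  rows[[view]] <- data.frame(
    view = view, n_components = cv$n_components,
    cv_sensitivity_pct = cvm$sensitivity_pct,
    cv_specificity_pct = cvm$specificity_pct,
    cv_accuracy_pct = cvm$accuracy_pct, cv_auc = cvr$auc,
    holdout_sensitivity_pct = hold$metrics$sensitivity_pct,
    holdout_specificity_pct = hold$metrics$specificity_pct,
    holdout_accuracy_pct = hold$metrics$accuracy_pct,
    holdout_auc = hold$roc$auc)
  if (view == "FP+HW") {
    write.csv(data.frame(threshold = cvr$thresholds, tpr = cvr$tpr,
                         fpr = cvr$fpr),
              "results/04_roc_fphw.csv", row.names = FALSE)
    write.csv(data.frame(spectrum_id = cv$spectrum_id,
                         patient_id = cv$patient_id,
                         posterior = cv$posterior, label = cv$label),
              "results/04_cv_predictions_fphw.csv", row.names = FALSE)
    write_metrics_report(cvm, "results/04_fphw_cv_report.csv", roc = cvr)
  }
}
tab <- do.call(rbind, rows)
tab <- tab[order(-tab$cv_accuracy_pct), ]
write.csv(tab, "results/04_view_comparison.csv", row.names = FALSE)
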