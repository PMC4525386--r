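# End-to-end orchestration: synthesize (or read) -> preprocess ->
# univariate statistics -> patient split -> LOPCV per view -> holdout
# evaluation, all reproducible from one master seed.

# Per-stage seeds derived from one master seed via a counter scheme, so
# individual stages can be rerun in isolation reproducibly.
derive_stage_seeds <- function(master_seed, stages = c("synth", "split")) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(master_seed))
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(stages)),
                  stages)
}

#' Configure an end-to-end pipeline run
#'
#' @param synthetic A [synthetic_config()] to generate the cohort, or
#'   `NULL` to supply `set` to [run_pipeline()] directly.
#' @param preprocess A [preprocess_config()].
#' @param alpha Significance threshold for spectral regions.
#' @param views Character vector of classifier views to run.
#' @param train_fraction Patient-level split target (fraction of
#'   spectra in train).
#' @param max_components Largest LV count for PLS-DA selection.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            preprocess = preprocess_config(),
                            alpha = 1e-10,
                            views = c("FP", "HW", "FP+HW"),
                            train_fraction = 0.8,
                            max_components = 8L,
                            seed = 1L) {
  views <- match.arg(views, c("FP", "HW", "FP+HW"), several.ok = TRUE)
  structure(list(synthetic = synthetic, preprocess = preprocess,
                 alpha = alpha, views = views,
                 train_fraction = train_fraction,
                 max_components = as.integer(max_components),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the complete analysis pipeline
#'
#' Generates (or takes) a raw cohort, preprocesses it, computes the
#' per-channel statistics, significant regions and peak panel on the
#' processed spectra, splits patients 80/20, cross-validates PLS-DA on
#' the training partition for every requested view, and evaluates the
#' refitted models on the held-out patients. Deterministic under a fixed
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param set Optional raw [spectra_set()]; overrides the synthetic
#'   block.
#' @return A `run_report` list: `processed` set, `rejections`,
#'   `channel_stats`, `regions`, `peak_panel`, `split` sizes, and
#'   per-view `cv` results with metrics/ROC plus `holdout` evaluations.
#' @export
run_pipeline <- function(config = pipeline_config(), set = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_stage_seeds(config$seed)
  if (is.null(set)) {
    if (is.null(config$synthetic))
      stop("stage synth: no synthetic config and no input set given")
    syn_cfg <- config$synthetic
    syn_cfg$seed <- as.integer(seeds[["synth"]])
    cohort <- generate_cohort(syn_cfg)
    set <- cohort$set
  }
  pre <- tryCatch(preprocess_set(set, config$preprocess),
                  error = function(e) stop("stage preprocess: ",
                                           conditionMessage(e)))
  processed <- pre$set
  stats <- channel_ttest(processed)
  regions <- find_significant_regions(stats, config$alpha)
  panel <- peak_panel(processed)
  split <- tryCatch(
    split_by_patient(processed, config$train_fraction,
                     seed = seeds[["split"]]),
    error = function(e) stop("stage split: ", conditionMessage(e)))
  views <- lapply(config$views, function(v) {
    cv <- lopcv(split$train, v, config$max_components)
    hold <- evaluate_holdout(split$train, split$test, v,
                             config$max_components)
    list(view = v,
         cv = cv,
         cv_metrics = confusion_from_predictions(cv),
         cv_roc = roc_curve(cv),
         holdout = hold)
  })
  names(views) <- config$views
  structure(list(config = config,
                 processed = processed,
                 rejections = pre$rejections,
                 channel_stats = stats,
                 regions = regions,
                 peak_panel = panel,
                 split = list(
                   train_patients = unique(split$train$manifest$patient_id),
                   test_patients = unique(split$test$manifest$patient_id),
                   n_train = n_spectra(split$train),
                   n_test = n_spectra(split$test)),
                 train = split$train, test = split$test,
                 views = views),
            class = "run_report")
}

#' Per-view performance comparison table
#'
#' @param report A [run_pipeline()] report containing at least two views.
#' @return Data frame (one row per view, ordered by decreasing
#'   cross-validated accuracy) of CV sensitivity/specificity/accuracy
#'   percents and AUC, plus the holdout counterparts, copied verbatim
#'   from the per-view results.
#' @export
compare_views <- function(report) {
  stopifnot(inherits(report, "run_report"))
  if (length(report$views) < 2)
    stop("need at least 2 views to compare")
  rows <- lapply(report$views, function(v) {
    data.frame(view = v$view,
               n_components = v$cv$n_components,
               cv_sensitivity_pct = v$cv_metrics$sensitivity_pct,
               cv_specificity_pct = v$cv_metrics$specificity_pct,
               cv_accuracy_pct = v$cv_metrics$accuracy_pct,
               cv_auc = v$cv_roc$auc,
               holdout_sensitivity_pct = v$holdout$metrics$sensitivity_pct,
               holdout_specificity_pct = v$holdout$metrics$specificity_pct,
               holdout_accuracy_pct = v$holdout$metrics$accuracy_pct,
               holdout_auc = v$holdout$roc$auc)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$cv_accuracy_pct), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
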