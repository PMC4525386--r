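# Text dialect for all tables: UTF-8, comma-delimited, "." decimal,
# mandatory header row. The 1800-2800 cm^-1 inter-range gap is never
# stored: FP and HW rows are distinguished by their wavenumber.

#' Read a dual-range spectra set from delimited text
#'
#' The spectra table holds one `wavenumber` column followed by one
#' intensity column per spectrum, FP rows (800--1800 cm^-1) and HW rows
#' (2800--3600 cm^-1) stacked in one file. The manifest links each
#' intensity column to its patient, site, replicate and histology label.
#'
#' @param spectra_path Path to the spectra CSV.
#' @param manifest_path Path to the manifest CSV with columns
#'   `spectrum_id`, `patient_id`, `site_id`, `replicate`, `label`.
#' @param stage Processing stage to record on the returned set.
#' @return A validated [spectra_set()].
#' @export
read_spectra <- function(spectra_path, manifest_path, stage = "raw") {
  spec <- utils::read.csv(spectra_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(spec) < 2 || names(spec)[1] != "wavenumber")
    stop("spectra file must have a leading 'wavenumber' column ",
         "followed by intensity columns")
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  if (!"spectrum_id" %in% names(manifest))
    stop("manifest must contain a 'spectrum_id' column")
  w <- spec$wavenumber
  if (any(diff(w) <= 0) && !all(diff(w[w <= FP_RANGE[2]]) > 0))
    stop("non-monotone wavenumber axis in spectra file")
  in_fp <- w >= FP_RANGE[1] - 1e-9 & w <= FP_RANGE[2] + 1e-9
  in_hw <- w >= HW_RANGE[1] - 1e-9 & w <= HW_RANGE[2] + 1e-9
  if (!all(in_fp | in_hw))
    stop("wavenumbers outside the FP [800,1800] / HW [2800,3600] ranges")
  ids <- names(spec)[-1]
  missing_manifest <- setdiff(ids, manifest$spectrum_id)
  if (length(missing_manifest) > 0)
    stop("spectra columns without a manifest row: ",
         paste(missing_manifest, collapse = ", "))
  missing_cols <- setdiff(manifest$spectrum_id, ids)
  if (length(missing_cols) > 0)
    stop("manifest rows without a spectra column: ",
         paste(missing_cols, collapse = ", "))
  manifest <- manifest[match(ids, manifest$spectrum_id), , drop = FALSE]
  intens <- as.matrix(spec[, -1, drop = FALSE])
  spectra_set(w[in_fp], w[in_hw],
              t(intens[in_fp, , drop = FALSE]),
              t(intens[in_hw, , drop = FALSE]),
              manifest, stage = stage)
}

#' Write a spectra set as delimited text
#'
#' Emits `spectra.csv` and `manifest.csv` in the dialect [read_spectra()]
#' accepts, with deterministic column order, so re-writing an unchanged
#' set reproduces the files byte for byte.
#'
#' @param set A non-empty [spectra_set()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_spectra <- function(set, out_dir) {
  stopifnot(inherits(set, "spectra_set"))
  if (n_spectra(set) == 0) stop("cannot write an empty spectra set")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tab <- data.frame(wavenumber = c(set$fp_wavenumbers, set$hw_wavenumbers),
                    rbind(t(set$fp), t(set$hw)), check.names = FALSE)
  names(tab)[-1] <- set$manifest$spectrum_id
  spectra_path <- file.path(out_dir, "spectra.csv")
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(tab, spectra_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(set$manifest, manifest_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(spectra = spectra_path, manifest = manifest_path))
}

#' Write a diagnostic-performance report
#'
#' Delimited (CSV) report of the confusion counts, the derived percent
#' metrics, and -- when a ROC curve is supplied -- the area under the ROC
#' curve, readable both by humans and by `read.csv`.
#'
#' @param metrics A [confusion_metrics()] object.
#' @param path Output file path.
#' @param roc Optional [roc_curve()] result; when `NULL` the AUC section
#'   is omitted.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path, roc = NULL) {
  stopifnot(inherits(metrics, "confusion_metrics"))
  rows <- data.frame(
    metric = c("TP", "FN", "TN", "FP",
               "sensitivity_pct", "specificity_pct", "accuracy_pct"),
    value = c(metrics$tp, metrics$fn, metrics$tn, metrics$fp,
              metrics$sensitivity_pct, metrics$specificity_pct,
              metrics$accuracy_pct))
  if (!is.null(roc)) {
    stopifnot(inherits(roc, "roc_curve"))
    rows <- rbind(rows, data.frame(metric = "AUC", value = roc$auc))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
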