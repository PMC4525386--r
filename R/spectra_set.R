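#' @keywords internal
"_PACKAGE"

FP_RANGE <- c(800, 1800)
HW_RANGE <- c(2800, 3600)
LABEL_LEVELS <- c("normal", "ESCC", "unknown")
STAGE_LEVELS <- c("raw", "smoothed", "background_removed", "normalized")

#' Validate a spectral axis
#'
#' Checks that a wavenumber axis is strictly ascending, uniformly spaced
#' (within relative tolerance), at least 16 channels long, and lies inside
#' the declared acquisition range: fingerprint (FP, 800--1800 cm^-1) or
#' high-wavenumber (HW, 2800--3600 cm^-1).
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1.
#' @param range_tag `"FP"` or `"HW"`.
#' @return The axis, invisibly, if valid; otherwise an error is raised.
#' @export
validate_axis <- function(wavenumbers, range_tag = c("FP", "HW")) {
  range_tag <- match.arg(range_tag)
  rng <- if (range_tag == "FP") FP_RANGE else HW_RANGE
  if (length(wavenumbers) < 16L)
    stop(sprintf("%s axis must have at least 16 channels, got %d",
                 range_tag, length(wavenumbers)))
  d <- diff(wavenumbers)
  if (any(d <= 0))
    stop(sprintf("%s axis must be strictly ascending", range_tag))
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop(sprintf("%s axis spacing is not uniform", range_tag))
  if (min(wavenumbers) < rng[1] - 1e-9 || max(wavenumbers) > rng[2] + 1e-9)
    stop(sprintf("%s axis must lie within [%g, %g] cm^-1", range_tag,
                 rng[1], rng[2]))
  invisible(wavenumbers)
}

#' Default dual-range wavenumber grids
#'
#' 2 cm^-1 sampling across the full FP (800--1800, 501 channels) and HW
#' (2800--3600, 401 channels) acquisition ranges, comfortably finer than
#' the ~9 cm^-1 optical resolution of the instrument class being modelled.
#'
#' @return A list with elements `fp` and `hw`, each a numeric wavenumber
#'   vector in cm^-1.
#' @export
default_axes <- function() {
  list(fp = seq(FP_RANGE[1], FP_RANGE[2], by = 2),
       hw = seq(HW_RANGE[1], HW_RANGE[2], by = 2))
}

#' Construct a labelled dual-range spectra set
#'
#' The central container of the package: a cohort of dual-range Raman
#' spectra sharing common FP and HW wavenumber axes, with a manifest
#' recording the patient/site/replicate hierarchy and the histology label
#' of every spectrum. Patient-aware splitting and cross-validation operate
#' on this unit.
#'
#' @param fp_wavenumbers,hw_wavenumbers Shared wavenumber axes (cm^-1).
#' @param fp,hw Intensity matrices, one row per spectrum, columns aligned
#'   to the respective axis.
#' @param manifest Data frame with columns `spectrum_id`, `patient_id`,
#'   `site_id`, `replicate` (integer >= 1) and `label`
#'   (`"normal"`, `"ESCC"` or `"unknown"`), one row per spectrum in the
#'   same order as the intensity rows.
#' @param stage Processing stage of all spectra in the set: `"raw"`,
#'   `"smoothed"`, `"background_removed"` or `"normalized"`.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(fp_wavenumbers, hw_wavenumbers, fp, hw, manifest,
                        stage = "raw") {
  validate_axis(fp_wavenumbers, "FP")
  validate_axis(hw_wavenumbers, "HW")
  stage <- match.arg(stage, STAGE_LEVELS)
  fp <- as.matrix(fp)
  hw <- as.matrix(hw)
  if (ncol(fp) != length(fp_wavenumbers))
    stop("fp intensity columns do not match the FP axis length")
  if (ncol(hw) != length(hw_wavenumbers))
    stop("hw intensity columns do not match the HW axis length")
  if (nrow(fp) != nrow(hw))
    stop("fp and hw must contain the same number of spectra")
  if (!all(is.finite(fp)) || !all(is.finite(hw)))
    stop("intensities must be finite")
  manifest <- validate_manifest(manifest, nrow(fp))
  rownames(fp) <- manifest$spectrum_id
  rownames(hw) <- manifest$spectrum_id
  structure(list(fp_wavenumbers = as.numeric(fp_wavenumbers),
                 hw_wavenumbers = as.numeric(hw_wavenumbers),
                 fp = fp, hw = hw, manifest = manifest, stage = stage),
            class = "spectra_set")
}

validate_manifest <- function(manifest, n_spectra) {
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  required <- c("spectrum_id", "patient_id", "site_id", "replicate", "label")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0)
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  manifest <- manifest[required]
  if (nrow(manifest) != n_spectra)
    stop(sprintf("manifest has %d rows but the set has %d spectra",
                 nrow(manifest), n_spectra))
  manifest$spectrum_id <- as.character(manifest$spectrum_id)
  manifest$patient_id <- as.character(manifest$patient_id)
  manifest$site_id <- as.character(manifest$site_id)
  manifest$replicate <- as.integer(manifest$replicate)
  manifest$label <- as.character(manifest$label)
  if (anyDuplicated(manifest$spectrum_id))
    stop("spectrum_id values must be unique")
  key <- paste(manifest$patient_id, manifest$site_id, manifest$replicate,
               sep = "\r")
  if (anyDuplicated(key))
    stop("(patient_id, site_id, replicate) keys must be unique")
  if (any(is.na(manifest$replicate)) || any(manifest$replicate < 1L))
    stop("replicate must be an integer >= 1")
  bad <- setdiff(unique(manifest$label), LABEL_LEVELS)
  if (length(bad) > 0)
    stop("labels outside the {normal, ESCC, unknown} vocabulary: ",
         paste(bad, collapse = ", "))
  rownames(manifest) <- NULL
  manifest
}

#' Number of spectra in a set
#' @param set A `spectra_set`.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(set) nrow(set$fp)

#' Subset a spectra set by spectrum index
#' @param x A `spectra_set`.
#' @param i Row indices (integer or logical) of the spectra to keep.
#' @param ... Unused.
#' @return A `spectra_set` containing the selected spectra.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$fp_wavenumbers, x$hw_wavenumbers,
              x$fp[i, , drop = FALSE], x$hw[i, , drop = FALSE],
              x$manifest[i, , drop = FALSE], stage = x$stage)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(paste0(
    "spectra_set: %d spectra (%d patients, %d sites), stage '%s'\n",
    "  FP: %d channels [%g, %g] cm^-1; HW: %d channels [%g, %g] cm^-1\n"),
    n_spectra(x), length(unique(x$manifest$patient_id)),
    length(unique(paste(x$manifest$patient_id, x$manifest$site_id))),
    x$stage,
    length(x$fp_wavenumbers), min(x$fp_wavenumbers), max(x$fp_wavenumbers),
    length(x$hw_wavenumbers), min(x$hw_wavenumbers), max(x$hw_wavenumbers)))
  tab <- table(factor(x$manifest$label, levels = LABEL_LEVELS))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Extract one dual-range spectrum from a set
#' @param set A `spectra_set`.
#' @param i Single spectrum index or spectrum id.
#' @return A list with the two axes, the two intensity vectors, the
#'   manifest row and the stage.
#' @export
get_spectrum <- function(set, i) {
  if (is.character(i)) i <- match(i, set$manifest$spectrum_id)
  if (is.na(i) || i < 1 || i > n_spectra(set)) stop("spectrum not found")
  list(fp_wavenumbers = set$fp_wavenumbers,
       hw_wavenumbers = set$hw_wavenumbers,
       fp_intensity = set$fp[i, ], hw_intensity = set$hw[i, ],
       patient_id = set$manifest$patient_id[i],
       site_id = set$manifest$site_id[i],
       replicate = set$manifest$replicate[i],
       label = set$manifest$label[i],
       stage = set$stage)
}

# Stage transitions are forward-only: raw -> smoothed ->
# background_removed -> normalized.
advance_stage <- function(set, new_stage) {
  new_stage <- match.arg(new_stage, STAGE_LEVELS)
  if (match(new_stage, STAGE_LEVELS) < match(set$stage, STAGE_LEVELS))
    stop(sprintf("cannot move stage backwards from '%s' to '%s'",
                 set$stage, new_stage))
  set$stage <- new_stage
  set
}
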