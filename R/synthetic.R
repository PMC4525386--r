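# Synthetic dual-range esophageal Raman cohort generator. Each spectrum is
#   baseline + sum(peaks) * patient_multiplier + shot-like noise
# with class effects entering as per-peak amplitude (and width)
# multipliers on ESCC sites.

#' Declare one synthetic Raman peak
#'
#' @param center Peak center, cm^-1; must lie inside the FP or HW range.
#' @param fwhm Full width at half maximum, cm^-1.
#' @param base_amplitude Peak height in the normal class, arbitrary units.
#' @param escc_multiplier Multiplicative class effect on amplitude for
#'   ESCC sites (1 = no effect, <1 reduced, >1 increased).
#' @param escc_width_multiplier Multiplicative class effect on FWHM.
#' @param shape `"lorentzian"` (narrow vibrational lines) or
#'   `"gaussian"` (broad OH-stretching water envelope).
#' @return A `peak_spec` list.
#' @export
peak_spec <- function(center, fwhm, base_amplitude, escc_multiplier = 1,
                      escc_width_multiplier = 1,
                      shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  in_fp <- center >= FP_RANGE[1] && center <= FP_RANGE[2]
  in_hw <- center >= HW_RANGE[1] && center <= HW_RANGE[2]
  if (!in_fp && !in_hw)
    stop("peak center must lie in the FP or HW range: ", center)
  width_limit <- diff(if (in_fp) FP_RANGE else HW_RANGE)
  stopifnot(fwhm > 0, fwhm < width_limit, base_amplitude >= 0,
            escc_multiplier >= 0, escc_width_multiplier > 0)
  structure(list(center = center, fwhm = fwhm,
                 base_amplitude = base_amplitude,
                 escc_multiplier = escc_multiplier,
                 escc_width_multiplier = escc_width_multiplier,
                 shape = shape),
            class = "peak_spec")
}

#' Default esophageal tissue peak table
#'
#' Sixteen prominent esophageal Raman bands: FP bands at 853, 1004, 1078,
#' 1265, 1302, 1335, 1445, 1618, 1655 and 1745 cm^-1 (proteins, lipids,
#' nucleic acids) and HW bands at 2850, 2885, 2940 cm^-1 (CH2/CH3
#' stretching), ~3300 cm^-1 (amide A) and the broad water OH-stretching
#' envelope at 3250 and 3400 cm^-1. Class directionality follows the
#' biochemistry of squamous cell carcinoma: reduced lipid bands (1078,
#' 2850, 2885), increased DNA and protein bands (1335, 1618, 2940),
#' amide-I broadening at 1655, and a raised asymmetric-to-symmetric OH
#' stretching ratio (3400 up relative to 3250).
#'
#' @return List of [peak_spec()] objects.
#' @export
default_peak_table <- function() {
  list(
    # FP: narrow vibrational lines
    peak_spec(853,  14, 0.80, escc_multiplier = 0.80),   # v(C-C) proteins
    peak_spec(1004, 10, 0.60),                           # phenylalanine
    peak_spec(1078, 18, 0.70, escc_multiplier = 0.55),   # v(C-C) lipids
    peak_spec(1265, 24, 0.50, escc_multiplier = 1.10),   # amide III
    peak_spec(1302, 18, 0.70, escc_multiplier = 0.90),   # CH2 twist, lipids
    peak_spec(1335, 20, 0.60, escc_multiplier = 1.50),   # CH3CH2 twist, DNA
    peak_spec(1445, 22, 1.00),                           # d(CH2) deformation
    peak_spec(1618, 16, 0.40, escc_multiplier = 1.60),   # v(C=C) porphyrins
    peak_spec(1655, 26, 0.90, escc_multiplier = 1.10,
              escc_width_multiplier = 1.40),             # amide I broadening
    peak_spec(1745, 18, 0.40, escc_multiplier = 0.90),   # v(C=O) phospholipids
    # HW: CH stretching lines + broad water envelope
    peak_spec(2850, 28, 1.20, escc_multiplier = 0.60),   # sym CH2, lipids
    peak_spec(2885, 30, 1.40, escc_multiplier = 0.70),   # asym CH2, lipids
    peak_spec(2940, 40, 2.00, escc_multiplier = 1.40),   # CH3, proteins
    peak_spec(3250, 150, 1.50, shape = "gaussian"),      # sym OH, water
    peak_spec(3300, 60, 0.80, escc_multiplier = 1.10),   # amide A
    peak_spec(3400, 150, 1.30, escc_multiplier = 1.25,
              shape = "gaussian")                        # asym OH, water
  )
}

#' Render one peak profile on an axis
#'
#' Lorentzian: `a * (w/2)^2 / ((v - c)^2 + (w/2)^2)`; gaussian with the
#' same FWHM parameterisation. The profile attains `amplitude` at the
#' peak center.
#'
#' @param peak A [peak_spec()].
#' @param wavenumbers Axis on which to render (cm^-1); must contain the
#'   peak center.
#' @param amplitude Peak height (>= 0).
#' @param width_multiplier Optional extra factor on the FWHM.
#' @return Intensity vector the length of `wavenumbers`.
#' @export
render_peak <- function(peak, wavenumbers, amplitude = peak$base_amplitude,
                        width_multiplier = 1) {
  stopifnot(inherits(peak, "peak_spec"), amplitude >= 0)
  if (peak$center < min(wavenumbers) || peak$center > max(wavenumbers))
    stop("peak center lies outside the axis: ", peak$center)
  w <- peak$fwhm * width_multiplier
  d <- wavenumbers - peak$center
  if (peak$shape == "lorentzian") {
    hw2 <- (w / 2)^2
    amplitude * hw2 / (d^2 + hw2)
  } else {
    amplitude * exp(-4 * log(2) * d^2 / w^2)
  }
}

#' Render a random polynomial autofluorescence baseline
#'
#' A polynomial of the given order in the normalized axis coordinate
#' `u in [-1, 1]`, with coefficients drawn `N(0, coeff_scale^2)`, shifted
#' up so the curve is non-negative everywhere. Order 5 models the intense
#' FP autofluorescence; order 1 the weak, nearly linear HW background.
#'
#' @param order Polynomial order (0 or more; defaults used here are 1
#'   and 5).
#' @param coeff_scale Coefficient magnitude in intensity units (>= 0).
#' @param wavenumbers Axis on which to render.
#' @return Non-negative intensity vector.
#' @export
render_baseline <- function(order, coeff_scale, wavenumbers) {
  stopifnot(order >= 0, order == round(order))
  if (coeff_scale < 0) stop("coeff_scale must be non-negative")
  u <- normalized_coord(wavenumbers)
  coef <- stats::rnorm(order + 1, sd = 1) * coeff_scale
  b <- drop(outer(u, 0:order, `^`) %*% coef)
  b - min(b, 0)
}

normalized_coord <- function(wavenumbers) {
  r <- range(wavenumbers)
  2 * (wavenumbers - r[1]) / (r[2] - r[1]) - 1
}

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the clinical study design the package targets:
#' 48 patients, roughly 100+ tissue sites (2--3 per patient), 8--12
#' replicate spectra per site for a cohort of roughly 1200 dual-range
#' spectra, ESCC sites confined to ESCC-designated patients, a dominant
#' order-5 polynomial autofluorescence background in FP and a weak
#' order-1 background in HW, shot-like noise (SD proportional to the
#' square root of the signal) and log-normal between-patient amplitude
#' variation.
#'
#' @param n_patients Number of patients.
#' @param escc_patient_fraction Fraction of patients designated ESCC
#'   carriers (their sites may be ESCC; other patients' sites are normal).
#' @param escc_site_fraction Probability that a site of an ESCC-designated
#'   patient is ESCC.
#' @param sites_per_patient Integer range `c(lo, hi)` of sites per patient.
#' @param replicates_per_site Integer range of replicate spectra per site.
#' @param peaks List of [peak_spec()]; defaults to [default_peak_table()].
#' @param fp_af_coeff_scale,hw_af_coeff_scale Autofluorescence polynomial
#'   coefficient scales (a.u.) for the FP (order 5) and HW (order 1)
#'   baselines.
#' @param noise_scale Shot-noise scale: per-channel noise SD is
#'   `noise_scale * sqrt(signal + 1)`.
#' @param patient_effect_sd Log-scale SD of the per-patient global
#'   amplitude multiplier.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 48,
                             escc_patient_fraction = 0.4,
                             escc_site_fraction = 2 / 3,
                             sites_per_patient = c(2L, 3L),
                             replicates_per_site = c(8L, 12L),
                             peaks = default_peak_table(),
                             fp_af_coeff_scale = 8,
                             hw_af_coeff_scale = 0.3,
                             noise_scale = 0.02,
                             patient_effect_sd = 0.15,
                             seed = 20150805) {
  stopifnot(n_patients >= 1,
            escc_patient_fraction >= 0, escc_patient_fraction <= 1,
            escc_site_fraction >= 0, escc_site_fraction <= 1,
            all(sites_per_patient >= 1), all(replicates_per_site >= 1),
            fp_af_coeff_scale >= 0, hw_af_coeff_scale >= 0,
            noise_scale >= 0, patient_effect_sd >= 0)
  structure(list(n_patients = as.integer(n_patients),
                 escc_patient_fraction = escc_patient_fraction,
                 escc_site_fraction = escc_site_fraction,
                 sites_per_patient = as.integer(rep(sites_per_patient,
                                                    length.out = 2)),
                 replicates_per_site = as.integer(rep(replicates_per_site,
                                                      length.out = 2)),
                 peaks = peaks,
                 fp_af_coeff_scale = fp_af_coeff_scale,
                 hw_af_coeff_scale = hw_af_coeff_scale,
                 noise_scale = noise_scale,
                 patient_effect_sd = patient_effect_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a labelled synthetic cohort with ground truth
#'
#' Draws the patient/site/replicate hierarchy, assigns ESCC labels at
#' site level within ESCC-designated patients, and synthesizes every raw
#' dual-range spectrum as autofluorescence baseline + class-modulated
#' Raman peaks scaled by a per-patient amplitude multiplier + shot-like
#' Gaussian noise. The ground truth records the noiseless Raman
#' component, the baselines and the patient multipliers for every
#' spectrum, keyed identically to the emitted set, so downstream recovery
#' can be tested exactly.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `set` (a raw-stage [spectra_set()]) and
#'   `truth` (list of matrices `fp_raman`, `hw_raman`, `fp_baseline`,
#'   `hw_baseline`, vector `patient_multiplier`, and the manifest).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_patients < 1) stop("need at least one patient")
  axes <- default_axes()
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  n_escc_pat <- round(config$n_patients * config$escc_patient_fraction)
  escc_patients <- sample.int(config$n_patients, n_escc_pat)
  pat_mult <- exp(stats::rnorm(config$n_patients,
                               sd = config$patient_effect_sd))

  rows <- list()
  for (p in seq_len(config$n_patients)) {
    n_sites <- sample_range(config$sites_per_patient)
    for (s in seq_len(n_sites)) {
      label <- if (p %in% escc_patients &&
                   stats::runif(1) < config$escc_site_fraction)
        "ESCC" else "normal"
      n_rep <- sample_range(config$replicates_per_site)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("P%02d", p),
        site_id = sprintf("S%d", s),
        replicate = seq_len(n_rep),
        label = label,
        patient_index = p)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$spectrum_id <- sprintf("%s_%s_r%02d", manifest$patient_id,
                                  manifest$site_id, manifest$replicate)
  n <- nrow(manifest)

  # Class-conditional noiseless peak profiles are shared, so precompute.
  profile <- function(wn, escc) {
    v <- numeric(length(wn))
    for (pk in config$peaks) {
      if (pk$center < min(wn) || pk$center > max(wn)) next
      amp <- pk$base_amplitude * if (escc) pk$escc_multiplier else 1
      wm <- if (escc) pk$escc_width_multiplier else 1
      v <- v + render_peak(pk, wn, amplitude = amp, width_multiplier = wm)
    }
    v
  }
  fp_prof <- list(normal = profile(axes$fp, FALSE),
                  ESCC = profile(axes$fp, TRUE))
  hw_prof <- list(normal = profile(axes$hw, FALSE),
                  ESCC = profile(axes$hw, TRUE))

  fp_raman <- matrix(0, n, length(axes$fp))
  hw_raman <- matrix(0, n, length(axes$hw))
  fp_base <- matrix(0, n, length(axes$fp))
  hw_base <- matrix(0, n, length(axes$hw))
  fp_raw <- matrix(0, n, length(axes$fp))
  hw_raw <- matrix(0, n, length(axes$hw))
  for (i in seq_len(n)) {
    m <- pat_mult[manifest$patient_index[i]]
    lab <- manifest$label[i]
    fp_raman[i, ] <- fp_prof[[lab]] * m
    hw_raman[i, ] <- hw_prof[[lab]] * m
    fp_base[i, ] <- render_baseline(5, config$fp_af_coeff_scale, axes$fp)
    hw_base[i, ] <- render_baseline(1, config$hw_af_coeff_scale, axes$hw)
    fp_sig <- fp_base[i, ] + fp_raman[i, ]
    hw_sig <- hw_base[i, ] + hw_raman[i, ]
    fp_raw[i, ] <- fp_sig + stats::rnorm(length(fp_sig)) *
      config$noise_scale * sqrt(pmax(fp_sig, 0) + 1)
    hw_raw[i, ] <- hw_sig + stats::rnorm(length(hw_sig)) *
      config$noise_scale * sqrt(pmax(hw_sig, 0) + 1)
  }

  keep <- c("spectrum_id", "patient_id", "site_id", "replicate", "label")
  set <- spectra_set(axes$fp, axes$hw, fp_raw, hw_raw,
                     manifest[keep], stage = "raw")
  dimnames(fp_raman) <- dimnames(fp_base) <- dimnames(set$fp)
  dimnames(hw_raman) <- dimnames(hw_base) <- dimnames(set$hw)
  truth <- list(fp_raman = fp_raman, hw_raman = hw_raman,
                fp_baseline = fp_base, hw_baseline = hw_base,
                patient_multiplier = stats::setNames(
                  pat_mult[manifest$patient_index], manifest$spectrum_id),
                manifest = set$manifest)
  list(set = set, truth = truth)
}

sample_range <- function(range2) {
  if (range2[1] == range2[2]) range2[1]
  else sample(seq(range2[1], range2[2]), 1)
}

#' Combined-area-normalized noiseless Raman truth
#'
#' Applies the same joint FP+HW trapezoidal area normalization the
#' preprocessing pipeline uses to the ground-truth noiseless Raman
#' component, giving the exact target the processed spectra should
#' recover.
#'
#' @param truth The `truth` element of [generate_cohort()].
#' @param fp_wavenumbers,hw_wavenumbers The shared axes of the cohort.
#' @return List of matrices `fp` and `hw`.
#' @export
normalized_truth <- function(truth, fp_wavenumbers, hw_wavenumbers) {
  area <- trapz_matrix(truth$fp_raman, fp_wavenumbers) +
    trapz_matrix(truth$hw_raman, hw_wavenumbers)
  list(fp = truth$fp_raman / area, hw = truth$hw_raman / area)
}
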