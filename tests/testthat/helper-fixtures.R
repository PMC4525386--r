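# Shared fixtures: all test data is built in code.

tiny_axes <- function() {
  list(fp = seq(800, 830, by = 2), hw = seq(2800, 2830, by = 2))
}

# A minimal valid spectra set with one spectrum per patient by default.
tiny_set <- function(n = 4,
                     labels = rep(c("normal", "ESCC"), length.out = n),
                     patients = sprintf("P%d", seq_len(n)),
                     seed = 1, stage = "normalized",
                     fp = NULL, hw = NULL) {
  ax <- tiny_axes()
  set.seed(seed)
  if (is.null(fp)) fp <- matrix(stats::rnorm(n * 16, mean = 10), n)
  if (is.null(hw)) hw <- matrix(stats::rnorm(n * 16, mean = 10), n)
  man <- data.frame(
    spectrum_id = sprintf("s%02d", seq_len(n)),
    patient_id = patients,
    site_id = "S1",
    replicate = stats::ave(seq_len(n), patients, FUN = seq_along),
    label = labels)
  spectra_set(ax$fp, ax$hw, fp, hw, man, stage = stage)
}

# Class-separated normalized-stage set: ESCC rows shifted on a block of
# FP channels and a block of HW channels, patient-clustered replicates.
separated_set <- function(n_patients = 6, reps = 5, effect = 6, seed = 3) {
  ax <- tiny_axes()
  set.seed(seed)
  labels_pat <- rep(c("normal", "ESCC"), length.out = n_patients)
  n <- n_patients * reps
  fp <- matrix(stats::rnorm(n * 16, sd = 1), n)
  hw <- matrix(stats::rnorm(n * 16, sd = 1), n)
  man <- data.frame(
    spectrum_id = sprintf("s%03d", seq_len(n)),
    patient_id = rep(sprintf("P%d", seq_len(n_patients)), each = reps),
    site_id = "S1",
    replicate = rep(seq_len(reps), n_patients),
    label = rep(labels_pat, each = reps))
  escc <- man$label == "ESCC"
  fp[escc, 4:6] <- fp[escc, 4:6] + effect
  hw[escc, 10:12] <- hw[escc, 10:12] - effect
  spectra_set(ax$fp, ax$hw, fp, hw, man, stage = "normalized")
}

# Small synthetic cohort at the generator's default noise conditions.
small_cohort <- function(n_patients = 6, seed = 11, ...) {
  generate_cohort(synthetic_config(n_patients = n_patients, seed = seed,
                                   ...))
}
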