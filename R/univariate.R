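# Per-channel two-group statistics, significant-region extraction,
# peak-intensity panels, ratio threshold classifiers and rater agreement.

#' Per-channel pooled-variance Student's t-test
#'
#' Classic unpaired two-sided Student's t with pooled variance at every
#' FP and HW channel, comparing two labelled groups of a normalized
#' spectra set. Channels where both groups are identical get t = 0 and
#' p = 1; p-values are floored at the smallest positive double.
#'
#' @param set A normalized-stage [spectra_set()].
#' @param group_a,group_b Labels of the two groups (defaults
#'   `"normal"` vs `"ESCC"`).
#' @return A `channel_statistics` list: the two axes, per-channel group
#'   means/SDs, t statistics, two-sided p-values and group sizes.
#' @export
channel_ttest <- function(set, group_a = "normal", group_b = "ESCC") {
  stopifnot(inherits(set, "spectra_set"))
  ia <- set$manifest$label == group_a
  ib <- set$manifest$label == group_b
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("each group needs at least 2 spectra")
  X <- cbind(set$fp, set$hw)
  na <- sum(ia); nb <- sum(ib)
  ma <- colMeans(X[ia, , drop = FALSE])
  mb <- colMeans(X[ib, , drop = FALSE])
  va <- apply(X[ia, , drop = FALSE], 2, stats::var)
  vb <- apply(X[ib, , drop = FALSE], 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t_stat <- ifelse(se > 0, (ma - mb) / se, 0)
  equal <- abs(ma - mb) <= 1e-12 * pmax(abs(ma), abs(mb), 1)
  t_stat[equal] <- 0
  p <- 2 * stats::pt(-abs(t_stat), df = na + nb - 2)
  p <- pmax(p, .Machine$double.xmin)
  structure(list(fp_wavenumbers = set$fp_wavenumbers,
                 hw_wavenumbers = set$hw_wavenumbers,
                 wavenumbers = c(set$fp_wavenumbers, set$hw_wavenumbers),
                 segment = rep(c("FP", "HW"),
                               c(length(set$fp_wavenumbers),
                                 length(set$hw_wavenumbers))),
                 mean_a = ma, mean_b = mb,
                 sd_a = sqrt(va), sd_b = sqrt(vb),
                 t = t_stat, p = p, n_a = na, n_b = nb,
                 group_a = group_a, group_b = group_b),
            class = "channel_statistics")
}

#' Extract contiguous significant spectral regions
#'
#' Maximal runs of contiguous channels with p below `alpha`, with runs
#' separated by a gap of at most one channel merged; runs never span the
#' FP/HW inter-range gap. Reported as closed wavenumber intervals.
#'
#' @param stats A `channel_statistics` from [channel_ttest()].
#' @param alpha Significance threshold (default 1e-10, a hard screen
#'   appropriate for ~900 simultaneous raw p-values).
#' @return Data frame with columns `start`, `end` (cm^-1), `segment`,
#'   `n_channels` and `min_p`; zero rows when nothing is significant.
#' @export
find_significant_regions <- function(stats, alpha = 1e-10) {
  stopifnot(inherits(stats, "channel_statistics"))
  out <- list()
  for (seg in c("FP", "HW")) {
    idx <- stats$segment == seg
    w <- stats$wavenumbers[idx]
    p <- stats$p[idx]
    sig <- p < alpha
    if (!any(sig)) next
    # merge runs separated by a single non-significant channel
    filled <- sig
    gap <- which(!sig)
    one_gap <- gap[gap > 1 & gap < length(sig) & sig[pmax(gap - 1, 1)] &
                     sig[pmin(gap + 1, length(sig))]]
    filled[one_gap] <- TRUE
    r <- rle(filled)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        start = w[starts[k]], end = w[ends[k]], segment = seg,
        n_channels = length(i), min_p = min(p[i]))
    }
  }
  if (length(out) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      segment = character(0), n_channels = integer(0),
                      min_p = numeric(0)))
  do.call(rbind, out)
}

#' Mean intensity in a window around a peak
#'
#' Mean of the channels within `center +/- half_width` cm^-1, a read-off
#' robust to the ~9 cm^-1 optical resolution.
#'
#' @param intensity Intensity vector of one segment.
#' @param wavenumbers Its axis.
#' @param center Peak position, cm^-1.
#' @param half_width Window half-width, cm^-1 (default 5).
#' @return Mean intensity (a.u.).
#' @export
extract_peak_intensity <- function(intensity, wavenumbers, center,
                                   half_width = 5) {
  if (center - half_width < min(wavenumbers) - 1e-9 ||
      center + half_width > max(wavenumbers) + 1e-9)
    stop("extraction window falls outside the axis")
  idx <- which(abs(wavenumbers - center) <= half_width + 1e-9)
  if (length(idx) == 0) idx <- which.min(abs(wavenumbers - center))
  mean(intensity[idx])
}

#' Peak intensity ratio of one spectrum
#'
#' Ratio of two [extract_peak_intensity()] read-offs (e.g. I2940/I2850,
#' whose elevation in carcinoma reflects decreased lipid and increased
#' protein content).
#'
#' @param intensity,wavenumbers One segment and its axis (both peaks must
#'   lie on it).
#' @param num_center,den_center Numerator and denominator peak positions.
#' @param half_width Window half-width, cm^-1.
#' @return Unitless ratio.
#' @export
intensity_ratio <- function(intensity, wavenumbers, num_center, den_center,
                            half_width = 5) {
  num <- extract_peak_intensity(intensity, wavenumbers, num_center,
                                half_width)
  den <- extract_peak_intensity(intensity, wavenumbers, den_center,
                                half_width)
  if (den == 0) stop("undefined ratio: zero denominator intensity")
  num / den
}

#' Peak panel intensities for a whole set
#'
#' @param set A normalized [spectra_set()].
#' @param centers Peak positions, cm^-1 (default: the nine most
#'   diagnostic esophageal bands).
#' @param half_width Window half-width, cm^-1.
#' @return Data frame: one row per spectrum with its label and one column
#'   per peak (named `I853`, `I1078`, ...).
#' @export
peak_panel <- function(set, centers = c(853, 1078, 1335, 1618, 1655,
                                        2850, 2885, 3250, 3400),
                       half_width = 5) {
  stopifnot(inherits(set, "spectra_set"))
  vals <- sapply(centers, function(cc) {
    if (cc <= FP_RANGE[2]) {
      idx <- abs(set$fp_wavenumbers - cc) <= half_width + 1e-9
      rowMeans(set$fp[, idx, drop = FALSE])
    } else {
      idx <- abs(set$hw_wavenumbers - cc) <= half_width + 1e-9
      rowMeans(set$hw[, idx, drop = FALSE])
    }
  })
  vals <- matrix(vals, nrow = n_spectra(set))
  colnames(vals) <- paste0("I", centers)
  cbind(set$manifest[c("spectrum_id", "patient_id", "site_id", "label")],
        as.data.frame(vals))
}

#' Youden-optimal single-ratio threshold classifier
#'
#' Scans every midpoint between consecutive sorted distinct values, in
#' both orientations (ratio >= threshold calls ESCC, or <=), and selects
#' the threshold maximizing Youden's J = sensitivity + specificity - 1.
#' Ties are broken toward higher sensitivity, then toward the lower
#' threshold (and, across orientations, toward the `">="` rule). Counts
#' are reported on the same data the threshold was selected on.
#'
#' @param values Per-spectrum ratio (or any scalar marker) values.
#' @param labels Matching labels; `positive` is the ESCC class.
#' @param positive Label treated as positive (default `"ESCC"`).
#' @return A `ratio_classifier_result` list: threshold, orientation,
#'   confusion counts, sensitivity/specificity (and percents), Youden J.
#' @export
ratio_threshold_classifier <- function(values, labels, positive = "ESCC") {
  stopifnot(length(values) == length(labels))
  y <- labels == positive
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present")
  v <- sort(unique(values))
  cand <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  cand <- c(min(v) - 1, cand, max(v) + 1)
  best <- NULL
  for (orientation in c(">=", "<=")) {
    for (th in cand) {
      call_pos <- if (orientation == ">=") values >= th else values <= th
      tp <- sum(call_pos & y); fp <- sum(call_pos & !y)
      sens <- tp / n_pos; spec <- (n_neg - fp) / n_neg
      j <- sens + spec - 1
      cand_res <- list(threshold = th, orientation = orientation,
                       tp = tp, fn = n_pos - tp, tn = n_neg - fp, fp = fp,
                       sensitivity = sens, specificity = spec, youden_j = j)
      if (is.null(best) ||
          j > best$youden_j + 1e-12 ||
          (abs(j - best$youden_j) <= 1e-12 &&
           (sens > best$sensitivity + 1e-12 ||
            (abs(sens - best$sensitivity) <= 1e-12 && th < best$threshold))))
        best <- cand_res
    }
  }
  best$sensitivity_pct <- round(100 * best$sensitivity, 1)
  best$specificity_pct <- round(100 * best$specificity, 1)
  structure(best, class = "ratio_classifier_result")
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with the
#' expected agreement `p_e` from the product of the raters' marginal
#' category frequencies.
#'
#' @param rater1,rater2 Equal-length categorical label vectors.
#' @return Kappa (unitless, <= 1).
#' @export
cohens_kappa <- function(rater1, rater2) {
  if (length(rater1) != length(rater2))
    stop("rating vectors must have equal length")
  cats <- union(unique(rater1), unique(rater2))
  if (length(cats) < 2)
    stop("need at least 2 categories across the raters")
  tab <- table(factor(rater1, levels = cats), factor(rater2, levels = cats))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e <= .Machine$double.eps)
    stop("undefined kappa: degenerate marginals (p_e = 1)")
  (p_o - p_e) / (1 - p_e)
}
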