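# Preprocessing chain: Savitzky-Golay smoothing -> range-specific
# polynomial autofluorescence removal (order 5 in FP, order 1 in HW) ->
# SNR quality control -> joint FP+HW area normalization.

#' Configure the preprocessing chain
#'
#' @param sg_window Savitzky-Golay window width in channels (odd).
#' @param sg_order Savitzky-Golay polynomial order (< `sg_window`). The
#'   default (5, 3) is the nearest mathematically valid neighborhood of
#'   the classical 3-pixel third-order setting used online by clinical
#'   Raman systems; `(3, 2)` reproduces that literal setting (which is an
#'   exact interpolation, i.e. no smoothing).
#' @param fp_poly_order Autofluorescence polynomial order in FP
#'   (default 5).
#' @param hw_poly_order Autofluorescence polynomial order in HW
#'   (default 1).
#' @param baseline_mode `"iterative"` (modified polyfit that converges to
#'   the fluorescence floor beneath the Raman peaks; default) or
#'   `"single_pass"` (one least-squares fit).
#' @param iterative_max_iter,iterative_tol Stopping rule for the
#'   iterative baseline: stop when the maximum absolute change of the
#'   fitted baseline falls below `iterative_tol`, or after
#'   `iterative_max_iter` refits (with a warning).
#' @param normalization `"combined_area"` (joint FP+HW trapezoidal area;
#'   default) or `"per_range"`.
#' @param qc_min_snr Minimum accepted signal-to-noise ratio at the
#'   2940 cm^-1 protein CH3 band.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 5L, sg_order = 3L,
                              fp_poly_order = 5L, hw_poly_order = 1L,
                              baseline_mode = c("iterative", "single_pass"),
                              iterative_max_iter = 2000L,
                              iterative_tol = 1e-5,
                              normalization = c("combined_area",
                                                "per_range"),
                              qc_min_snr = 3) {
  baseline_mode <- match.arg(baseline_mode)
  normalization <- match.arg(normalization)
  if (sg_window %% 2 != 1) stop("sg_window must be odd")
  if (sg_order >= sg_window)
    stop("sg_order must be smaller than sg_window")
  stopifnot(sg_order >= 0, fp_poly_order >= 0, hw_poly_order >= 0,
            iterative_max_iter >= 1, iterative_tol > 0, qc_min_snr >= 0)
  structure(list(sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 fp_poly_order = as.integer(fp_poly_order),
                 hw_poly_order = as.integer(hw_poly_order),
                 baseline_mode = baseline_mode,
                 iterative_max_iter = as.integer(iterative_max_iter),
                 iterative_tol = iterative_tol,
                 normalization = normalization,
                 qc_min_snr = qc_min_snr),
            class = "preprocess_config")
}

#' Fit a pixel-to-wavenumber calibration polynomial
#'
#' Least-squares polynomial mapping detector pixel index to wavenumber,
#' fitted from reference emission/standard lines (e.g. a mercury/argon
#' lamp in FP, or the 2931 and 3064 cm^-1 bands of 4-acetamidophenol in
#' HW). With exactly `degree + 1` pairs the map interpolates the
#' references exactly.
#'
#' @param pixel_positions Observed pixel positions of the reference lines.
#' @param reference_lines Their true wavenumbers (cm^-1).
#' @param degree Polynomial degree.
#' @return A `calibration_map` with coefficients (ascending powers),
#'   degree and residual RMS in cm^-1. The fitted map must be strictly
#'   increasing over the pixel domain.
#' @export
fit_wavenumber_calibration <- function(pixel_positions, reference_lines,
                                       degree = 1L) {
  n <- length(pixel_positions)
  if (length(reference_lines) != n)
    stop("pixel_positions and reference_lines must have equal length")
  if (anyDuplicated(pixel_positions)) stop("pixel positions must be distinct")
  if (n < degree + 1)
    stop(sprintf("need at least %d (pixel, line) pairs for degree %d",
                 degree + 1L, degree))
  X <- outer(pixel_positions, 0:degree, `^`)
  fit <- stats::lm.fit(X, reference_lines)
  coef <- fit$coefficients
  rms <- sqrt(mean(fit$residuals^2))
  grid <- seq(min(pixel_positions), max(pixel_positions), length.out = 256)
  mapped <- drop(outer(grid, 0:degree, `^`) %*% coef)
  if (any(diff(mapped) <= 0))
    stop("calibration map is not strictly increasing over the pixel domain")
  structure(list(coefficients = unname(coef), degree = as.integer(degree),
                 residual_rms = rms),
            class = "calibration_map")
}

#' Evaluate a calibration map at pixel positions
#' @param map A `calibration_map` from [fit_wavenumber_calibration()].
#' @param pixels Pixel positions.
#' @return Wavenumbers in cm^-1.
#' @export
apply_calibration <- function(map, pixels) {
  stopifnot(inherits(map, "calibration_map"))
  drop(outer(pixels, 0:map$degree, `^`) %*% map$coefficients)
}

#' Divide out the relative system spectral response
#'
#' @param intensity Intensity vector (or matrix, spectra in rows).
#' @param response Per-channel relative response (> 0), aligned to the
#'   same axis.
#' @return Corrected intensities: `intensity / response` per channel.
#' @export
apply_response_correction <- function(intensity, response) {
  if (any(response <= 0)) stop("response values must be positive")
  if (is.matrix(intensity)) {
    if (ncol(intensity) != length(response))
      stop("response length does not match the channel count")
    sweep(intensity, 2, response, `/`)
  } else {
    if (length(intensity) != length(response))
      stop("response length does not match the channel count")
    intensity / response
  }
}

# Truncated-window Savitzky-Golay weights: row i of the returned n x n
# action is the least-squares polynomial smoother evaluated at channel i,
# fitted on the window clipped to the data range. Interior rows equal the
# classical convolution coefficients.
sg_smooth_vector <- function(y, window, order) {
  n <- length(y)
  h <- (window - 1L) %/% 2L
  if (n <= window) {
    ord <- min(order, n - 1L)
    X <- outer(seq_len(n) - 1, 0:ord, `^`)
    return(drop(X %*% qr.coef(qr(X), y)))
  }
  # interior: symmetric window convolution
  Xw <- outer(-h:h, 0:order, `^`)
  w_center <- solve(crossprod(Xw), t(Xw))[1, ]  # row for power 0 at x = 0
  out <- stats::filter(y, rev(w_center), sides = 2)
  out <- as.numeric(out)
  # edges: truncated window, polynomial order capped at points - 1
  for (i in c(seq_len(h), (n - h + 1L):n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    x <- (lo:hi) - i
    ord <- min(order, length(x) - 1L)
    X <- outer(x, 0:ord, `^`)
    beta <- qr.coef(qr(X), y[lo:hi])
    out[i] <- beta[1]
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing applied independently per
#' segment; reproduces polynomials up to the fitted order exactly. Edge
#' channels are smoothed with the window truncated to the data range.
#'
#' @param y Intensity vector, or matrix with spectra in rows.
#' @param window Odd window width in channels.
#' @param order Polynomial order, < `window`.
#' @return Smoothed intensities, same shape as `y`.
#' @export
smooth_sg <- function(y, window = 5L, order = 3L) {
  if (window %% 2 != 1) stop("window must be odd")
  if (order >= window) stop("order must be smaller than window")
  if (is.matrix(y)) t(apply(y, 1, sg_smooth_vector, window = window,
                            order = order))
  else sg_smooth_vector(y, window, order)
}

# Orthonormal polynomial basis on normalized coordinates, shared by all
# spectra on one axis.
poly_basis <- function(n_channels, order) {
  u <- seq(-1, 1, length.out = n_channels)
  qr.Q(qr(outer(u, 0:order, `^`)))
}

#' Remove the autofluorescence baseline from one segment
#'
#' Fits a polynomial of order `poly_order` to the segment and subtracts
#' it. `single_pass` performs one least-squares fit (the literal
#' fit-and-subtract reading). `iterative` performs the modified-polyfit
#' iteration: refit on `pmin(input, previous fit)` until the fit changes
#' by less than `tol` everywhere (or `max_iter` is reached, with a
#' warning), which converges onto the fluorescence floor beneath the
#' Raman peaks.
#'
#' @param y Segment intensity vector (or matrix, spectra in rows).
#' @param poly_order Baseline polynomial order.
#' @param mode `"single_pass"` or `"iterative"`.
#' @param max_iter,tol Iterative stopping rule.
#' @return List with `raman` (= `y` - baseline) and `baseline`, each the
#'   shape of `y`.
#' @export
remove_autofluorescence <- function(y, poly_order,
                                    mode = c("iterative", "single_pass"),
                                    max_iter = 2000L, tol = 1e-5) {
  mode <- match.arg(mode)
  mat <- is.matrix(y)
  Y <- if (mat) y else matrix(y, nrow = 1)
  if (ncol(Y) <= poly_order + 1)
    stop("segment must be longer than poly_order + 1")
  Q <- poly_basis(ncol(Y), poly_order)
  fit <- Y %*% Q %*% t(Q)
  if (mode == "iterative") {
    active <- rep(TRUE, nrow(Y))
    work <- pmin(Y, fit)
    for (k in seq_len(max_iter)) {
      new_fit <- fit
      new_fit[active, ] <- work[active, , drop = FALSE] %*% Q %*% t(Q)
      delta <- abs(new_fit - fit)
      active <- apply(delta, 1, max) >= tol
      fit <- new_fit
      work <- pmin(work, fit)
      if (!any(active)) break
    }
    if (any(active))
      warning(sprintf(
        "baseline iteration did not converge for %d spectrum/spectra after %d iterations; returning last iterate",
        sum(active), max_iter))
  }
  raman <- Y - fit
  if (!mat) list(raman = drop(raman), baseline = drop(fit))
  else list(raman = raman, baseline = fit)
}

trapz <- function(y, x) {
  n <- length(x)
  sum((abs(y[-1]) + abs(y[-n])) * diff(x)) / 2
}

trapz_matrix <- function(Y, x) {
  n <- length(x)
  dx <- diff(x)
  A <- abs(Y)
  drop((A[, -1, drop = FALSE] + A[, -n, drop = FALSE]) %*% dx) / 2
}

#' Normalize a dual-range spectrum to unit combined area
#'
#' Divides both segments by the total trapezoidal area (of the absolute
#' intensity) over the FP plus the HW range, so relative band intensities
#' and spectral shapes become comparable across spectra. With
#' `per_range = TRUE`, each range is instead normalized to its own unit
#' area.
#'
#' @param fp,hw Segment intensity vectors (or matrices, spectra in rows).
#' @param fp_wavenumbers,hw_wavenumbers The segment axes.
#' @param per_range Normalize each range separately (non-default).
#' @return List of normalized `fp` and `hw`.
#' @export
normalize_combined_area <- function(fp, hw, fp_wavenumbers, hw_wavenumbers,
                                    per_range = FALSE) {
  mat <- is.matrix(fp)
  FPm <- if (mat) fp else matrix(fp, nrow = 1)
  HWm <- if (mat) hw else matrix(hw, nrow = 1)
  a_fp <- trapz_matrix(FPm, fp_wavenumbers)
  a_hw <- trapz_matrix(HWm, hw_wavenumbers)
  if (per_range) {
    if (any(a_fp <= .Machine$double.eps) || any(a_hw <= .Machine$double.eps))
      stop("degenerate spectrum: zero integrated area")
    FPm <- FPm / a_fp
    HWm <- HWm / a_hw
  } else {
    a <- a_fp + a_hw
    if (any(a <= .Machine$double.eps))
      stop("degenerate spectrum: zero combined integrated area")
    FPm <- FPm / a
    HWm <- HWm / a
  }
  if (!mat) list(fp = drop(FPm), hw = drop(HWm))
  else list(fp = FPm, hw = HWm)
}

#' Signal-to-noise quality check
#'
#' Accepts a background-removed spectrum iff the intensity at the channel
#' nearest 2940 cm^-1 (the strong protein CH3 stretching band, present in
#' any in-contact tissue spectrum) divided by a robust noise estimate --
#' the median absolute second difference of the HW segment divided by
#' 1.048 -- reaches `qc_min_snr`. Probe-off-tissue acquisitions lack the
#' band and are rejected.
#'
#' @param fp,hw Background-removed segment intensities (vectors).
#' @param fp_wavenumbers,hw_wavenumbers Segment axes.
#' @param config A [preprocess_config()].
#' @return List with `accept` (logical), `snr` and `reason`.
#' @export
qc_accept <- function(fp, hw, fp_wavenumbers, hw_wavenumbers,
                      config = preprocess_config()) {
  i2940 <- which.min(abs(hw_wavenumbers - 2940))
  peak <- hw[i2940]
  noise <- stats::median(abs(diff(hw, differences = 2))) / 1.048
  snr <- if (noise > 0) peak / noise else if (peak > 0) Inf else 0
  accept <- snr >= config$qc_min_snr
  list(accept = accept, snr = snr,
       reason = if (accept) "ok"
       else sprintf("SNR %.3g below threshold %.3g", snr, config$qc_min_snr))
}

#' Preprocess a raw spectra set
#'
#' Applies the full chain to every spectrum: Savitzky-Golay smoothing,
#' polynomial autofluorescence removal (order `fp_poly_order` in FP,
#' `hw_poly_order` in HW), SNR quality control, and combined-area
#' normalization of the survivors. Non-convergent baseline iterations are
#' counted into the log rather than warned per spectrum.
#'
#' @param set A raw-stage [spectra_set()].
#' @param config A [preprocess_config()].
#' @return List with `set` (normalized-stage [spectra_set()] of accepted
#'   spectra) and `rejections` (data frame of spectrum id, reason, SNR).
#' @export
preprocess_set <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"),
            inherits(config, "preprocess_config"))
  if (set$stage != "raw")
    stop("preprocess_set expects a raw-stage set")
  fp_s <- smooth_sg(set$fp, config$sg_window, config$sg_order)
  hw_s <- smooth_sg(set$hw, config$sg_window, config$sg_order)
  n_nonconv <- 0L
  strip <- function(Y, order) {
    withCallingHandlers(
      remove_autofluorescence(Y, order, mode = config$baseline_mode,
                              max_iter = config$iterative_max_iter,
                              tol = config$iterative_tol),
      warning = function(w) {
        n_nonconv <<- n_nonconv + 1L
        invokeRestart("muffleWarning")
      })
  }
  fp_b <- strip(fp_s, config$fp_poly_order)
  hw_b <- strip(hw_s, config$hw_poly_order)

  qc <- lapply(seq_len(n_spectra(set)), function(i)
    qc_accept(fp_b$raman[i, ], hw_b$raman[i, ],
              set$fp_wavenumbers, set$hw_wavenumbers, config))
  accept <- vapply(qc, `[[`, logical(1), "accept")
  rejections <- data.frame(
    spectrum_id = set$manifest$spectrum_id[!accept],
    reason = vapply(qc[!accept], `[[`, character(1), "reason"),
    snr = vapply(qc[!accept], `[[`, numeric(1), "snr"))
  if (!any(accept))
    stop("all spectra rejected by quality control")
  if (n_nonconv > 0)
    message(sprintf("baseline iteration hit max_iter for %d segment batch(es)",
                    n_nonconv))

  norm <- normalize_combined_area(
    fp_b$raman[accept, , drop = FALSE], hw_b$raman[accept, , drop = FALSE],
    set$fp_wavenumbers, set$hw_wavenumbers,
    per_range = config$normalization == "per_range")
  out <- spectra_set(set$fp_wavenumbers, set$hw_wavenumbers,
                     norm$fp, norm$hw,
                     set$manifest[accept, , drop = FALSE],
                     stage = "normalized")
  list(set = out, rejections = rejections)
}
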