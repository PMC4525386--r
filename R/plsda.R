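# Mean-centered PLS-DA via NIPALS (PLS1 on a 0/1 class response),
# logistic posterior calibration, leave-one-patient-out cross-validation,
# patient-level train/test splitting, confusion metrics and ROC.

#' Build a feature matrix from a spectra set
#'
#' Rows are spectra (FP channels, HW channels, or FP followed by HW);
#' the class vector codes ESCC = 1 and normal = 0.
#'
#' @param set A normalized-stage [spectra_set()].
#' @param view `"FP"`, `"HW"` or `"FP+HW"`.
#' @return A `feature_matrix` list: matrix `x`, response `y`, `view`, and
#'   the manifest `keys`.
#' @export
build_feature_matrix <- function(set, view = c("FP+HW", "FP", "HW")) {
  stopifnot(inherits(set, "spectra_set"))
  view <- match.arg(view)
  if (any(set$manifest$label == "unknown"))
    stop("cannot build a class vector: 'unknown' labels present")
  x <- switch(view, "FP" = set$fp, "HW" = set$hw,
              "FP+HW" = cbind(set$fp, set$hw))
  colnames(x) <- switch(view,
    "FP" = paste0("fp_", set$fp_wavenumbers),
    "HW" = paste0("hw_", set$hw_wavenumbers),
    "FP+HW" = c(paste0("fp_", set$fp_wavenumbers),
                paste0("hw_", set$hw_wavenumbers)))
  structure(list(x = x,
                 y = as.numeric(set$manifest$label == "ESCC"),
                 view = view,
                 keys = set$manifest[c("spectrum_id", "patient_id",
                                       "site_id", "replicate", "label")]),
            class = "feature_matrix")
}

#' Patient-level train/test split
#'
#' Partitions patients (never individual spectra) into train and test so
#' replicate spectra of one patient can never leak across the split,
#' targeting a given fraction of *spectra* in the training partition.
#' Random patient orders are tried greedily until the achieved fraction
#' is within `tolerance` of the target and both classes appear in both
#' partitions.
#'
#' @param set A [spectra_set()] with at least two patients per class.
#' @param train_fraction Target fraction of spectra in train
#'   (default 0.8).
#' @param seed Integer seed for the randomized search.
#' @param tolerance Allowed deviation of the achieved spectra fraction
#'   (default 0.03).
#' @param max_tries Number of random orders to try before giving up.
#' @return List of `train` and `test` [spectra_set()]s.
#' @export
split_by_patient <- function(set, train_fraction = 0.8, seed = 1L,
                             tolerance = 0.03, max_tries = 200L) {
  stopifnot(inherits(set, "spectra_set"),
            train_fraction > 0, train_fraction < 1)
  man <- set$manifest
  patients <- unique(man$patient_id)
  if (length(patients) < 2) stop("need at least 2 patients to split")
  sizes <- table(man$patient_id)[patients]
  total <- n_spectra(set)
  target <- train_fraction * total
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  best <- NULL
  for (try in seq_len(max_tries)) {
    ord <- sample(patients)
    cum <- cumsum(as.numeric(sizes[ord]))
    k <- which(cum >= target)[1]
    # take whichever cut (before/after patient k) is closer to the target
    if (k > 1 && abs(cum[k - 1] - target) < abs(cum[k] - target))
      k <- k - 1L
    train_pat <- ord[seq_len(k)]
    in_train <- man$patient_id %in% train_pat
    frac <- mean(in_train)
    if (abs(frac - train_fraction) > tolerance) next
    lab_tr <- unique(man$label[in_train])
    lab_te <- unique(man$label[!in_train])
    if (!all(c("normal", "ESCC") %in% lab_tr) ||
        !all(c("normal", "ESCC") %in% lab_te)) next
    best <- in_train
    break
  }
  if (is.null(best))
    stop(sprintf(paste0(
      "no patient partition reaches a train spectra fraction of ",
      "%.2f +/- %.2f with both classes in both partitions ",
      "(%d patients, sizes %s)"),
      train_fraction, tolerance, length(patients),
      paste(as.integer(sizes), collapse = ",")))
  list(train = set[best], test = set[!best])
}

# NIPALS PLS1 on centered X and y. Returns per-component weights W,
# X-loadings P, y-loadings q and the score normalizations, from which
# nested coefficient vectors for any number of components <= A follow.
nipals_pls1 <- function(Xc, yc, n_components) {
  n <- nrow(Xc); m <- ncol(Xc)
  A <- n_components
  W <- matrix(0, m, A); P <- matrix(0, m, A); q <- numeric(A)
  Tm <- matrix(0, n, A)
  X <- Xc; y <- yc
  for (a in seq_len(A)) {
    w <- drop(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t <- drop(X %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) { A <- a - 1L; break }
    p <- drop(crossprod(X, t)) / tt
    qa <- sum(y * t) / tt
    X <- X - tcrossprod(t, p)
    y <- y - t * qa
    W[, a] <- w; P[, a] <- p; q[a] <- qa; Tm[, a] <- t
  }
  if (A == 0) stop("X carries no covariance with the response")
  list(W = W[, seq_len(A), drop = FALSE],
       P = P[, seq_len(A), drop = FALSE],
       q = q[seq_len(A)], scores = Tm[, seq_len(A), drop = FALSE],
       n_components = A)
}

# Coefficient vector for the first k components: B = W (P'W)^-1 q.
pls_coefficients <- function(nip, k = nip$n_components) {
  W <- nip$W[, seq_len(k), drop = FALSE]
  P <- nip$P[, seq_len(k), drop = FALSE]
  q <- nip$q[seq_len(k)]
  drop(W %*% solve(crossprod(P, W), q))
}

# Logistic calibration of PLS scores to posterior probabilities; falls
# back to a steep sigmoid through the class-mean midpoint when glm
# cannot produce finite coefficients (perfect separation).
fit_calibration <- function(scores, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm(y ~ scores,
                                family = stats::binomial())),
    error = function(e) NULL)
  co <- if (!is.null(fit)) stats::coef(fit) else c(NA_real_, NA_real_)
  if (any(!is.finite(co)) || co[2] == 0) {
    mid <- (mean(scores[y == 1]) + mean(scores[y == 0])) / 2
    spread <- stats::sd(scores)
    if (!is.finite(spread) || spread == 0) spread <- 1
    slope <- 50 / spread
    co <- c(-slope * mid, slope)
  }
  list(intercept = unname(co[1]), slope = unname(co[2]))
}

#' Fit a PLS-DA model
#'
#' Mean-centers the training matrix and the 0/1 class response, runs the
#' NIPALS PLS1 iteration for `n_components` latent variables (LVs), and
#' fits a logistic calibration mapping the continuous PLS prediction
#' score to a posterior probability of ESCC.
#'
#' @param fm A training [build_feature_matrix()] result.
#' @param n_components Number of latent variables (1 <=
#'   `n_components` <= min(rows - 1, columns)).
#' @return A `plsda_model`: centering vector, per-LV weights/loadings,
#'   assembled regression coefficients, calibration parameters.
#' @export
fit_plsda <- function(fm, n_components) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$y
  if (length(unique(y)) < 2) stop("response is constant: one class only")
  n <- nrow(fm$x); m <- ncol(fm$x)
  if (n_components < 1 || n_components > min(n - 1, m))
    stop("n_components out of bounds")
  center <- colMeans(fm$x)
  Xc <- sweep(fm$x, 2, center)
  if (all(abs(Xc) < 1e-14)) stop("zero-variance feature matrix")
  ybar <- mean(y)
  nip <- nipals_pls1(Xc, y - ybar, n_components)
  B <- pls_coefficients(nip)
  scores <- drop(Xc %*% B) + ybar
  cal <- fit_calibration(scores, y)
  structure(list(center = center, ybar = ybar,
                 weights = nip$W, x_loadings = nip$P, y_loadings = nip$q,
                 coefficients = B, n_components = nip$n_components,
                 calibration = cal, nipals = nip, view = fm$view),
            class = "plsda_model")
}

#' Posterior ESCC probabilities for new spectra
#'
#' Centers with the training means, forms the PLS prediction score
#' `(x - center) . B + ybar`, and applies the logistic calibration.
#' Posteriors >= 0.5 call ESCC.
#'
#' @param model A [fit_plsda()] model.
#' @param x_new Feature matrix (or vector) with the training column
#'   layout.
#' @return Numeric vector of posterior probabilities in `[0, 1]`.
#' @export
predict_posterior <- function(model, x_new) {
  stopifnot(inherits(model, "plsda_model"))
  if (!is.matrix(x_new)) x_new <- matrix(x_new, nrow = 1)
  if (ncol(x_new) != length(model$center))
    stop("column layout does not match the training matrix")
  score <- drop(sweep(x_new, 2, model$center) %*% model$coefficients) +
    model$ybar
  stats::plogis(model$calibration$intercept +
                  model$calibration$slope * score)
}

#' Leave-one-patient-out cross-validation
#'
#' For every candidate LV count `1..max_components`, each patient's
#' spectra are predicted by a model fitted on all other patients (one
#' NIPALS run per fold gives all nested component counts). The LV count
#' maximizing pooled cross-validated accuracy at the 0.5 posterior
#' threshold is selected, ties going to fewer LVs. Folds whose training
#' part lacks a class are skipped with a warning.
#'
#' @param set A normalized [spectra_set()] with >= 3 patients, both
#'   classes present.
#' @param view `"FP+HW"`, `"FP"` or `"HW"`.
#' @param max_components Largest LV count considered.
#' @return A `cv_result` list: per-spectrum held-out `posterior`, true
#'   0/1 `label`, `patient_id`, `fold`, the chosen `n_components`, and
#'   `accuracy_by_k` over all candidates.
#' @export
lopcv <- function(set, view = "FP+HW", max_components = 8L) {
  stopifnot(inherits(set, "spectra_set"))
  fm <- build_feature_matrix(set, view)
  patients <- unique(fm$keys$patient_id)
  if (length(patients) < 3) stop("need at least 3 patients for LOPCV")
  if (length(unique(fm$y)) < 2) stop("both classes must be present")
  n <- nrow(fm$x)
  kmax <- min(max_components, ncol(fm$x))
  for (p in patients) {
    ntr <- sum(fm$keys$patient_id != p)
    kmax <- min(kmax, ntr - 1L)
  }
  post <- matrix(NA_real_, n, kmax)
  fold <- rep(NA_integer_, n)
  skipped <- character(0)
  for (f in seq_along(patients)) {
    hold <- fm$keys$patient_id == patients[f]
    ytr <- fm$y[!hold]
    if (length(unique(ytr)) < 2) {
      skipped <- c(skipped, patients[f])
      next
    }
    Xtr <- fm$x[!hold, , drop = FALSE]
    center <- colMeans(Xtr)
    ybar <- mean(ytr)
    nip <- nipals_pls1(sweep(Xtr, 2, center), ytr - ybar, kmax)
    Xte_c <- sweep(fm$x[hold, , drop = FALSE], 2, center)
    Xtr_c <- sweep(Xtr, 2, center)
    for (k in seq_len(nip$n_components)) {
      B <- pls_coefficients(nip, k)
      str <- drop(Xtr_c %*% B) + ybar
      cal <- fit_calibration(str, ytr)
      ste <- drop(Xte_c %*% B) + ybar
      post[hold, k] <- stats::plogis(cal$intercept + cal$slope * ste)
    }
    if (nip$n_components < kmax)
      for (k in (nip$n_components + 1L):kmax)
        post[hold, k] <- post[hold, nip$n_components]
    fold[hold] <- f
  }
  if (length(skipped) > 0)
    warning("patients skipped (training fold lacked a class): ",
            paste(skipped, collapse = ", "))
  done <- !is.na(fold)
  if (!any(done)) stop("every LOPCV fold was skipped")
  acc <- vapply(seq_len(kmax), function(k)
    mean((post[done, k] >= 0.5) == (fm$y[done] == 1)), numeric(1))
  best_k <- which.max(acc)  # which.max takes the first (fewest LVs) on ties
  structure(list(posterior = post[, best_k],
                 label = fm$y, patient_id = fm$keys$patient_id,
                 spectrum_id = fm$keys$spectrum_id,
                 fold = fold, n_components = best_k,
                 accuracy_by_k = acc, view = view,
                 skipped_patients = skipped),
            class = "cv_result")
}

#' Confusion metrics from counts
#'
#' @param tp,fn,tn,fp Confusion counts (ESCC positive).
#' @return A `confusion_metrics` list with counts, sensitivity =
#'   TP/(TP+FN), specificity = TN/(TN+FP), accuracy, and the same as
#'   percents rounded to one decimal.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / (tp + fn + tn + fp)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 sensitivity_pct = round(100 * sens, 1),
                 specificity_pct = round(100 * spec, 1),
                 accuracy_pct = round(100 * acc, 1)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "confusion: TP=%d FN=%d TN=%d FP=%d\n",
    "  sensitivity %.1f%% (%d/%d), specificity %.1f%% (%d/%d), ",
    "accuracy %.1f%% (%d/%d)\n"),
    x$tp, x$fn, x$tn, x$fp,
    x$sensitivity_pct, x$tp, x$tp + x$fn,
    x$specificity_pct, x$tn, x$tn + x$fp,
    x$accuracy_pct, x$tp + x$tn, x$tp + x$fn + x$tn + x$fp))
  invisible(x)
}

#' Confusion metrics from cross-validated predictions
#'
#' @param result A `cv_result` (from [lopcv()]) or any list with
#'   `posterior` and 0/1 `label` (NAs from skipped folds are dropped).
#' @param threshold Posterior decision threshold (default 0.5).
#' @return A [confusion_metrics()] object.
#' @export
confusion_from_predictions <- function(result, threshold = 0.5) {
  ok <- !is.na(result$posterior)
  post <- result$posterior[ok]
  y <- result$label[ok]
  call_pos <- post >= threshold
  confusion_metrics(tp = sum(call_pos & y == 1),
                    fn = sum(!call_pos & y == 1),
                    tn = sum(!call_pos & y == 0),
                    fp = sum(call_pos & y == 0))
}

#' ROC curve over posterior thresholds
#'
#' Thresholds are the sorted distinct posteriors with -Inf/+Inf
#' sentinels; a spectrum is called ESCC when its posterior is >= the
#' threshold. The AUC is the trapezoidal area under TPR vs FPR.
#'
#' @param result As in [confusion_from_predictions()].
#' @return A `roc_curve` list: `thresholds` (descending), `tpr`, `fpr`,
#'   `auc`.
#' @export
roc_curve <- function(result) {
  ok <- !is.na(result$posterior)
  post <- result$posterior[ok]
  y <- result$label[ok]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present for a ROC curve")
  th <- c(Inf, sort(unique(post), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) sum(post >= t & y == 1) / n_pos, numeric(1))
  fpr <- vapply(th, function(t) sum(post >= t & y == 0) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' Train/test evaluation with patient-disjoint sets
#'
#' Chooses the LV count by [lopcv()] on the training set only, refits on
#' all training spectra, and evaluates posteriors on the held-out test
#' set. Any patient overlap between the two sets is a protocol violation.
#'
#' @param train,test Normalized [spectra_set()]s with disjoint patients.
#' @param view `"FP+HW"`, `"FP"` or `"HW"`.
#' @param max_components Largest LV count considered during selection.
#' @return List: `metrics` ([confusion_metrics()]), `roc`
#'   ([roc_curve()]), `posterior`, `label`, `n_components`, and the
#'   training `cv` result.
#' @export
evaluate_holdout <- function(train, test, view = "FP+HW",
                             max_components = 8L) {
  overlap <- intersect(unique(train$manifest$patient_id),
                       unique(test$manifest$patient_id))
  if (length(overlap) > 0)
    stop("protocol violation: patients present in both train and test: ",
         paste(overlap, collapse = ", "))
  cv <- lopcv(train, view, max_components)
  model <- fit_plsda(build_feature_matrix(train, view), cv$n_components)
  fm_test <- build_feature_matrix(test, view)
  post <- predict_posterior(model, fm_test$x)
  res <- list(posterior = post, label = fm_test$y)
  list(metrics = confusion_from_predictions(res),
       roc = roc_curve(res),
       posterior = post, label = fm_test$y,
       n_components = cv$n_components, cv = cv, model = model)
}
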