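test_that("feature matrices respect view layout and set order", {
  set <- tiny_set(n = 4)
  expect_equal(ncol(build_feature_matrix(set, "FP")$x), 16)
  expect_equal(ncol(build_feature_matrix(set, "HW")$x), 16)
  fm <- build_feature_matrix(set, "FP+HW")
  expect_equal(ncol(fm$x), 32)
  expect_equal(fm$keys$spectrum_id, set$manifest$spectrum_id)
  expect_equal(fm$y, as.numeric(set$manifest$label == "ESCC"))
  expect_equal(unname(fm$x[, 1:16]), unname(set$fp))

  bad <- tiny_set(n = 4, labels = c("normal", "ESCC", "unknown", "normal"))
  expect_error(build_feature_matrix(bad), "unknown")
})

test_that("patient-level split partitions patients and hits the target", {
  # divisible case: 10 patients x 10 spectra
  set <- tiny_set(n = 100,
                  labels = rep(rep(c("normal", "ESCC"), each = 10), 5),
                  patients = rep(sprintf("P%02d", 1:10), each = 10))
  sp <- split_by_patient(set, 0.8, seed = 2)
  expect_equal(n_spectra(sp$train), 80)
  expect_equal(length(unique(sp$train$manifest$patient_id)), 8)
  tr <- unique(sp$train$manifest$patient_id)
  te <- unique(sp$test$manifest$patient_id)
  expect_length(intersect(tr, te), 0)
  expect_setequal(c(tr, te), sprintf("P%02d", 1:10))

  # unequal patient sizes: enumeration says 80/100 is achievable exactly,
  # and no other subset sum lies within the 3-point tolerance
  sizes <- c(30, 25, 20, 15, 10)
  subset_sums <- unique(colSums(
    t(expand.grid(rep(list(0:1), 5))) * sizes))
  in_tol <- subset_sums[abs(subset_sums / 100 - 0.8) <= 0.03]
  expect_equal(in_tol, 80)
  labs <- rep(c("normal", "ESCC"), 50)
  set2 <- tiny_set(n = 100, labels = labs,
                   patients = rep(sprintf("P%d", 1:5), times = sizes))
  sp2 <- split_by_patient(set2, 0.8, seed = 5)
  expect_equal(n_spectra(sp2$train), 80)

  # unreachable target: one dominating patient
  set3 <- tiny_set(n = 20, labels = rep(c("normal", "ESCC"), 10),
                   patients = rep(c("P1", "P1", "P1", "P2"), each = 5))
  set3$manifest$patient_id <- c(rep("P1", 18), "P2", "P3")
  set3$manifest$replicate <- ave(seq_len(20), set3$manifest$patient_id,
                                 FUN = seq_along)
  set3 <- spectra_set(set3$fp_wavenumbers, set3$hw_wavenumbers, set3$fp,
                      set3$hw, set3$manifest, stage = "normalized")
  expect_error(split_by_patient(set3, 0.8, seed = 1, max_tries = 50),
               "fraction")
})

test_that("NIPALS PLS-DA matches its algebraic oracles", {
  set.seed(6)
  n <- 14; m <- 5
  X <- matrix(rnorm(n * m), n)
  y <- rep(c(0, 1), each = 7)
  fm <- structure(list(x = X, y = y, view = "FP",
                       keys = data.frame(spectrum_id = as.character(1:n))),
                  class = "feature_matrix")

  # first weight vector is proportional to centered X'y
  model <- fit_plsda(fm, 2)
  Xc <- scale(X, scale = FALSE)
  w1 <- drop(crossprod(Xc, y - mean(y)))
  w1 <- w1 / sqrt(sum(w1^2))
  expect_equal(abs(sum(model$weights[, 1] * w1)), 1, tolerance = 1e-10)

  # at full rank the PLS prediction equals ordinary least squares
  full <- fit_plsda(fm, m)
  pls_scores <- drop(Xc %*% full$coefficients) + mean(y)
  ls <- lm.fit(cbind(1, X), y)
  expect_equal(pls_scores, unname(drop(cbind(1, X) %*% ls$coefficients)),
               tolerance = 1e-8)

  # scores are mutually orthogonal
  G <- crossprod(full$nipals$scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)

  # assembled coefficient vector equals sequential componentwise prediction
  nip <- model$nipals
  seq_pred <- numeric(n)
  Xd <- Xc
  for (a in seq_len(model$n_components)) {
    t_a <- drop(Xd %*% nip$W[, a])
    seq_pred <- seq_pred + t_a * nip$q[a]
    Xd <- Xd - tcrossprod(t_a, nip$P[, a])
  }
  expect_equal(seq_pred, drop(Xc %*% model$coefficients),
               tolerance = 1e-10)

  expect_error(fit_plsda(fm, 0), "bounds")
  expect_error(fit_plsda(fm, n), "bounds")
  fm_const <- fm; fm_const$y <- rep(1, n)
  expect_error(fit_plsda(fm_const, 2), "constant|one class")
})

test_that("a one-component model separates rank-1 separable data", {
  set.seed(61)
  n <- 20
  direction <- rnorm(8)
  y <- rep(c(0, 1), each = 10)
  X <- outer(ifelse(y == 1, 3, -3) + rnorm(n, sd = 0.1), direction) +
    matrix(rnorm(n * 8, sd = 0.05), n)
  fm <- structure(list(x = X, y = y, view = "FP",
                       keys = data.frame(spectrum_id = as.character(1:n))),
                  class = "feature_matrix")
  model <- fit_plsda(fm, 1)
  post <- predict_posterior(model, X)
  expect_equal(as.numeric(post >= 0.5), y)
})

test_that("posterior calibration is monotone in the PLS score", {
  set.seed(62)
  X <- matrix(rnorm(60), 12)
  y <- rep(c(0, 1), 6)
  fm <- structure(list(x = X, y = y, view = "FP",
                       keys = data.frame(spectrum_id = as.character(1:12))),
                  class = "feature_matrix")
  model <- fit_plsda(fm, 2)
  Xnew <- matrix(rnorm(10 * ncol(X)), 10)
  score <- drop(sweep(Xnew, 2, model$center) %*% model$coefficients) +
    model$ybar
  post <- predict_posterior(model, Xnew)
  expect_equal(order(post), order(score))
  # logistic definition: posterior 0.5 exactly at the calibration midpoint
  cal <- model$calibration
  expect_equal(plogis(cal$intercept +
                        cal$slope * (-cal$intercept / cal$slope)), 0.5)
  expect_error(predict_posterior(model, Xnew[, 1:3]), "layout")
})

test_that("LOPCV predicts each spectrum once, from other patients' folds", {
  set <- separated_set(n_patients = 6, reps = 4)
  cv <- lopcv(set, "FP+HW", max_components = 3)
  expect_equal(length(unique(cv$fold[!is.na(cv$fold)])), 6)
  expect_true(all(!is.na(cv$posterior)))
  expect_gte(mean((cv$posterior >= 0.5) == (cv$label == 1)), 0.95)

  # the reported posterior is reproduced by refitting without that patient
  p1 <- cv$patient_id == "P1"
  rest <- set[!p1]
  model <- fit_plsda(build_feature_matrix(rest, "FP+HW"),
                     cv$n_components)
  manual <- predict_posterior(model,
                              build_feature_matrix(set[p1], "FP+HW")$x)
  expect_equal(unname(cv$posterior[p1]), unname(manual), tolerance = 1e-10)

  expect_error(lopcv(set[set$manifest$patient_id %in% c("P1", "P2")]),
               "3 patients")
})

test_that("LOPCV skips folds whose training part loses a class", {
  # all carcinoma spectra concentrated in one patient
  set <- separated_set(n_patients = 6, reps = 4)
  man <- set$manifest
  man$label <- ifelse(man$patient_id == "P2", "ESCC", "normal")
  set <- spectra_set(set$fp_wavenumbers, set$hw_wavenumbers, set$fp,
                     set$hw, man, stage = "normalized")
  expect_warning(cv <- lopcv(set, "FP", max_components = 2), "skipped")
  expect_true(all(is.na(cv$posterior[man$patient_id == "P2"])))
  expect_true(all(!is.na(cv$posterior[man$patient_id != "P2"])))
})

test_that("confusion metrics reproduce count-derived percentages", {
  m <- confusion_metrics(tp = 196, fn = 6, tn = 717, fp = 19)
  expect_equal(m$sensitivity_pct, 97.0)
  expect_equal(m$specificity_pct, 97.4)
  expect_equal(m$accuracy_pct, 97.3)

  m2 <- confusion_metrics(tp = 102, fn = 8, tn = 116, fp = 8)
  expect_equal(m2$sensitivity_pct, 92.7)
  expect_equal(m2$specificity_pct, 93.5)  # 116/124 = 93.548...%
  expect_equal(m2$accuracy_pct, 93.2)

  perfect <- confusion_from_predictions(list(posterior = c(0.9, 0.9, 0.1),
                                             label = c(1, 1, 0)))
  expect_equal(perfect$accuracy_pct, 100)
  expect_equal(perfect$sensitivity_pct, 100)
  expect_equal(perfect$specificity_pct, 100)
})

test_that("ROC curves match the Mann-Whitney pairwise oracle", {
  perfect <- roc_curve(list(posterior = c(0.8, 0.9, 0.1, 0.2),
                            label = c(1, 1, 0, 0)))
  expect_equal(perfect$auc, 1)

  # 8-point toy scores with a tie across classes
  post <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.4, 0.9, 0.5)
  lab <- c(0, 0, 0, 1, 1, 1, 1, 0)
  r <- roc_curve(list(posterior = post, label = lab))
  pairs <- expand.grid(p = post[lab == 1], n = post[lab == 0])
  mw <- mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
  expect_equal(r$auc, mw, tolerance = 1e-12)

  # TPR/FPR are non-decreasing along descending thresholds
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  expect_equal(r$tpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)

  # permuted labels give a chance-level AUC
  set.seed(77)
  big_post <- runif(600)
  big_lab <- sample(rep(c(0, 1), each = 300))
  null_auc <- roc_curve(list(posterior = big_post, label = big_lab))$auc
  expect_lt(abs(null_auc - 0.5), 0.05)

  expect_error(roc_curve(list(posterior = c(0.4, 0.5), label = c(1, 1))),
               "classes")

  skip_if_not_installed("pROC")
  ref <- pROC::auc(pROC::roc(lab, post, quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("holdout evaluation enforces patient disjointness and
           generalizes on separated cohorts", {
  set <- separated_set(n_patients = 8, reps = 4, seed = 13)
  sp <- split_by_patient(set, 0.75, seed = 3, tolerance = 0.1)
  expect_error(evaluate_holdout(sp$train, sp$train), "protocol")

  ev1 <- evaluate_holdout(sp$train, sp$test, "FP+HW", max_components = 3)
  ev2 <- evaluate_holdout(sp$train, sp$test, "FP+HW", max_components = 3)
  expect_gte(ev1$metrics$accuracy_pct, 90)
  expect_identical(ev1$posterior, ev2$posterior)
  expect_identical(ev1$metrics, ev2$metrics)
})
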