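test_that("pooled t statistics match the closed form and stats::t.test", {
  set <- tiny_set(n = 6, labels = rep(c("normal", "ESCC"), each = 3),
                  seed = 4)
  st <- channel_ttest(set)
  expect_equal(length(st$t), 32)
  expect_true(all(st$p > 0 & st$p <= 1))

  # hand-computed pooled t at one channel, 3 vs 3
  a <- set$fp[1:3, 5]; b <- set$fp[4:6, 5]
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(st$t[5], unname(t_hand), tolerance = 1e-12)
  expect_equal(st$p[5], 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)

  # independent oracle at several channels
  for (j in c(1, 10, 20)) {
    x <- cbind(set$fp, set$hw)[, j]
    ref <- t.test(x[1:3], x[4:6], var.equal = TRUE)
    expect_equal(st$t[j], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(st$p[j], ref$p.value, tolerance = 1e-10)
  }

  # swapping groups negates t, preserves p
  sw <- channel_ttest(set, group_a = "ESCC", group_b = "normal")
  expect_equal(sw$t, -st$t)
  expect_equal(sw$p, st$p)

  # joint positive rescaling leaves p untouched
  sc <- set; sc$fp <- sc$fp * 12; sc$hw <- sc$hw * 12
  expect_equal(channel_ttest(sc)$p, st$p, tolerance = 1e-12)

  expect_error(channel_ttest(tiny_set(n = 3,
                                      labels = c("normal", "normal",
                                                 "ESCC"))),
               "at least 2")
})

test_that("identical groups give t = 0 and p = 1 everywhere", {
  half <- matrix(rnorm(3 * 16, 10), 3)
  set <- tiny_set(n = 6, labels = rep(c("normal", "ESCC"), each = 3),
                  fp = rbind(half, half), hw = rbind(half, half))
  st <- channel_ttest(set)
  expect_equal(st$t, rep(0, 32) , ignore_attr = TRUE)
  expect_equal(st$p, rep(1, 32), ignore_attr = TRUE)
})

test_that("significant-region extraction partitions sub-threshold runs", {
  fake_stats <- function(p_fp, p_hw) {
    structure(list(
      wavenumbers = c(seq(800, by = 2, length.out = length(p_fp)),
                      seq(2800, by = 2, length.out = length(p_hw))),
      segment = rep(c("FP", "HW"), c(length(p_fp), length(p_hw))),
      p = c(p_fp, p_hw)), class = "channel_statistics")
  }
  expect_equal(nrow(find_significant_regions(
    fake_stats(rep(1, 20), rep(1, 20)))), 0)

  # one sub-threshold channel: a single single-channel region
  p <- rep(1, 20); p[7] <- 1e-12
  r <- find_significant_regions(fake_stats(p, rep(1, 20)))
  expect_equal(nrow(r), 1)
  expect_equal(r$start, r$end)
  expect_equal(r$start, 800 + 6 * 2)

  # single-channel gaps are bridged, two-channel gaps are not
  p2 <- rep(1, 20)
  p2[c(3, 4, 6, 7)] <- 1e-12   # gap of one at index 5
  p2[c(12, 15)] <- 1e-12       # gap of two
  r2 <- find_significant_regions(fake_stats(p2, rep(1, 20)))
  expect_equal(nrow(r2), 3)
  expect_equal(r2$n_channels[1], 5)

  # runs never span the FP/HW inter-range gap
  r3 <- find_significant_regions(fake_stats(rep(1e-12, 20), rep(1e-12, 20)))
  expect_equal(nrow(r3), 2)
  expect_equal(r3$segment, c("FP", "HW"))

  # property: regions are sorted, disjoint and sub-threshold at each end
  set.seed(44)
  for (k in 1:10) {
    pv <- 10^runif(60, -14, 0)
    rr <- find_significant_regions(fake_stats(pv, rep(1, 20)), alpha = 1e-10)
    if (nrow(rr) > 1) {
      expect_true(all(diff(rr$start) > 0))
      expect_true(all(rr$start[-1] > rr$end[-nrow(rr)]))
    }
    if (nrow(rr) > 0) expect_true(all(rr$min_p < 1e-10))
  }
})

test_that("region recovery matches the generator's configured effects", {
  ch <- small_cohort(n_patients = 12, seed = 37)
  pre <- preprocess_set(ch$set)
  st <- channel_ttest(pre$set)
  regions <- find_significant_regions(st, alpha = 1e-10)
  expect_gt(nrow(regions), 0)
  covered <- function(w) any(regions$start - 2 <= w & regions$end + 2 >= w)
  # the strongest configured class effects must be rediscovered
  for (w in c(1078, 1335, 1618, 2850, 2885, 2940)) {
    expect_true(covered(w), label = sprintf("region covering %d cm^-1", w))
  }
})

test_that("peak intensity extraction averages the requested window", {
  ax <- default_axes()
  pk <- render_peak(peak_spec(1445, 22, 1), ax$fp)
  got <- extract_peak_intensity(pk, ax$fp, 1445, half_width = 5)
  oracle <- mean(pk[abs(ax$fp - 1445) <= 5])
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_equal(extract_peak_intensity(rep(3.5, 501), ax$fp, 1200, 8), 3.5)
  imp <- numeric(501); imp[which(ax$fp == 1004)] <- 2
  expect_equal(extract_peak_intensity(imp, ax$fp, 1004, half_width = 0), 2)
  expect_error(extract_peak_intensity(pk, ax$fp, 802, half_width = 10),
               "outside")
})

test_that("intensity ratios behave linearly and follow the class effects", {
  ax <- default_axes()
  two <- render_peak(peak_spec(2850, 28, 1), ax$hw) +
    render_peak(peak_spec(2940, 40, 1), ax$hw)
  r <- intensity_ratio(two, ax$hw, 2940, 2850)
  expect_equal(r, 1, tolerance = 0.06)  # equal peaks, small overlap tails
  doubled <- two + render_peak(peak_spec(2940, 40, 1), ax$hw)
  expect_equal(intensity_ratio(doubled, ax$hw, 2940, 2850), 2 * r,
               tolerance = 0.06)
  expect_error(intensity_ratio(numeric(401) + c(1, rep(0, 400)), ax$hw,
                               2940, 2850), "denominator")

  # I2940/I2850 is higher in the carcinoma class, as configured
  ch <- small_cohort(n_patients = 8, seed = 41)
  pre <- preprocess_set(ch$set)
  ratios <- vapply(seq_len(n_spectra(pre$set)), function(i)
    intensity_ratio(pre$set$hw[i, ], pre$set$hw_wavenumbers, 2940, 2850),
    numeric(1))
  lab <- pre$set$manifest$label
  expect_gt(mean(ratios[lab == "ESCC"]), mean(ratios[lab == "normal"]))
})

test_that("Youden threshold scan equals exhaustive search", {
  brute_force_best_j <- function(values, labels) {
    pos <- labels == "ESCC"
    thresholds <- c(sort(unique(values)) - 1e-9,
                    sort(unique(values)) + 1e-9)
    best <- -Inf
    for (th in thresholds) for (ge in c(TRUE, FALSE)) {
      call <- if (ge) values >= th else values <= th
      j <- sum(call & pos) / sum(pos) + sum(!call & !pos) / sum(!pos) - 1
      best <- max(best, j)
    }
    best
  }

  # perfectly separated values
  sep <- ratio_threshold_classifier(c(1, 2, 3, 11, 12, 13),
                                    c(rep("normal", 3), rep("ESCC", 3)))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)

  # one constant value: no discrimination possible
  flat <- ratio_threshold_classifier(rep(2, 10),
                                     rep(c("normal", "ESCC"), 5))
  expect_equal(flat$youden_j, 0)
  expect_equal(flat$sensitivity + flat$specificity, 1)

  # 20-point toy set against the exhaustive oracle
  set.seed(55)
  v <- round(rnorm(20), 1)
  lab <- sample(rep(c("normal", "ESCC"), 10))
  got <- ratio_threshold_classifier(v, lab)
  expect_equal(got$youden_j, brute_force_best_j(v, lab), tolerance = 1e-12)

  # property: scan equals exhaustive search on random instances, and the
  # counts partition each class
  for (s in 1:8) {
    set.seed(100 + s)
    n <- sample(6:50, 1)
    v <- rnorm(n)
    lab <- c("normal", "ESCC",
             sample(c("normal", "ESCC"), n - 2, replace = TRUE))
    res <- ratio_threshold_classifier(v, lab)
    expect_equal(res$youden_j, brute_force_best_j(v, lab),
                 tolerance = 1e-12)
    expect_equal(res$tp + res$fn, sum(lab == "ESCC"))
    expect_equal(res$tn + res$fp, sum(lab == "normal"))
  }

  expect_error(ratio_threshold_classifier(1:4, rep("ESCC", 4)), "classes")
})

test_that("Cohen's kappa matches its definition", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # constructed independence: observed agreement equals chance agreement
  expect_equal(cohens_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B")), 0)
  # 2x2 table (a,b,c,d) = (20,5,10,15): p_o = 0.7, p_e = 0.5, kappa = 0.4
  r1 <- rep(c("N", "N", "E", "E"), c(20, 5, 10, 15))
  r2 <- rep(c("N", "E", "N", "E"), c(20, 5, 10, 15))
  expect_equal(cohens_kappa(r1, r2), 0.4, tolerance = 1e-12)

  skip_if_not_installed("e1071")
  tab <- table(r1, r2)
  expect_equal(cohens_kappa(r1, r2), e1071::classAgreement(tab)$kappa,
               tolerance = 1e-12)

  expect_error(cohens_kappa(c("a", "a"), c("a", "a")), "categories")
  expect_error(cohens_kappa(c("a", "b"), c("a")), "length")
})
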