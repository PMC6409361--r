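test_that("AUC handles the canonical small cases", {
  expect_equal(roc_auc(c(1, 2, 3, 10), c("normal", "normal", "abnormal", "abnormal")), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("normal", "abnormal"), 3)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8),
                       c("normal", "normal", "abnormal", "abnormal")), 0.75)
  expect_error(roc_auc(1:3, rep("abnormal", 3)), "both classes")
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1))) # induce ties sometimes
    labels <- ifelse(rbinom(n, 1, 0.5) == 1, "abnormal", "normal")
    if (length(unique(labels)) < 2) labels[1:2] <- c("abnormal", "normal")
    expect_equal(roc_auc(scores, labels), auc_pairs_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  for (i in 1:10) {
    scores <- rnorm(40)
    labels <- ifelse(rbinom(40, 1, 0.6) == 1, "abnormal", "normal")
    ref <- as.numeric(pROC::auc(pROC::roc(
      labels, scores, levels = c("normal", "abnormal"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("complementing the scores complements the AUC", {
  set.seed(57)
  scores <- rnorm(60) # tie-free
  labels <- ifelse(rbinom(60, 1, 0.5) == 1, "abnormal", "normal")
  labels[1:2] <- c("abnormal", "normal")
  expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1)
})

test_that("confusion metrics count the abnormal class as positive", {
  truth <- rep(c("abnormal", "normal"), c(6, 4))
  perfect <- confusion_metrics(truth, truth)
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  all_ab <- confusion_metrics(rep("abnormal", 10), truth)
  expect_equal(unlist(all_ab[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 0.6, sensitivity = 1, specificity = 0))
  flip <- ifelse(truth == "abnormal", "normal", "abnormal")
  inv <- confusion_metrics(flip, truth)
  expect_equal(unlist(inv[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 0, sensitivity = 0, specificity = 0))
  onesided <- confusion_metrics(truth, rep("abnormal", 10))
  expect_true(onesided$flagged)
  expect_true(is.na(onesided$specificity))
})

test_that("R-squared follows its definition including negative values", {
  y <- c(1, 3, 5, 9)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(rep(mean(y), 4), y), 0)
  expect_lt(r_squared(rev(y), y), 0)
  expect_error(r_squared(y, rep(2, 4)), "constant")
})

test_that("separable levels give the midpoint threshold for every criterion", {
  levels <- c(100, 150, 200, 250)
  status <- c("abnormal", "abnormal", "normal", "normal")
  for (crit in cutpoint_criteria()) {
    cut <- select_cutoff(levels, status, crit)
    expect_equal(cut$threshold, 175)
    expect_equal(cut$sensitivity, 1)
    expect_equal(cut$specificity, 1)
    expect_false(cut$degenerate)
  }
})

test_that("identical predicted levels yield a flagged degenerate cutoff", {
  cut <- select_cutoff(rep(180, 8), rep(c("abnormal", "normal"), 4), "Youden")
  expect_true(cut$degenerate)
  expect_equal(cut$threshold, 180)
})

test_that("every criterion attains the exhaustive-scan optimum", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    levels <- round(rnorm(n, 185, 30), sample(0:1, 1))
    status <- ifelse(rbinom(n, 1, 0.6) == 1, "abnormal", "normal")
    if (length(unique(status)) < 2) status[1:2] <- c("abnormal", "normal")
    for (crit in cutpoint_criteria()) {
      cut <- select_cutoff(levels, status, crit)
      oracle <- cutoff_scan_oracle(levels, status, crit)
      achieved <- switch(crit,
                         Youden = cut$sensitivity + cut$specificity - 1,
                         ROC01 = (1 - cut$sensitivity)^2 + (1 - cut$specificity)^2,
                         MaxSpSe = min(cut$sensitivity, cut$specificity),
                         MaxProdSpSe = cut$sensitivity * cut$specificity,
                         MaxEfficiency = cut$accuracy,
                         MaxKappa = cut$kappa)
      expect_equal(achieved, oracle$value, tolerance = 1e-12)
      expect_true(any(cut$threshold == oracle$thresholds |
                        abs(cut$threshold - oracle$thresholds) < 1e-12))
    }
  }
})

test_that("cutoffs transform with increasing affine maps of the levels", {
  set.seed(63)
  levels <- rnorm(40, 185, 25)
  status <- ifelse(rbinom(40, 1, 0.6) == 1, "abnormal", "normal")
  status[1:2] <- c("abnormal", "normal")
  for (crit in c("Youden", "MaxEfficiency", "MaxKappa")) {
    base <- select_cutoff(levels, status, crit)
    shifted <- select_cutoff(3 * levels + 10, status, crit)
    expect_equal(shifted$threshold, 3 * base$threshold + 10, tolerance = 1e-9)
    expect_equal(shifted$sensitivity, base$sensitivity)
    expect_equal(shifted$specificity, base$specificity)
  }
})

test_that("criterion choice maximizes mean inner accuracy with fixed-order ties", {
  dominant <- list(Youden = c(0.9, 0.95), ROC01 = c(0.7, 0.6))
  expect_identical(choose_best_criterion(dominant), "Youden")
  tie <- list(MaxKappa = c(0.8, 0.8), ROC01 = c(0.8, 0.8))
  expect_identical(choose_best_criterion(tie), "ROC01") # earlier in fixed order
  arith <- list(Youden = c(0.7, 0.8), ROC01 = c(0.9, 0.58))
  expect_identical(choose_best_criterion(arith), "Youden") # 0.75 > 0.74
  expect_error(choose_best_criterion(list()), "no inner-fold")
  expect_error(choose_best_criterion(list(Bogus = 0.5)), "named by criteria")
})
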