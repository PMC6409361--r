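#' Feature-set codes
#'
#' Models are named by the feature classes they include: `B` (baseline: age
#' and APOEe4 carrier status, always included), `P` (protein analytes) and
#' `M` (metabolite analytes).
#'
#' @return the valid codes.
#' @export
feature_set_codes <- function() c("B", "BM", "BP", "BPM")

#' Build the feature matrix for a feature-set code
#'
#' @param cohort a complete (imputed) `csf_cohort`.
#' @param feature_set one of [feature_set_codes()].
#' @return data.frame of features (baseline covariates first).
#' @export
feature_matrix <- function(cohort, feature_set = feature_set_codes()) {
  feature_set <- match.arg(feature_set)
  cols <- c("age", "apoe4_carrier")
  if (grepl("P", feature_set)) cols <- c(cols, cohort$protein_names)
  if (grepl("M", feature_set)) cols <- c(cols, cohort$metabolite_names)
  cohort$subjects[, cols, drop = FALSE]
}

#' Build a repeated k-fold plan
#'
#' Per repetition, subjects are randomly partitioned into `k` near-equal
#' folds (sizes differ by at most one). With `stratified = TRUE` (the
#' default) the partition is drawn within each status class, keeping class
#' counts per fold within one subject of proportionality.
#'
#' @param subject_ids character vector of ids.
#' @param true_status status labels (required when `stratified`).
#' @param k folds per repetition (>= 2).
#' @param reps repetitions.
#' @param seed integer seed.
#' @param stratified stratify folds by status?
#' @return an object of class `fold_plan` with an `n x reps` matrix of fold
#'   assignments.
#' @export
make_fold_plan <- function(subject_ids, true_status = NULL, k = 10, reps = 10,
                           seed = 1L, stratified = TRUE) {
  n <- length(subject_ids)
  stop_if_not_count(k, "k", min = 2)
  stop_if_not_count(reps, "reps")
  if (n < k) stop("need at least k subjects")
  if (stratified) {
    if (is.null(true_status)) stop("stratified plans require 'true_status'")
    st <- status_factor(true_status)
    if (min(table(st)) < k)
      stop("a status class has fewer members than k; use stratified = FALSE or smaller k")
  }
  assignments <- matrix(NA_integer_, n, reps,
                        dimnames = list(subject_ids, NULL))
  with_seed(seed, {
    for (r in seq_len(reps)) {
      if (stratified) {
        for (cls in levels(st)) {
          idx <- sample(which(st == cls))
          assignments[idx, r] <- rep_len(sample(k), length(idx))
        }
      } else {
        assignments[sample(n), r] <- rep_len(sample(k), n)
      }
    }
  })
  structure(list(assignments = assignments, k = as.integer(k),
                 reps = as.integer(reps), subject_ids = subject_ids,
                 stratified = stratified, seed = as.integer(seed)),
            class = "fold_plan")
}

# iterate (rep, fold) pairs of a plan
plan_splits <- function(plan) {
  out <- list()
  for (r in seq_len(plan$reps))
    for (f in seq_len(plan$k))
      out[[length(out) + 1]] <- list(rep = r, fold = f,
                                     test = which(plan$assignments[, r] == f))
  out
}

# inner-loop selection of the cutoff criterion on one outer-train set:
# per inner fold, fit a regression forest on the inner-train rows, derive a
# threshold per criterion from the inner-train OOB predictions, apply it to
# the inner-test predictions and record the accuracy; the winner maximizes
# the mean accuracy over all inner test folds
select_criterion_inner <- function(X, y_level, y_status, spec,
                                   inner_k, inner_reps, seed) {
  plan <- make_fold_plan(seq_len(nrow(X)), y_status, k = inner_k,
                         reps = inner_reps, seed = seed, stratified = TRUE)
  accs <- stats::setNames(rep(list(numeric(0)), 6), cutpoint_criteria())
  for (sp in plan_splits(plan)) {
    tr <- setdiff(seq_len(nrow(X)), sp$test)
    if (length(unique(y_status[tr])) < 2 || length(unique(y_status[sp$test])) < 2)
      stop(sprintf("degenerate inner fold (rep %d, fold %d): one class absent",
                   sp$rep, sp$fold))
    fspec <- spec
    fspec$seed <- derive_seed(seed, "inner-fit", sp$rep, sp$fold)
    fit <- fit_forest(X[tr, , drop = FALSE], y_level[tr], fspec)
    te_pred <- predict_forest(fit, X[sp$test, , drop = FALSE])
    for (crit in cutpoint_criteria()) {
      cut <- select_cutoff(fit$oob_predictions, y_status[tr], crit)
      pred_st <- status_factor(te_pred < cut$threshold)
      accs[[crit]] <- c(accs[[crit]],
                        confusion_metrics(pred_st, y_status[sp$test])$accuracy)
    }
  }
  list(winner = choose_best_criterion(accs), accuracies = accs)
}

#' Run the nested cross-validation
#'
#' The outer loop estimates generalization performance; for the regression
#' task an inner loop run on each outer-train set selects the cutoff
#' criterion (the one maximizing mean accuracy over the inner test folds),
#' after which the forest is refit on the full outer-train set, the
#' threshold is derived from its out-of-bag predictions with the winning
#' criterion, and the outer-test fold is scored. The binary task needs no
#' inner loop: class-vote probabilities are thresholded at 0.5 for the
#' confusion metrics and used directly as ROC scores. Regression ROC scores
#' are negated predicted levels (higher = more abnormal).
#'
#' @param cohort a complete `csf_cohort` with CSF measured for all subjects.
#' @param feature_set one of [feature_set_codes()].
#' @param task `"regression"` or `"binary"`.
#' @param plan an outer [make_fold_plan()] over the cohort's subjects.
#' @param spec a [forest_spec()] (its `task` is overridden by `task`).
#' @param inner_k,inner_reps inner-loop folds and repetitions (regression
#'   task only).
#' @return an object of class `csfsig_cv`: `folds` (one metric row per outer
#'   split: auc, accuracy, sensitivity, specificity, r_squared, criterion,
#'   threshold), `pooled` (all outer-test scores and labels), and `summary`
#'   (mean and SD per metric).
#' @export
run_nested_cv <- function(cohort, feature_set = "BP",
                          task = c("regression", "binary"),
                          plan, spec = forest_spec(),
                          inner_k = 3, inner_reps = 3) {
  task <- match.arg(task)
  subj <- cohort$subjects
  if (anyNA(subj$csf_ab42))
    stop("all subjects need a CSF measure; split the cohort first")
  X <- feature_matrix(cohort, feature_set)
  if (anyNA(X)) stop("feature matrix has missing values; run QC/imputation first")
  y_level <- subj$csf_ab42
  y_status <- csf_status(y_level, cohort$clinical_threshold)
  if (!identical(rownames(plan$assignments), subj$subject_id))
    stop("fold plan does not match the cohort's subjects")
  spec$task <- task

  rows <- list(); pooled_scores <- numeric(0); pooled_labels <- character(0)
  for (sp in plan_splits(plan)) {
    tr <- setdiff(seq_len(nrow(X)), sp$test)
    if (length(unique(y_status[tr])) < 2 || length(unique(y_status[sp$test])) < 2)
      stop(sprintf("degenerate outer fold (rep %d, fold %d): one class absent",
                   sp$rep, sp$fold))
    fspec <- spec
    fspec$seed <- derive_seed(spec$seed, "outer-fit", sp$rep, sp$fold)
    if (task == "binary") {
      fit <- fit_forest(X[tr, , drop = FALSE], y_status[tr], fspec)
      prob <- predict_forest(fit, X[sp$test, , drop = FALSE])
      pred_st <- status_factor(prob >= 0.5)
      cm <- confusion_metrics(pred_st, y_status[sp$test])
      rows[[length(rows) + 1]] <- data.frame(
        rep = sp$rep, fold = sp$fold,
        auc = roc_auc(prob, y_status[sp$test]),
        accuracy = cm$accuracy, sensitivity = cm$sensitivity,
        specificity = cm$specificity, r_squared = NA_real_,
        criterion = NA_character_, threshold = NA_real_,
        stringsAsFactors = FALSE)
      pooled_scores <- c(pooled_scores, prob)
    } else {
      inner <- select_criterion_inner(
        X[tr, , drop = FALSE], y_level[tr], y_status[tr], fspec,
        inner_k, inner_reps,
        seed = derive_seed(spec$seed, "inner-plan", sp$rep, sp$fold))
      fit <- fit_forest(X[tr, , drop = FALSE], y_level[tr], fspec)
      cut <- select_cutoff(fit$oob_predictions, y_status[tr], inner$winner)
      te_pred <- predict_forest(fit, X[sp$test, , drop = FALSE])
      pred_st <- status_factor(te_pred < cut$threshold)
      cm <- confusion_metrics(pred_st, y_status[sp$test])
      rows[[length(rows) + 1]] <- data.frame(
        rep = sp$rep, fold = sp$fold,
        auc = roc_auc(-te_pred, y_status[sp$test]),
        accuracy = cm$accuracy, sensitivity = cm$sensitivity,
        specificity = cm$specificity,
        r_squared = r_squared(te_pred, y_level[sp$test]),
        criterion = inner$winner, threshold = cut$threshold,
        stringsAsFactors = FALSE)
      pooled_scores <- c(pooled_scores, -te_pred)
    }
    pooled_labels <- c(pooled_labels, as.character(y_status[sp$test]))
  }
  folds <- do.call(rbind, rows)
  metrics <- c("auc", "accuracy", "sensitivity", "specificity", "r_squared")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(folds[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(folds = folds,
                 pooled = data.frame(score = pooled_scores,
                                     status = pooled_labels,
                                     stringsAsFactors = FALSE),
                 summary = summary,
                 feature_set = feature_set, task = task),
            class = "csfsig_cv")
}

#' @export
print.csfsig_cv <- function(x, ...) {
  cat(sprintf("<csfsig_cv> %s task, feature set %s, %d outer folds\n",
              x$task, x$feature_set, nrow(x$folds)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Paired one-tailed Wilcoxon comparison of per-fold AUCs
#'
#' Tests whether model A's per-fold AUCs exceed model B's with a one-tailed
#' Wilcoxon signed-rank test. Zero differences are dropped by the standard
#' convention; ties among the absolute differences receive midranks. Up to
#' 50 non-zero differences the p-value is exact, computed from the full
#' permutation distribution of the signed-rank statistic (which remains
#' valid under ties, where the large-sample shortcut does not); beyond that
#' a tie-corrected normal approximation with continuity correction is used.
#' When every paired difference is zero the p-value is undefined and
#' flagged.
#'
#' @param aucs_a,aucs_b per-fold AUCs, paired by fold, length >= 6.
#' @return list with `p_value`, `statistic` (the signed-rank sum V) and
#'   `flagged`.
#' @export
compare_models_wilcoxon <- function(aucs_a, aucs_b) {
  if (length(aucs_a) != length(aucs_b) || length(aucs_a) < 6)
    stop("need paired vectors of equal length >= 6")
  d <- aucs_a - aucs_b
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(p_value = NA_real_, statistic = NA_real_, flagged = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  if (n <= 50) {
    # exact: convolve the sign-flip distribution; doubled midranks are integers
    w <- as.integer(round(2 * r))
    f <- 1
    for (wi in w) {
      g <- c(f, numeric(wi)) + c(numeric(wi), f)
      f <- g / 2
    }
    p <- sum(f[seq.int(as.integer(round(2 * v)) + 1L, length(f))])
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- stats::pnorm(v - 0.5, mu, sqrt(sigma2), lower.tail = FALSE)
  }
  list(p_value = min(max(p, 0), 1), statistic = v, flagged = FALSE)
}

#' ROC curve over pooled outer-test predictions
#'
#' Builds the step ROC curve from predictions aggregated across all outer
#' test folds, together with the pooled AUC.
#'
#' @param scores pooled scores (higher = more abnormal).
#' @param labels pooled status labels with both classes present.
#' @return list with `points` (data.frame `fpr`, `tpr`, monotone
#'   non-decreasing, from (0,0) to (1,1)) and `auc`.
#' @export
aggregate_roc <- function(scores, labels) {
  labels <- status_factor(labels)
  auc <- roc_auc(scores, labels) # errors on single-class input
  ord <- order(scores, decreasing = TRUE)
  pos <- labels[ord] == "abnormal"
  n1 <- sum(pos); n0 <- sum(!pos)
  tp <- cumsum(pos); fp <- cumsum(!pos)
  # one point per distinct score (end of each tie group), plus the origin
  keep <- c(diff(scores[ord]) != 0, TRUE)
  points <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  list(points = points, auc = auc)
}
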