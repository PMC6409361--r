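#' Recursive-elimination schedule
#'
#' Subset sizes visited by the recursive feature elimination: starting from
#' `p`, 20% of the remaining features are dropped per step while more than
#' `stepwise_below` remain, then one feature at a time down to a single
#' feature. This keeps single-feature resolution near the optimum while
#' staying tractable at p around 150.
#'
#' @param p starting number of features.
#' @param drop_frac fraction dropped per bulk step.
#' @param stepwise_below size below which elimination proceeds one at a time.
#' @return strictly decreasing integer vector from `p` to 1.
#' @export
rfe_schedule <- function(p, drop_frac = 0.2, stepwise_below = 30) {
  stop_if_not_count(p, "p")
  sizes <- p
  while (sizes[length(sizes)] > 1) {
    s <- sizes[length(sizes)]
    nxt <- if (s > stepwise_below)
      max(floor(s * (1 - drop_frac)), stepwise_below) else s - 1
    sizes <- c(sizes, nxt)
  }
  as.integer(sizes)
}

# one recursive-elimination pass on a train set: fit at each schedule size,
# rank by permutation importance (recomputed after every elimination), keep
# the top features for the next size; optionally score a test set at each
# size. Subsets along the path are nested by construction.
rfe_path <- function(X_tr, y_tr, spec, schedule,
                     X_te = NULL, status_te = NULL, seed = 1L) {
  current <- colnames(X_tr)
  subsets <- vector("list", length(schedule))
  aucs <- rep(NA_real_, length(schedule))
  for (i in seq_along(schedule)) {
    fspec <- spec
    fspec$seed <- derive_seed(seed, "rfe-fit", i)
    fit <- fit_forest(X_tr[, current, drop = FALSE], y_tr, fspec)
    subsets[[i]] <- current
    if (!is.null(X_te))
      aucs[i] <- roc_auc(forest_scores(fit, X_te), status_te)
    if (i < length(schedule)) {
      imp <- sort(fit$importances, decreasing = TRUE)
      current <- names(imp)[seq_len(schedule[i + 1])]
    }
  }
  list(sizes = schedule, subsets = subsets, aucs = aucs)
}

#' Recursive feature elimination profile from an inner cross-validation
#'
#' Within each inner training fold a forest is fit, features are ranked by
#' OOB permutation importance, the lowest-ranked features are dropped to the
#' next schedule size, the forest is refit, and the inner-test AUC is
#' recorded at every size (importances are recomputed after every
#' elimination). The profile is the mean test AUC per subset size across
#' inner folds.
#'
#' @param X complete feature matrix (data.frame).
#' @param y_level continuous CSF levels (regression task) or status labels
#'   (binary task), matching `spec$task`.
#' @param true_status status labels used for stratification and AUC.
#' @param spec a [forest_spec()].
#' @param inner_k,inner_reps inner-loop folds and repetitions.
#' @param schedule elimination schedule; defaults to [rfe_schedule()] on the
#'   full feature count.
#' @param seed integer seed for the inner plan.
#' @return an object of class `rfe_profile`: `sizes`, `auc_by_size` (mean
#'   over folds), `fold_aucs` (folds x sizes matrix).
#' @export
rfe_profile <- function(X, y_level, true_status, spec = forest_spec(),
                        inner_k = 3, inner_reps = 3, schedule = NULL,
                        seed = 1L) {
  X <- as.data.frame(X)
  st <- status_factor(true_status)
  if (length(unique(st)) < 2) stop("both classes must be present")
  if (is.null(schedule)) schedule <- rfe_schedule(ncol(X))
  plan <- make_fold_plan(seq_len(nrow(X)), st, k = inner_k, reps = inner_reps,
                         seed = derive_seed(seed, "rfe-plan"), stratified = TRUE)
  splits <- plan_splits(plan)
  fold_aucs <- matrix(NA_real_, length(splits), length(schedule))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    tr <- setdiff(seq_len(nrow(X)), sp$test)
    if (length(unique(st[sp$test])) < 2)
      stop(sprintf("degenerate inner fold (rep %d, fold %d): one class absent",
                   sp$rep, sp$fold))
    path <- rfe_path(X[tr, , drop = FALSE], y_level[tr], spec, schedule,
                     X_te = X[sp$test, , drop = FALSE],
                     status_te = st[sp$test],
                     seed = derive_seed(seed, "rfe-fold", sp$rep, sp$fold))
    fold_aucs[i, ] <- path$aucs
  }
  structure(list(sizes = schedule,
                 auc_by_size = colMeans(fold_aucs),
                 fold_aucs = fold_aucs),
            class = "rfe_profile")
}

#' Select the subset size under the parsimony rule
#'
#' Returns the smallest subset size whose profile AUC is within the
#' tolerance of the maximal observed AUC. With `relative = TRUE` (default)
#' "within 4%" is read relatively: AUC(s) >= (1 - tolerance) * max AUC;
#' with `relative = FALSE` absolutely: AUC(s) >= max AUC - tolerance.
#'
#' @param profile an [rfe_profile()], or a named numeric vector mapping
#'   sizes to AUCs.
#' @param tolerance parsimony tolerance (default 0.04).
#' @param relative interpret the tolerance relatively?
#' @return the selected size.
#' @export
select_subset_size <- function(profile, tolerance = 0.04, relative = TRUE) {
  stop_if_not_fraction(tolerance, "tolerance")
  if (inherits(profile, "rfe_profile")) {
    sizes <- profile$sizes; aucs <- profile$auc_by_size
  } else {
    if (length(profile) == 0) stop("empty profile")
    sizes <- as.numeric(names(profile)); aucs <- as.numeric(profile)
  }
  if (length(sizes) == 0) stop("empty profile")
  floor_auc <- if (relative) (1 - tolerance) * max(aucs) else max(aucs) - tolerance
  ok <- sizes[aucs >= floor_auc]
  min(ok)
}

#' Nested cross-validation with per-fold feature selection
#'
#' For each outer fold: an inner-CV elimination profile on the outer-train
#' set determines the subset size via the parsimony rule; a fresh
#' elimination pass on the full outer-train set yields the feature subset of
#' that size; a forest restricted to the subset is refit on the outer-train
#' set and scored on the outer-test fold. For the regression task the
#' dichotomization threshold is derived from the restricted forest's OOB
#' predictions under the `cut_criterion`.
#'
#' @inheritParams run_nested_cv
#' @param tolerance parsimony tolerance passed to [select_subset_size()].
#' @param relative relative reading of the tolerance?
#' @param cut_criterion cutoff criterion for dichotomizing regression
#'   predictions of the reduced models.
#' @return an object of class `csfsig_cv` with extra columns
#'   `selected_size` in `folds` and a list-column attribute
#'   `selected_features` (one character vector per outer fold).
#' @export
run_rfe_nested <- function(cohort, feature_set = "BP", plan,
                           spec = forest_spec(), inner_k = 3, inner_reps = 3,
                           tolerance = 0.04, relative = TRUE,
                           cut_criterion = "Youden") {
  subj <- cohort$subjects
  if (anyNA(subj$csf_ab42)) stop("all subjects need a CSF measure")
  X <- feature_matrix(cohort, feature_set)
  if (anyNA(X)) stop("feature matrix has missing values; run QC/imputation first")
  y_level <- subj$csf_ab42
  y_status <- csf_status(y_level, cohort$clinical_threshold)
  y_fit <- if (spec$task == "regression") y_level else y_status
  schedule <- rfe_schedule(ncol(X))

  rows <- list(); sel_features <- list()
  pooled_scores <- numeric(0); pooled_labels <- character(0)
  for (sp in plan_splits(plan)) {
    tr <- setdiff(seq_len(nrow(X)), sp$test)
    prof <- rfe_profile(X[tr, , drop = FALSE], y_fit[tr], y_status[tr], spec,
                        inner_k, inner_reps, schedule,
                        seed = derive_seed(spec$seed, "rfe-inner", sp$rep, sp$fold))
    size <- select_subset_size(prof, tolerance, relative)
    path <- rfe_path(X[tr, , drop = FALSE], y_fit[tr], spec,
                     schedule[schedule >= size],
                     seed = derive_seed(spec$seed, "rfe-final", sp$rep, sp$fold))
    feats <- path$subsets[[length(path$subsets)]]
    fspec <- spec
    fspec$seed <- derive_seed(spec$seed, "rfe-refit", sp$rep, sp$fold)
    fit <- fit_forest(X[tr, feats, drop = FALSE], y_fit[tr], fspec)
    te_scores <- forest_scores(fit, X[sp$test, , drop = FALSE])
    if (spec$task == "regression") {
      cut <- select_cutoff(fit$oob_predictions, y_status[tr], cut_criterion)
      pred_st <- status_factor(-te_scores < cut$threshold)
      r2 <- r_squared(-te_scores, y_level[sp$test])
      thr <- cut$threshold
    } else {
      pred_st <- status_factor(te_scores >= 0.5)
      r2 <- NA_real_; thr <- NA_real_
    }
    cm <- confusion_metrics(pred_st, y_status[sp$test])
    rows[[length(rows) + 1]] <- data.frame(
      rep = sp$rep, fold = sp$fold,
      auc = roc_auc(te_scores, y_status[sp$test]),
      accuracy = cm$accuracy, sensitivity = cm$sensitivity,
      specificity = cm$specificity, r_squared = r2,
      criterion = if (spec$task == "regression") cut_criterion else NA_character_,
      threshold = thr, selected_size = size,
      stringsAsFactors = FALSE)
    sel_features[[length(sel_features) + 1]] <- feats
    pooled_scores <- c(pooled_scores, te_scores)
    pooled_labels <- c(pooled_labels, as.character(y_status[sp$test]))
  }
  folds <- do.call(rbind, rows)
  metrics <- c("auc", "accuracy", "sensitivity", "specificity", "r_squared")
  res <- structure(list(
    folds = folds,
    pooled = data.frame(score = pooled_scores, status = pooled_labels,
                        stringsAsFactors = FALSE),
    summary = data.frame(
      metric = metrics,
      mean = vapply(metrics, function(m) mean(folds[[m]]), numeric(1)),
      sd = vapply(metrics, function(m) stats::sd(folds[[m]]), numeric(1)),
      row.names = NULL),
    feature_set = feature_set, task = spec$task,
    selected_features = sel_features),
    class = "csfsig_cv")
  res
}

#' Final parsimonious feature set on the full training cohort
#'
#' Applies the elimination profile (inner CV over the whole training set)
#' and the parsimony rule once to the full training data, then reruns the
#' elimination on all of it to name the production feature subset -- the
#' analog of reducing a full analyte panel to a handful of markers plus
#' APOEe4 carrier status.
#'
#' @inheritParams run_rfe_nested
#' @param seed integer seed (defaults to the seed of the forest
#'   specification).
#' @return character vector of selected feature names, with attributes
#'   `size` and `profile`.
#' @export
final_feature_set <- function(cohort, feature_set = "BP",
                              spec = forest_spec(), inner_k = 3,
                              inner_reps = 3, tolerance = 0.04,
                              relative = TRUE, seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  subj <- cohort$subjects
  if (anyNA(subj$csf_ab42)) stop("all subjects need a CSF measure")
  X <- feature_matrix(cohort, feature_set)
  if (anyNA(X)) stop("feature matrix has missing values; run QC/imputation first")
  y_level <- subj$csf_ab42
  y_status <- csf_status(y_level, cohort$clinical_threshold)
  y_fit <- if (spec$task == "regression") y_level else y_status
  schedule <- rfe_schedule(ncol(X))
  prof <- rfe_profile(X, y_fit, y_status, spec, inner_k, inner_reps, schedule,
                      seed = derive_seed(seed, "final-profile"))
  size <- select_subset_size(prof, tolerance, relative)
  path <- rfe_path(X, y_fit, spec, schedule[schedule >= size],
                   seed = derive_seed(seed, "final-path"))
  feats <- path$subsets[[length(path$subsets)]]
  attr(feats, "size") <- size
  attr(feats, "profile") <- prof
  feats
}
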