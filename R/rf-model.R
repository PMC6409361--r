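#' Random-forest hyperparameter specification
#'
#' Forests use 2000 trees by default, each split drawing `floor(p^0.75)`
#' candidate features (a denser sampling than the classical `sqrt(p)`,
#' suited to many weakly informative analytes); all other tree parameters
#' stay at the backend's defaults.
#'
#' @param n_trees number of trees.
#' @param task `"regression"` (continuous CSF level) or `"binary"`
#'   (dichotomized status).
#' @param seed integer seed for tree growth.
#' @return an object of class `forest_spec`.
#' @export
forest_spec <- function(n_trees = 2000, task = c("regression", "binary"),
                        seed = 1L) {
  stop_if_not_count(n_trees, "n_trees")
  task <- match.arg(task)
  structure(list(n_trees = as.integer(n_trees), task = task,
                 mtry_rule = "floor(p^0.75)", seed = as.integer(seed)),
            class = "forest_spec")
}

#' Features sampled per split
#'
#' `floor(p^0.75)`, with a minimum of 1. Monotone non-decreasing in `p`.
#'
#' @param p number of features (>= 1).
#' @return integer mtry.
#' @export
compute_mtry <- function(p) {
  stop_if_not_count(p, "p")
  max(1L, as.integer(floor(p^0.75 + 1e-9)))
}

#' Fit a random forest for the regression or binary task
#'
#' Regression forests predict the continuous CSF level (pg/ml); binary
#' forests predict the abnormal-class probability as the fraction of tree
#' votes. Out-of-bag error and OOB permutation importances (increase in OOB
#' error when a feature is shuffled) are recorded. Reproducible from the
#' spec seed.
#'
#' @param X complete numeric feature matrix or data.frame.
#' @param y numeric levels (regression) or a status factor/character with
#'   values `normal`/`abnormal` (binary).
#' @param spec a [forest_spec()].
#' @return an object of class `csfsig_forest` with elements `model`,
#'   `task`, `feature_names`, `oob_error`, `oob_predictions` (OOB level for
#'   regression, OOB abnormal probability for binary), `importances`, and
#'   `constant_response` flag.
#' @export
fit_forest <- function(X, y, spec = forest_spec()) {
  X <- as.data.frame(X)
  if (anyNA(X)) stop("feature matrix contains missing values; impute first")
  if (nrow(X) != length(y)) stop("X and y are not aligned")
  constant <- FALSE
  if (spec$task == "binary") {
    y <- status_factor(y)
    if (length(unique(stats::na.omit(y))) < 2)
      stop("binary task requires both classes in y")
  } else {
    if (!is.numeric(y)) stop("regression task requires numeric y")
    constant <- stats::var(y) == 0
  }
  fit <- ranger::ranger(
    x = X, y = y,
    num.trees = spec$n_trees,
    mtry = compute_mtry(ncol(X)),
    importance = "permutation",
    probability = spec$task == "binary",
    seed = spec$seed,
    num.threads = 1)
  oob_pred <- if (spec$task == "binary")
    fit$predictions[, "abnormal"] else fit$predictions
  structure(list(model = fit, task = spec$task,
                 feature_names = colnames(X),
                 training_X = X,
                 oob_error = fit$prediction.error,
                 oob_predictions = oob_pred,
                 importances = fit$variable.importance,
                 constant_response = constant,
                 spec = spec),
            class = "csfsig_forest")
}

#' @export
print.csfsig_forest <- function(x, ...) {
  cat(sprintf("<csfsig_forest> %s task, %d trees, %d features, OOB error %.4g\n",
              x$task, x$model$num.trees, length(x$feature_names), x$oob_error))
  invisible(x)
}

check_features <- function(forest, X_new) {
  X_new <- as.data.frame(X_new)
  miss <- setdiff(forest$feature_names, names(X_new))
  if (length(miss) > 0)
    stop("prediction data lacks training feature(s): ", paste(miss, collapse = ", "))
  X_new[, forest$feature_names, drop = FALSE]
}

#' Predict from a fitted forest
#'
#' @param forest a `csfsig_forest`.
#' @param X_new data with the training feature set (extra columns ignored).
#' @return numeric vector: predicted CSF level (regression) or abnormal
#'   probability in `[0, 1]` (binary).
#' @export
predict_forest <- function(forest, X_new) {
  X_new <- check_features(forest, X_new)
  pr <- stats::predict(forest$model, data = X_new, num.threads = 1)$predictions
  if (forest$task == "binary") pr[, "abnormal"] else pr
}

#' Abnormality score of a forest
#'
#' A score oriented so that higher means more abnormal: the negated
#' predicted CSF level for regression forests, the abnormal-class
#' probability for binary forests. This is the score all ROC analyses use.
#'
#' @inheritParams predict_forest
#' @return numeric score vector.
#' @export
forest_scores <- function(forest, X_new) {
  pr <- predict_forest(forest, X_new)
  if (forest$task == "regression") -pr else pr
}

#' Partial dependence of a forest on one feature
#'
#' For each grid value `v`, the mean prediction over the training rows with
#' the feature forced to `v`.
#'
#' @param forest a `csfsig_forest`.
#' @param feature feature name.
#' @param grid numeric grid values; defaults to 25 quantile-spaced points of
#'   the training values (the unique values for binary features).
#' @return data.frame with columns `value` and `prediction`.
#' @export
partial_dependence <- function(forest, feature, grid = NULL) {
  if (!feature %in% forest$feature_names)
    stop("unknown feature: ", feature)
  xv <- forest$training_X[[feature]]
  if (is.null(grid)) {
    ux <- sort(unique(xv))
    grid <- if (length(ux) <= 25) ux else
      unique(stats::quantile(xv, probs = seq(0.02, 0.98, length.out = 25), names = FALSE))
  }
  pred <- vapply(grid, function(v) {
    Xg <- forest$training_X
    Xg[[feature]] <- v
    mean(predict_forest(forest, Xg))
  }, numeric(1))
  data.frame(value = grid, prediction = pred)
}
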