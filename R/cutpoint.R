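#' The six cutoff-selection criteria
#'
#' The closed set of criteria evaluated when converting continuous predicted
#' CSF levels into binary status, in the fixed order used for tie-breaking:
#' Youden (max sens + spec - 1), ROC01 (min squared distance to the (0,1)
#' ROC corner), MaxSpSe (max of min(sens, spec)), MaxProdSpSe (max
#' sens * spec), MaxEfficiency (max accuracy) and MaxKappa (max Cohen's
#' kappa).
#'
#' @return character vector of the six criterion names.
#' @export
cutpoint_criteria <- function() {
  c("Youden", "ROC01", "MaxSpSe", "MaxProdSpSe", "MaxEfficiency", "MaxKappa")
}

#' Area under the ROC curve
#'
#' Tie-corrected Mann-Whitney concordance: the fraction of
#' (abnormal, normal) pairs in which the abnormal subject scores higher,
#' counting ties as half. Computed via midranks.
#'
#' @param scores numeric scores, higher = more abnormal.
#' @param labels status labels (`normal`/`abnormal`, logical, or factor).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- status_factor(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must be complete")
  pos <- labels == "abnormal"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Accuracy, sensitivity and specificity
#'
#' Abnormal is the positive class: sensitivity = TP / (TP + FN) over the
#' true-abnormal subjects, specificity = TN / (TN + FP) over the
#' true-normal subjects. If a class is absent the corresponding rate is NA
#' and the result is flagged rather than silently zeroed.
#'
#' @param predicted_status,true_status aligned status vectors.
#' @return list with `accuracy`, `sensitivity`, `specificity` and a
#'   `flagged` logical.
#' @export
confusion_metrics <- function(predicted_status, true_status) {
  p <- status_factor(predicted_status)
  a <- status_factor(true_status)
  if (length(p) != length(a) || length(p) == 0)
    stop("predicted and true status must be non-empty and aligned")
  tp <- sum(p == "abnormal" & a == "abnormal")
  tn <- sum(p == "normal" & a == "normal")
  n_pos <- sum(a == "abnormal"); n_neg <- sum(a == "normal")
  list(accuracy = (tp + tn) / length(a),
       sensitivity = if (n_pos > 0) tp / n_pos else NA_real_,
       specificity = if (n_neg > 0) tn / n_neg else NA_real_,
       flagged = n_pos == 0 || n_neg == 0)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`. May be negative on held-out data when the
#' predictor is worse than the mean.
#'
#' @param predicted,actual aligned numeric vectors (`actual` non-constant,
#'   n >= 2).
#' @return R-squared.
#' @export
r_squared <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) < 2)
    stop("need aligned vectors of length >= 2")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop("'actual' is constant; R-squared undefined")
  1 - sum((actual - predicted)^2) / ss_tot
}

cohen_kappa <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

#' Select an optimal cutoff on predicted CSF levels
#'
#' Evaluates every candidate threshold -- the midpoints of adjacent distinct
#' predicted levels, plus `-Inf` and `+Inf` -- under the orientation
#' "predicted level strictly below the threshold implies abnormal", and
#' returns the threshold optimizing the chosen criterion. Ties are broken
#' toward the threshold closest to the median predicted level (then toward
#' the smaller threshold).
#'
#' @param predicted_levels numeric predicted CSF levels (pg/ml).
#' @param true_status aligned status labels with both classes present.
#' @param criterion one of [cutpoint_criteria()].
#' @return an object of class `csfsig_cutpoint`: `criterion`, `threshold`,
#'   achieved `sensitivity`, `specificity`, `accuracy`, `kappa`, and a
#'   `degenerate` flag (all predicted levels identical).
#' @export
select_cutoff <- function(predicted_levels, true_status,
                          criterion = cutpoint_criteria()) {
  criterion <- match.arg(criterion)
  a <- status_factor(true_status)
  if (length(predicted_levels) != length(a))
    stop("levels and status are not aligned")
  if (length(unique(stats::na.omit(a))) < 2)
    stop("both classes must be present to select a cutoff")
  if (anyNA(predicted_levels)) stop("predicted levels must be complete")
  u <- sort(unique(predicted_levels))
  degenerate <- length(u) == 1
  cand <- if (degenerate) u else c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  ev <- cutpoint_scan(predicted_levels, a, cand)
  val <- ev[[criterion]]
  best <- if (criterion == "ROC01") val == min(val) else val == max(val)
  idx <- which(best)
  if (length(idx) > 1) {
    med <- stats::median(predicted_levels)
    d <- abs(cand[idx] - med)
    d[!is.finite(cand[idx])] <- Inf
    idx <- idx[order(d, cand[idx])][1]
  }
  structure(list(criterion = criterion,
                 threshold = cand[idx],
                 sensitivity = ev$sensitivity[idx],
                 specificity = ev$specificity[idx],
                 accuracy = ev$accuracy[idx],
                 kappa = ev$kappa[idx],
                 degenerate = degenerate),
            class = "csfsig_cutpoint")
}

# criterion values at each candidate threshold (orientation: level < t => abnormal)
cutpoint_scan <- function(levels, status, thresholds) {
  pos <- status == "abnormal"
  n1 <- sum(pos); n0 <- sum(!pos)
  sens <- spec <- acc <- kap <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred_ab <- levels < thresholds[i]
    tp <- sum(pred_ab & pos); fn <- n1 - tp
    fp <- sum(pred_ab & !pos); tn <- n0 - fp
    sens[i] <- tp / n1; spec[i] <- tn / n0
    acc[i] <- (tp + tn) / (n1 + n0)
    kap[i] <- cohen_kappa(tp, fp, fn, tn)
  }
  list(sensitivity = sens, specificity = spec, accuracy = acc, kappa = kap,
       Youden = sens + spec - 1,
       ROC01 = (1 - sens)^2 + (1 - spec)^2,
       MaxSpSe = pmin(sens, spec),
       MaxProdSpSe = sens * spec,
       MaxEfficiency = acc,
       MaxKappa = kap)
}

#' @export
print.csfsig_cutpoint <- function(x, ...) {
  cat(sprintf("<cutpoint> %s: threshold %.4g (sens %.3f, spec %.3f, acc %.3f)%s\n",
              x$criterion, x$threshold, x$sensitivity, x$specificity,
              x$accuracy, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Choose the cutoff criterion from inner-fold accuracies
#'
#' Returns the criterion with the highest mean accuracy across inner test
#' folds; exact ties are broken by the fixed order of
#' [cutpoint_criteria()].
#'
#' @param inner_fold_results named list (criterion -> numeric vector of
#'   accuracies over inner test folds, each with >= 1 fold).
#' @return the winning criterion name.
#' @export
choose_best_criterion <- function(inner_fold_results) {
  if (length(inner_fold_results) == 0) stop("no inner-fold results supplied")
  bad <- setdiff(names(inner_fold_results), cutpoint_criteria())
  if (length(bad) > 0 || is.null(names(inner_fold_results)))
    stop("results must be named by criteria from cutpoint_criteria()")
  if (any(lengths(inner_fold_results) == 0))
    stop("every criterion needs at least one inner fold")
  means <- vapply(inner_fold_results, mean, numeric(1))
  ord <- intersect(cutpoint_criteria(), names(means))
  means <- means[ord]
  ord[which.max(means)] # which.max takes the first maximum => fixed order
}
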