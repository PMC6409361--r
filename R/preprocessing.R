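#' Quality-control configuration
#'
#' @param max_analyte_missing_frac analytes with a missing fraction strictly
#'   greater than this are removed (default 0.15).
#' @param max_sample_missing_frac samples with a missing fraction strictly
#'   greater than this are flagged (default 0.05).
#' @param impute_max_iter maximum sweeps of the iterative imputer.
#' @param impute_trees trees per imputation forest; imputation forests are
#'   smaller than modeling forests since each one only fills a single column.
#' @param impute_seed integer seed for the imputer.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(max_analyte_missing_frac = 0.15,
                      max_sample_missing_frac = 0.05,
                      impute_max_iter = 10,
                      impute_trees = 100,
                      impute_seed = 1L) {
  stop_if_not_fraction(max_analyte_missing_frac, "max_analyte_missing_frac")
  stop_if_not_fraction(max_sample_missing_frac, "max_sample_missing_frac")
  stop_if_not_count(impute_max_iter, "impute_max_iter")
  stop_if_not_count(impute_trees, "impute_trees")
  structure(list(max_analyte_missing_frac = max_analyte_missing_frac,
                 max_sample_missing_frac = max_sample_missing_frac,
                 impute_max_iter = as.integer(impute_max_iter),
                 impute_trees = as.integer(impute_trees),
                 impute_seed = as.integer(impute_seed)),
            class = "qc_config")
}

#' Remove analytes with excessive missingness
#'
#' An analyte is removed iff its missing fraction is strictly greater than
#' `max_frac`; the column order of survivors is preserved.
#'
#' @param x numeric matrix or data.frame (subjects x analytes).
#' @param max_frac maximum tolerated missing fraction.
#' @return list with `matrix` (the reduced table) and `removed` (names).
#' @export
filter_analytes_by_missingness <- function(x, max_frac = 0.15) {
  if (NCOL(x) < 1) stop("'x' must have at least one analyte")
  stop_if_not_fraction(max_frac, "max_frac")
  frac <- colMeans(is.na(x))
  drop <- frac > max_frac
  if (all(drop)) stop("all analytes exceed the missingness threshold")
  list(matrix = x[, !drop, drop = FALSE], removed = colnames(x)[drop])
}

#' Flag samples with excessive missingness
#'
#' Returns the identifiers of samples whose missing fraction across analytes
#' is strictly greater than `max_frac`. The caller decides whether to drop
#' them; typical cohorts have sample-level missingness well under 5% after
#' analyte filtering.
#'
#' @param x numeric matrix or data.frame with rownames as sample ids.
#' @param max_frac maximum tolerated missing fraction.
#' @return character vector of flagged ids (possibly empty).
#' @export
flag_samples_by_missingness <- function(x, max_frac = 0.05) {
  stop_if_not_fraction(max_frac, "max_frac")
  frac <- rowMeans(is.na(x))
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(NROW(x)))
  ids[frac > max_frac]
}

#' Iterative random-forest imputation
#'
#' Fills missing cells by chained regression forests: missing cells are
#' initialized with column medians, then variables are visited in order of
#' increasing missingness, each regressed on all others over its observed
#' rows with a regression forest, and its missing cells replaced by the
#' forest predictions. Sweeps repeat until the sum of squared changes in
#' the imputed values increases (the previous sweep's values are then
#' returned) or `impute_max_iter` is reached. Observed cells are never
#' altered.
#'
#' @param x numeric matrix or data.frame with missing values; no column may
#'   be entirely missing.
#' @param config a [qc_config()].
#' @return a complete numeric matrix with attributes `iterations` (sweeps
#'   performed) and `deltas` (sum of squared changes per sweep).
#' @export
impute_rf <- function(x, config = qc_config()) {
  xm <- as.matrix(x)
  if (!is.numeric(xm)) stop("imputation requires numeric columns")
  if (is.null(colnames(xm))) colnames(xm) <- paste0("V", seq_len(ncol(xm)))
  na_mask <- is.na(xm)
  if (!any(na_mask)) {
    attr(xm, "iterations") <- 0L
    attr(xm, "deltas") <- numeric(0)
    return(xm)
  }
  if (any(colMeans(na_mask) == 1)) stop("column(s) entirely missing cannot be imputed")
  # median initialization
  for (j in which(colSums(na_mask) > 0))
    xm[na_mask[, j], j] <- stats::median(xm[, j], na.rm = TRUE)
  # visitation order: increasing missingness, ties by column order
  order_j <- order(colSums(na_mask), seq_len(ncol(xm)))
  order_j <- order_j[colSums(na_mask)[order_j] > 0]
  deltas <- numeric(0)
  prev <- xm
  for (iter in seq_len(config$impute_max_iter)) {
    before <- xm
    for (j in order_j) {
      obs <- !na_mask[, j]
      df <- as.data.frame(xm[, -j, drop = FALSE])
      fit <- ranger::ranger(
        x = df[obs, , drop = FALSE], y = xm[obs, j],
        num.trees = config$impute_trees,
        mtry = compute_mtry(ncol(df)),
        seed = derive_seed(config$impute_seed, "impute", iter, j),
        num.threads = 1)
      xm[na_mask[, j], j] <- stats::predict(
        fit, data = df[na_mask[, j], , drop = FALSE], num.threads = 1)$predictions
    }
    delta <- sum((xm[na_mask] - before[na_mask])^2)
    deltas <- c(deltas, delta)
    if (iter > 1 && delta > deltas[iter - 1]) {
      xm <- prev # diverging: keep the previous sweep
      break
    }
    prev <- xm
    if (delta == 0) break
  }
  stopifnot(!anyNA(xm), all(is.finite(xm)))
  attr(xm, "iterations") <- length(deltas)
  attr(xm, "deltas") <- deltas
  xm
}

#' Quality control and imputation of a cohort
#'
#' Applies the analyte missingness filter, flags (but does not drop) samples
#' with excessive missingness, verifies that age and APOEe4 carrier status
#' are complete, and imputes remaining gaps with [impute_rf()].
#'
#' @param cohort a `csf_cohort`.
#' @param config a [qc_config()].
#' @return list with `cohort` (complete analytes), and `report`: removed
#'   analytes, flagged samples, imputation iterations and per-sweep deltas.
#' @export
qc_cohort <- function(cohort, config = qc_config()) {
  if (anyNA(cohort$subjects$age) || anyNA(cohort$subjects$apoe4_carrier))
    stop("age and apoe4_carrier must be complete; found missing covariate values")
  nms <- analyte_names(cohort)
  X <- as.matrix(cohort$subjects[, nms, drop = FALSE])
  rownames(X) <- cohort$subjects$subject_id
  filt <- filter_analytes_by_missingness(X, config$max_analyte_missing_frac)
  flagged <- flag_samples_by_missingness(filt$matrix, config$max_sample_missing_frac)
  imp <- impute_rf(filt$matrix, config)
  kept <- colnames(imp)
  out <- cohort
  out$subjects <- cbind(
    cohort$subjects[, setdiff(names(cohort$subjects), nms), drop = FALSE],
    as.data.frame(imp, row.names = NULL))
  out$protein_names <- intersect(cohort$protein_names, kept)
  out$metabolite_names <- intersect(cohort$metabolite_names, kept)
  list(cohort = out,
       report = list(removed_analytes = filt$removed,
                     flagged_samples = flagged,
                     n_imputed_cells = sum(is.na(X[, kept])),
                     imputation_iterations = attr(imp, "iterations"),
                     imputation_deltas = attr(imp, "deltas")))
}
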