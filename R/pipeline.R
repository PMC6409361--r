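#' Configuration for the full study pipeline
#'
#' Bundles the generator, QC, forest and cross-validation settings of an
#' end-to-end run: simulate, QC/impute, split, nested CV over feature sets
#' and tasks, model comparison, recursive feature elimination, and
#' survival + PET validation.
#'
#' @param generator a [generator_config()].
#' @param qc a [qc_config()].
#' @param n_trees trees per modeling forest.
#' @param outer_k,outer_reps outer cross-validation plan.
#' @param inner_k,inner_reps inner cross-validation plan.
#' @param feature_sets subset of [feature_set_codes()] to evaluate.
#' @param tasks modeling tasks to evaluate.
#' @param rfe_feature_set feature set for the elimination analysis.
#' @param rfe_outer_k,rfe_outer_reps outer plan for the per-fold elimination
#'   run (typically smaller than the main plan; elimination is expensive).
#' @param rfe_tolerance parsimony tolerance.
#' @param comparison_alpha significance level for model comparisons.
#' @param bonferroni_divisor divisor applied to `comparison_alpha`.
#' @param output_dir directory for result files (`NULL` = do not write).
#' @param global_seed the single seed from which every random draw in the
#'   pipeline is derived.
#' @return an object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       qc = qc_config(),
                       n_trees = 2000,
                       outer_k = 10, outer_reps = 10,
                       inner_k = 3, inner_reps = 3,
                       feature_sets = feature_set_codes(),
                       tasks = c("regression", "binary"),
                       rfe_feature_set = "BP",
                       rfe_outer_k = 10, rfe_outer_reps = 10,
                       rfe_tolerance = 0.04,
                       comparison_alpha = 0.05,
                       bonferroni_divisor = 5,
                       output_dir = NULL,
                       global_seed = 1L) {
  stopifnot(all(feature_sets %in% feature_set_codes()),
            all(tasks %in% c("regression", "binary")),
            bonferroni_divisor >= 1)
  structure(list(generator = generator, qc = qc,
                 n_trees = as.integer(n_trees),
                 outer_k = as.integer(outer_k), outer_reps = as.integer(outer_reps),
                 inner_k = as.integer(inner_k), inner_reps = as.integer(inner_reps),
                 feature_sets = feature_sets, tasks = tasks,
                 rfe_feature_set = rfe_feature_set,
                 rfe_outer_k = as.integer(rfe_outer_k),
                 rfe_outer_reps = as.integer(rfe_outer_reps),
                 rfe_tolerance = rfe_tolerance,
                 comparison_alpha = comparison_alpha,
                 bonferroni_divisor = bonferroni_divisor,
                 output_dir = output_dir,
                 global_seed = as.integer(global_seed)),
            class = "run_config")
}

# QC/impute the training cohort, then apply the same procedure to the
# validation cohort restricted to the analytes the training QC retained
# (no information flows from validation to training)
qc_split_cohorts <- function(cohort, qc) {
  parts <- split_cohorts(cohort)
  qc_tr <- qc
  qc_tr$impute_seed <- derive_seed(qc$impute_seed, "train")
  tr <- qc_cohort(parts$training, qc_tr)
  va <- parts$validation
  report_va <- NULL
  if (nrow(va$subjects) > 0) {
    kept <- analyte_names(tr$cohort)
    va$protein_names <- tr$cohort$protein_names
    va$metabolite_names <- tr$cohort$metabolite_names
    va$subjects <- va$subjects[, c(setdiff(names(va$subjects), analyte_names(cohort)),
                                   kept), drop = FALSE]
    qc_va <- qc
    qc_va$max_analyte_missing_frac <- 1 # analyte panel fixed by the training QC
    qc_va$impute_seed <- derive_seed(qc$impute_seed, "validation")
    va_res <- qc_cohort(va, qc_va)
    va <- va_res$cohort
    report_va <- va_res$report
  }
  list(training = tr$cohort, validation = va,
       report = list(training = tr$report, validation = report_va))
}

# fit a production model on the full training cohort: forest on the given
# features plus, for the regression task, a dichotomization threshold chosen
# by the inner-CV criterion selection on OOB predictions
train_final_model <- function(training_cohort, features, spec,
                              inner_k = 3, inner_reps = 3, seed = 1L) {
  subj <- training_cohort$subjects
  X <- subj[, features, drop = FALSE]
  y_level <- subj$csf_ab42
  y_status <- csf_status(y_level, training_cohort$clinical_threshold)
  fspec <- spec
  fspec$seed <- derive_seed(seed, "final-fit")
  if (spec$task == "regression") {
    inner <- select_criterion_inner(X, y_level, y_status, fspec,
                                    inner_k, inner_reps,
                                    seed = derive_seed(seed, "final-inner"))
    fit <- fit_forest(X, y_level, fspec)
    cut <- select_cutoff(fit$oob_predictions, y_status, inner$winner)
    list(forest = fit, cutpoint = cut, criterion = inner$winner)
  } else {
    fit <- fit_forest(X, y_status, fspec)
    list(forest = fit, cutpoint = NULL, criterion = NA_character_)
  }
}

predict_final_status <- function(model, newdata) {
  if (model$forest$task == "regression") {
    lev <- predict_forest(model$forest, newdata)
    status_factor(lev < model$cutpoint$threshold)
  } else {
    status_factor(predict_forest(model$forest, newdata) >= 0.5)
  }
}

#' Run the end-to-end study analog
#'
#' Simulates a cohort, runs QC and imputation separately within the
#' training and validation cohorts, evaluates every requested feature set
#' and task under nested cross-validation, compares per-fold AUCs of each
#' model against the best one with one-tailed Wilcoxon signed-rank tests
#' (Bonferroni-corrected threshold `comparison_alpha / bonferroni_divisor`),
#' runs the recursive-elimination analysis and derives the final
#' parsimonious feature set, trains production models (baseline, full
#' proteomic, and parsimonious), and validates them on the held-out cohort
#' by survival stratification and PET concordance. All results are returned
#' and, when `output_dir` is set, written as CSV/JSON files together with a
#' manifest recording the configuration and seeds.
#'
#' @param config a [run_config()].
#' @return a list with elements `summary`, `cv_runs`, `comparisons`, `rfe`,
#'   `final_features`, `survival`, `pet`, `qc_report`, `cohorts`.
#' @export
run_full_study <- function(config = run_config()) {
  gen <- config$generator
  gen$seed <- derive_seed(config$global_seed, "simulate")
  cohort <- generate_cohort(gen)

  qc <- config$qc
  qc$impute_seed <- derive_seed(config$global_seed, "impute")
  parts <- qc_split_cohorts(cohort, qc)
  training <- parts$training
  validation <- parts$validation

  plan <- make_fold_plan(training$subjects$subject_id,
                         csf_status(training$subjects$csf_ab42,
                                    training$clinical_threshold),
                         k = config$outer_k, reps = config$outer_reps,
                         seed = derive_seed(config$global_seed, "outer-plan"))

  cv_runs <- list(); summary_rows <- list()
  for (task in config$tasks) {
    for (fs in config$feature_sets) {
      spec <- forest_spec(config$n_trees, task,
                          seed = derive_seed(config$global_seed, "cv", fs, task))
      run <- run_nested_cv(training, fs, task, plan, spec,
                           config$inner_k, config$inner_reps)
      cv_runs[[paste(fs, task, sep = ".")]] <- run
      s <- run$summary
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        feature_set = fs, task = task, metric = s$metric,
        mean = s$mean, sd = s$sd, stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, summary_rows)

  # one-tailed Wilcoxon of the best model's per-fold AUCs over each other model
  comparisons <- list()
  for (task in config$tasks) {
    runs <- cv_runs[grepl(paste0("\\.", task, "$"), names(cv_runs))]
    if (length(runs) < 2) next
    aucs <- lapply(runs, function(r) r$folds$auc)
    best <- names(which.max(vapply(aucs, mean, numeric(1))))
    for (other in setdiff(names(runs), best)) {
      w <- compare_models_wilcoxon(aucs[[best]], aucs[[other]])
      comparisons[[length(comparisons) + 1]] <- data.frame(
        task = task, better = best, worse = other, p_value = w$p_value,
        significant = !is.na(w$p_value) &
          w$p_value < config$comparison_alpha / config$bonferroni_divisor,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(comparisons) > 0) do.call(rbind, comparisons) else NULL

  # recursive feature elimination: per-fold profile + the production subset
  rfe_spec <- forest_spec(config$n_trees, "regression",
                          seed = derive_seed(config$global_seed, "rfe"))
  rfe_plan <- make_fold_plan(training$subjects$subject_id,
                             csf_status(training$subjects$csf_ab42,
                                        training$clinical_threshold),
                             k = config$rfe_outer_k, reps = config$rfe_outer_reps,
                             seed = derive_seed(config$global_seed, "rfe-plan"))
  rfe <- run_rfe_nested(training, config$rfe_feature_set, rfe_plan, rfe_spec,
                        config$inner_k, config$inner_reps, config$rfe_tolerance)
  final_features <- final_feature_set(training, config$rfe_feature_set,
                                      rfe_spec, config$inner_k,
                                      config$inner_reps, config$rfe_tolerance)

  # production models for the held-out validation
  reg_spec <- forest_spec(config$n_trees, "regression",
                          seed = derive_seed(config$global_seed, "final"))
  model_features <- list(
    B = colnames(feature_matrix(training, "B")),
    BP = colnames(feature_matrix(training, "BP")))
  model_features[["BPfs"]] <- as.character(final_features)
  models <- list()
  for (nm in names(model_features))
    models[[nm]] <- train_final_model(
      training, model_features[[nm]], reg_spec,
      config$inner_k, config$inner_reps,
      seed = derive_seed(config$global_seed, "final", nm))

  survival <- NULL
  if (nrow(validation$subjects) > 0) {
    predicted <- lapply(models, predict_final_status,
                        newdata = validation$subjects)
    survival <- validate_survival_stratification(validation, predicted, training)
  }

  # PET concordance of each model's scores, per cohort
  pet_rows <- list()
  for (side in c("training", "validation")) {
    co <- if (side == "training") training else validation
    if (nrow(co$subjects) == 0 || nrow(co$pet) == 0) next
    ep <- earliest_pet(co$pet)
    pstat <- pet_status(ep$tracer, ep$suvr)
    idx <- match(ep$subject_id, co$subjects$subject_id)
    if (length(unique(pstat)) < 2) next
    for (nm in names(models)) {
      sc <- forest_scores(models[[nm]]$forest, co$subjects[idx, , drop = FALSE])
      pet_rows[[length(pet_rows) + 1]] <- data.frame(
        cohort = side, model = nm, n = length(sc),
        auc = pet_concordance_auc(sc, pstat)$auc, stringsAsFactors = FALSE)
    }
  }
  pet <- if (length(pet_rows) > 0) do.call(rbind, pet_rows) else NULL

  results <- list(summary = summary, cv_runs = cv_runs,
                  comparisons = comparisons, rfe = rfe,
                  final_features = final_features, models = models,
                  survival = survival, pet = pet,
                  qc_report = parts$report,
                  cohorts = list(training = training, validation = validation),
                  config = config)
  if (!is.null(config$output_dir)) write_study_results(results, config)
  invisible(results)
}

write_study_results <- function(results, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  utils::write.csv(results$summary, out("summary.csv"), row.names = FALSE)
  for (nm in names(results$cv_runs))
    utils::write.csv(results$cv_runs[[nm]]$folds,
                     out(sprintf("folds_%s.csv", nm)), row.names = FALSE)
  if (!is.null(results$comparisons))
    utils::write.csv(results$comparisons, out("wilcoxon.csv"), row.names = FALSE)
  utils::write.csv(results$rfe$folds, out("rfe_folds.csv"), row.names = FALSE)
  if (!is.null(results$pet))
    utils::write.csv(results$pet, out("pet_auc.csv"), row.names = FALSE)
  if (!is.null(results$survival)) {
    surv <- results$survival
    jsonlite::write_json(
      list(equivalence = surv$equivalence,
           analyses = lapply(surv$analyses, function(a)
             list(n_per_stratum = as.list(a$n_per_stratum),
                  hazard_ratio = a$cox$hazard_ratio,
                  hr_ci95 = a$cox$ci95,
                  logrank_p = a$logrank$p_value))),
      out("survival.json"), auto_unbox = TRUE, digits = NA)
  }
  cfg <- results$config
  manifest <- list(global_seed = cfg$global_seed,
                   n_trees = cfg$n_trees,
                   outer = c(cfg$outer_reps, cfg$outer_k),
                   inner = c(cfg$inner_reps, cfg$inner_k),
                   feature_sets = cfg$feature_sets, tasks = cfg$tasks,
                   final_features = as.character(results$final_features),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("csfsig")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
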