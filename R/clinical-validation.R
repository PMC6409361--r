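#' Kaplan-Meier curve with Greenwood bands
#'
#' Product-limit estimator at the event times with log-transformed Greenwood
#' 95% intervals clipped to `[0, 1]`. With no events the curve is flat at 1.
#'
#' @param time follow-up times (months).
#' @param event event indicator (1 = conversion to AD, 0 = censored).
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv`, `lower`,
#'   `upper`.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0) stop("no survival records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log", conf.int = 0.95)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv,
             lower = pmax(ifelse(is.na(fit$lower), 0, fit$lower), 0),
             upper = pmin(ifelse(is.na(fit$upper), 1, fit$upper), 1))
}

#' Cox hazard ratio for a two-stratum comparison
#'
#' Single-binary-covariate Cox model (Breslow tie handling) of the abnormal
#' vs normal stratum, with the Wald 95% confidence interval. A stratum with
#' no events leaves the partial likelihood monotone; the result is then
#' flagged.
#'
#' @param time,event survival outcome.
#' @param stratum status labels (`normal`/`abnormal`).
#' @return list with `hazard_ratio`, `ci95` (length-2), `p_value`,
#'   `n_events` per stratum, and `flagged`.
#' @export
cox_hr <- function(time, event, stratum) {
  st <- status_factor(stratum)
  if (any(is.na(st))) stop("stratum labels must be complete")
  ev <- tapply(event, st, sum)
  flagged <- any(is.na(ev)) || any(ev == 0)
  fit <- survival::coxph(survival::Surv(time, event) ~ st, ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  list(hazard_ratio = exp(beta),
       ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       p_value = 2 * stats::pnorm(-abs(beta / se)),
       n_events = as.list(ev),
       flagged = flagged)
}

#' Log-rank test for two groups
#'
#' Standard observed-minus-expected chi-square statistic on one degree of
#' freedom. With no events at all the statistic is 0 and p = 1.
#'
#' @param time,event survival outcome.
#' @param group two-level grouping vector.
#' @return list with `statistic` and `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("both groups must be non-empty")
  if (sum(event) == 0) return(list(statistic = 0, p_value = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Earliest PET record per subject
#'
#' Selects, per subject, the record with the smallest months-from-baseline;
#' ties at the same month are resolved in tracer order (PiB before AV45).
#'
#' @param pet data.frame with `subject_id`, `tracer`, `suvr`,
#'   `months_from_baseline`.
#' @return one-row-per-subject data.frame.
#' @export
earliest_pet <- function(pet) {
  if (nrow(pet) == 0) return(pet)
  tracer_rank <- match(pet$tracer, names(pet_thresholds()))
  if (anyNA(tracer_rank)) stop("unknown tracer in PET records")
  ord <- order(pet$subject_id, pet$months_from_baseline, tracer_rank)
  pet <- pet[ord, , drop = FALSE]
  pet[!duplicated(pet$subject_id), , drop = FALSE]
}

#' Dichotomize PET records into amyloid status
#'
#' Abnormal iff SUVR is at or above the tracer threshold (PiB 1.5,
#' AV45 1.11).
#'
#' @param tracer tracer names (`PiB`/`AV45`).
#' @param suvr standardized uptake value ratios.
#' @return status factor.
#' @export
pet_status <- function(tracer, suvr) {
  thr <- pet_thresholds()[as.character(tracer)]
  if (anyNA(thr)) stop("unknown tracer; expected one of: ",
                       paste(names(pet_thresholds()), collapse = ", "))
  status_factor(suvr >= thr)
}

#' Concordance of model scores with PET status
#'
#' AUC of the model's abnormality scores against PET-derived status.
#'
#' @param scores abnormality scores (higher = more abnormal).
#' @param statuses PET status labels with both classes present.
#' @return list with `auc` and the ROC `points` (see [aggregate_roc()]).
#' @export
pet_concordance_auc <- function(scores, statuses) {
  roc <- aggregate_roc(scores, statuses)
  list(auc = roc$auc, points = roc$points)
}

survival_frame <- function(cohort, stratum, label) {
  keep <- cohort$subjects$diagnosis == "MCI"
  data.frame(subject_id = cohort$subjects$subject_id[keep],
             time = cohort$subjects$conversion_months[keep],
             event = cohort$subjects$conversion_event[keep],
             stratum = status_factor(stratum[keep]),
             analysis = label, stringsAsFactors = FALSE)
}

one_survival_comparison <- function(df) {
  by_stratum <- split(df, df$stratum)
  km <- lapply(by_stratum, function(d) kaplan_meier(d$time, d$event))
  list(n_per_stratum = vapply(by_stratum, nrow, integer(1)),
       km = km,
       cox = cox_hr(df$time, df$event, df$stratum),
       logrank = logrank_test(df$time, df$event, df$stratum))
}

#' Survival stratification of predicted CSF status
#'
#' Runs the clinical-validation survival analyses: Kaplan-Meier curves, the
#' Cox hazard ratio and the log-rank test for (i) the measured CSF status on
#' the training cohort and (ii) each supplied model's predicted status on
#' the validation cohort; plus cross-cohort log-rank equivalence tests
#' comparing each model's predicted-normal (resp. predicted-abnormal)
#' stratum on the validation cohort against the measured-normal
#' (resp. -abnormal) stratum on the training cohort. Only baseline-MCI
#' subjects enter (conversion to AD is the endpoint; CN subjects are
#' excluded by design and baseline-AD subjects have already converted).
#'
#' @param validation_cohort a `csf_cohort` without CSF measures.
#' @param predicted_status named list (model name -> status vector over all
#'   validation subjects, in cohort order).
#' @param training_cohort a `csf_cohort` with CSF measures.
#' @return list with one `SurvivalComparison` per analysis (`actual` first,
#'   then the models) and `equivalence`: per-model log-rank p-values for the
#'   normal and abnormal strata across cohorts.
#' @export
validate_survival_stratification <- function(validation_cohort,
                                             predicted_status,
                                             training_cohort) {
  if (is.null(names(predicted_status)) || any(names(predicted_status) == ""))
    stop("'predicted_status' must be a named list of per-model status vectors")
  actual <- csf_status(training_cohort$subjects$csf_ab42,
                       training_cohort$clinical_threshold)
  if (anyNA(actual)) stop("training cohort must have CSF measures for all subjects")
  tr_df <- survival_frame(training_cohort, actual, "actual")
  analyses <- list(actual = one_survival_comparison(tr_df))
  equivalence <- list()
  for (model in names(predicted_status)) {
    ps <- predicted_status[[model]]
    if (length(ps) != nrow(validation_cohort$subjects))
      stop("predicted status for model '", model,
           "' does not cover the validation cohort")
    va_df <- survival_frame(validation_cohort, ps, model)
    analyses[[model]] <- one_survival_comparison(va_df)
    eq <- list()
    for (cls in c("normal", "abnormal")) {
      a <- va_df[va_df$stratum == cls, ]
      b <- tr_df[tr_df$stratum == cls, ]
      comb <- rbind(a, b)
      eq[[cls]] <- logrank_test(comb$time, comb$event,
                                rep(c("predicted", "actual"),
                                    c(nrow(a), nrow(b))))$p_value
    }
    equivalence[[model]] <- eq
  }
  list(analyses = analyses, equivalence = equivalence)
}
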