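#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter bundle for [generate_cohort()]. The defaults emulate
#' the statistical structure of a memory-clinic cohort in which a latent
#' continuous CSF amyloid-beta 1-42 level (pg/ml) is driven by APOEe4 carrier
#' status and a handful of informative plasma analytes hidden among many
#' noise analytes, dichotomized at a clinical threshold of 192 pg/ml.
#'
#' Default effect sizes are calibrated so that the oracle linear score (the
#' systematic part of the latent level) discriminates abnormal from normal
#' subjects with AUC close to 0.85, and so that roughly 67% of subjects with
#' a CSF measure are abnormal. The four default informative analytes carry
#' the effect directions established for chromogranin-A (positive), plasma
#' amyloid-beta 1-42 (positive), plasma apolipoprotein E (positive) and
#' eotaxin-3 (negative).
#'
#' @param n_subjects number of subjects (>= 20).
#' @param n_protein_analytes number of protein analytes (informative analytes
#'   are placed among these).
#' @param n_metabolite_analytes number of metabolite analytes (noise only).
#' @param informative_features data.frame with columns `name`, `sign`
#'   (+1/-1) and `size` (latent-CSF pg/ml shift per SD of the analyte).
#' @param apoe4_effect latent-CSF shift (pg/ml) for APOEe4 carriers
#'   (negative: carriers have lower levels).
#' @param carrier_prevalence fraction of APOEe4 carriers.
#' @param csf_mean,csf_sd baseline mean and residual SD of the latent CSF
#'   level (pg/ml).
#' @param clinical_threshold dichotomization threshold (pg/ml); levels
#'   strictly below it are "abnormal".
#' @param csf_absent_frac fraction of subjects whose CSF measure is withheld
#'   (the validation cohort).
#' @param pet_rate fraction of subjects with amyloid PET records.
#' @param pet_discordance_rate probability that a subject's PET status
#'   disagrees with the true CSF status (default 7/108).
#' @param hazard_rate_normal per-month exponential hazard of conversion to a
#'   clinical AD diagnosis for CSF-normal subjects.
#' @param hazard_ratio_abnormal multiplicative hazard ratio for CSF-abnormal
#'   subjects (> 0).
#' @param followup_months administrative censoring horizon (months).
#' @param missing_rate per-cell MCAR missingness rate applied to analytes.
#' @param seed integer seed; the generated table is a pure function of the
#'   configuration including this seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 566,
                             n_protein_analytes = 149,
                             n_metabolite_analytes = 138,
                             informative_features = default_informative_features(),
                             apoe4_effect = -50,
                             carrier_prevalence = 0.511,
                             csf_mean = 193,
                             csf_sd = 38,
                             clinical_threshold = 192,
                             csf_absent_frac = 210 / 566,
                             pet_rate = 0.4,
                             pet_discordance_rate = 7 / 108,
                             hazard_rate_normal = 0.004,
                             hazard_ratio_abnormal = 2.5,
                             followup_months = 120,
                             missing_rate = 0.02,
                             seed = 1L) {
  stop_if_not_count(n_subjects, "n_subjects", min = 20)
  stop_if_not_count(n_protein_analytes, "n_protein_analytes", min = 0)
  stop_if_not_count(n_metabolite_analytes, "n_metabolite_analytes", min = 0)
  for (nm in c("carrier_prevalence", "csf_absent_frac", "pet_rate",
               "pet_discordance_rate", "missing_rate"))
    stop_if_not_fraction(get(nm), nm)
  if (!is.numeric(clinical_threshold) || clinical_threshold <= 0)
    stop("'clinical_threshold' must be positive")
  if (!is.numeric(hazard_ratio_abnormal) || hazard_ratio_abnormal <= 0)
    stop("'hazard_ratio_abnormal' must be > 0")
  if (hazard_rate_normal < 0) stop("'hazard_rate_normal' must be >= 0")
  if (csf_sd < 0) stop("'csf_sd' must be >= 0")
  inf <- as.data.frame(informative_features)
  if (nrow(inf) > 0) {
    if (!all(c("name", "sign", "size") %in% names(inf)))
      stop("'informative_features' needs columns name, sign, size")
    if (anyDuplicated(inf$name))
      stop("informative feature names must be unique")
    if (!all(is.finite(inf$size)) || !all(is.finite(inf$sign)))
      stop("informative effect sizes and signs must be finite")
    if (!all(inf$sign %in% c(-1, 1)))
      stop("informative feature 'sign' must be +1 or -1")
    if (nrow(inf) > n_protein_analytes + n_metabolite_analytes)
      stop("more informative features than analytes")
    if (nrow(inf) > n_protein_analytes)
      stop("informative features are placed among the protein analytes; increase 'n_protein_analytes'")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_protein_analytes = as.integer(n_protein_analytes),
    n_metabolite_analytes = as.integer(n_metabolite_analytes),
    informative_features = inf,
    apoe4_effect = apoe4_effect,
    carrier_prevalence = carrier_prevalence,
    csf_mean = csf_mean, csf_sd = csf_sd,
    clinical_threshold = clinical_threshold,
    csf_absent_frac = csf_absent_frac,
    pet_rate = pet_rate,
    pet_discordance_rate = pet_discordance_rate,
    hazard_rate_normal = hazard_rate_normal,
    hazard_ratio_abnormal = hazard_ratio_abnormal,
    followup_months = followup_months,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default informative plasma analytes
#'
#' Four analytes with the effect directions of chromogranin-A (`CGA`, +),
#' plasma amyloid-beta 1-42 (`AB42`, +), plasma apolipoprotein E
#' (`APOE_PLASMA`, +) and eotaxin-3 (`EOTAXIN3`, -) on the latent CSF level.
#'
#' @return data.frame with columns `name`, `sign`, `size`.
#' @export
default_informative_features <- function() {
  data.frame(
    name = c("CGA", "AB42", "APOE_PLASMA", "EOTAXIN3"),
    sign = c(1, 1, 1, -1),
    size = c(15, 18, 15, 12),
    stringsAsFactors = FALSE
  )
}

# tracer-specific SUVR thresholds for amyloid PET positivity
pet_thresholds <- function() c(PiB = 1.5, AV45 = 1.11)

#' Construct a cohort object
#'
#' A cohort bundles the per-subject table (covariates, analyte matrix with
#' missingness, optional CSF level, survival outcome, diagnosis), the
#' long-format PET records, and bookkeeping: which analyte columns are
#' proteins vs metabolites, the clinical threshold and follow-up horizon.
#' Synthetic cohorts additionally carry a `truth` table (latent level, true
#' status, oracle score) that the analysis functions never touch; it exists
#' for testing and validation only.
#'
#' @param subjects data.frame with columns `subject_id`, `age`,
#'   `apoe4_carrier`, `diagnosis`, `csf_ab42`, `conversion_months`,
#'   `conversion_event`, plus one column per analyte.
#' @param pet data.frame with columns `subject_id`, `tracer`, `suvr`,
#'   `months_from_baseline` (may have zero rows).
#' @param protein_names,metabolite_names character vectors naming the
#'   analyte columns of each modality.
#' @param clinical_threshold pg/ml threshold defining abnormal status.
#' @param followup_months censoring horizon.
#' @param truth optional data.frame of generator ground truth.
#' @return an object of class `csf_cohort`.
#' @export
csf_cohort <- function(subjects, pet = NULL, protein_names, metabolite_names,
                       clinical_threshold = 192, followup_months = 120,
                       truth = NULL) {
  required <- c("subject_id", "age", "apoe4_carrier", "diagnosis",
                "csf_ab42", "conversion_months", "conversion_event")
  miss <- setdiff(required, names(subjects))
  if (length(miss) > 0)
    stop("cohort table is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop("subject_id values must be unique")
  analytes <- c(protein_names, metabolite_names)
  miss <- setdiff(analytes, names(subjects))
  if (length(miss) > 0)
    stop("analyte column(s) absent from cohort table: ", paste(miss, collapse = ", "))
  if (any(subjects$conversion_months < 0, na.rm = TRUE))
    stop("conversion_months must be >= 0")
  if (!all(subjects$conversion_event %in% c(0, 1)))
    stop("conversion_event must be 0 or 1")
  if (is.null(pet))
    pet <- data.frame(subject_id = character(0), tracer = character(0),
                      suvr = numeric(0), months_from_baseline = numeric(0))
  structure(list(
    subjects = subjects,
    pet = pet,
    protein_names = protein_names,
    metabolite_names = metabolite_names,
    clinical_threshold = clinical_threshold,
    followup_months = followup_months,
    truth = truth
  ), class = "csf_cohort")
}

#' @export
print.csf_cohort <- function(x, ...) {
  n <- nrow(x$subjects)
  cat(sprintf("<csf_cohort> %d subjects, %d protein + %d metabolite analytes\n",
              n, length(x$protein_names), length(x$metabolite_names)))
  cat(sprintf("  CSF measured: %d | PET subjects: %d | threshold: %g pg/ml\n",
              sum(!is.na(x$subjects$csf_ab42)),
              length(unique(x$pet$subject_id)), x$clinical_threshold))
  invisible(x)
}

#' Analyte names of a cohort
#' @param cohort a `csf_cohort`.
#' @return character vector of analyte column names (proteins first).
#' @export
analyte_names <- function(cohort) c(cohort$protein_names, cohort$metabolite_names)

#' Dichotomize CSF levels at the clinical threshold
#'
#' Status is "abnormal" iff the level is strictly below the threshold.
#'
#' @param csf_ab42 numeric levels (pg/ml); NA allowed.
#' @param threshold clinical threshold (pg/ml).
#' @return factor with levels `normal`, `abnormal` (NA where level is NA).
#' @export
csf_status <- function(csf_ab42, threshold = 192) {
  status_factor(csf_ab42 < threshold)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort in which the latent CSF amyloid-beta 1-42 level is
#' `csf_mean + apoe4_effect * carrier + sum(size_j * sign_j * z_j) +
#' N(0, csf_sd)`, with `z_j` the standardized informative analytes;
#' remaining analytes are independent standard-normal noise. True status is
#' abnormal iff the latent level is strictly below the clinical threshold.
#' PET status equals true status except for a Bernoulli discordance flip,
#' with SUVR values drawn just above/below the tracer threshold to realize
#' it. Conversion-to-AD times are exponential with hazard
#' `hazard_rate_normal * hazard_ratio_abnormal^(abnormal)`, administratively
#' censored at `followup_months`. Subjects without a CSF measure (the
#' validation cohort) are labeled MCI; subjects with CSF are assigned
#' CN/MCI/AD baseline diagnoses in proportions typical of a memory-clinic
#' training cohort. MCAR missingness at `missing_rate` is applied to the
#' analyte columns. Output is a pure function of the configuration.
#'
#' @param config a [generator_config()].
#' @return a [csf_cohort()] whose `truth` element records `latent_csf`,
#'   `true_status`, `pet_status` and `oracle_score` (higher = more abnormal).
#' @export
generate_cohort <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    stop("'config' must be created by generator_config()")
  with_seed(config$seed, {
    n <- config$n_subjects
    inf <- config$informative_features
    subject_id <- sprintf("S%04d", seq_len(n))

    age <- pmin(pmax(stats::rnorm(n, 74.7, 7.4), 55), 90)
    carrier <- stats::rbinom(n, 1, config$carrier_prevalence)

    n_inf <- nrow(inf)
    prot_names <- c(inf$name,
                    sprintf("PROT_%03d", seq_len(config$n_protein_analytes - n_inf)))
    met_names <- if (config$n_metabolite_analytes > 0)
      sprintf("MET_%03d", seq_len(config$n_metabolite_analytes)) else character(0)
    p_all <- length(prot_names) + length(met_names)
    X <- matrix(stats::rnorm(n * p_all), n, p_all,
                dimnames = list(NULL, c(prot_names, met_names)))

    signal <- config$apoe4_effect * carrier
    if (n_inf > 0)
      signal <- signal + drop(X[, inf$name, drop = FALSE] %*% (inf$size * inf$sign))
    latent <- config$csf_mean + signal + stats::rnorm(n, 0, config$csf_sd)
    true_abnormal <- latent < config$clinical_threshold

    # validation subjects: CSF withheld, baseline diagnosis MCI
    n_val <- round(config$csf_absent_frac * n)
    val_idx <- sample.int(n, n_val)
    csf_ab42 <- latent
    csf_ab42[val_idx] <- NA_real_
    diagnosis <- rep(NA_character_, n)
    diagnosis[val_idx] <- "MCI"
    tr_idx <- setdiff(seq_len(n), val_idx)
    diagnosis[tr_idx] <- sample(c("CN", "MCI", "AD"), length(tr_idx),
                                replace = TRUE, prob = c(58, 198, 100) / 356)

    # conversion to clinical AD: exponential, censored administratively
    hz <- config$hazard_rate_normal *
      ifelse(true_abnormal, config$hazard_ratio_abnormal, 1)
    tconv <- ifelse(hz > 0, stats::rexp(n, pmax(hz, 1e-12)), Inf)
    conversion_event <- as.integer(tconv <= config$followup_months)
    conversion_months <- pmin(tconv, config$followup_months)

    # PET: subject-level status flips with the discordance rate; SUVR drawn
    # within +/-0.5 of the tracer threshold on the side realizing the status
    has_pet <- stats::rbinom(n, 1, config$pet_rate) == 1
    flip <- stats::rbinom(n, 1, config$pet_discordance_rate) == 1
    pet_abnormal <- ifelse(flip, !true_abnormal, true_abnormal)
    pet_rows <- list()
    thr <- pet_thresholds()
    for (i in which(has_pet)) {
      k <- sample(1:3, 1)
      months <- round(sort(stats::runif(k, 0, 60)), 1)
      tracer <- sample(names(thr), k, replace = TRUE, prob = c(0.3, 0.7))
      off <- stats::runif(k, 0, 0.5)
      suvr <- ifelse(rep(pet_abnormal[i], k), thr[tracer] + pmax(off, 1e-6),
                     thr[tracer] - pmax(off, 1e-6))
      pet_rows[[length(pet_rows) + 1]] <- data.frame(
        subject_id = subject_id[i], tracer = tracer, suvr = round(suvr, 4),
        months_from_baseline = months, stringsAsFactors = FALSE)
    }
    pet <- if (length(pet_rows) > 0) do.call(rbind, pet_rows) else NULL

    subjects <- data.frame(subject_id = subject_id, age = round(age, 1),
                           apoe4_carrier = carrier, diagnosis = diagnosis,
                           csf_ab42 = round(csf_ab42, 2),
                           conversion_months = round(conversion_months, 2),
                           conversion_event = conversion_event,
                           stringsAsFactors = FALSE)
    subjects <- cbind(subjects, as.data.frame(round(X, 4)))

    truth <- data.frame(
      subject_id = subject_id,
      latent_csf = latent,
      true_status = status_factor(true_abnormal),
      pet_status = status_factor(pet_abnormal),
      oracle_score = -signal, # higher = more abnormal
      stringsAsFactors = FALSE)

    cohort <- csf_cohort(subjects, pet, prot_names, met_names,
                         clinical_threshold = config$clinical_threshold,
                         followup_months = config$followup_months,
                         truth = truth)
    if (config$missing_rate > 0)
      cohort <- inject_missingness(cohort, config$missing_rate,
                                   seed = derive_seed(config$seed, "missingness"))
    cohort
  })
}

#' Inject MCAR missingness into the analyte matrix
#'
#' Each analyte cell is independently set missing with its analyte-specific
#' rate. Non-analyte columns are untouched.
#'
#' @param cohort a `csf_cohort`.
#' @param rates a single rate, or a named vector of per-analyte rates
#'   (analytes not named keep their values).
#' @param seed integer seed.
#' @return the cohort with missing analyte cells.
#' @export
inject_missingness <- function(cohort, rates, seed = 1L) {
  nms <- analyte_names(cohort)
  if (is.null(names(rates))) {
    if (length(rates) != 1) stop("unnamed 'rates' must be a single rate")
    rates <- stats::setNames(rep(rates, length(nms)), nms)
  }
  if (any(rates < 0 | rates > 1)) stop("missingness rates must be in [0, 1]")
  unknown <- setdiff(names(rates), nms)
  if (length(unknown) > 0)
    stop("rates given for unknown analyte(s): ", paste(unknown, collapse = ", "))
  with_seed(seed, {
    n <- nrow(cohort$subjects)
    for (a in names(rates)) {
      if (rates[[a]] == 0) next
      hit <- stats::runif(n) < rates[[a]]
      cohort$subjects[[a]][hit] <- NA_real_
    }
  })
  cohort
}

#' Split a cohort by CSF availability
#'
#' Subjects with a CSF measure form the training cohort; subjects without
#' one form the validation cohort. The split is exhaustive and disjoint.
#'
#' @param cohort a `csf_cohort`.
#' @return list with elements `training` and `validation`, both `csf_cohort`.
#' @export
split_cohorts <- function(cohort) {
  has_csf <- !is.na(cohort$subjects$csf_ab42)
  if (!any(has_csf)) stop("no subjects with a CSF measure; cannot form a training cohort")
  if (all(has_csf)) warning("all subjects have CSF measures; validation cohort is empty")
  subset_cohort <- function(keep) {
    ids <- cohort$subjects$subject_id[keep]
    csf_cohort(cohort$subjects[keep, , drop = FALSE],
               cohort$pet[cohort$pet$subject_id %in% ids, , drop = FALSE],
               cohort$protein_names, cohort$metabolite_names,
               cohort$clinical_threshold, cohort$followup_months,
               truth = if (!is.null(cohort$truth))
                 cohort$truth[keep, , drop = FALSE] else NULL)
  }
  list(training = subset_cohort(has_csf), validation = subset_cohort(!has_csf))
}
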