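test_that("generator config rejects invalid parameters", {
  expect_error(generator_config(n_subjects = 10), "n_subjects")
  expect_error(generator_config(carrier_prevalence = 1.2), "fraction")
  expect_error(generator_config(hazard_ratio_abnormal = 0), "hazard_ratio")
  expect_error(generator_config(clinical_threshold = -1), "clinical_threshold")
  inf <- data.frame(name = c("A", "A"), sign = c(1, 1), size = c(1, 1))
  expect_error(generator_config(informative_features = inf), "unique")
  inf2 <- data.frame(name = "A", sign = 1, size = Inf)
  expect_error(generator_config(informative_features = inf2), "finite")
  inf3 <- data.frame(name = paste0("A", 1:5), sign = 1, size = 1)
  expect_error(generator_config(n_protein_analytes = 3, n_metabolite_analytes = 0,
                                informative_features = inf3), "analytes")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- small_config(n = 60, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$pet, b$pet)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(small_config(n = 60, seed = 12))
  expect_false(identical(a$subjects, c2$subjects))
})

test_that("null configuration decouples analytes from CSF levels", {
  inf <- data.frame(name = character(0), sign = numeric(0), size = numeric(0))
  cfg <- small_config(n = 5000, p_prot = 8, p_met = 4, seed = 3,
                      informative_features = inf, apoe4_effect = 0,
                      missing_rate = 0, csf_absent_frac = 0)
  co <- suppressWarnings(generate_cohort(cfg))
  for (a in analyte_names(co)) {
    r <- cor(co$subjects[[a]], co$subjects$csf_ab42)
    expect_lt(abs(r), 0.04) # large-sample null, ~3/sqrt(n)
  }
})

test_that("default effect directions and prevalence are realized", {
  cfg <- small_config(n = 5000, seed = 5, missing_rate = 0, csf_absent_frac = 0)
  co <- suppressWarnings(generate_cohort(cfg))
  s <- co$subjects
  expect_gt(cor(s$CGA, s$csf_ab42), 0)
  expect_gt(cor(s$AB42, s$csf_ab42), 0)
  expect_lt(cor(s$EOTAXIN3, s$csf_ab42), 0)
  expect_lt(mean(s$csf_ab42[s$apoe4_carrier == 1]),
            mean(s$csf_ab42[s$apoe4_carrier == 0]))
  prev <- mean(csf_status(s$csf_ab42) == "abnormal")
  expect_lt(abs(prev - 0.674), 0.03)
})

test_that("oracle score discriminability matches an independent simulation", {
  cfg <- small_config(n = 10000, seed = 21, missing_rate = 0)
  co <- generate_cohort(cfg)
  emp_auc <- roc_auc(co$truth$oracle_score, co$truth$true_status)

  # independent oracle: the same latent model simulated directly at large n
  set.seed(4242)
  n <- 4e5
  carrier <- rbinom(n, 1, cfg$carrier_prevalence)
  z <- matrix(rnorm(n * 4), n, 4)
  inf <- cfg$informative_features
  s <- cfg$apoe4_effect * carrier + drop(z %*% (inf$size * inf$sign))
  latent <- cfg$csf_mean + s + rnorm(n, 0, cfg$csf_sd)
  ref_auc <- roc_auc(-s, latent < cfg$clinical_threshold)

  expect_lt(abs(emp_auc - ref_auc), 0.02)
  expect_lt(abs(ref_auc - 0.85), 0.02) # calibrated discriminability
})

test_that("missingness injection is MCAR at the requested rates", {
  cfg <- small_config(n = 2000, p_prot = 5, p_met = 0, seed = 9, missing_rate = 0)
  co <- generate_cohort(cfg)
  expect_identical(inject_missingness(co, 0, seed = 1)$subjects, co$subjects)
  all_gone <- inject_missingness(co, c(CGA = 1), seed = 1)
  expect_true(all(is.na(all_gone$subjects$CGA)))
  expect_identical(all_gone$subjects$AB42, co$subjects$AB42)
  part <- inject_missingness(co, c(PROT_001 = 0.2), seed = 2)
  expect_lt(abs(mean(is.na(part$subjects$PROT_001)) - 0.2), 0.03)
  expect_error(inject_missingness(co, 1.5), "\\[0, 1\\]")
  expect_error(inject_missingness(co, c(NOPE = 0.1)), "unknown analyte")
})

test_that("splitting by CSF availability is an exact partition", {
  co <- generate_cohort(generator_config(n_subjects = 566,
                                         n_protein_analytes = 10,
                                         n_metabolite_analytes = 5, seed = 2))
  parts <- split_cohorts(co)
  expect_equal(nrow(parts$training$subjects), 356)
  expect_equal(nrow(parts$validation$subjects), 210)
  expect_setequal(c(parts$training$subjects$subject_id,
                    parts$validation$subjects$subject_id),
                  co$subjects$subject_id)
  expect_length(intersect(parts$training$subjects$subject_id,
                          parts$validation$subjects$subject_id), 0)
  expect_true(all(parts$validation$subjects$diagnosis == "MCI"))

  full <- generate_cohort(small_config(n = 40, seed = 2, csf_absent_frac = 0))
  expect_warning(p2 <- split_cohorts(full), "validation cohort is empty")
  expect_equal(nrow(p2$training$subjects), 40)
})

test_that("abnormal subjects convert to AD faster when the hazard ratio exceeds 1", {
  cfg <- small_config(n = 2000, p_prot = 4, p_met = 0, seed = 13,
                      hazard_rate_normal = 0.01, hazard_ratio_abnormal = 3,
                      missing_rate = 0)
  co <- generate_cohort(cfg)
  med <- function(keep) {
    fit <- survival::survfit(survival::Surv(
      co$subjects$conversion_months[keep],
      co$subjects$conversion_event[keep]) ~ 1)
    unname(summary(fit)$table["median"])
  }
  abn <- co$truth$true_status == "abnormal"
  expect_lt(med(abn), med(!abn))
})

test_that("PET status disagrees with true status at the discordance rate", {
  cfg <- small_config(n = 4000, p_prot = 4, p_met = 0, seed = 17,
                      pet_rate = 1, missing_rate = 0)
  co <- generate_cohort(cfg)
  ep <- earliest_pet(co$pet)
  idx <- match(ep$subject_id, co$truth$subject_id)
  disc <- mean(pet_status(ep$tracer, ep$suvr) != co$truth$true_status[idx])
  expect_lt(abs(disc - 7 / 108), 0.02)
})
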