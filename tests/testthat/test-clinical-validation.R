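test_that("Kaplan-Meier reproduces hand-computed product-limit values", {
  # no events: flat at one
  km0 <- kaplan_meier(c(10, 20, 30), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # uncensored events at 1..n: S(t_k) = (n - k) / n
  n <- 8
  km1 <- kaplan_meier(1:n, rep(1, n))
  expect_equal(km1$surv, (n - seq_len(n)) / n)

  # toy schedule: events at 2 and 4, censoring at 3, n = 4
  km2 <- kaplan_meier(c(2, 3, 4, 5), c(1, 0, 1, 0))
  expect_equal(km2$surv[km2$time == 2], 0.75)
  expect_equal(km2$surv[km2$time == 4], 0.375) # 3/4 * 1/2

  expect_true(all(km2$lower >= 0 & km2$upper <= 1))
  expect_true(all(diff(km2$surv) <= 0))
})

test_that("uncensored KM equals the empirical survival function", {
  set.seed(81)
  t <- round(rexp(50, 0.05), 1)
  km <- kaplan_meier(t, rep(1, 50))
  for (i in seq_len(nrow(km)))
    expect_equal(km$surv[i], mean(t > km$time[i]))
})

test_that("Cox hazard ratio matches a brute-force partial likelihood", {
  time <- c(2, 4, 4, 6, 7, 9)
  event <- c(1, 1, 0, 1, 1, 1)
  stratum <- c("abnormal", "normal", "abnormal", "abnormal", "normal", "normal")
  fit <- cox_hr(time, event, stratum)
  z <- as.numeric(stratum == "abnormal")
  grid <- optimize(function(b) -breslow_loglik(b, time, event, z),
                   interval = c(-10, 10), tol = 1e-9)
  expect_equal(fit$hazard_ratio, exp(grid$minimum), tolerance = 1e-4)
  expect_true(fit$ci95[1] <= fit$hazard_ratio &
                fit$hazard_ratio <= fit$ci95[2])
})

test_that("exchangeable strata give a hazard ratio compatible with one", {
  set.seed(83)
  n <- 600
  t <- rexp(n, 0.02); cens <- pmin(t, 60)
  fit <- cox_hr(cens, as.numeric(t <= 60),
                rep(c("normal", "abnormal"), n / 2))
  expect_true(fit$ci95[1] < 1 && 1 < fit$ci95[2])
  expect_false(fit$flagged)
})

test_that("a stratum without events is flagged", {
  fit <- suppressWarnings(
    cox_hr(c(1, 2, 3, 4), c(1, 1, 0, 0),
           c("abnormal", "abnormal", "normal", "normal")))
  expect_true(fit$flagged)
})

test_that("log-rank handles degenerate and powered comparisons", {
  # two identical copies of the same group: statistic 0, p = 1
  t <- c(2, 4, 6, 8); e <- c(1, 1, 0, 1)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  none <- logrank_test(c(1, 2, 3, 4), rep(0, 4), rep(c("a", "b"), 2))
  expect_equal(none$statistic, 0)
  expect_equal(none$p_value, 1)
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "both groups")

  set.seed(85) # strong effect: HR = 3 at n = 100 per arm
  t1 <- rexp(100, 0.03); t2 <- rexp(100, 0.01)
  tt <- pmin(c(t1, t2), 120); ee <- as.numeric(c(t1, t2) <= 120)
  lr2 <- logrank_test(tt, ee, rep(c("abnormal", "normal"), each = 100))
  expect_lt(lr2$p_value, 0.05)
})

test_that("log-rank and the Cox score test agree at large n", {
  set.seed(87)
  n <- 1000
  g <- rep(c("normal", "abnormal"), n / 2)
  t <- rexp(n, ifelse(g == "abnormal", 0.02, 0.012))
  tt <- pmin(t, 120); ee <- as.numeric(t <= 120)
  lr <- logrank_test(tt, ee, g)
  cox <- survival::coxph(survival::Surv(tt, ee) ~ g)
  score <- summary(cox)$sctest["test"]
  expect_lt(abs(lr$statistic - score) / score, 0.05)
})

test_that("earliest PET record selection follows time then tracer order", {
  pet <- data.frame(
    subject_id = c("A", "B", "B", "C", "C"),
    tracer = c("AV45", "AV45", "PiB", "AV45", "PiB"),
    suvr = c(1.2, 1.0, 1.6, 1.3, 1.4),
    months_from_baseline = c(12, 36, 24, 18, 18))
  ep <- earliest_pet(pet)
  expect_equal(nrow(ep), 3)
  expect_equal(ep$months_from_baseline[ep$subject_id == "B"], 24)
  expect_equal(ep$tracer[ep$subject_id == "C"], "PiB") # tie at 18 months
  expect_error(earliest_pet(data.frame(subject_id = "X", tracer = "FDG",
                                       suvr = 1, months_from_baseline = 0)),
               "unknown tracer")
})

test_that("PET dichotomization applies tracer-specific thresholds", {
  expect_equal(as.character(pet_status("PiB", 1.6)), "abnormal")
  expect_equal(as.character(pet_status("AV45", 1.05)), "normal")
  expect_equal(as.character(pet_status("PiB", 1.5)), "abnormal") # boundary: >=
  expect_equal(as.character(pet_status("AV45", 1.11)), "abnormal")
  expect_equal(as.character(pet_status(c("PiB", "AV45"), c(1.4, 1.2))),
               c("normal", "abnormal"))
  expect_error(pet_status("FDG", 1.2), "unknown tracer")
})

test_that("PET concordance AUC degrades gracefully with discordance", {
  set.seed(91)
  n <- 500
  true_st <- ifelse(rbinom(n, 1, 0.6) == 1, "abnormal", "normal")
  oracle_scores <- as.numeric(true_st == "abnormal") # perfect CSF predictor
  low <- ifelse(runif(n) < 7 / 108,
                ifelse(true_st == "abnormal", "normal", "abnormal"),
                true_st)
  expect_gte(pet_concordance_auc(oracle_scores, low)$auc, 0.9)
  half <- ifelse(runif(n) < 0.5,
                 ifelse(true_st == "abnormal", "normal", "abnormal"),
                 true_st)
  expect_lt(abs(pet_concordance_auc(oracle_scores, half)$auc - 0.5), 0.1)
})

test_that("survival stratification validates predictions end to end", {
  cfg <- small_config(n = 500, p_prot = 6, p_met = 0, seed = 97,
                      hazard_rate_normal = 0.008, hazard_ratio_abnormal = 3,
                      missing_rate = 0)
  parts <- split_cohorts(generate_cohort(cfg))
  val <- parts$validation
  predicted <- list(oracle = val$truth$true_status)
  res <- validate_survival_stratification(val, predicted, parts$training)
  expect_named(res$analyses, c("actual", "oracle"))
  expect_lt(res$analyses$actual$logrank$p_value, 0.05)
  expect_lt(res$analyses$oracle$logrank$p_value, 0.05)
  expect_gt(res$analyses$oracle$cox$hazard_ratio, 1)
  # stratum sizes are reported and cover only the MCI subjects
  expect_equal(sum(res$analyses$oracle$n_per_stratum),
               sum(val$subjects$diagnosis == "MCI"))
  expect_named(res$equivalence$oracle, c("normal", "abnormal"))
  # oracle predictions on an exchangeable cohort: no cross-cohort difference
  expect_gt(res$equivalence$oracle$normal, 0.001)
  expect_error(validate_survival_stratification(val, list(val$truth$true_status),
                                                parts$training), "named list")
})
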