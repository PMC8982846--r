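test_that("standardized difference is symmetric, zero iff equal", {
  expect_equal(standardized_difference(0.3, 0.3), 0)
  expect_equal(standardized_difference(0, 0), 0)
  expect_equal(standardized_difference(1, 1), 0)
  p <- runif(20); q <- runif(20)
  expect_equal(standardized_difference(p, q), standardized_difference(q, p))
  expect_true(all(standardized_difference(p, q)[p != q] > 0))
  # hand-checked value: |.25-.4|/sqrt((.1875+.24)/2)
  expect_equal(standardized_difference(0.25, 0.4),
               0.15 / sqrt((0.25 * 0.75 + 0.4 * 0.6) / 2))
})

test_that("balance table percentages sum to 100 within each covariate", {
  pop <- generate_population(sim_config(2000, seed = 21))
  b <- build_cohort(pop, need = character(0))
  bt <- balance_table(b$cohort)
  sums <- tapply(bt$pct_hydrocodone, bt$covariate, sum)
  expect_true(all(abs(sums - 100) < 1e-8))
  sums2 <- tapply(bt$pct_oxycodone, bt$covariate, sum)
  expect_true(all(abs(sums2 - 100) < 1e-8))
  expect_true(all(bt$std_diff >= 0))
})

test_that("report ratios are exp(estimate) and CIs are Wald on the log scale", {
  pop <- generate_population(sim_config(4000, seed = 22))
  b <- build_cohort(pop, need = c("chronic", "survival"))
  rep1 <- fit_chronic_logistic(b$cohort, b$chronic, random_effect = "off")
  est <- rep1$estimates[!rep1$estimates$reference &
                          !is.na(rep1$estimates$estimate), ]
  expect_true(all(abs(est$ratio - exp(est$estimate)) < 1e-12))
  expect_equal(est$ci_low, exp(est$estimate - 1.96 * est$se))
  expect_equal(est$ci_high, exp(est$estimate + 1.96 * est$se))
  expect_true(all(est$ci_low <= est$ratio & est$ratio <= est$ci_high))
  refs <- rep1$estimates[rep1$estimates$reference, ]
  expect_true(all(refs$ratio == 1))
})

test_that("the single-level fit matches glmer when the prescriber variance is zero", {
  pop <- generate_population(sim_config(
    6000, seed = 23, overrides = list(chronic = list(prescriber_sd = 0))))
  b <- build_cohort(pop, need = "chronic")
  covs <- c("drug_group", "mme_category", "days_supply_category")
  off <- fit_chronic_logistic(b$cohort, b$chronic, random_effect = "off",
                              covariates = covs)
  on <- fit_chronic_logistic(b$cohort, b$chronic, random_effect = "on",
                             covariates = covs)
  expect_match(on$method, "glmer")
  expect_lt(on$random_effect_variance, 0.05)
  d <- dplyr::inner_join(
    off$estimates[!off$estimates$reference, c("term", "level", "estimate")],
    on$estimates[!on$estimates$reference, c("term", "level", "estimate")],
    by = c("term", "level"))
  expect_equal(d$estimate.x, d$estimate.y, tolerance = 0.02)
})

test_that("an all-censored sample yields a clean warning and no estimates", {
  pop <- generate_population(sim_config(
    500, seed = 24, overrides = list(overdose = list(base_daily_rate = 0))))
  b <- build_cohort(pop, need = "survival")
  expect_warning(rep <- fit_overdose_cox(b$cohort, b$survival),
                 "no overdose events")
  expect_false(rep$converged)
  expect_true(all(is.na(rep$estimates$estimate[!rep$estimates$reference])))
})

test_that("the frailty subgroup restricts to qualifying prescribers", {
  set.seed(25)
  n <- 600
  pres <- rep(sprintf("D%02d", 1:12), times = c(rep(90, 6), rep(10, 6)))
  cohort <- tibble::tibble(
    patient_id = sprintf("P%04d", 1:n),
    prescriber_id = pres,
    drug_group = factor(sample(c("hydrocodone_SA", "oxycodone_SA"), n, TRUE),
                        levels = cohort_levels_drug()),
    gender = factor(sample(c("M", "F"), n, TRUE), levels = c("M", "F")))
  surv <- tibble::tibble(
    patient_id = cohort$patient_id,
    survival_days = sample(100:1400, n, TRUE),
    event = runif(n) < 0.10)
  rep <- fit_overdose_cox(cohort, surv, frailty = "on",
                          min_patients_per_prescriber = 50,
                          covariates = c("drug_group", "gender"))
  expect_equal(rep$n, 540)  # six prescribers x 90 patients
  expect_match(rep$method, "frailty")
})

test_that("ZINB recovers a zero-inflation probability near zero for plain counts", {
  set.seed(26)
  n <- 3000
  x <- sample(c("hydrocodone_SA", "oxycodone_SA"), n, TRUE)
  y <- rpois(n, exp(1 + 0.2 * (x == "oxycodone_SA")))
  cohort <- tibble::tibble(
    patient_id = as.character(1:n),
    drug_group = factor(x, levels = cohort_levels_drug()))
  secondary <- tibble::tibble(patient_id = cohort$patient_id,
                              cumulative_mme_6mo = y,
                              any_additional_fill = y > 0, switched = NA)
  rep <- fit_cumulative_zinb(cohort, secondary, covariates = "drug_group")
  count <- rep$estimates[rep$estimates$component == "count" &
                           !rep$estimates$reference, ]
  expect_lt(abs(count$estimate - 0.2), 0.1)
  # structural-zero probability at the reference is near zero
  if (!is.null(rep$zero_inflation_ref_prob)) {
    expect_lt(rep$zero_inflation_ref_prob, 0.15)
  }
})

test_that("ZINB flags a degenerate zero portion when there are no zeros", {
  cohort <- tibble::tibble(
    patient_id = as.character(1:500),
    drug_group = factor(sample(c("hydrocodone_SA", "oxycodone_SA"), 500,
                               TRUE), levels = cohort_levels_drug()))
  secondary <- tibble::tibble(patient_id = cohort$patient_id,
                              cumulative_mme_6mo = rpois(500, 50) + 1,
                              any_additional_fill = TRUE, switched = NA)
  rep <- fit_cumulative_zinb(cohort, secondary, covariates = "drug_group")
  expect_match(paste(rep$notes, collapse = " "), "degenerate")
  expect_false("zero" %in% rep$estimates$component)
})

test_that("switching model errors without at-risk patients", {
  cohort <- tibble::tibble(patient_id = "P1",
                           drug_group = factor("hydrocodone_SA"))
  secondary <- tibble::tibble(patient_id = "P1", cumulative_mme_6mo = 0,
                              any_additional_fill = FALSE, switched = NA)
  expect_error(fit_switch_logistic(cohort, secondary), "no at-risk")
})

test_that("the combination subgroup requires at least two formulation levels", {
  pop <- generate_population(sim_config(800, seed = 27))
  b <- build_cohort(pop, need = c("chronic", "survival"))
  one <- b$cohort
  one$subgroup_drug <- factor("hydro_apap_5mg",
                              levels = levels(b$cohort$subgroup_drug))
  expect_error(run_combination_subgroup(one, b$chronic, b$survival),
               "inestimable")
})
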