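# Balance diagnostics and the estimation stages: multilevel logistic models
# for chronic use and switching, Cox models for overdose, and a
# zero-inflated negative binomial model for cumulative 6-month MME.

default_covariates <- c("drug_group", "age_category", "gender",
                        "race_ethnicity", "insurance", "urbanization",
                        "index_year", "mme_category",
                        "days_supply_category")

#' Standardized difference for two proportions
#'
#' Cohen's d effect-size index in its pooled-variance two-proportion form,
#' `|p1 - p2| / sqrt((p1(1-p1) + p2(1-p2)) / 2)`. Returns 0 when both
#' proportions are equal (including the degenerate 0/0 and 1/1 cases).
#'
#' @param p1,p2 Proportions in `[0, 1]` (vectorized).
#' @return Non-negative numeric vector.
#' @export
#' @examples
#' standardized_difference(190687 / 352953, 95801 / 166113)
standardized_difference <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  pooled <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  out <- abs(p1 - p2) / sqrt(pooled)
  out[p1 == p2] <- 0
  out
}

#' Covariate balance table by index drug
#'
#' Counts, within-group percentages, and the absolute standardized
#' difference for every level of every categorical cohort covariate,
#' comparing the hydrocodone and oxycodone index groups.
#'
#' @param cohort Cohort table from [categorize()].
#' @param covariates Covariates to tabulate (default all model covariates
#'   except the exposure).
#' @return Tibble: `covariate`, `level`, `n_hydrocodone`, `pct_hydrocodone`,
#'   `n_oxycodone`, `pct_oxycodone`, `std_diff`.
#' @export
balance_table <- function(cohort,
                          covariates = setdiff(default_covariates,
                                               "drug_group")) {
  g <- cohort$drug_group
  n1 <- sum(g == "hydrocodone_SA")
  n2 <- sum(g == "oxycodone_SA")
  rows <- lapply(covariates, function(v) {
    lv <- levels(factor(cohort[[v]]))
    k1 <- unname(vapply(lv, function(l) {
      sum(cohort[[v]] == l & g == "hydrocodone_SA", na.rm = TRUE)
    }, numeric(1)))
    k2 <- unname(vapply(lv, function(l) {
      sum(cohort[[v]] == l & g == "oxycodone_SA", na.rm = TRUE)
    }, numeric(1)))
    tibble::tibble(
      covariate = v, level = lv,
      n_hydrocodone = k1, pct_hydrocodone = 100 * k1 / n1,
      n_oxycodone = k2, pct_oxycodone = 100 * k2 / n2,
      std_diff = standardized_difference(k1 / n1, k2 / n2))
  })
  dplyr::bind_rows(rows)
}

# ---- model-report plumbing -------------------------------------------------

new_model_report <- function(model, method, n, events, estimates,
                             random_effect_variance = NA_real_,
                             converged = TRUE, notes = character(0)) {
  structure(list(model = model, method = method, n = n, events = events,
                 estimates = estimates,
                 random_effect_variance = random_effect_variance,
                 converged = converged, notes = notes),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> ", x$model, "\n", sep = "")
  cat("  method: ", x$method, "   n = ", x$n, ", events = ", x$events,
      "\n", sep = "")
  if (!is.na(x$random_effect_variance)) {
    cat("  random-effect variance: ",
        format(x$random_effect_variance, digits = 4), "\n", sep = "")
  }
  if (!x$converged) cat("  ** did not converge; estimates withheld **\n")
  for (nt in x$notes) cat("  note: ", nt, "\n", sep = "")
  print(x$estimates, n = 50)
  invisible(x)
}

# Expand a coefficient matrix (est, se, p) into an estimates tibble with
# reference rows for each categorical term.
tidy_estimates <- function(est, se, p, data, covariates,
                           component = NA_character_, se_cap = 10) {
  rows <- list()
  for (v in covariates) {
    lv <- levels(data[[v]])
    lv <- lv[lv %in% unique(as.character(data[[v]]))]
    for (i in seq_along(lv)) {
      nm <- paste0(v, lv[i])
      if (i == 1) {
        rows[[nm]] <- tibble::tibble(
          term = v, level = lv[i], reference = TRUE, estimate = 0,
          se = NA_real_, ratio = 1, ci_low = NA_real_, ci_high = NA_real_,
          p_value = NA_real_)
      } else if (nm %in% names(est)) {
        b <- est[[nm]]; s <- se[[nm]]
        withhold <- is.na(s) || s > se_cap
        rows[[nm]] <- tibble::tibble(
          term = v, level = lv[i], reference = FALSE,
          estimate = ifelse(withhold, NA_real_, b),
          se = ifelse(withhold, NA_real_, s),
          ratio = ifelse(withhold, NA_real_, exp(b)),
          ci_low = ifelse(withhold, NA_real_, exp(b - 1.96 * s)),
          ci_high = ifelse(withhold, NA_real_, exp(b + 1.96 * s)),
          p_value = ifelse(withhold, NA_real_, p[[nm]]))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.na(component)) out$component <- component
  out
}

usable_covariates <- function(data, covariates) {
  keep <- vapply(covariates, function(v) {
    length(unique(as.character(data[[v]][!is.na(data[[v]])]))) >= 2
  }, logical(1))
  covariates[keep]
}

prep_model_frame <- function(data, covariates) {
  for (v in covariates) {
    data[[v]] <- droplevels(factor(data[[v]],
      levels = cohort_levels[[v]] %||% sort(unique(as.character(data[[v]])))))
  }
  data
}

#' Multilevel logistic model for first-year chronic use
#'
#' Fits adjusted odds ratios for chronic use with fixed effects for patient
#' and index-prescription characteristics and, optionally, a random
#' intercept for prescriber (Laplace-approximate maximum likelihood via
#' `lme4::glmer`; the estimation method is recorded in the report). With
#' `include_mme = FALSE` the index-MME category is omitted, reproducing the
#' no-dosage specification.
#'
#' @param cohort Cohort table from [categorize()].
#' @param chronic Chronic-use results from [compute_chronic_use()].
#' @param random_effect `"on"` for a prescriber random intercept, `"off"`
#'   for a single-level fit.
#' @param include_mme Include the MME category covariate.
#' @param covariates Fixed-effect covariates (default: all study
#'   covariates).
#' @param outcome `"primary"` or `"alternative"` chronic-use definition.
#' @return A `model_report`.
#' @export
fit_chronic_logistic <- function(cohort, chronic,
                                 random_effect = c("on", "off"),
                                 include_mme = TRUE,
                                 covariates = default_covariates,
                                 outcome = c("primary", "alternative")) {
  random_effect <- match.arg(random_effect)
  outcome <- match.arg(outcome)
  ycol <- if (outcome == "primary") "chronic_primary" else
    "chronic_alternative"
  data <- dplyr::inner_join(cohort, chronic, by = "patient_id")
  data$.y <- data[[ycol]]
  if (!include_mme) covariates <- setdiff(covariates, "mme_category")
  covariates <- usable_covariates(data, covariates)
  data <- prep_model_frame(data, covariates)
  fit_logistic_report(data, "chronic_use_logistic", covariates,
                      random_effect)
}

fit_logistic_report <- function(data, model_name, covariates,
                                random_effect) {
  rhs <- paste(covariates, collapse = " + ")
  notes <- character(0)
  converged <- TRUE
  re_var <- NA_real_
  if (random_effect == "on") {
    fml <- as.formula(paste(".y ~", rhs, "+ (1 | prescriber_id)"))
    fit <- withCallingHandlers(
      lme4::glmer(fml, data = data, family = binomial(),
                  nAGQ = 1,
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    method <- "glmer Laplace approximation (nAGQ = 1)"
    co <- coef(summary(fit))
    re_var <- as.numeric(lme4::VarCorr(fit)$prescriber_id[1, 1])
    converged <- length(fit@optinfo$conv$lme4$messages) == 0
  } else {
    fml <- as.formula(paste(".y ~", rhs))
    fit <- withCallingHandlers(
      glm(fml, data = data, family = binomial()),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    method <- "glm maximum likelihood (single level)"
    co <- coef(summary(fit))
    converged <- fit$converged
  }
  est <- setNames(co[, 1], rownames(co))
  se <- setNames(co[, 2], rownames(co))
  p <- setNames(co[, 4], rownames(co))
  new_model_report(
    model_name, method, n = nrow(data), events = sum(data$.y),
    estimates = tidy_estimates(est, se, p, data, covariates),
    random_effect_variance = re_var, converged = converged, notes = notes)
}

#' Cox proportional-hazards model for time to opioid overdose
#'
#' Fits adjusted hazard ratios (Efron tie handling). With `frailty = "on"`
#' the sample is restricted to prescribers with at least
#' `min_patients_per_prescriber` cohort patients and a gamma-frailty
#' prescriber random effect is added (`survival::frailty`).
#'
#' @param cohort Cohort table.
#' @param survival_records Output of [compute_survival()].
#' @param frailty `"off"` or `"on"`.
#' @param min_patients_per_prescriber Prescriber panel-size threshold used
#'   when `frailty = "on"` (default 200).
#' @param covariates Adjustment covariates.
#' @param exposure Column giving the exposure factor (default
#'   `"drug_group"`; use `"subgroup_drug"` for the combination-product
#'   analysis).
#' @return A `model_report`.
#' @export
fit_overdose_cox <- function(cohort, survival_records,
                             frailty = c("off", "on"),
                             min_patients_per_prescriber = 200L,
                             covariates = default_covariates,
                             exposure = "drug_group") {
  frailty <- match.arg(frailty)
  data <- dplyr::inner_join(cohort, survival_records, by = "patient_id")
  stopifnot(all(data$survival_days >= 0))
  covariates <- union(exposure, setdiff(covariates, "drug_group"))
  if (exposure != "drug_group") covariates <- setdiff(covariates, "drug_group")
  notes <- character(0)
  if (frailty == "on") {
    sizes <- table(data$prescriber_id)
    keep <- names(sizes)[sizes >= min_patients_per_prescriber]
    data <- data[data$prescriber_id %in% keep, , drop = FALSE]
    notes <- c(notes, sprintf(
      "restricted to %d prescribers with >= %d patients (n = %d)",
      length(keep), min_patients_per_prescriber, nrow(data)))
  }
  covariates <- usable_covariates(data, covariates)
  data <- prep_model_frame(data, covariates)
  if (sum(data$event) == 0) {
    warning("no overdose events; returning empty report")
    return(new_model_report("overdose_cox", "coxph (Efron ties)",
                            n = nrow(data), events = 0L,
                            estimates = tidy_estimates(
                              numeric(0), numeric(0), numeric(0), data,
                              covariates),
                            converged = FALSE,
                            notes = c(notes, "no events")))
  }
  # warn about covariate levels with no events (their HRs are inestimable)
  for (v in covariates) {
    ev <- tapply(data$event, data[[v]], sum)
    if (any(ev == 0, na.rm = TRUE)) {
      warning("no events in level(s) of ", v, ": ",
              paste(names(ev)[which(ev == 0)], collapse = ", "),
              "; estimates withheld")
    }
  }
  rhs <- paste(covariates, collapse = " + ")
  if (frailty == "on") rhs <- paste(rhs, "+ frailty(prescriber_id)")
  fml <- as.formula(paste("survival::Surv(survival_days, event) ~", rhs))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  # frailty rows are appended by coxph; keep named fixed-effect rows only
  est <- setNames(coef(fit), names(coef(fit)))
  se <- sqrt(diag(vcov(fit)))[seq_along(est)]
  names(se) <- names(est)
  z <- est / se
  p <- setNames(2 * pnorm(-abs(z)), names(est))
  method <- if (frailty == "on") {
    "coxph, Efron ties, gamma frailty by prescriber"
  } else "coxph, Efron ties"
  re_var <- NA_real_
  if (frailty == "on" && !is.null(fit$history)) {
    re_var <- tryCatch(fit$history[[1]]$theta, error = function(e) NA_real_)
  }
  new_model_report(
    "overdose_cox", method, n = nrow(data), events = sum(data$event),
    estimates = tidy_estimates(est, se, p, data, covariates),
    random_effect_variance = re_var, converged = TRUE, notes = notes)
}

#' Zero-inflated negative binomial model for cumulative 6-month MME
#'
#' Models the cumulative MME in the six months after the index fill
#' (discretized to 1-MME units): a logistic zero portion for the odds of
#' zero cumulative MME and a negative binomial count portion for the dose
#' among fillers. Fit with `glmmTMB` (nbinom2 + zero-inflation formula);
#' on non-convergence falls back to a plain negative binomial and then to a
#' hurdle fit (binomial zero model + truncated count model), with the stage
#' used recorded in the report.
#'
#' @param cohort Cohort table.
#' @param secondary Output of [compute_secondary()].
#' @param covariates Covariates for both portions.
#' @return A `model_report` whose `estimates` carry a `component` column
#'   (`"count"` rate ratios, `"zero"` odds ratios for zero MME).
#' @export
fit_cumulative_zinb <- function(cohort, secondary,
                                covariates = default_covariates) {
  data <- dplyr::inner_join(cohort, secondary, by = "patient_id")
  data$.y <- as.integer(round(data$cumulative_mme_6mo))
  covariates <- usable_covariates(data, covariates)
  data <- prep_model_frame(data, covariates)
  rhs <- paste(covariates, collapse = " + ")
  notes <- character(0)
  if (!any(data$.y == 0)) {
    notes <- c(notes, "zero portion degenerate: no zero counts; NB fit only")
    fit <- MASS::glm.nb(as.formula(paste(".y ~", rhs)), data = data)
    co <- coef(summary(fit))
    ests <- tidy_estimates(setNames(co[, 1], rownames(co)),
                           setNames(co[, 2], rownames(co)),
                           setNames(co[, 4], rownames(co)),
                           data, covariates, component = "count")
    return(new_model_report("cumulative_mme_zinb",
                            "glm.nb (no zeros; zero portion skipped)",
                            n = nrow(data), events = sum(data$.y > 0),
                            estimates = ests, converged = TRUE,
                            notes = notes))
  }
  fml <- as.formula(paste(".y ~", rhs))
  zfml <- as.formula(paste("~", rhs))
  fit <- tryCatch(
    withCallingHandlers(
      glmmTMB::glmmTMB(fml, ziformula = zfml, family = glmmTMB::nbinom2,
                       data = data),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  ok <- !is.null(fit) && isTRUE(fit$fit$convergence == 0) &&
    !anyNA(suppressWarnings(
      summary(fit)$coefficients$cond[, 2]))
  if (ok) {
    sm <- summary(fit)
    cond <- sm$coefficients$cond
    zi <- sm$coefficients$zi
    ests <- dplyr::bind_rows(
      tidy_estimates(setNames(cond[, 1], rownames(cond)),
                     setNames(cond[, 2], rownames(cond)),
                     setNames(cond[, 4], rownames(cond)),
                     data, covariates, component = "count"),
      tidy_estimates(setNames(zi[, 1], rownames(zi)),
                     setNames(zi[, 2], rownames(zi)),
                     setNames(zi[, 4], rownames(zi)),
                     data, covariates, component = "zero"))
    out <- new_model_report(
      "cumulative_mme_zinb", "glmmTMB zero-inflated nbinom2",
      n = nrow(data), events = sum(data$.y > 0), estimates = ests,
      converged = TRUE, notes = notes)
    out$zero_inflation_ref_prob <- plogis(zi["(Intercept)", 1])
    return(out)
  }
  # staged fallback: hurdle = logistic zero model + NB on positives
  notes <- c(notes, "ZINB did not converge; hurdle fallback used")
  zfit <- glm(as.formula(paste("I(.y == 0) ~", rhs)), data = data,
              family = binomial())
  czero <- coef(summary(zfit))
  pos <- data[data$.y > 0, , drop = FALSE]
  cfit <- MASS::glm.nb(fml, data = pos)
  ccnt <- coef(summary(cfit))
  ests <- dplyr::bind_rows(
    tidy_estimates(setNames(ccnt[, 1], rownames(ccnt)),
                   setNames(ccnt[, 2], rownames(ccnt)),
                   setNames(ccnt[, 4], rownames(ccnt)),
                   pos, covariates, component = "count"),
    tidy_estimates(setNames(czero[, 1], rownames(czero)),
                   setNames(czero[, 2], rownames(czero)),
                   setNames(czero[, 4], rownames(czero)),
                   data, covariates, component = "zero"))
  new_model_report("cumulative_mme_zinb",
                   "hurdle fallback: binomial zero + glm.nb count",
                   n = nrow(data), events = sum(data$.y > 0),
                   estimates = ests, converged = TRUE, notes = notes)
}

#' Logistic model for six-month drug switching
#'
#' Adjusted odds ratios for switching to a different opioid, restricted to
#' patients with at least one additional fill in the six months after index
#' (switching is undefined otherwise).
#'
#' @inheritParams fit_chronic_logistic
#' @param secondary Output of [compute_secondary()].
#' @return A `model_report`.
#' @export
fit_switch_logistic <- function(cohort, secondary,
                                random_effect = c("on", "off"),
                                covariates = default_covariates) {
  random_effect <- match.arg(random_effect)
  data <- dplyr::inner_join(cohort, secondary, by = "patient_id")
  data <- data[!is.na(data$switched) & data$any_additional_fill, ,
               drop = FALSE]
  if (nrow(data) == 0) stop("no at-risk patients (no additional fills)")
  data$.y <- data$switched
  covariates <- usable_covariates(data, covariates)
  data <- prep_model_frame(data, covariates)
  fit_logistic_report(data, "switch_logistic", covariates, random_effect)
}

#' Combination-product subgroup models
#'
#' Restricts the cohort to the 5 mg immediate-release subgroup
#' (hydrocodone-acetaminophen, oxycodone-acetaminophen, oxycodone
#' monotherapy; reference hydrocodone-acetaminophen) and fits the
#' chronic-use logistic model and the overdose Cox model with the 3-level
#' formulation exposure.
#'
#' @param cohort Cohort table.
#' @param chronic Chronic-use results.
#' @param survival_records Survival records.
#' @param include_mme Include the MME category in the chronic-use model.
#' @param random_effect Prescriber random effect for the logistic model.
#' @param covariates Adjustment covariates.
#' @return List with `model_report`s `chronic` and `overdose`.
#' @export
run_combination_subgroup <- function(cohort, chronic, survival_records,
                                     include_mme = TRUE,
                                     random_effect = c("on", "off"),
                                     covariates = default_covariates) {
  random_effect <- match.arg(random_effect)
  sub <- cohort[cohort$subgroup_drug != "other", , drop = FALSE]
  sub$subgroup_drug <- droplevels(factor(
    sub$subgroup_drug, levels = cohort_levels$subgroup_drug))
  if (length(unique(as.character(sub$subgroup_drug))) < 2) {
    stop("subgroup exposure inestimable: all patients in one formulation")
  }
  covs <- union("subgroup_drug", setdiff(covariates, "drug_group"))
  chronic_rep <- fit_chronic_logistic(
    sub, chronic, random_effect = random_effect, include_mme = include_mme,
    covariates = covs)
  chronic_rep$model <- "subgroup_chronic_logistic"
  cox_rep <- fit_overdose_cox(sub, survival_records,
                              covariates = covs, exposure = "subgroup_drug")
  cox_rep$model <- "subgroup_overdose_cox"
  list(chronic = chronic_rep, overdose = cox_rep)
}
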