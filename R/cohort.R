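# Opioid-naive index events, enrollment eligibility, exposure categories.

cohort_levels <- list(
  drug_group = c("hydrocodone_SA", "oxycodone_SA"),
  age_category = c("18-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75+"),
  gender = c("M", "F"),
  race_ethnicity = c("White", "Black", "Hispanic", "Asian-Pacific Islander",
                     "Other", "Unknown"),
  insurance = c("commercial", "medicaid", "medicare", "dual", "unknown"),
  urbanization = c("Noncore", "Large central metro", "Large fringe metro",
                   "Medium metro", "Small metro", "Micropolitan", "Unknown"),
  index_year = c("2015", "2016", "2017"),
  mme_category = c("<=75", "76-100", "101-200", "201-300", ">300"),
  days_supply_category = c("<=3", "4-6", "7+"),
  subgroup_drug = c("hydro_apap_5mg", "oxy_apap_5mg", "oxy_mono_5mg", "other")
)

#' Identify opioid-naive index events
#'
#' An index event is a patient's earliest short-acting hydrocodone or
#' oxycodone fill inside the index window such that the 365 days strictly
#' before it (`[index_date - 365, index_date)`) contain no opioid fill of any
#' type and no opioid-related ED/inpatient encounter. At most one index
#' event is returned per patient.
#'
#' @param fills Cleaned prescription fills.
#' @param claims Encounter claims (`diagnosis_codes` as ";"-separated ICD-10
#'   strings); used to detect opioid-related encounters in the lookback.
#' @param code_set Code set whose `nonfatal_dx_prefixes` define an
#'   opioid-related encounter; default [default_code_set()].
#' @param window Length-2 index window (dates), default 2015-01-01 to
#'   2017-12-31 inclusive.
#' @param lookback_days Naive lookback length in days (365).
#' @return Tibble of index events: `patient_id`, `index_date`,
#'   `prescriber_id`, `drug_base`, `combination_ingredient`,
#'   `strength_per_unit`, `quantity`, `days_supply`, `drug_group`,
#'   `subgroup_drug`, `index_year`.
#' @export
find_index_events <- function(fills, claims, code_set = default_code_set(),
                              window = as.Date(c("2015-01-01", "2017-12-31")),
                              lookback_days = 365L) {
  window <- as.Date(window)
  empty <- tibble::tibble(
    patient_id = character(0), index_date = as.Date(character(0)),
    prescriber_id = character(0), drug_base = character(0),
    combination_ingredient = character(0), strength_per_unit = numeric(0),
    quantity = numeric(0), days_supply = numeric(0), drug_group = character(0),
    subgroup_drug = character(0), index_year = integer(0))
  if (nrow(fills) == 0) return(empty)

  fl <- data.table::as.data.table(fills)
  fl[, fill_date := as.integer(as.Date(fill_date))]
  window_i <- as.integer(window)
  cand <- fl[drug_base %in% c("hydrocodone", "oxycodone") & !long_acting &
               fill_date >= window_i[1] & fill_date <= window_i[2]]
  if (nrow(cand) == 0) return(empty)
  data.table::setorder(cand, patient_id, fill_date)

  all_fills <- fl[, .(patient_id, fill_date)]
  data.table::setkey(all_fills, patient_id, fill_date)

  opioid_claims <- NULL
  if (!is.null(claims) && nrow(claims) > 0) {
    cl <- data.table::as.data.table(claims)
    hit <- any_prefix_match_list(split_codes(cl$diagnosis_codes),
                                 code_set$nonfatal_dx_prefixes)
    opioid_claims <- cl[hit, .(patient_id,
                               service_date = as.integer(
                                 as.Date(service_date)))]
    data.table::setkey(opioid_claims, patient_id, service_date)
  }

  # Try each patient's earliest remaining candidate; on lookback failure,
  # drop that candidate and retry with the next. Few rounds in practice.
  chosen <- NULL
  while (nrow(cand) > 0) {
    top <- cand[cand[, .I[1], by = patient_id]$V1]
    probe <- top[, .(patient_id, idx_date = fill_date,
                     lookback_start = fill_date - lookback_days)]
    prior_fill <- all_fills[probe,
      on = .(patient_id, fill_date >= lookback_start, fill_date < idx_date),
      .N, by = .EACHI]$N > 0
    prior_claim <- rep(FALSE, nrow(top))
    if (!is.null(opioid_claims) && nrow(opioid_claims) > 0) {
      prior_claim <- opioid_claims[probe,
        on = .(patient_id, service_date >= lookback_start,
               service_date < idx_date),
        .N, by = .EACHI]$N > 0
    }
    ok <- !(prior_fill | prior_claim)
    chosen <- rbind(chosen, top[ok])
    failed <- top[!ok, .(patient_id, fill_date)]
    if (nrow(failed) == 0) break
    cand <- cand[!failed, on = .(patient_id, fill_date)]
    cand <- cand[!chosen[, .(patient_id)], on = "patient_id"]
  }
  if (is.null(chosen) || nrow(chosen) == 0) return(empty)

  out <- tibble::as_tibble(chosen) %>%
    dplyr::rename(index_date = "fill_date") %>%
    dplyr::mutate(
      index_date = as.Date(.data$index_date, origin = "1970-01-01"),
      drug_group = ifelse(.data$drug_base == "hydrocodone",
                          "hydrocodone_SA", "oxycodone_SA"),
      index_year = as.integer(format(.data$index_date, "%Y"))) %>%
    dplyr::select(dplyr::all_of(setdiff(names(empty), "subgroup_drug")))
  out$subgroup_drug <- recode_combination_subgroup(out)
  out %>% dplyr::select(dplyr::all_of(names(empty))) %>%
    dplyr::arrange(.data$patient_id)
}

#' Label the 5 mg combination-product subgroup
#'
#' Assigns each index event to `hydro_apap_5mg`, `oxy_apap_5mg`, or
#' `oxy_mono_5mg` when the index fill is an immediate-release 5 mg tablet of
#' the corresponding formulation, and `"other"` otherwise (other strengths,
#' ibuprofen combinations, hydrocodone monotherapy).
#'
#' @param index_events Tibble of index events.
#' @return Character vector of subgroup labels, one per row.
#' @export
recode_combination_subgroup <- function(index_events) {
  with(index_events, dplyr::case_when(
    strength_per_unit == 5 & drug_base == "hydrocodone" &
      combination_ingredient == "acetaminophen" ~ "hydro_apap_5mg",
    strength_per_unit == 5 & drug_base == "oxycodone" &
      combination_ingredient == "acetaminophen" ~ "oxy_apap_5mg",
    strength_per_unit == 5 & drug_base == "oxycodone" &
      combination_ingredient == "none" ~ "oxy_mono_5mg",
    TRUE ~ "other"))
}

#' Apply the continuous-enrollment filter
#'
#' A patient is kept when, within the index calendar year, every uncovered
#' gap (leading, between spans, trailing) is shorter than `max_gap_days`.
#' For patients who died in the index year the continuity requirement is
#' evaluated only up to the death date, so decedents who were continuously
#' enrolled while alive are not excluded.
#'
#' @param index_events Index events from [find_index_events()].
#' @param spans Enrollment spans (`start_date`, `end_date` half-open).
#' @param deaths Death records (may be empty).
#' @param max_gap_days Maximum tolerated gap; gaps must be strictly shorter
#'   (default 90, i.e. "gaps less than 90 days allowed").
#' @return List with `kept` (index events) and `excluded`
#'   (`patient_id`, `reason` in `no_enrollment` / `enrollment_gap`).
#' @export
apply_enrollment_filter <- function(index_events, spans, deaths,
                                    max_gap_days = 90) {
  if (nrow(index_events) == 0) {
    return(list(kept = index_events,
                excluded = tibble::tibble(patient_id = character(0),
                                          reason = character(0))))
  }
  ie <- data.table::as.data.table(
    index_events[, c("patient_id", "index_date")])
  ie[, `:=`(period_start = as.Date(paste0(format(index_date, "%Y"), "-01-01")),
            period_end = as.Date(paste0(
              as.integer(format(index_date, "%Y")) + 1L, "-01-01")))]
  if (!is.null(deaths) && nrow(deaths) > 0) {
    dd <- data.table::as.data.table(deaths[, c("patient_id", "death_date")])
    ie <- dd[ie, on = "patient_id"]
    died_in_year <- !is.na(ie$death_date) & ie$death_date < ie$period_end &
      ie$death_date >= ie$period_start
    ie[died_in_year, period_end := death_date]
  }
  has_span <- unique(spans$patient_id)
  gaps <- max_uncovered_gap(
    spans, ie[, .(patient_id, period_id = patient_id,
                  period_start, period_end)])
  res <- merge(ie[, .(patient_id, period_start, period_end)], gaps,
               by.x = "patient_id", by.y = "period_id", all.x = TRUE)
  res[is.na(max_gap), max_gap := as.numeric(period_end - period_start)]
  res[, keep := max_gap < max_gap_days]
  keep_ids <- res$patient_id[res$keep]
  excl <- res[!(keep)]
  excl[, reason := ifelse(patient_id %in% has_span, "enrollment_gap",
                          "no_enrollment")]
  list(kept = index_events[index_events$patient_id %in% keep_ids, ,
                           drop = FALSE],
       excluded = tibble::as_tibble(excl[, .(patient_id, reason)]))
}

#' Total MME of a prescription fill
#'
#' `strength_per_unit x quantity x conversion factor`, using the per-drug
#' MME-per-mg factors in `mme_table`.
#'
#' @param fill Tibble (one or more rows) with `drug_base`,
#'   `strength_per_unit`, `quantity`.
#' @param mme_table Conversion table, default [default_mme_table()].
#' @return Numeric vector of total MME per row.
#' @export
#' @examples
#' compute_index_mme(tibble::tibble(drug_base = "oxycodone",
#'                                  strength_per_unit = 5, quantity = 40))
compute_index_mme <- function(fill, mme_table = default_mme_table()) {
  idx <- match(fill$drug_base, mme_table$drug_base)
  if (anyNA(idx)) {
    stop("no MME conversion factor for drug: ",
         paste(unique(fill$drug_base[is.na(idx)]), collapse = ", "))
  }
  fill$strength_per_unit * fill$quantity * mme_table$mme_factor[idx]
}

bin_mme <- function(mme, breakpoints = c(75, 100, 200, 300)) {
  labs <- cohort_levels$mme_category
  cut(mme, breaks = c(-Inf, breakpoints, Inf), labels = labs, right = TRUE)
}

bin_days_supply <- function(ds) {
  cut(ds, breaks = c(-Inf, 3, 6, Inf),
      labels = cohort_levels$days_supply_category, right = TRUE)
}

bin_age <- function(age) {
  cut(age, breaks = c(-Inf, 24, 34, 44, 54, 64, 74, Inf),
      labels = cohort_levels$age_category, right = TRUE)
}

# Insurance plan held at least `min_days` days of the index calendar year;
# "unknown" when no plan reaches the threshold.
derive_insurance <- function(index_events, spans, min_days = 183) {
  out <- rep("unknown", nrow(index_events))
  if (is.null(spans) || nrow(spans) == 0) return(out)
  ie <- data.table::as.data.table(index_events[, c("patient_id", "index_date")])
  ie[, `:=`(period_start = as.Date(paste0(format(index_date, "%Y"), "-01-01")),
            period_end = as.Date(paste0(
              as.integer(format(index_date, "%Y")) + 1L, "-01-01")))]
  sp <- data.table::as.data.table(spans)
  sp <- sp[ie, on = "patient_id", nomatch = NULL, allow.cartesian = TRUE]
  sp[, `:=`(ov = pmax(0, as.numeric(pmin(end_date, period_end) -
                                      pmax(start_date, period_start))))]
  days <- sp[ov > 0, .(days = sum(ov)), by = .(patient_id, plan)]
  days <- days[days >= min_days]
  data.table::setorder(days, patient_id, -days)
  best <- days[, .SD[1], by = patient_id]
  idx <- match(index_events$patient_id, best$patient_id)
  out[!is.na(idx)] <- best$plan[idx[!is.na(idx)]]
  out
}

#' Build the analysis cohort table
#'
#' Joins demographics onto index events and derives every model covariate:
#' age category (7 levels), index-year insurance plan (held >= 183 days of
#' the index calendar year, else "unknown"), index MME and its 5-level
#' category, and the days'-supply category. Categorical covariates are
#' returned as factors with the study reference levels first (hydrocodone
#' SA, age 18-24, male, White, commercial, noncore, 2015, MME <=75,
#' <=3 days).
#'
#' @param index_events Index events (after enrollment filtering).
#' @param demographics One demographics row per index patient.
#' @param spans Enrollment spans, used to derive the insurance covariate.
#' @param mme_table MME conversion table.
#' @param mme_breakpoints Upper bin edges for the MME categories (right
#'   closed), default `c(75, 100, 200, 300)` -- the source study's sample
#'   25/50/75/90th percentiles, frozen for cross-run comparability. Set
#'   `mme_percentile_mode = TRUE` to recompute them from the data at those
#'   percentiles instead.
#' @param mme_percentile_mode Recompute breakpoints from the data.
#' @param insurance_min_days Days of coverage needed to assign a plan (183).
#' @return A cohort tibble, one row per patient.
#' @export
categorize <- function(index_events, demographics, spans,
                       mme_table = default_mme_table(),
                       mme_breakpoints = c(75, 100, 200, 300),
                       mme_percentile_mode = FALSE,
                       insurance_min_days = 183) {
  cohort <- index_events %>%
    dplyr::left_join(demographics, by = "patient_id") %>%
    dplyr::mutate(index_mme = compute_index_mme(index_events, mme_table))
  if (mme_percentile_mode && nrow(cohort) > 0) {
    mme_breakpoints <- unname(
      quantile(cohort$index_mme, c(0.25, 0.5, 0.75, 0.9)))
  }
  cohort <- cohort %>%
    dplyr::mutate(
      age_category = bin_age(.data$age_years),
      mme_category = bin_mme(.data$index_mme, mme_breakpoints),
      days_supply_category = bin_days_supply(.data$days_supply),
      insurance = derive_insurance(index_events, spans,
                                   min_days = insurance_min_days),
      index_year = as.character(.data$index_year))
  for (v in names(cohort_levels)) {
    if (v %in% names(cohort)) {
      cohort[[v]] <- factor(as.character(cohort[[v]]),
                            levels = cohort_levels[[v]])
    }
  }
  cohort %>%
    dplyr::select(dplyr::all_of(c(
      "patient_id", "index_date", "prescriber_id", "drug_group",
      "subgroup_drug", "age_category", "gender", "race_ethnicity",
      "insurance", "urbanization", "index_year", "index_mme", "mme_category",
      "days_supply_category")))
}
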