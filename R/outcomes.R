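# First-year chronic use, overdose events, survival construction, and
# 6-month secondary outcomes.

# In-window opioid fills per index patient: [index_date, index_date + 365).
# Dates are carried as integers for speed.
window_fills <- function(fills, index_events, window_days = 365L) {
  fl <- data.table::data.table(
    patient_id = fills$patient_id,
    fill_date = as.integer(as.Date(fills$fill_date)),
    days_supply = fills$days_supply)
  ie <- data.table::data.table(
    patient_id = index_events$patient_id,
    index_date = as.integer(as.Date(index_events$index_date)))
  fl <- fl[ie, on = "patient_id", nomatch = NULL]
  fl <- fl[fill_date >= index_date & fill_date < index_date + window_days]
  data.table::setorder(fl, patient_id, fill_date)
  fl
}

#' Classify first-year chronic opioid use (primary definition)
#'
#' Over the 365-day window starting at the index fill, a patient is a
#' chronic user when (a) they filled at least six opioid prescriptions of
#' any type including the index, and (b) the average uncovered period
#' between refills was at most 30 days. The uncovered period for each gap
#' is `max(0, next fill date - (fill date + days' supply))` (early refills
#' clip to zero; no stockpiling carryover), the terminal gap substitutes
#' day 365 for the next fill date, and the average divides total uncovered
#' days by the number of inter-fill gaps plus one.
#'
#' @param fills All opioid fills (cleaned); must contain each patient's
#'   index fill.
#' @param index_events Index events.
#' @param window_days Follow-up window (365).
#' @param min_fills,max_avg_uncovered Chronic-use thresholds (6 fills,
#'   30 days).
#' @return Tibble: `patient_id`, `n_fills_365`, `total_uncovered_days`,
#'   `n_gaps`, `avg_uncovered`, `chronic_primary`.
#' @export
classify_chronic_primary <- function(fills, index_events, window_days = 365L,
                                     min_fills = 6L, max_avg_uncovered = 30) {
  fl <- window_fills(fills, index_events, window_days)
  miss <- setdiff(index_events$patient_id, unique(fl$patient_id))
  if (length(miss) > 0) {
    stop("index fill missing from `fills` for patient(s): ",
         paste(head(miss, 3), collapse = ", "))
  }
  fl[, nxt := data.table::shift(fill_date, type = "lead"), by = patient_id]
  fl[, uncovered := pmax(0, data.table::fifelse(
    is.na(nxt), index_date + window_days, nxt) -
      (fill_date + days_supply))]
  res <- fl[, .(n_fills_365 = .N, total_uncovered_days = sum(uncovered),
                n_gaps = .N - 1L), by = patient_id]
  res[, avg_uncovered := total_uncovered_days / (n_gaps + 1L)]
  res[, chronic_primary := n_fills_365 >= min_fills &
        avg_uncovered <= max_avg_uncovered]
  tibble::as_tibble(res)
}

#' Classify first-year chronic opioid use (alternative definition)
#'
#' The episode runs from the index date to the last opioid fill date within
#' the 365-day window. Chronic use under this definition requires an episode
#' longer than 90 days together with either a total days' supply of at least
#' 120 or at least 10 fills.
#'
#' @inheritParams classify_chronic_primary
#' @param min_episode_days,min_total_supply,min_fills_alt Thresholds
#'   (90 days, 120 days' supply, 10 fills).
#' @return Tibble: `patient_id`, `episode_length_days`, `total_days_supply`,
#'   `n_fills_365`, `chronic_alternative`.
#' @export
classify_chronic_alternative <- function(fills, index_events,
                                         window_days = 365L,
                                         min_episode_days = 90,
                                         min_total_supply = 120,
                                         min_fills_alt = 10L) {
  fl <- window_fills(fills, index_events, window_days)
  res <- fl[, .(
    episode_length_days = as.integer(max(fill_date) - min(index_date)),
    total_days_supply = sum(days_supply),
    n_fills_365 = .N), by = patient_id]
  res[, chronic_alternative := episode_length_days > min_episode_days &
        (total_days_supply >= min_total_supply | n_fills_365 >= min_fills_alt)]
  tibble::as_tibble(res)
}

#' Combined chronic-use accounting
#'
#' Runs both chronic-use classifiers and returns the full uncovered-days
#' accounting per patient. With `exclude_deceased = TRUE`, patients who died
#' within the follow-up window are dropped (sensitivity variant).
#'
#' @inheritParams classify_chronic_primary
#' @param deaths Death records (used only for `exclude_deceased`).
#' @param exclude_deceased Drop patients who died within `window_days` of
#'   index.
#' @return Tibble with both flags plus the accounting fields.
#' @export
compute_chronic_use <- function(fills, index_events, deaths = NULL,
                                window_days = 365L,
                                exclude_deceased = FALSE) {
  if (exclude_deceased && !is.null(deaths) && nrow(deaths) > 0) {
    d <- index_events %>%
      dplyr::left_join(deaths[, c("patient_id", "death_date")],
                       by = "patient_id") %>%
      dplyr::filter(is.na(.data$death_date) |
                      .data$death_date >= .data$index_date + window_days)
    index_events <- index_events[index_events$patient_id %in% d$patient_id, ]
  }
  prim <- classify_chronic_primary(fills, index_events, window_days)
  alt <- classify_chronic_alternative(fills, index_events, window_days)
  dplyr::left_join(prim,
                   alt[, c("patient_id", "episode_length_days",
                           "total_days_supply", "chronic_alternative")],
                   by = "patient_id")
}

#' Concordance between the two chronic-use definitions
#'
#' @param results Output of [compute_chronic_use()].
#' @return List with `pct_alt_also_primary` and `pct_primary_also_alt`
#'   (0-100 scale; `NA` when the respective denominator is empty).
#' @export
definition_overlap <- function(results) {
  alt <- results$chronic_alternative
  prim <- results$chronic_primary
  list(
    pct_alt_also_primary = if (any(alt)) 100 * mean(prim[alt]) else NA_real_,
    pct_primary_also_alt = if (any(prim)) 100 * mean(alt[prim]) else NA_real_)
}

#' Detect fatal and non-fatal opioid overdoses
#'
#' A fatal overdose is a death record whose underlying cause is in the
#' poisoning cause set and at least one multiple-cause code matches an
#' opioid T-code prefix, or whose literal text contains any configured term
#' (case-insensitive substring). A non-fatal overdose is an ED/inpatient
#' claim with any diagnosis matching the non-fatal prefix set. The earliest
#' event on or after the index date is returned per patient; when a fatal
#' and a non-fatal signal share that date, the fatal event wins.
#'
#' @param claims Encounter claims.
#' @param deaths Death records.
#' @param index_events Index events (defines `index_date` per patient).
#' @param code_set Overdose code set, default [default_code_set()].
#' @return Tibble: `patient_id`, `event_date`, `fatal`, `source`
#'   (`death_codes`, `death_literal`, `ED_claim`, `inpatient_claim`);
#'   patients with no event are absent.
#' @export
detect_overdose <- function(claims, deaths, index_events,
                            code_set = default_code_set()) {
  events <- list()
  if (!is.null(deaths) && nrow(deaths) > 0) {
    und <- normalize_icd(deaths$underlying_cause)
    code_hit <- any_prefix_match_list(
      lapply(und, identity), code_set$underlying_cause_codes) &
      any_prefix_match_list(split_codes(deaths$multiple_causes),
                            code_set$t_codes)
    lit <- tolower(ifelse(is.na(deaths$literal_text), "",
                          deaths$literal_text))
    lit_hit <- Reduce(`|`, lapply(code_set$literal_terms,
                                  function(tm) grepl(tm, lit, fixed = TRUE)),
                      init = rep(FALSE, nrow(deaths)))
    is_fatal <- code_hit | lit_hit
    if (any(is_fatal)) {
      src <- ifelse(code_hit[is_fatal], "death_codes", "death_literal")
      events$fatal <- tibble::tibble(
        patient_id = deaths$patient_id[is_fatal],
        event_date = as.Date(deaths$death_date[is_fatal]),
        fatal = TRUE,
        source = src)
    }
  }
  if (!is.null(claims) && nrow(claims) > 0) {
    hit <- any_prefix_match_list(split_codes(claims$diagnosis_codes),
                                 code_set$nonfatal_dx_prefixes)
    if (any(hit)) {
      events$nonfatal <- tibble::tibble(
        patient_id = claims$patient_id[hit],
        event_date = as.Date(claims$service_date[hit]),
        fatal = FALSE,
        source = ifelse(claims$setting[hit] == "inpatient",
                        "inpatient_claim", "ED_claim"))
    }
  }
  empty <- tibble::tibble(patient_id = character(0),
                          event_date = as.Date(character(0)),
                          fatal = logical(0), source = character(0))
  ev <- dplyr::bind_rows(events)
  if (nrow(ev) == 0) return(empty)
  ev <- ev %>%
    dplyr::inner_join(index_events[, c("patient_id", "index_date")],
                      by = "patient_id") %>%
    dplyr::filter(.data$event_date >= .data$index_date) %>%
    dplyr::arrange(.data$patient_id, .data$event_date,
                   dplyr::desc(.data$fatal)) %>%
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) %>%
    dplyr::select(-"index_date")
  ev
}

# Calendar years whose continuous-enrollment check fails, per patient,
# considering only years strictly after the index year and truncating the
# checked period at the death date. Returns earliest censor date
# (Dec 31 of the year preceding the first failing year) per patient, NA if
# none fails through `study_end`.
enrollment_censor_date <- function(index_events, spans, deaths,
                                   study_end, max_gap_days = 90) {
  ie <- data.table::as.data.table(index_events[, c("patient_id", "index_date")])
  ie[, index_year := as.integer(format(index_date, "%Y"))]
  end_year <- as.integer(format(study_end, "%Y"))
  ie <- ie[index_year < end_year]
  grid <- ie[, .(year = seq.int(index_year + 1L, end_year)),
             by = .(patient_id, index_year)]
  if (nrow(grid) == 0) {
    return(tibble::tibble(patient_id = character(0),
                          censor_date = as.Date(character(0))))
  }
  grid[, `:=`(period_start = as.Date(paste0(year, "-01-01")),
              period_end = pmin(as.Date(paste0(year + 1L, "-01-01")),
                                study_end + 1L))]
  if (!is.null(deaths) && nrow(deaths) > 0) {
    dd <- data.table::as.data.table(deaths[, c("patient_id", "death_date")])
    grid <- dd[grid, on = "patient_id"]
    grid <- grid[is.na(death_date) | death_date > period_start]
    grid[!is.na(death_date), period_end := pmin(period_end, death_date)]
  }
  grid[, pkey := paste(patient_id, year)]
  gaps <- max_uncovered_gap(
    spans, grid[, .(patient_id, period_id = pkey, period_start, period_end)])
  grid <- merge(grid, gaps, by.x = "pkey", by.y = "period_id", all.x = TRUE)
  grid[is.na(max_gap), max_gap := as.numeric(period_end - period_start)]
  fails <- grid[max_gap >= max_gap_days]
  if (nrow(fails) == 0) {
    return(tibble::tibble(patient_id = character(0),
                          censor_date = as.Date(character(0))))
  }
  first_fail <- fails[, .(year = min(year)), by = patient_id]
  tibble::tibble(
    patient_id = first_fail$patient_id,
    censor_date = as.Date(paste0(first_fail$year - 1L, "-12-31")))
}

#' Construct time-to-overdose survival records
#'
#' Survival days run from the index date to the earliest of: the first
#' fatal/non-fatal opioid overdose (the event), loss of continuous
#' enrollment in a post-index calendar year (censored at December 31 of the
#' preceding year, per year-level enrollment determination), death from a
#' non-opioid cause, or the study end. Enrollment continuity uses the same
#' strictly-less-than-90-day gap rule as cohort entry, evaluated within each
#' calendar year and truncated at death.
#'
#' @param index_events Index events.
#' @param spans Enrollment spans.
#' @param overdose_events Output of [detect_overdose()].
#' @param deaths Death records.
#' @param study_end Study end date (default 2018-12-31).
#' @param max_gap_days Enrollment gap tolerance (90).
#' @return Tibble: `patient_id`, `survival_days`, `event`, `censor_reason`
#'   (`none` for events, else `enrollment_loss`, `non_opioid_death`,
#'   `study_end`).
#' @export
compute_survival <- function(index_events, spans, overdose_events, deaths,
                             study_end = as.Date("2018-12-31"),
                             max_gap_days = 90) {
  study_end <- as.Date(study_end)
  out <- tibble::tibble(patient_id = index_events$patient_id,
                        index_date = index_events$index_date)
  # censor candidates
  out$end_study <- study_end
  enr <- enrollment_censor_date(index_events, spans, deaths, study_end,
                                max_gap_days)
  out <- dplyr::left_join(out, enr, by = "patient_id")
  if (!is.null(deaths) && nrow(deaths) > 0) {
    dd <- deaths[, c("patient_id", "death_date")]
    out <- dplyr::left_join(out, dd, by = "patient_id")
  } else {
    out$death_date <- as.Date(NA)
  }
  ov <- overdose_events[, c("patient_id", "event_date", "fatal")]
  out <- dplyr::left_join(out, ov, by = "patient_id")
  # a fatal overdose death is not a non-opioid death
  out$death_date[!is.na(out$fatal) & out$fatal &
                   !is.na(out$death_date) &
                   out$death_date == out$event_date] <- as.Date(NA)

  cand <- cbind(
    enrollment_loss = as.integer(out$censor_date),
    non_opioid_death = as.integer(out$death_date),
    study_end = as.integer(out$end_study))
  censor_at <- apply(cand, 1, min, na.rm = TRUE)
  censor_why <- colnames(cand)[apply(
    cand, 1, function(z) which.min(replace(z, is.na(z), Inf)))]
  event <- !is.na(out$event_date) &
    as.integer(out$event_date) <= censor_at
  end_at <- ifelse(event, as.integer(out$event_date), censor_at)
  survival_days <- end_at - as.integer(out$index_date)
  if (any(survival_days < 0)) {
    stop("negative survival interval for patient(s): ",
         paste(head(out$patient_id[survival_days < 0], 3), collapse = ", "))
  }
  tibble::tibble(
    patient_id = out$patient_id,
    survival_days = as.integer(survival_days),
    event = event,
    censor_reason = ifelse(event, "none", censor_why))
}

#' Cumulative MME in the six months after the index fill
#'
#' Sums per-fill MME over all opioid fills in the half-open window
#' `(index_date, index_date + 183)`, excluding the index fill (and any other
#' same-day fill).
#'
#' @param fills All opioid fills.
#' @param index_events Index events.
#' @param mme_table MME conversion table.
#' @param window_days Window length (183 days = 6 months).
#' @return Tibble: `patient_id`, `cumulative_mme_6mo`, `any_additional_fill`.
#' @export
cumulative_mme_6mo <- function(fills, index_events,
                               mme_table = default_mme_table(),
                               window_days = 183L) {
  fl <- data.table::as.data.table(
    fills[, c("patient_id", "fill_date", "drug_base", "strength_per_unit",
              "quantity")])
  ie <- data.table::as.data.table(index_events[, c("patient_id", "index_date")])
  fl <- fl[ie, on = "patient_id", nomatch = NULL]
  fl <- fl[fill_date > index_date & fill_date < index_date + window_days]
  fl[, mme := compute_index_mme(fl, mme_table)]
  agg <- fl[, .(cumulative_mme_6mo = sum(mme)), by = patient_id]
  out <- tibble::tibble(patient_id = index_events$patient_id)
  out <- dplyr::left_join(out, tibble::as_tibble(agg), by = "patient_id")
  out$cumulative_mme_6mo[is.na(out$cumulative_mme_6mo)] <- 0
  out$any_additional_fill <- out$cumulative_mme_6mo > 0
  out
}

#' Six-month drug-switching flag
#'
#' `TRUE` when any fill in the half-open window `(index_date, index_date +
#' 183)` has a base ingredient different from the index drug, `FALSE` when
#' all in-window fills share it, and `NA` (not applicable) when there is no
#' additional fill.
#'
#' @inheritParams cumulative_mme_6mo
#' @return Tibble: `patient_id`, `switched`.
#' @export
switch_flag <- function(fills, index_events, window_days = 183L) {
  fl <- data.table::as.data.table(
    fills[, c("patient_id", "fill_date", "drug_base")])
  ie <- data.table::as.data.table(
    index_events[, c("patient_id", "index_date", "drug_base")])
  data.table::setnames(ie, "drug_base", "index_drug")
  fl <- fl[ie, on = "patient_id", nomatch = NULL]
  fl <- fl[fill_date > index_date & fill_date < index_date + window_days]
  agg <- fl[, .(switched = any(drug_base != index_drug)), by = patient_id]
  out <- tibble::tibble(patient_id = index_events$patient_id)
  dplyr::left_join(out, tibble::as_tibble(agg), by = "patient_id")
}

#' Secondary outcomes table
#'
#' @inheritParams cumulative_mme_6mo
#' @return Tibble: `patient_id`, `cumulative_mme_6mo`,
#'   `any_additional_fill`, `switched`.
#' @export
compute_secondary <- function(fills, index_events,
                              mme_table = default_mme_table(),
                              window_days = 183L) {
  dplyr::left_join(
    cumulative_mme_6mo(fills, index_events, mme_table, window_days),
    switch_flag(fills, index_events, window_days),
    by = "patient_id")
}
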