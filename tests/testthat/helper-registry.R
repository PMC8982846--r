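# Builders for small typed fixtures used across test files.

mk_fill <- function(patient_id = "P1", prescriber_id = "D1",
                    fill_date = "2016-01-01", drug_base = "hydrocodone",
                    combination_ingredient = "acetaminophen",
                    strength_per_unit = 5, quantity = 30, days_supply = 5,
                    long_acting = FALSE) {
  tibble::tibble(patient_id = patient_id, prescriber_id = prescriber_id,
                 fill_date = as.Date(fill_date), drug_base = drug_base,
                 combination_ingredient = combination_ingredient,
                 strength_per_unit = strength_per_unit, quantity = quantity,
                 days_supply = days_supply, long_acting = long_acting)
}

mk_span <- function(patient_id = "P1", start_date = "2016-01-01",
                    end_date = "2017-01-01", plan = "commercial") {
  tibble::tibble(patient_id = patient_id, start_date = as.Date(start_date),
                 end_date = as.Date(end_date), plan = plan)
}

mk_claim <- function(patient_id = "P1", service_date = "2016-06-01",
                     setting = "ED", diagnosis_codes = "T402X1A") {
  tibble::tibble(patient_id = patient_id,
                 service_date = as.Date(service_date), setting = setting,
                 diagnosis_codes = diagnosis_codes)
}

mk_death <- function(patient_id = "P1", death_date = "2016-06-01",
                     underlying_cause = "I251", multiple_causes = "I500",
                     literal_text = "heart disease") {
  tibble::tibble(patient_id = patient_id, death_date = as.Date(death_date),
                 underlying_cause = underlying_cause,
                 multiple_causes = multiple_causes,
                 literal_text = literal_text)
}

mk_demo <- function(patient_id = "P1", age_years = 40, gender = "M",
                    race_ethnicity = "White", urbanization = "Noncore") {
  tibble::tibble(patient_id = patient_id, age_years = age_years,
                 gender = gender, race_ethnicity = race_ethnicity,
                 urbanization = urbanization)
}

mk_index <- function(patient_id = "P1", index_date = "2016-01-01",
                     drug_base = "hydrocodone", days_supply = 5,
                     strength_per_unit = 5, quantity = 30,
                     combination_ingredient = "acetaminophen",
                     prescriber_id = "D1") {
  tibble::tibble(patient_id = patient_id, index_date = as.Date(index_date),
                 prescriber_id = prescriber_id, drug_base = drug_base,
                 combination_ingredient = combination_ingredient,
                 strength_per_unit = strength_per_unit, quantity = quantity,
                 days_supply = days_supply,
                 drug_group = ifelse(drug_base == "hydrocodone",
                                     "hydrocodone_SA", "oxycodone_SA"),
                 subgroup_drug = "other",
                 index_year = as.integer(format(as.Date(index_date), "%Y")))
}

cohort_levels_drug <- function() c("hydrocodone_SA", "oxycodone_SA")

# Independent day-by-day coverage oracle for the chronic-use classifier:
# coverage from each fill runs until the earliest of fill date + supply,
# the next fill date (per-fill restart, no stockpiling carryover), or the
# window end. Returns total uncovered days in [0, window).
oracle_uncovered <- function(offsets, supplies, window = 365) {
  covered <- logical(window)
  k <- length(offsets)
  for (i in seq_len(k)) {
    start <- offsets[i]
    stop_at <- min(start + supplies[i],
                   if (i < k) offsets[i + 1] else window,
                   window)
    if (stop_at > start) covered[(start + 1):stop_at] <- TRUE
  }
  window - sum(covered)
}

# Run the cohort-construction stages on a generated population, returning
# the pieces the model tests need.
build_cohort <- function(pop, need = c("chronic", "survival", "secondary")) {
  cl <- clean_fills(pop$fills)
  idx <- find_index_events(cl$fills, pop$claims)
  flt <- apply_enrollment_filter(idx, pop$spans, pop$deaths)
  out <- list(pop = pop, fills = cl$fills, index = flt$kept,
              cohort = categorize(flt$kept, pop$demographics, pop$spans))
  if ("chronic" %in% need) {
    out$chronic <- compute_chronic_use(cl$fills, flt$kept)
  }
  if ("survival" %in% need) {
    out$overdose <- detect_overdose(pop$claims, pop$deaths, flt$kept)
    out$survival <- compute_survival(flt$kept, pop$spans, out$overdose,
                                     pop$deaths)
  }
  if ("secondary" %in% need) {
    out$secondary <- compute_secondary(cl$fills, flt$kept)
  }
  out
}
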