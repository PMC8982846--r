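test_that("first-ever short-acting fill in window becomes the index event", {
  fills <- mk_fill(drug_base = "oxycodone", combination_ingredient = "none",
                   fill_date = "2016-03-01")
  idx <- find_index_events(fills, mk_claim()[0, ])
  expect_equal(nrow(idx), 1)
  expect_equal(idx$drug_group, "oxycodone_SA")
  expect_equal(idx$index_date, as.Date("2016-03-01"))
})

test_that("any opioid fill or opioid-related encounter in the lookback disqualifies", {
  fills <- dplyr::bind_rows(
    mk_fill(drug_base = "codeine", fill_date = "2016-02-20"),
    mk_fill(drug_base = "oxycodone", fill_date = "2016-05-31"))  # 100 d later
  expect_equal(nrow(find_index_events(fills, mk_claim()[0, ])), 0)

  fills2 <- mk_fill(drug_base = "oxycodone", fill_date = "2016-08-01")
  claim <- mk_claim(service_date = "2016-01-14")  # 200 d before
  expect_equal(nrow(find_index_events(fills2, claim)), 0)

  # a fill outside the 365-day lookback does not disqualify
  fills3 <- dplyr::bind_rows(
    mk_fill(drug_base = "codeine", fill_date = "2015-01-01"),
    mk_fill(drug_base = "oxycodone", fill_date = "2016-06-01"))
  expect_equal(nrow(find_index_events(fills3, mk_claim()[0, ])), 1)
})

test_that("long-acting and out-of-window fills are never index events", {
  la <- mk_fill(long_acting = TRUE)
  expect_equal(nrow(find_index_events(la, mk_claim()[0, ])), 0)
  pre <- mk_fill(fill_date = "2014-06-01")
  expect_equal(nrow(find_index_events(pre, mk_claim()[0, ])), 0)
})

test_that("no patient appears twice and the naive property holds (brute force)", {
  pop <- generate_population(sim_config(
    2000, seed = 3, overrides = list(history = list(p_prior_fill = 0.2,
                                                    p_prior_claim = 0.1))))
  cl <- clean_fills(pop$fills)
  idx <- find_index_events(cl$fills, pop$claims)
  expect_equal(anyDuplicated(idx$patient_id), 0)
  cs <- default_code_set()
  # brute-force scan of every index patient's history
  for (i in seq_len(nrow(idx))) {
    p <- idx$patient_id[i]; d <- idx$index_date[i]
    f <- cl$fills[cl$fills$patient_id == p, ]
    expect_false(any(f$fill_date >= d - 365 & f$fill_date < d))
    cj <- pop$claims[pop$claims$patient_id == p, ]
    if (nrow(cj) > 0) {
      hits <- vapply(strsplit(cj$diagnosis_codes, ";"), function(z) {
        any(startsWith(normalize_icd(z), cs$nonfatal_dx_prefixes[1:6]))
      }, logical(1))
      expect_false(any(hits & cj$service_date >= d - 365 &
                         cj$service_date < d))
    }
  }
})

test_that("enrollment filter honours the strictly-less-than-90-day gap rule", {
  idx <- mk_index(index_date = "2016-06-01")
  full <- mk_span(start_date = "2016-01-01", end_date = "2017-01-01")
  expect_equal(nrow(apply_enrollment_filter(idx, full, NULL)$kept), 1)

  gap89 <- dplyr::bind_rows(
    mk_span(start_date = "2015-12-01", end_date = "2016-04-01"),
    mk_span(start_date = "2016-06-29", end_date = "2017-02-01"))
  expect_equal(nrow(apply_enrollment_filter(idx, gap89, NULL)$kept), 1)

  gap90 <- dplyr::bind_rows(
    mk_span(start_date = "2015-12-01", end_date = "2016-04-01"),
    mk_span(start_date = "2016-06-30", end_date = "2017-02-01"))
  res <- apply_enrollment_filter(idx, gap90, NULL)
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$excluded$reason, "enrollment_gap")
})

test_that("decedents continuously enrolled while alive are kept", {
  idx <- mk_index(index_date = "2016-02-01")
  sp <- mk_span(start_date = "2016-01-01", end_date = "2016-03-01")
  death <- mk_death(death_date = "2016-03-15")
  expect_equal(nrow(apply_enrollment_filter(idx, sp, death)$kept), 1)
  # without the death the trailing gap (306 days) excludes the patient
  expect_equal(nrow(apply_enrollment_filter(idx, sp, NULL)$kept), 0)
})

test_that("patients with no spans at all are excluded as no_enrollment", {
  idx <- mk_index(index_date = "2016-06-01")
  res <- apply_enrollment_filter(idx, mk_span()[0, ], NULL)
  expect_equal(res$excluded$reason, "no_enrollment")
})

test_that("index MME multiplies strength, quantity, and conversion factor", {
  expect_equal(compute_index_mme(
    mk_fill(drug_base = "oxycodone", strength_per_unit = 5, quantity = 40)),
    300)
  expect_equal(compute_index_mme(
    mk_fill(drug_base = "hydrocodone", strength_per_unit = 5,
            quantity = 10)), 50)
  expect_equal(compute_index_mme(
    mk_fill(drug_base = "codeine", strength_per_unit = 30, quantity = 20)),
    90)
  expect_error(compute_index_mme(
    mk_fill(drug_base = "carfentanil")), "carfentanil")
})

test_that("categorize bins MME, days' supply, age, and insurance correctly", {
  idx <- dplyr::bind_rows(
    mk_index("P1", drug_base = "oxycodone", quantity = 40,
             combination_ingredient = "none", days_supply = 3),
    mk_index("P2", drug_base = "oxycodone", quantity = 40.0667,
             combination_ingredient = "none", days_supply = 4),
    mk_index("P3", days_supply = 7, quantity = 10))
  demo <- dplyr::bind_rows(mk_demo("P1", age_years = 18),
                           mk_demo("P2", age_years = 64),
                           mk_demo("P3", age_years = 75))
  spans <- dplyr::bind_rows(
    mk_span("P1", "2016-01-01", "2016-07-19", plan = "medicaid"),  # 200 d
    mk_span("P1", "2016-07-19", "2017-01-01", plan = "commercial"), # 166 d
    mk_span("P2", "2016-01-01", "2016-05-01", plan = "commercial"), # 121 d
    mk_span("P3", "2016-01-01", "2017-01-01", plan = "dual"))
  coh <- categorize(idx, demo, spans)
  # 40 x 5 mg oxycodone = 300 MME -> "201-300"; 40.0667 x 5 x 1.5 = 300.5
  expect_equal(as.character(coh$mme_category), c("201-300", ">300", "<=75"))
  expect_equal(as.character(coh$days_supply_category), c("<=3", "4-6", "7+"))
  expect_equal(as.character(coh$age_category), c("18-24", "55-64", "75+"))
  expect_equal(as.character(coh$insurance), c("medicaid", "unknown", "dual"))
})

test_that("combination subgroup labels follow formulation and 5 mg strength", {
  idx <- dplyr::bind_rows(
    mk_index("P1", drug_base = "oxycodone", combination_ingredient = "none"),
    mk_index("P2", drug_base = "hydrocodone",
             combination_ingredient = "acetaminophen"),
    mk_index("P3", drug_base = "oxycodone",
             combination_ingredient = "acetaminophen",
             strength_per_unit = 10),
    mk_index("P4", drug_base = "oxycodone",
             combination_ingredient = "acetaminophen"))
  expect_equal(recode_combination_subgroup(idx),
               c("oxy_mono_5mg", "hydro_apap_5mg", "other", "oxy_apap_5mg"))
})

test_that("category bins partition their domains at the boundaries", {
  mme <- c(74.9, 75, 75.1, 100, 100.5, 200, 200.1, 300, 300.0001, 1000)
  bins <- as.character(opioidcohort:::bin_mme(mme))
  expect_false(anyNA(bins))
  expect_equal(bins[c(2, 4, 6, 8)], c("<=75", "76-100", "101-200", "201-300"))
  expect_equal(bins[c(3, 5, 7, 9)],
               c("76-100", "101-200", "201-300", ">300"))
  ages <- 18:100
  expect_false(anyNA(opioidcohort:::bin_age(ages)))
})
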