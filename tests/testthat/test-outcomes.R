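idx1 <- mk_index("P1", index_date = "2016-01-01")

test_that("uncovered-days accounting matches the worked examples", {
  # single fill, 30-day supply: 335 uncovered, avg 335, not chronic
  r <- classify_chronic_primary(fill_trajectory(0, 30), idx1)
  expect_equal(r$n_fills_365, 1)
  expect_equal(r$total_uncovered_days, 335)
  expect_equal(r$avg_uncovered, 335)
  expect_false(r$chronic_primary)

  # six 30-day fills at 0,30,...,150: terminal gap 185, avg 185/6 -> fails
  # the 30-day criterion by 0.83 days
  r <- classify_chronic_primary(fill_trajectory(seq(0, 150, 30), 30), idx1)
  expect_equal(r$n_fills_365, 6)
  expect_equal(r$total_uncovered_days, 185)
  expect_equal(r$avg_uncovered, 185 / 6)
  expect_false(r$chronic_primary)

  # six 60-day fills at 0,60,...,300: terminal uncovered 5, avg 5/6
  r <- classify_chronic_primary(fill_trajectory(seq(0, 300, 60), 60), idx1)
  expect_equal(r$total_uncovered_days, 5)
  expect_true(r$chronic_primary)

  # twelve 30-day fills at 0,...,330: avg 5/12
  r <- classify_chronic_primary(fill_trajectory(seq(0, 330, 30), 30), idx1)
  expect_equal(r$avg_uncovered, 5 / 12)
  expect_true(r$chronic_primary)
})

test_that("early refills clip to zero uncovered days", {
  # 30-day supplies refilled every 20 days: every gap negative -> 0;
  # last fill at day 80 covers to 110, terminal uncovered 255
  r <- classify_chronic_primary(fill_trajectory(seq(0, 80, 20), 30), idx1)
  expect_equal(r$total_uncovered_days, 255)
})

test_that("a missing index fill is a contract violation", {
  fills <- fill_trajectory(c(0, 30), 30, patient_id = "P2")
  expect_error(classify_chronic_primary(fills, idx1), "P1")
})

test_that("alternative definition uses episode length, supply, and count", {
  r <- classify_chronic_alternative(fill_trajectory(0, 30), idx1)
  expect_equal(r$episode_length_days, 0)
  expect_false(r$chronic_alternative)

  # 10 fills of 10-day supply every 15 days: episode 135, >= 10 fills
  r <- classify_chronic_alternative(
    fill_trajectory(seq(0, 135, 15), 10), idx1)
  expect_equal(r$episode_length_days, 135)
  expect_true(r$chronic_alternative)

  # 5 fills of 30-day supply: episode 120, total supply 150 >= 120
  r <- classify_chronic_alternative(
    fill_trajectory(seq(0, 120, 30), 30), idx1)
  expect_true(r$chronic_alternative)

  # episode > 90 but neither supply nor count criterion
  r <- classify_chronic_alternative(
    fill_trajectory(c(0, 50, 100), 10), idx1)
  expect_false(r$chronic_alternative)
})

test_that("definition overlap percentages count the right denominators", {
  res <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    chronic_primary = c(TRUE, TRUE, TRUE, FALSE),
    chronic_alternative = c(FALSE, TRUE, TRUE, TRUE))
  ov <- definition_overlap(res)
  expect_equal(ov$pct_alt_also_primary, 200 / 3, tolerance = 1e-10)
  expect_equal(ov$pct_primary_also_alt, 200 / 3, tolerance = 1e-10)

  res$chronic_alternative <- res$chronic_primary
  ov <- definition_overlap(res)
  expect_equal(ov$pct_alt_also_primary, 100)
  expect_equal(ov$pct_primary_also_alt, 100)

  res$chronic_alternative <- FALSE
  ov <- definition_overlap(res)
  expect_true(is.na(ov$pct_alt_also_primary))
  expect_equal(ov$pct_primary_also_alt, 0)
})

test_that("fatal overdoses need a qualifying cause pair or a literal match", {
  death <- mk_death(death_date = "2016-06-01", underlying_cause = "X42",
                    multiple_causes = "T401;J9600",
                    literal_text = "found unresponsive")
  ev <- detect_overdose(mk_claim()[0, ], death, idx1)
  expect_equal(nrow(ev), 1)
  expect_true(ev$fatal)
  expect_equal(ev$source, "death_codes")

  # underlying cause qualifies but no opioid T-code: not an overdose
  death$multiple_causes <- "J9600"
  expect_equal(nrow(detect_overdose(mk_claim()[0, ], death, idx1)), 0)

  # literal text alone qualifies
  death$underlying_cause <- "R99"
  death$literal_text <- "acute Fentanyl toxicity"
  ev <- detect_overdose(mk_claim()[0, ], death, idx1)
  expect_equal(ev$source, "death_literal")

  expect_equal(nrow(detect_overdose(mk_claim()[0, ], mk_death()[0, ], idx1)),
               0)
})

test_that("the earliest on-or-after-index event wins", {
  claim <- mk_claim(service_date = "2016-04-10",
                    diagnosis_codes = "T402X1A;R0902")   # day 100
  death <- mk_death(death_date = "2016-07-19")            # non-opioid, day 200
  ev <- detect_overdose(claim, death, idx1)
  expect_equal(nrow(ev), 1)
  expect_false(ev$fatal)
  expect_equal(ev$event_date, as.Date("2016-04-10"))
  expect_equal(ev$source, "ED_claim")

  # pre-index overdoses are ignored
  pre <- mk_claim(service_date = "2015-12-01")
  expect_equal(nrow(detect_overdose(pre, mk_death()[0, ], idx1)), 0)
})

test_that("survival days and censoring follow the calendar rules", {
  idx <- mk_index("P1", index_date = "2017-06-01")
  full <- mk_span(start_date = "2016-01-01", end_date = "2019-06-01")
  no_ev <- detect_overdose(mk_claim()[0, ], mk_death()[0, ], idx)

  sv <- compute_survival(idx, full, no_ev, NULL)
  expect_equal(sv$survival_days, 578)
  expect_equal(sv$censor_reason, "study_end")

  # enrollment continuity fails in 2018 -> censored 2017-12-31 -> 213 days
  short <- mk_span(start_date = "2016-01-01", end_date = "2018-03-01")
  sv <- compute_survival(idx, short, no_ev, NULL)
  expect_equal(sv$survival_days, 213)
  expect_equal(sv$censor_reason, "enrollment_loss")

  # overdose on the index date: zero survival days, event
  ev0 <- detect_overdose(
    mk_claim(service_date = "2017-06-01"), mk_death()[0, ], idx)
  sv <- compute_survival(idx, full, ev0, NULL)
  expect_equal(sv$survival_days, 0)
  expect_true(sv$event)
  expect_equal(sv$censor_reason, "none")

  # non-opioid death censors at the death date
  death <- mk_death(death_date = "2018-02-01")
  sv <- compute_survival(idx, full, no_ev, death)
  expect_equal(sv$survival_days, 245)
  expect_equal(sv$censor_reason, "non_opioid_death")

  # an overdose after the censor date is not observed as an event
  late <- detect_overdose(
    mk_claim(service_date = "2018-06-01"), mk_death()[0, ], idx)
  sv <- compute_survival(idx, short, late, NULL)
  expect_false(sv$event)
  expect_equal(sv$survival_days, 213)
})

test_that("survival is bounded by index-to-study-end with equality iff study_end", {
  pop <- generate_population(sim_config(2000, seed = 5))
  b <- build_cohort(pop, need = "survival")
  cap <- as.integer(as.Date("2018-12-31") - b$index$index_date)
  expect_true(all(b$survival$survival_days <= cap))
  at_cap <- b$survival$survival_days == cap
  expect_equal(at_cap, b$survival$censor_reason == "study_end")
})

test_that("six-month cumulative MME excludes the index fill and day 183", {
  idx <- mk_index("P1", index_date = "2016-01-01", drug_base = "oxycodone")
  only_index <- fill_trajectory(0, 5, drug_base = "oxycodone")
  r <- cumulative_mme_6mo(only_index, idx)
  expect_equal(r$cumulative_mme_6mo, 0)
  expect_false(r$any_additional_fill)

  # one additional fill of 20 x 5 mg oxycodone at day 30: 150 MME
  extra <- dplyr::bind_rows(
    only_index,
    mk_fill(fill_date = "2016-01-31", drug_base = "oxycodone",
            combination_ingredient = "none", quantity = 20))
  r <- cumulative_mme_6mo(extra, idx)
  expect_equal(r$cumulative_mme_6mo, 150)

  # a fill exactly at day 183 is outside the half-open window
  at183 <- dplyr::bind_rows(
    only_index,
    mk_fill(fill_date = as.character(as.Date("2016-01-01") + 183),
            drug_base = "oxycodone", quantity = 20))
  expect_equal(cumulative_mme_6mo(at183, idx)$cumulative_mme_6mo, 0)
})

test_that("switching compares base ingredients within six months", {
  idx <- mk_index("P1", index_date = "2016-01-01", drug_base = "oxycodone",
                  combination_ingredient = "acetaminophen")
  only_index <- fill_trajectory(0, 5, drug_base = "oxycodone")
  expect_true(is.na(switch_flag(only_index, idx)$switched))

  hyd <- dplyr::bind_rows(
    only_index, mk_fill(fill_date = "2016-01-11",
                        drug_base = "hydrocodone"))
  expect_true(switch_flag(hyd, idx)$switched)

  # oxycodone monotherapy after an oxycodone-acetaminophen index:
  # same base ingredient, not a switch
  mono <- dplyr::bind_rows(
    only_index, mk_fill(fill_date = "2016-01-11", drug_base = "oxycodone",
                        combination_ingredient = "none"))
  expect_false(switch_flag(mono, idx)$switched)
})

test_that("cumulative MME is zero exactly when there is no additional fill", {
  pop <- generate_population(sim_config(1500, seed = 9))
  b <- build_cohort(pop, need = "secondary")
  expect_equal(b$secondary$cumulative_mme_6mo == 0,
               !b$secondary$any_additional_fill)
  expect_equal(is.na(b$secondary$switched),
               !b$secondary$any_additional_fill)
})
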