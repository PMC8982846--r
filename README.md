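# opioidcohort

Tools for building and analyzing opioid-naïve prescription cohorts from
linked public-health registry tables — dispensed fills (PDMP-style),
insurance enrollment spans (APCD-style), ED/inpatient encounter claims with
ICD-10 diagnoses, and vital-records death certificates.

The package is aimed at pharmacoepidemiologists studying what happens after
a patient's *first* short-acting hydrocodone or oxycodone prescription:
do they progress to chronic opioid use within a year, and what is their
hazard of a fatal or non-fatal opioid overdose? Because real linked
registries are protected by data-use agreements, the package also ships a
synthetic linked-registry generator with configurable ground-truth effects,
so every stage of the pipeline is testable at desk scale.

## What it computes

**Cohort construction.** PDMP cleaning (duplicates, missing prescriber,
quantity < 4 or ≥ the 99th-percentile cutoff, days' supply outside 0–90);
opioid-naïve index events (no opioid fill and no opioid-related ED or
inpatient encounter in the 365 days before the first qualifying short-acting
hydrocodone/oxycodone fill, 2015–2017); calendar-year continuous-enrollment
eligibility (gaps < 90 days, decedents exempted); exposure covariates
including total index morphine milligram equivalents
(MME = strength × quantity × CDC conversion factor) binned at
{75, 100, 200, 300}.

**Outcome phenotyping.** First-year chronic use, primary definition:
≥ 6 fills in 365 days (including index) *and* mean uncovered days ≤ 30,
where each gap's uncovered days are
`max(0, next fill date − (fill date + days' supply))`, the terminal gap ends
at day 365, and the mean divides total uncovered days by (number of
inter-fill gaps + 1). Alternative definition: episode > 90 days with total
days' supply ≥ 120 or ≥ 10 fills. Overdose events from death certificates
(underlying cause X40–X44, X60–X64, X85, Y10–Y14 with an opioid T-code
T40.0–T40.4/T40.6 among multiple causes, or a literal-text keyword) and
from ED/inpatient claims (T40.x prefixes). Survival records censored at
enrollment loss (backdated to December 31 of the preceding year),
non-opioid death, or study end (2018-12-31). Secondary outcomes: 6-month
cumulative MME excluding the index fill, and drug switching.

**Models.** Multilevel logistic regression (prescriber random intercept via
`lme4`) for chronic use and switching, Cox proportional hazards (`survival`,
Efron ties, optional prescriber frailty restricted to high-volume
prescribers) for overdose, a zero-inflated negative binomial (`glmmTMB`)
for 6-month cumulative MME, covariate balance via the two-proportion
standardized difference `|p1 − p2| / sqrt((p1(1−p1) + p2(1−p2))/2)`, and a
5 mg combination-product subgroup analysis
(hydrocodone-acetaminophen vs oxycodone-acetaminophen vs oxycodone
monotherapy).

## Worked example

```r
library(opioidcohort)

pop <- generate_population(sim_config(n_patients = 20000, seed = 42))
cl  <- clean_fills(pop$fills)
idx <- find_index_events(cl$fills, pop$claims)
flt <- apply_enrollment_filter(idx, pop$spans, pop$deaths)
coh <- categorize(flt$kept, pop$demographics, pop$spans)
chron <- compute_chronic_use(cl$fills, flt$kept)

mean(chron$chronic_primary)
#> [1] 0.02757502
ov <- detect_overdose(pop$claims, pop$deaths, flt$kept)
sv <- compute_survival(flt$kept, pop$spans, ov, pop$deaths)
mean(sv$event)
#> [1] 0.002757502

rep <- fit_chronic_logistic(coh, chron, random_effect = "off")
subset(rep$estimates, term == "drug_group" & !reference,
       c(level, ratio, ci_low, ci_high))
#> # A tibble: 1 × 4
#>   level        ratio ci_low ci_high
#>   <chr>        <dbl>  <dbl>   <dbl>
#> 1 oxycodone_SA 0.889  0.716    1.11
```

Under the default configuration about 2.8 % of patients meet the chronic-use
definition and about 0.3 % experience an overdose before censoring, matching
the regime the generator is calibrated to. The adjusted odds ratio for
oxycodone is the drug effect after controlling for patient and
index-prescription characteristics including dosage; its confidence interval
covers the configured ground truth.

The same analysis runs as a staged, manifest-logged pipeline:

```r
run_pipeline(sim_config(20000, seed = 42), outdir = "run1")
```

which writes `fills.csv` … `model_reports.json`, report tables, and a
`manifest.json` with the config hash and row counts. Identical seed and
config reproduce every output byte for byte.

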