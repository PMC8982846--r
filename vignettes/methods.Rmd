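---
title: "Methods: cohort construction, chronic-use phenotyping, and overdose risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort construction, chronic-use phenotyping, and overdose risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(opioidcohort)
```

# Scope and design

`opioidcohort` implements a linked-registry analysis of the adverse
consequences of a first opioid prescription: progression to chronic use in
the first year and time to a fatal or non-fatal opioid overdose, comparing
patients whose index prescription was short-acting hydrocodone versus
short-acting oxycodone. The package covers the full chain from raw
registry tables to adjusted effect estimates, plus a synthetic
linked-registry generator so that every stage is testable without access
to protected health data. The exported R functions, the staged
`run_pipeline()`, and `scripts/acceptance.R` are the interface; the
package deliberately ships no shell tool, since its users work in R.

# Cohort construction

**Cleaning.** Prescription-monitoring data are noisy: duplicate
submissions, missing prescriber identifiers, and implausible quantities or
days' supplies. `clean_fills()` removes exact duplicates (identical on all
prescription fields), fills missing a prescriber id, quantities below 4
tablets or at/above a high-percentile cutoff, and days' supply outside
0–90. The quantity cutoff (default the 99th percentile) is computed *once*
over the full input and then frozen; this makes cleaning idempotent and
reproducible, at the price of ignoring any ordering interaction among the
filters (which rule claims a row that violates several is an arbitrary but
documented precedence: duplicate, missing prescriber, quantity, days'
supply). The percentile is global rather than per-drug; a per-drug cutoff
would remove legitimately large fills of low-potency agents, and the
removal log makes the consequences of either choice auditable.

**Opioid-naïve index events.** A patient enters the cohort at their
earliest short-acting hydrocodone or oxycodone fill in 2015–2017 such that
the 365 days strictly before it (`[index − 365 d, index)`) contain no
opioid fill of any kind and no opioid-related ED or inpatient encounter.
Calendar phrases are fixed as day counts: 12 months = 365 days, 6 months =
183 days; all intervals are half-open `[start, end)` and all dates
ISO-8601. If a patient's earliest candidate fails the lookback, later
candidates are still examined — the definition is "first *qualifying*
fill", which matches the naïve-patient intent and keeps the rule a pure
function of the fill history.

**Enrollment eligibility.** A patient must be continuously enrolled during
the index calendar year, where every uncovered gap — leading, between
spans, trailing — must be strictly shorter than 90 days. Patients who died
during the index year are not excluded for the coverage they missed after
death: the continuity check simply stops at the death date. Gap days are
counted within the calendar year only; a gap straddling the year boundary
counts only its within-year days, which is the natural reading of a
year-level eligibility rule.

**Exposure covariates.** Index MME is `strength × quantity × factor`, with
CDC-style conversion factors shipped as an editable CSV (hydrocodone 1.0,
oxycodone 1.5). MME categories use fixed breakpoints {75, 100, 200, 300} —
the sample 25/50/75/90th percentiles of the reference cohort — rather than
re-computed percentiles, so that category labels mean the same thing
across datasets; `mme_percentile_mode = TRUE` restores the data-driven
behaviour. Insurance is the plan held at least 183 days of the index
calendar year, else "unknown". Age is binned into the seven conventional
categories from 18–24 to 75+.

# Outcome phenotyping

**Chronic use, primary definition.** Within `[index, index + 365 d)`, a
patient is a chronic user when they filled ≥ 6 opioid prescriptions
(including the index) *and* the average uncovered period between refills
was ≤ 30 days. Each gap contributes
`max(0, next fill − (fill date + days' supply))` uncovered days; the
terminal gap substitutes day 365 for the next fill; and the average
divides total uncovered days by (inter-fill gaps + 1), the +1 reflecting
that terminal gap. Early refills produce negative differences, which are
clipped to zero: uncovered time cannot be negative, and the formula is
deliberately gap-wise — there is no stockpiling carryover from one fill to
the next. The terminal gap is clipped at zero too when coverage extends
past day 365. These clipping rules are exactly mirrored by the test
suite's independent day-by-day coverage oracle, in which each fill's
coverage runs until the earliest of its exhaustion date, the next fill, or
the window end.

**Chronic use, alternative definition.** An episode runs from the index
date to the last in-window fill; chronic use requires an episode > 90 days
with either total days' supply ≥ 120 or ≥ 10 fills.
`definition_overlap()` reports the two cross-classification percentages.
A sensitivity flag excludes patients who died within the follow-up year.

**Overdose.** Fatal overdoses require an underlying cause of death in
X40–X44, X60–X64, X85, Y10–Y14 *and* an opioid T-code (T40.0–T40.4,
T40.6) among the multiple causes, *or* a literal-text keyword match
(lower-case substring over a configurable term list — a deliberate,
simple stand-in for dedicated death-certificate text classifiers, and
editable YAML like the code sets). Non-fatal overdoses are ED/inpatient
claims with any T40.x-prefixed diagnosis. Codes are matched prefix-wise
after normalization (uppercase, dots stripped), so the 4-character
category T401 matches the 7-character claim code T40.1X1A. The earliest
event on/after index wins; a same-day fatal signal outranks a non-fatal
one.

**Survival construction.** Survival days run from the index date to the
earliest of the overdose event, enrollment-based censoring, non-opioid
death, or 2018-12-31. Enrollment is assessed in whole calendar years after
the index year with the same < 90-day gap rule; the first failing year
censors the patient at December 31 of the *preceding* year. This
backdating means events occurring in a failing year are treated as
unobserved — the information structure a year-granular enrollment feed
actually provides. Years are truncated at death so post-mortem gaps never
censor anyone before their death date.

# Models

Reference levels are fixed throughout (hydrocodone SA; age 18–24; male;
White; commercial; noncore; 2015; MME ≤ 75; ≤ 3 days), 95% intervals are
Wald on the log scale, and no multiplicity adjustment is applied. Chronic
use and switching use logistic regression with an optional prescriber
random intercept, estimated by Laplace-approximate maximum likelihood
(`lme4::glmer`, nAGQ = 1); the estimation method is recorded in each
`model_report` because penalized and quadrature methods can differ in the
third decimal. Overdose uses Cox proportional hazards with Efron tie
handling; the prescriber-clustered variant adds a gamma frailty and, to
keep the frailty estimable, restricts to prescribers with at least 200
cohort patients (configurable). Cumulative 6-month MME, rounded to 1-MME
units, uses a zero-inflated negative binomial (`glmmTMB`, nbinom2): the
zero portion models the odds of no additional dispensing, the count
portion the dose among fillers. Non-convergence falls back in stages to a
plain negative binomial and then a hurdle fit, with the stage recorded.
Covariate levels with zero events are flagged and their estimates
withheld (standard error cap) rather than reported as numeric noise.

The covariate balance table uses the pooled-variance two-proportion
standardized difference
`|p1 − p2| / sqrt((p1(1−p1) + p2(1−p2)) / 2)`, defined as 0 when
`p1 = p2` (including both degenerate endpoints).

# The synthetic generator

`sim_config()` fixes the study conditions: 68% hydrocodone index fills;
covariate margins taken from the shipped reference-cohort margins table;
per-drug index MME and days'-supply distributions (oxycodone shifted
higher on both); and ground-truth effects — drug log-OR log(0.95) for
chronic use, drug log-HR log(1.65) for overdose (or per-formulation
log-HRs for the 5 mg subgroup), a 1.20 cumulative-MME rate ratio, a 1.24
switching OR, and covariate effects on the category scale so the fitted
models are correctly specified. Two intercept-like scalars were calibrated
once against the reference margins and then frozen: the chronic intercept
(−5.8, giving ≈ 2.8% chronic use) and the base daily overdose hazard
(1.1 × 10⁻⁶, giving ≈ 0.3% overdose before censoring, with ≈ 42% of
patients filling again within six months and ≈ 37% of those switching).

Chronic use is generated *mechanistically*: a latent persistent-refiller
propensity (logistic in the configured effects, plus an optional
prescriber random effect) drives ~monthly 30-day refills with small
Poisson-distributed uncovered gaps, while non-persistent patients draw a
small number of short fills at 7–90-day gaps. The chronic label is never
stamped directly, so the classifier is genuinely tested against
trajectories; `fill_trajectory()` builds exact trajectories for unit
tests. Refill dose is drawn as a target MME (gamma, mean 120) scaled by
the configured count-portion effects and back-converted to tablets, so
the configured rate ratio is the true conditional mean ratio regardless
of drug-specific strengths and conversion factors. Overdose times are
exponential conditional on covariates (a piecewise-constant hazard is all
that recovery testing requires — the real hazard shape is unknown and
irrelevant to that purpose); fatal events emit qualifying death records
(with a configurable fraction detectable only through literal text),
non-fatal events emit T40.x claims. Enrollment churn (annual probability
0.10 after the index year, 0.03 within it) generates calendar-year
censoring and eligibility exclusions; optional injected lookback history
creates non-naïve patients for exclusion tests.

What the generator does *not* emulate: seasonal prescribing, geographic
or drug-market structure, record-linkage error, correlated comorbidity,
or informative (outcome-dependent) censoring. Passing tests therefore
demonstrate that the pipeline recovers known effects under a clean,
correctly-specified data-generating process — not that any particular
real-world estimate is unbiased.

# Verification strategy and problem sizes

The test suite checks, at sizes chosen to balance statistical power
against a desk-scale runtime: oracle equivalence of the uncovered-days
accounting on 1,200 random trajectories; the calendar-censoring edge
cases by hand-computed date arithmetic; null recovery of the chronic-use
logistic stage (50 zero-effect replicates at n = 20,000; the drug CI must
cover 1 in ≥ 44, the exact binomial 95% band); Cox recovery of HR 1.65
(50 replicates at n = 30,000, ≈ 0.3% event rate; coverage in ≥ 45 of 50);
ZINB count-portion recovery of the 1.20 rate ratio and switching recovery
of the 1.24 OR within their fitted CIs; the dosage-confounding sign flip
(three replicates at n = 150,000 — the drug OR sits below 1 with MME in
the model and above 1 without, because oxycodone is assigned higher MME
and MME independently raises chronic-use odds); ordering recovery of the
subgroup hazards (monotherapy > combination > reference, pooled over
three replicates at n = 150,000); and byte-identical pipeline re-runs.
Replicate simulations switch off the prescriber random effect and other
nuisance effects not under test so each fitted model is exactly the
generating model; recovery fits adjust for the covariates that truly
enter the hazard rather than the full covariate set, avoiding
small-sample bias from estimating dozens of parameters on ~80 events.

# Known limitations

NDC-dictionary resolution is out of scope (the generator emits the base
ingredient directly; an NDC→ingredient mapping can be applied upstream).
Overdoses from prescribed versus illicit opioids are not distinguished —
ICD-10 coding cannot reliably separate them. The literal-text matcher is
a keyword list, not a trained classifier. Numerical agreement with other
statistical engines' mixed-model estimates is not a contract; estimation
methods are therefore recorded in every report.
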