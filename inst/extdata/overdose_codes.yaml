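# Default opioid-overdose code set.
# Fatal: underlying cause in `underlying_cause_codes` AND at least one
# multiple-cause code with a prefix in `t_codes`, OR a literal-text match.
# Non-fatal: any ED/inpatient diagnosis with a prefix in
# `nonfatal_dx_prefixes`. Codes are matched prefix-wise after normalization
# (uppercase, dots removed), so T401 matches T40.1X1A.
name: opioid_overdose_default
underlying_cause_codes:
  - X40
  - X41
  - X42
  - X43
  - X44
  - X60
  - X61
  - X62
  - X63
  - X64
  - X85
  - Y10
  - Y11
  - Y12
  - Y13
  - Y14
t_codes:
  - T400
  - T401
  - T402
  - T403
  - T404
  - T406
nonfatal_dx_prefixes:
  - T400
  - T401
  - T402
  - T403
  - T404
  - T406
literal_terms:
  - heroin
  - fentanyl
  - opioid
  - opiate
  - oxycodone
  - hydrocodone
  - morphine
  - methadone
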