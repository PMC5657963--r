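# Variable map for the NHANES 2011-2012 public-use files (DEMO_G, AUX_G,
# AUQ_G). This encodes one reading of the 2011-2012 codebooks and is an
# overridable configuration, not a package constant: column names and code
# collapses here are documented assumptions.
#
# Notes on assumptions:
#   * weight: MEC exam weight (WTMEC2YR), the standard choice for
#     exam-based outcomes, not the interview weight.
#   * exposure: the work-noise item ("ever exposed to loud noise at work"
#     where loud means having to speak in a raised voice to be heard);
#     codes 7/9 (refused / don't know) become missing via the ".na" label.
#   * retest_1k: the 1 kHz threshold is measured twice; the primary
#     (first) measurement is used, the retest filling in only when the
#     primary is missing. Policies "best" and "mean" are available.
#   * missing_codes: audiometric sentinel codes (could not test / no
#     response) treated as missing thresholds.
id: SEQN
demographics:
  age: RIDAGEYR
  sex:
    column: RIAGENDR
    codes:
      "1": Male
      "2": Female
  race:
    column: RIDRETH1
    codes:
      "1": Mexican American
      "2": Other
      "3": White non-Hispanic
      "4": Black non-Hispanic
      "5": Other
  education:
    column: DMDEDUC2
    codes:
      "1": Less than high school
      "2": Less than high school
      "3": Completed high school
      "4": More than high school
      "5": More than high school
      "7": .na
      "9": .na
  pir:
    column: INDFMPIR
design:
  weight: WTMEC2YR
  stratum: SDMVSTRA
  psu: SDMVPSU
questionnaire:
  exposure:
    column: AUQ370
    codes:
      "1": "Yes"
      "2": "No"
      "7": .na
      "9": .na
  hearing:
    column: AUQ054
    codes:
      "1": Excellent/good
      "2": Excellent/good
      "3": Trouble hearing
      "4": Trouble hearing
      "5": Trouble hearing
      "6": Trouble hearing
      "7": .na
      "9": .na
audiometry:
  right:
    "500": AUXU500R
    "1000": AUXU1K1R
    "2000": AUXU2KR
    "3000": AUXU3KR
    "4000": AUXU4KR
    "6000": AUXU6KR
    "8000": AUXU8KR
  left:
    "500": AUXU500L
    "1000": AUXU1K1L
    "2000": AUXU2KL
    "3000": AUXU3KL
    "4000": AUXU4KL
    "6000": AUXU6KL
    "8000": AUXU8KL
  retest_1k:
    right: AUXU1K2R
    left: AUXU1K2L
    policy: primary
  missing_codes: [666, 888]
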