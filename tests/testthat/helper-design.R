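# Design shorthands used across the estimation tests.

# Simple random sample lookalike: equal weights, every row its own PSU in
# one stratum.
srs_design <- function(n, weight = 1) {
  survey_design(weight = rep(weight, n), stratum = rep(1L, n), psu = seq_len(n))
}

# Balanced stratified design: `strata` strata x `psus` PSUs, rows assigned
# round-robin.
stratified_design <- function(n, strata = 15, psus = 2, weight = NULL) {
  s <- rep_len(seq_len(strata), n)
  p <- rep_len(rep(seq_len(psus), each = strata), n)
  if (is.null(weight)) weight <- rep(1, n)
  survey_design(weight = weight, stratum = s, psu = p)
}

# Exact-detection generator settings: fixed 30 dB notch, no measurement
# noise, no age slope, no clustering shift — the rule detects injected
# notches perfectly, so estimator properties are tested free of
# misclassification.
exact_detection_spec <- function(n, seed, ...) {
  flat <- c("0.5" = 0, "1" = 0, "2" = 0, "3" = 0, "4" = 0, "6" = 0, "8" = 0)
  args <- list(
    n_participants = n, seed = seed,
    baseline_thresholds = c("0.5" = 5, "1" = 5, "2" = 5, "3" = 5,
                            "4" = 5, "6" = 5, "8" = 5),
    age_slope = flat,
    notch_depth_mean = 30, notch_depth_sd = 0,
    noise_sd = 0, psu_shift_sd = 0
  )
  do.call(cohort_spec, utils::modifyList(args, list(...)))
}
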