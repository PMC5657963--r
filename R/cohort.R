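# Synthetic audiogram cohort generator with known ground truth: age/sex
# structured hearing thresholds, an injectable high-frequency notch tied to
# a noise-exposure covariate, 5-dB quantization, and a stratified
# multistage survey design with unequal weights.

#' Specify a synthetic survey cohort
#'
#' Collects every parameter of the synthetic-cohort generator, validated
#' once. Defaults describe the study conditions used throughout the test
#' suite: a stratified design of 15 strata with 2 PSUs each, log-normal
#' weights scaled to a population of 160 million (approximately US adults
#' aged 20-69), uniform ages 20-69, half male, 34% reporting loud-noise
#' exposure at work, and per-ear notch injection probabilities
#' \eqn{1 - \sqrt{0.8}} (unexposed) and \eqn{1 - \sqrt{2/3}} (exposed).
#' With independent ears those per-ear values give participant-level
#' any-ear injection probabilities of exactly 0.20 and 1/3 — a
#' participant-level exposure odds ratio of exactly 2.
#'
#' The injected notch has full depth at its center frequency (3, 4 or
#' 6 kHz), half depth at the adjacent high frequencies among 3/4/6 kHz,
#' and leaves 0.5, 1, 2 and 8 kHz untouched, so the 8 kHz recovery
#' condition of the notch rule stays meaningful. The age effect applies
#' only to 3-8 kHz by default (high-frequency presbycusis), producing
#' sloping losses that the rule correctly rejects (8 kHz worsens too,
#' so there is no recovery).
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; fully determines the cohort.
#' @param strata_count,psus_per_stratum Survey design shape.
#' @param weight_sdlog Log-normal sigma of the raw weights (CV
#'   \eqn{\sqrt{e^{\sigma^2} - 1}}; the default 0.5 gives CV ~ 0.53).
#' @param population_total Weights are rescaled to sum to this.
#' @param age_range Inclusive integer age range sampled uniformly.
#' @param sex_ratio Proportion male.
#' @param exposure_prevalence Proportion reporting work noise exposure.
#' @param baseline_thresholds Named vector (names: kHz) of mean thresholds
#'   at the youngest age, dB HL.
#' @param age_slope Named vector, dB per decade of age, per frequency.
#' @param notch_prob_unexposed,notch_prob_exposed Per-ear injection
#'   probability by exposure status; ears are independent.
#' @param notch_depth_mean,notch_depth_sd Injected notch depth
#'   distribution (dB), normal truncated at zero.
#' @param notch_center_probs Probabilities of centering the notch at 3, 4,
#'   6 kHz (named vector, sums to 1).
#' @param noise_sd Test-retest measurement noise SD (dB) added to every
#'   threshold before quantization.
#' @param quantization_step Audiometric step (dB); thresholds are rounded
#'   to its multiples and clipped to \[-10, 120\].
#' @param missing_rate Probability each threshold is missing, applied
#'   independently per ear-frequency.
#' @param psu_shift_sd SD (dB) of a PSU-level random shift added to the
#'   3-8 kHz thresholds; nonzero values create intra-cluster correlation
#'   and hence design effects above 1.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [generate_cohort()], [design_effect_probe()]
#' @export
cohort_spec <- function(n_participants,
                        seed = 1L,
                        strata_count = 15L,
                        psus_per_stratum = 2L,
                        weight_sdlog = 0.5,
                        population_total = 160e6,
                        age_range = c(20L, 69L),
                        sex_ratio = 0.5,
                        exposure_prevalence = 0.34,
                        baseline_thresholds = c("0.5" = 5, "1" = 5, "2" = 5,
                                                "3" = 5, "4" = 5, "6" = 5,
                                                "8" = 5),
                        age_slope = c("0.5" = 0, "1" = 0, "2" = 0,
                                      "3" = 4, "4" = 6, "6" = 8, "8" = 9),
                        notch_prob_unexposed = 1 - sqrt(0.8),
                        notch_prob_exposed = 1 - sqrt(2 / 3),
                        notch_depth_mean = 25,
                        notch_depth_sd = 5,
                        notch_center_probs = c("3" = 0.25, "4" = 0.5,
                                               "6" = 0.25),
                        noise_sd = 2,
                        quantization_step = 5,
                        missing_rate = 0,
                        psu_shift_sd = 0) {
  stopifnot(
    length(n_participants) == 1, n_participants >= 1,
    n_participants == round(n_participants),
    length(seed) == 1, is.finite(seed),
    strata_count >= 1, psus_per_stratum >= 1,
    weight_sdlog >= 0, population_total > 0,
    length(age_range) == 2, age_range[1] <= age_range[2],
    age_range[1] >= 20, age_range[2] <= 69
  )
  probs <- c(sex_ratio, exposure_prevalence, notch_prob_unexposed,
             notch_prob_exposed, missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (notch_depth_mean < 0 || notch_depth_sd < 0) {
    stop("notch depth distribution must have non-negative support",
         call. = FALSE)
  }
  fr <- as.character(AUDIOMETRIC_FREQS)
  if (!all(fr %in% names(baseline_thresholds)) ||
      !all(fr %in% names(age_slope))) {
    stop("baseline_thresholds and age_slope need entries for all of ",
         paste(fr, collapse = ", "), " kHz", call. = FALSE)
  }
  if (!all(names(notch_center_probs) %in% as.character(NOTCH_FREQS)) ||
      abs(sum(notch_center_probs) - 1) > 1e-8) {
    stop("notch_center_probs must be over 3/4/6 kHz and sum to 1",
         call. = FALSE)
  }
  if (noise_sd < 0 || quantization_step <= 0 || psu_shift_sd < 0) {
    stop("noise_sd, psu_shift_sd must be >= 0 and quantization_step > 0",
         call. = FALSE)
  }
  spec <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    strata_count = as.integer(strata_count),
    psus_per_stratum = as.integer(psus_per_stratum),
    weight_sdlog = weight_sdlog, population_total = population_total,
    age_range = as.integer(age_range), sex_ratio = sex_ratio,
    exposure_prevalence = exposure_prevalence,
    baseline_thresholds = baseline_thresholds[fr],
    age_slope = age_slope[fr],
    notch_prob_unexposed = notch_prob_unexposed,
    notch_prob_exposed = notch_prob_exposed,
    notch_depth_mean = notch_depth_mean, notch_depth_sd = notch_depth_sd,
    notch_center_probs = notch_center_probs,
    noise_sd = noise_sd, quantization_step = quantization_step,
    missing_rate = missing_rate, psu_shift_sd = psu_shift_sd
  )
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec: n = %d, seed = %d, %d strata x %d PSUs, exposure %.0f%%, per-ear injection %.3f/%.3f>\n",
    x$n_participants, x$seed, x$strata_count, x$psus_per_stratum,
    100 * x$exposure_prevalence, x$notch_prob_unexposed,
    x$notch_prob_exposed
  ))
  invisible(x)
}

# Round to the audiometric step and clip to the legal range.
quantize_thresholds <- function(x, step) {
  pmin(pmax(round(x / step) * step, THRESHOLD_RANGE[1]), THRESHOLD_RANGE[2])
}

#' Generate a synthetic survey cohort of audiograms
#'
#' Draws a complete cohort from a [cohort_spec()]: survey design
#' (stratum, PSU, log-normal weight rescaled to the population total),
#' demographics and questionnaire covariates, per-ear notch injection with
#' known ground truth, and the resulting quantized audiograms. The same
#' seed always reproduces the identical cohort. Draws are vectorized
#' attribute-by-attribute under the single seed, so changing
#' `n_participants` redraws the cohort rather than extending it.
#'
#' Threshold construction per ear and frequency: baseline + age slope
#' (per decade past the minimum age) + PSU-level shift (3-8 kHz only, when
#' `psu_shift_sd > 0`) + injected notch bump (full depth at the center
#' frequency, half depth at adjacent frequencies among 3/4/6 kHz) +
#' Gaussian measurement noise, then rounding to the quantization step and
#' clipping to \[-10, 120\] dB HL.
#'
#' @param spec A [cohort_spec()].
#'
#' @return A data.frame, one row per participant, with columns `id`,
#'   `age`, `age_group`, `sex`, `race`, `education`, `pir`, `exposure`,
#'   `hearing`, `weight`, `stratum`, `psu`, threshold columns `l_500` ...
#'   `l_8000` and `r_500` ... `r_8000` (generic audiogram CSV layout,
#'   frequencies in Hz), and ground-truth columns `notch_injected_left`,
#'   `notch_injected_right` recording injection events (not rule
#'   outcomes).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(old(), add = TRUE)

  # --- survey design ---
  stratum <- sample.int(spec$strata_count, n, replace = TRUE)
  psu <- sample.int(spec$psus_per_stratum, n, replace = TRUE)
  w_raw <- stats::rlnorm(n, meanlog = 0, sdlog = spec$weight_sdlog)
  weight <- w_raw * spec$population_total / sum(w_raw)

  # --- demographics / covariates (round-number marginals) ---
  age <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < spec$sex_ratio, "Male", "Female")
  race <- sample(c("White non-Hispanic", "Black non-Hispanic",
                   "Mexican American", "Other"), n, replace = TRUE,
                 prob = c(0.4, 0.2, 0.2, 0.2))
  education <- sample(c("Less than high school", "Completed high school",
                        "More than high school"), n, replace = TRUE,
                      prob = c(0.2, 0.3, 0.5))
  pir <- sample(c("<=1", ">1 to <5", ">=5"), n, replace = TRUE,
                prob = c(0.2, 0.6, 0.2))
  exposure <- ifelse(stats::runif(n) < spec$exposure_prevalence, "Yes", "No")
  hearing <- sample(c("Excellent/good", "Trouble hearing"), n,
                    replace = TRUE, prob = c(0.8, 0.2))

  # --- notch injection (per ear, independent, exposure-dependent) ---
  p_ear <- ifelse(exposure == "Yes", spec$notch_prob_exposed,
                  spec$notch_prob_unexposed)
  inj_l <- stats::runif(n) < p_ear
  inj_r <- stats::runif(n) < p_ear

  # PSU-level high-frequency shift (intra-cluster correlation).
  psu_key <- paste(stratum, psu, sep = "//")
  psu_levels <- unique(psu_key)
  shift_by_psu <- stats::setNames(
    stats::rnorm(length(psu_levels), 0, spec$psu_shift_sd), psu_levels)
  psu_shift <- shift_by_psu[psu_key]

  freqs <- AUDIOMETRIC_FREQS
  fr <- as.character(freqs)
  decades <- (age - spec$age_range[1]) / 10

  make_ear <- function(injected) {
    depth <- pmax(stats::rnorm(n, spec$notch_depth_mean,
                               spec$notch_depth_sd), 0)
    center <- sample(as.numeric(names(spec$notch_center_probs)), n,
                     replace = TRUE, prob = spec$notch_center_probs)
    th <- matrix(NA_real_, n, length(freqs), dimnames = list(NULL, fr))
    for (j in seq_along(freqs)) {
      f <- freqs[j]
      base <- spec$baseline_thresholds[[fr[j]]] +
        spec$age_slope[[fr[j]]] * decades
      if (f >= 3) base <- base + psu_shift
      bump <- numeric(n)
      if (f %in% NOTCH_FREQS) {
        dist <- abs(match(f, NOTCH_FREQS) - match(center, NOTCH_FREQS))
        bump <- ifelse(injected & dist == 0, depth,
                       ifelse(injected & dist == 1, depth / 2, 0))
      }
      noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
      th[, j] <- quantize_thresholds(base + bump + noise,
                                     spec$quantization_step)
    }
    if (spec$missing_rate > 0) {
      drop <- matrix(stats::runif(n * length(freqs)) < spec$missing_rate,
                     n, length(freqs))
      th[drop] <- NA_real_
    }
    th
  }
  th_l <- make_ear(inj_l)
  th_r <- make_ear(inj_r)

  out <- data.frame(
    id = seq_len(n), age = age,
    age_group = cut(age, breaks = c(19, 29, 39, 49, 59, 69),
                    labels = c("20-29", "30-39", "40-49", "50-59", "60-69")),
    sex = factor(sex, levels = c("Male", "Female")),
    race = factor(race, levels = c("White non-Hispanic",
                                   "Black non-Hispanic", "Mexican American",
                                   "Other")),
    education = factor(education,
                       levels = c("More than high school",
                                  "Completed high school",
                                  "Less than high school")),
    pir = factor(pir, levels = c(">=5", ">1 to <5", "<=1")),
    exposure = factor(exposure, levels = c("No", "Yes")),
    hearing = factor(hearing, levels = c("Excellent/good",
                                         "Trouble hearing")),
    weight = weight, stratum = stratum, psu = psu,
    stringsAsFactors = FALSE
  )
  hz <- AUDIOMETRIC_FREQS * 1000
  for (j in seq_along(hz)) out[[paste0("l_", hz[j])]] <- th_l[, j]
  for (j in seq_along(hz)) out[[paste0("r_", hz[j])]] <- th_r[, j]
  out$notch_injected_left <- inj_l
  out$notch_injected_right <- inj_r
  out
}

# Save/restore the caller's RNG state so generation is a pure function of
# the cohort_spec seed.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() suppressWarnings(
      rm(".Random.seed", envir = globalenv())
    )
  }
}

#' Probe the design effect of a generated cohort
#'
#' Summarizes how far the cohort's survey design departs from simple
#' random sampling: the coefficient of variation of the weights, the Kish
#' approximation to the unequal-weighting design effect
#' \eqn{1 + CV^2}, the intra-PSU correlation (ANOVA estimator) of a binary
#' indicator, and the implied overall design effect
#' \eqn{(1 + CV^2)\,(1 + (\bar m - 1)\rho)} with \eqn{\bar m} the mean PSU
#' size.
#'
#' @param cohort A data.frame from [generate_cohort()], already classified
#'   (see [classify_audiograms()]) or not; if the indicator column is
#'   absent the cohort is classified on the fly.
#' @param indicator Name of the 0/1 column to assess clustering on
#'   (default `"notch_any"`).
#'
#' @return A list with `weight_cv`, `kish_deff`, `icc` (NA with a note
#'   when every PSU has a single member), `mean_psu_size` and `deff`.
#' @export
design_effect_probe <- function(cohort, indicator = "notch_any") {
  if (!indicator %in% names(cohort)) {
    cohort <- classify_audiograms(cohort)
  }
  w <- cohort$weight
  cv <- stats::sd(w) / mean(w)
  kish <- 1 + cv^2

  y <- cohort[[indicator]]
  keep <- !is.na(y)
  y <- y[keep]
  cl <- factor(paste(cohort$stratum, cohort$psu, sep = "//"))[keep]
  sizes <- table(cl)
  if (all(sizes <= 1)) {
    icc <- NA_real_
    note <- "single-member PSUs: intra-cluster correlation undefined"
    mbar <- 1
  } else {
    note <- NULL
    # One-way ANOVA estimator of the intraclass correlation.
    k <- nlevels(cl)
    nn <- length(y)
    mbar <- nn / k
    grand <- mean(y)
    means <- tapply(y, cl, mean)
    ssb <- sum(sizes * (means - grand)^2)
    ssw <- sum((y - means[cl])^2)
    msb <- ssb / (k - 1)
    msw <- ssw / (nn - k)
    n0 <- (nn - sum(sizes^2) / nn) / (k - 1)
    icc <- (msb - msw) / (msb + (n0 - 1) * msw)
  }
  deff <- kish * (1 + (mbar - 1) * max(icc, 0, na.rm = TRUE))
  out <- list(weight_cv = cv, kish_deff = kish, icc = icc,
              mean_psu_size = mbar, deff = deff)
  if (!is.null(note)) out$note <- note
  out
}

#' Write a cohort to the generic audiogram and design CSV files
#'
#' Emits the two-file interchange format: an audiogram CSV (one row per
#' participant, threshold columns `<side>_<freq>` in Hz, covariates) and a
#' design CSV (`id`, `weight`, `stratum`, `psu`).
#'
#' @param cohort A [generate_cohort()] data.frame.
#' @param audiogram_file,design_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_csv <- function(cohort, audiogram_file, design_file) {
  design_cols <- c("id", "weight", "stratum", "psu")
  utils::write.csv(cohort[setdiff(names(cohort), c("weight", "stratum", "psu"))],
                   audiogram_file, row.names = FALSE, na = "")
  utils::write.csv(cohort[design_cols], design_file, row.names = FALSE)
  invisible(c(audiogram_file, design_file))
}
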