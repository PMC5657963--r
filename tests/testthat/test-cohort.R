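# Synthetic cohort generator: determinism, ground truth, quantization,
# and design effects.

test_that("the same seed reproduces the identical cohort", {
  spec <- cohort_spec(300, seed = 99)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  # a different seed gives a different cohort
  c2 <- generate_cohort(cohort_spec(300, seed = 100))
  expect_false(identical(a$l_4000, c2$l_4000))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(runif(1))
  invisible(generate_cohort(cohort_spec(50, seed = 1)))
  after <- runif(2)
  expect_identical(before[2:3], after)
})

test_that("no injection, no slope, no noise yields zero notches", {
  spec <- cohort_spec(400, seed = 5,
                      age_slope = c("0.5" = 0, "1" = 0, "2" = 0, "3" = 0,
                                    "4" = 0, "6" = 0, "8" = 0),
                      notch_prob_unexposed = 0, notch_prob_exposed = 0,
                      noise_sd = 0, psu_shift_sd = 0)
  cl <- classify_audiograms(generate_cohort(spec))
  expect_identical(sum(cl$notch_any), 0L)
  expect_true(all(cl$classifiable))
})

test_that("emitted thresholds are quantized and in range", {
  co <- generate_cohort(cohort_spec(500, seed = 6, noise_sd = 8))
  th_cols <- grep("^[lr]_\\d+$", names(co), value = TRUE)
  th <- unlist(co[th_cols])
  expect_true(all(th %% 5 == 0))
  expect_true(all(th >= -10 & th <= 120))
})

test_that("detected prevalence matches the independent-ears closed form", {
  # per-ear injection 0.25 regardless of exposure, perfect detection:
  # participant-level any-notch probability is 1 - 0.75^2
  spec <- exact_detection_spec(20000, seed = 41,
                               notch_prob_unexposed = 0.25,
                               notch_prob_exposed = 0.25)
  cl <- classify_audiograms(generate_cohort(spec))
  p_true <- 1 - 0.75^2
  p_hat <- mean(cl$notch_any)
  se <- sqrt(p_true * (1 - p_true) / nrow(cl))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("rule verdicts equal injection truth under exact detection", {
  spec <- exact_detection_spec(2000, seed = 42)
  cl <- classify_audiograms(generate_cohort(spec))
  expect_identical(cl$notch_left, cl$notch_injected_left)
  expect_identical(cl$notch_right, cl$notch_injected_right)
})

test_that("notches shallower than the rule depth are injected but never detected", {
  spec <- cohort_spec(2000, seed = 43,
                      age_slope = c("0.5" = 0, "1" = 0, "2" = 0, "3" = 0,
                                    "4" = 0, "6" = 0, "8" = 0),
                      notch_prob_unexposed = 0.3, notch_prob_exposed = 0.3,
                      notch_depth_mean = 10, notch_depth_sd = 0,
                      noise_sd = 0, psu_shift_sd = 0)
  cl <- classify_audiograms(generate_cohort(spec))
  expect_gt(sum(cl$notch_injected_left), 0)
  expect_identical(sum(cl$notch_any), 0L)
})

test_that("age-sloping loss without injection is rule-negative", {
  # steep presbycusis slope but no notch: 8 kHz worsens at least as fast
  # as 3-6 kHz, so the recovery condition fails
  spec <- cohort_spec(2000, seed = 44,
                      notch_prob_unexposed = 0, notch_prob_exposed = 0,
                      noise_sd = 0, psu_shift_sd = 0)
  cl <- classify_audiograms(generate_cohort(spec))
  expect_identical(sum(cl$notch_any), 0L)
})

test_that("missingness produces unclassifiable participants", {
  spec <- cohort_spec(800, seed = 45, missing_rate = 0.05)
  cl <- classify_audiograms(generate_cohort(spec))
  expect_gt(sum(!cl$classifiable), 0)
  expect_true(all(is.na(cl$notch_any[!cl$classifiable])))
})

test_that("design_effect_probe reports weight variation and clustering", {
  # equal weights, no cluster effect: design effect ~ 1
  flat <- exact_detection_spec(4000, seed = 46, weight_sdlog = 0)
  probe <- design_effect_probe(generate_cohort(flat))
  expect_equal(probe$weight_cv, 0, tolerance = 1e-12)
  expect_equal(probe$kish_deff, 1, tolerance = 1e-12)
  expect_lt(abs(probe$deff - 1), 0.15)

  # weights with CV 0.5: Kish approximation pushes the design effect up
  skew <- exact_detection_spec(4000, seed = 47,
                               weight_sdlog = sqrt(log(1.25)))
  probe2 <- design_effect_probe(generate_cohort(skew))
  expect_gt(probe2$kish_deff, 1.15)
  expect_gt(probe2$deff, 1.15)

  # PSU-level shifts create intra-cluster correlation
  clus <- exact_detection_spec(4000, seed = 48, psu_shift_sd = 10,
                               noise_sd = 2)
  probe3 <- design_effect_probe(generate_cohort(clus))
  expect_gt(probe3$icc, 0.01)

  # one participant per PSU: ICC undefined, reported as such
  lone <- generate_cohort(exact_detection_spec(30, seed = 49,
                                               strata_count = 15L))
  lone$stratum <- rep(1:15, each = 2)
  lone$psu <- seq_len(30)
  probe4 <- design_effect_probe(lone)
  expect_true(is.na(probe4$icc))
  expect_match(probe4$note, "undefined")
})

test_that("spec validation refuses malformed parameters", {
  expect_error(cohort_spec(0), "n_participants")
  expect_error(cohort_spec(10, exposure_prevalence = 1.2), "probabilities")
  expect_error(cohort_spec(10, notch_depth_mean = -5), "non-negative")
  expect_error(cohort_spec(10, notch_center_probs = c("3" = 0.5, "4" = 0.2,
                                                      "6" = 0.2)),
               "sum to 1")
  expect_error(cohort_spec(10, age_range = c(15, 69)))
})

test_that("cohort CSVs round-trip through the csv pipeline input", {
  co <- generate_cohort(exact_detection_spec(300, seed = 50))
  af <- tempfile(fileext = ".csv"); df <- tempfile(fileext = ".csv")
  write_cohort_csv(co, af, df)
  back <- merge(utils::read.csv(af), utils::read.csv(df), by = "id")
  expect_identical(nrow(back), nrow(co))
  expect_equal(back$l_4000, co$l_4000)
  expect_equal(back$weight, co$weight)
})
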