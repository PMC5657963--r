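# Notch rule: worked examples, validation, and rule properties.

make_ear <- function(...) ear_audiogram(c(...))

test_that("classify_ear_notch reproduces the worked examples", {
  cases <- list(
    # 4 kHz exceeds baseline 10 by 20; 8 kHz (20) is 10 below max high (30)
    list(th = c("0.5" = 10, "1" = 10, "3" = 10, "4" = 30, "6" = 15, "8" = 20),
         notch = TRUE),
    # flat audiogram: zero depth
    list(th = c("0.5" = 10, "1" = 10, "2" = 10, "3" = 10, "4" = 10,
                "6" = 10, "8" = 10),
         notch = FALSE),
    # boundary case: depth exactly 15, recovery exactly 5 — both inclusive
    list(th = c("0.5" = 5, "1" = 5, "3" = 10, "4" = 20, "6" = 10, "8" = 15),
         notch = TRUE),
    # sloping loss: no recovery at 8 kHz
    list(th = c("0.5" = 10, "1" = 10, "3" = 30, "4" = 40, "6" = 50, "8" = 50),
         notch = FALSE)
  )
  for (cs in cases) {
    res <- classify_ear_notch(make_ear(cs$th))
    expect_true(res$classifiable)
    expect_identical(res$notch_present, cs$notch)
  }

  # diagnostics recompute directly from the first case
  res <- classify_ear_notch(make_ear(c("0.5" = 10, "1" = 10, "3" = 10,
                                       "4" = 30, "6" = 15, "8" = 20)))
  expect_equal(res$baseline_low_freq, 10)
  expect_equal(res$max_high_freq, 30)
  expect_equal(res$notch_depth, 20)
  expect_equal(res$recovery_margin, 10)
})

test_that("an ear missing any rule frequency is unclassifiable", {
  res <- classify_ear_notch(make_ear(c("0.5" = 10, "1" = 10, "3" = 10,
                                       "4" = 30, "8" = 20)))  # 6 kHz absent
  expect_false(res$classifiable)
  expect_false(res$notch_present)
  expect_true(is.na(res$notch_depth))

  # 2 kHz is carried but never required nor consulted
  with2 <- classify_ear_notch(make_ear(c("0.5" = 10, "1" = 10, "2" = 120,
                                         "3" = 10, "4" = 30, "6" = 15,
                                         "8" = 20)))
  without2 <- classify_ear_notch(make_ear(c("0.5" = 10, "1" = 10, "3" = 10,
                                            "4" = 30, "6" = 15, "8" = 20)))
  expect_identical(with2$notch_present, without2$notch_present)
})

test_that("audiogram validation names the offending field", {
  expect_error(make_ear(c("0.5" = 10, "2.5" = 10)), "2.5")
  expect_error(make_ear(c("0.5" = 10, "4" = 125)), "4 kHz")
  expect_error(make_ear(c("0.5" = -15, "4" = 10)), "0.5 kHz")
  expect_warning(make_ear(c("0.5" = 12, "1" = 10)), "multiple of 5")
})

test_that("participant categories follow the two-ear contract", {
  notch <- classify_ear_notch(make_ear(c("0.5" = 10, "1" = 10, "3" = 10,
                                         "4" = 30, "6" = 15, "8" = 20)))
  clean <- classify_ear_notch(make_ear(c("0.5" = 10, "1" = 10, "3" = 10,
                                         "4" = 10, "6" = 10, "8" = 10)))
  unc <- classify_ear_notch(make_ear(c("0.5" = 10, "1" = 10)))

  expect_identical(classify_participant(notch, notch)$category, "bilateral")
  expect_identical(classify_participant(notch, clean)$category, "unilateral")
  expect_identical(classify_participant(clean, notch)$category, "unilateral")
  expect_identical(classify_participant(clean, clean)$category, "none")
  expect_identical(classify_participant(unc, notch)$category, "unclassifiable")
})

test_that("grid audit enumerates and matches the literal oracle", {
  grid <- audit_notch_rule()   # {0, 20} at each of 6 frequencies
  expect_identical(nrow(grid), 64L)
  expect_identical(grid$notch_present, oracle_notch_rows(grid))

  # every 8 kHz value above all high-frequency values: recovery impossible
  g2 <- audit_notch_rule(list("8" = c(60, 80),
                              "3" = c(0, 20), "4" = c(0, 20),
                              "6" = c(0, 20)))
  expect_identical(sum(g2$notch_present), 0L)

  expect_error(audit_notch_rule(list("0.5" = seq(0, 100, 5)), cap = 100),
               "cap")
})

test_that("rule agrees with the oracle on an exhaustive grid", {
  vals <- seq(0, 30, 10)
  grid <- audit_notch_rule(setNames(rep(list(vals), 6),
                                    c("0.5", "1", "3", "4", "6", "8")),
                           cap = 5000)
  expect_identical(nrow(grid), as.integer(length(vals)^6))
  expect_identical(grid$notch_present, oracle_notch_rows(grid))
})

test_that("raising a high-frequency threshold never destroys a notch", {
  set.seed(11)
  for (i in 1:200) {
    th <- c("0.5" = 5 * sample(0:8, 1), "1" = 5 * sample(0:8, 1),
            "3" = 5 * sample(0:16, 1), "4" = 5 * sample(0:16, 1),
            "6" = 5 * sample(0:16, 1), "8" = 0)  # 8 kHz fixed low
    base <- classify_ear_notch(make_ear(th))
    f <- sample(c("3", "4", "6"), 1)
    th2 <- th
    th2[f] <- min(th2[f] + 5 * sample(1:4, 1), 120)
    raised <- classify_ear_notch(make_ear(th2))
    if (base$notch_present) expect_true(raised$notch_present)
  }
})

test_that("the rule is invariant to a constant shift of all thresholds", {
  set.seed(12)
  for (i in 1:200) {
    th <- setNames(5 * sample(0:12, 6, replace = TRUE),
                   c("0.5", "1", "3", "4", "6", "8"))
    shift <- 5 * sample(-2:4, 1)
    th2 <- pmin(pmax(th + shift, -10), 120)
    if (any(th2 != th + shift)) next  # clipped: shift not constant
    a <- classify_ear_notch(make_ear(th))
    b <- classify_ear_notch(make_ear(th2))
    expect_identical(a$notch_present, b$notch_present)
    if (a$classifiable) expect_equal(a$notch_depth, b$notch_depth)
  }
})

test_that("classify_audiograms matches ear-by-ear classification", {
  set.seed(13)
  n <- 50
  df <- as.data.frame(setNames(
    lapply(1:14, function(i) 5 * sample(0:12, n, replace = TRUE)),
    as.vector(outer(c("l", "r"), c(500, 1000, 2000, 3000, 4000, 6000, 8000),
                    paste, sep = "_"))
  ))
  df$l_6000[1:5] <- NA  # unclassifiable left ears
  out <- classify_audiograms(df)
  expect_identical(as.character(out$notch_category[1:5]),
                   rep("unclassifiable", 5))
  for (i in sample(6:n, 10)) {
    le <- classify_ear_notch(make_ear(setNames(
      as.numeric(df[i, paste0("l_", c(500, 1000, 3000, 4000, 6000, 8000))]),
      c("0.5", "1", "3", "4", "6", "8"))))
    re <- classify_ear_notch(make_ear(setNames(
      as.numeric(df[i, paste0("r_", c(500, 1000, 3000, 4000, 6000, 8000))]),
      c("0.5", "1", "3", "4", "6", "8"))))
    expect_identical(as.character(out$notch_category[i]),
                     classify_participant(le, re)$category)
  }
})
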