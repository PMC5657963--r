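# SAS XPORT round-trips and config-driven harmonization, on fixtures
# built in code.

test_that("XPT writer round-trips bit-exactly through the reader", {
  df <- data.frame(SEQN = c(1, 2, 3), VALA = c(25.5, NA, -42),
                   VALB = c(1e4, 0.1, 123456.789))
  path <- tempfile(fileext = ".xpt")
  notchsurv:::write_xpt(df, path, "FIX")
  back <- read_xpt_table(path)
  expect_identical(dim(back), c(3L, 2L + 1L))
  expect_identical(unname(as.matrix(back)), unname(as.matrix(df)))

  # SAS missing comes back as NA, never 0
  expect_true(is.na(back$VALA[2]))

  # stress the IBM float encoding across magnitudes and signs
  set.seed(61)
  x <- c(0, -0.5, 2^-20, -2^30, pi, exp(1), 5 * (-2:24),
         rlnorm(50, 0, 10), -rlnorm(50, 0, 10))
  df2 <- data.frame(X = x)
  p2 <- tempfile(fileext = ".xpt")
  notchsurv:::write_xpt(df2, p2)
  expect_identical(read_xpt_table(p2)$X, x)
})

test_that("empty tables and malformed files are handled", {
  p <- tempfile(fileext = ".xpt")
  notchsurv:::write_xpt(data.frame(A = numeric(0), B = numeric(0)), p)
  empty <- read_xpt_table(p)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), c("A", "B"))

  txt <- tempfile(fileext = ".xpt")
  writeLines("this is not a transport file", txt)
  expect_error(read_xpt_table(txt), "not a SAS XPORT")
  expect_error(read_xpt_table(tempfile()), "not found")
})

# Fixture tables in the shipped variable map's vocabulary.
fixture_tables <- function() {
  demo <- data.frame(
    SEQN = c(1, 2, 3, 4, 5),
    RIDAGEYR = c(25, 40, 60, 19, 69),
    RIAGENDR = c(1, 2, 1, 1, 2),
    RIDRETH1 = c(3, 4, 1, 3, 5),
    DMDEDUC2 = c(5, 3, 1, 4, 9),
    INDFMPIR = c(1.0, 5.0, 2.3, 0.5, NA),
    WTMEC2YR = c(1e4, 2e4, 1.5e4, 1e4, 3e4),
    SDMVSTRA = c(90, 90, 91, 91, 92),
    SDMVPSU = c(1, 2, 1, 2, 1)
  )
  aux <- data.frame(SEQN = c(1, 2, 3, 5))
  th <- list(c(10, 10, 10, 30, 15, 20, 10),   # notch at 4 kHz
             c(5, 5, 5, 5, 5, 5, 5),          # flat
             c(10, 10, 20, 888, 25, 20, 15),  # 3 kHz not testable
             c(15, 15, 15, 15, 35, 20, 15))   # notch at 6 kHz
  cols <- c("500", "1K1", "2K", "3K", "4K", "6K", "8K")
  for (j in seq_along(cols)) {
    aux[[paste0("AUXU", cols[j], "R")]] <- vapply(th, `[`, 0, j)
    aux[[paste0("AUXU", cols[j], "L")]] <- vapply(th, `[`, 0, j)
  }
  auq <- data.frame(SEQN = c(1, 2, 3),
                    AUQ370 = c(1, 2, 2), AUQ054 = c(1, 2, 3))
  list(demo = demo, aux = aux, auq = auq)
}

test_that("merge and harmonize collapses codes and filters age", {
  tabs <- fixture_tables()
  map <- default_variable_map()
  expect_message(rec <- merge_and_harmonize(tabs, map), "outside ages")
  # participant 4 is 19 and dropped; drop is logged
  expect_identical(nrow(rec), 4L)
  expect_identical(attr(rec, "n_dropped_age"), 1L)
  expect_false(4 %in% rec$id)

  # PIR boundaries: 1.0 -> "<=1", 5.0 -> ">=5"
  expect_identical(rec$pir[rec$id == 1], "<=1")
  expect_identical(rec$pir[rec$id == 2], ">=5")
  expect_identical(rec$pir[rec$id == 3], ">1 to <5")
  expect_true(is.na(rec$pir[rec$id == 5]))

  # code collapses
  expect_identical(rec$sex[rec$id == 1], "Male")
  expect_identical(rec$race[rec$id == 3], "Mexican American")
  expect_identical(rec$education[rec$id == 3], "Less than high school")
  expect_true(is.na(rec$education[rec$id == 5]))  # refused -> NA
  expect_identical(rec$exposure[rec$id == 1], "Yes")
  expect_identical(rec$hearing[rec$id == 3], "Trouble hearing")

  # participant 5 shares no questionnaire row: missing block, not dropped
  expect_true(is.na(rec$exposure[rec$id == 5]))

  # audiometric sentinel 888 became a missing threshold
  expect_true(is.na(rec$r_3000[rec$id == 3]))
})

test_that("harmonization errors on duplicates and unmapped codes", {
  tabs <- fixture_tables()
  map <- default_variable_map()
  dup <- tabs
  dup$auq <- rbind(dup$auq, dup$auq[1, ])
  expect_error(merge_and_harmonize(dup, map), "duplicate ids")

  badcode <- tabs
  badcode$demo$RIAGENDR[1] <- 3
  expect_error(suppressMessages(merge_and_harmonize(badcode, map)),
               "unmapped code '3' for variable 'sex'")
})

test_that("harmonized XPT fixtures flow through the inclusion filters", {
  tabs <- fixture_tables()
  paths <- lapply(names(tabs), function(nm) {
    p <- tempfile(fileext = ".xpt")
    notchsurv:::write_xpt(tabs[[nm]], p, toupper(nm))
    p
  })
  tabs2 <- lapply(paths, read_xpt_table)
  names(tabs2) <- names(tabs)
  rec <- suppressMessages(merge_and_harmonize(tabs2,
                                              default_variable_map()))
  out <- apply_inclusion_filters(rec)
  # of the 4 age-eligible: id 1, 2, 5 complete; id 3 lacks 3 kHz
  expect_identical(out$report$interviewed, 4L)
  expect_identical(out$report$complete_audiometry, 3L)
  expect_identical(out$report$analytic_n, 3L)
  expect_equal(out$report$response_rate, 75)
  expect_identical(sort(out$records$id), c(1, 2, 5))
  # notch classification carried through: id 1 notched both ears
  expect_identical(as.character(
    out$records$notch_category[out$records$id == 1]), "bilateral")
})

test_that("inclusion counts are non-increasing along the chain", {
  spec <- cohort_spec(500, seed = 62, missing_rate = 0.04)
  co <- generate_cohort(spec)
  out <- apply_inclusion_filters(co)
  r <- out$report
  expect_lte(r$analytic_n, r$complete_audiometry)
  expect_lte(r$complete_audiometry, r$examined)
  expect_lte(r$examined, r$interviewed)
  expect_true(r$response_rate >= 0 && r$response_rate <= 100)
  expect_identical(r$analytic_n, as.integer(nrow(out$records)))
})

test_that("variable map validation names the missing block", {
  m <- yaml::read_yaml(system.file("extdata", "nhanes_2011_2012_map.yaml",
                                   package = "notchsurv"))
  m$design$psu <- NULL
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(m, p)
  expect_error(read_variable_map(p), "psu")
})
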