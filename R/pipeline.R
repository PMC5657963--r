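# End-to-end orchestration: input -> notch classification -> inclusion
# filters -> design-based estimate tables (prevalence % (SE) and OR
# (95% CI) per characteristic, overall and stratified by work-noise
# exposure), with full-precision intermediates and render-time rounding.

default_characteristics <- function() {
  list(sex = "Male",
       age_group = "20-29",
       race = "White non-Hispanic",
       education = "More than high school",
       pir = ">=5",
       exposure = "No",
       hearing = "Excellent/good")
}

#' Configure an end-to-end notch prevalence analysis
#'
#' @param input `"synthetic"` (generate a cohort from `cohort_spec`),
#'   `"csv"` (generic audiogram + design CSVs) or `"nhanes"` (SAS XPORT
#'   files plus a variable map).
#' @param cohort_spec A [cohort_spec()] (synthetic mode).
#' @param audiogram_file,design_file CSV paths (csv mode). The design CSV
#'   may be omitted when the audiogram CSV already carries `weight`,
#'   `stratum`, `psu`.
#' @param nhanes_files Named list of XPT paths, demographics table first
#'   (nhanes mode).
#' @param variable_map A [read_variable_map()]; defaults to the shipped
#'   map (nhanes mode).
#' @param characteristics Named list mapping characteristic column to its
#'   referent level. The default referents: sex Male, age group 20-29,
#'   race White non-Hispanic, education more than high school, poverty
#'   income ratio >=5, work-noise exposure No, self-reported hearing
#'   excellent/good.
#' @param outcomes Subset of `c("any", "bilateral", "unilateral")`.
#' @param stratify_by Optional characteristic (typically `"exposure"`) to
#'   repeat the whole table within each of its levels (the Table-2
#'   layout).
#' @param out_dir Optional directory: writes `table1.csv`, `table2.csv`
#'   (when stratified), `inclusion.json` and `log.jsonl`.
#' @param seed Seed for synthetic mode when `cohort_spec` is absent.
#' @param lonely_psu Passed to [survey_design()].
#'
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(input = c("synthetic", "csv", "nhanes"),
                            cohort_spec = NULL,
                            audiogram_file = NULL, design_file = NULL,
                            nhanes_files = NULL, variable_map = NULL,
                            characteristics = default_characteristics(),
                            outcomes = c("any", "bilateral", "unilateral"),
                            stratify_by = NULL,
                            out_dir = NULL, seed = 1L,
                            lonely_psu = "error") {
  input <- match.arg(input)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  if (input == "synthetic") {
    if (is.null(cohort_spec)) {
      cohort_spec <- cohort_spec(n_participants = 2000L, seed = seed)
    }
    stopifnot(inherits(cohort_spec, "cohort_spec"))
  }
  if (input == "csv" && is.null(audiogram_file)) {
    stop("csv mode needs `audiogram_file`", call. = FALSE)
  }
  if (input == "nhanes") {
    if (is.null(nhanes_files)) stop("nhanes mode needs `nhanes_files`",
                                    call. = FALSE)
    if (is.null(variable_map)) variable_map <- default_variable_map()
  }
  if (!is.null(stratify_by) && !stratify_by %in% names(characteristics)) {
    stop(sprintf("`stratify_by` ('%s') is not a configured characteristic",
                 stratify_by), call. = FALSE)
  }
  structure(list(
    input = input, cohort_spec = cohort_spec,
    audiogram_file = audiogram_file, design_file = design_file,
    nhanes_files = nhanes_files, variable_map = variable_map,
    characteristics = characteristics, outcomes = outcomes,
    stratify_by = stratify_by, out_dir = out_dir, seed = as.integer(seed),
    lonely_psu = lonely_psu
  ), class = "analysis_config")
}

load_pipeline_input <- function(config) {
  switch(config$input,
    synthetic = {
      cohort <- generate_cohort(config$cohort_spec)
      list(records = cohort, interviewed = nrow(cohort))
    },
    csv = {
      rec <- utils::read.csv(config$audiogram_file, stringsAsFactors = FALSE)
      if (!is.null(config$design_file)) {
        des <- utils::read.csv(config$design_file, stringsAsFactors = FALSE)
        rec <- merge(rec, des, by = "id", sort = TRUE)
      }
      list(records = rec, interviewed = nrow(rec))
    },
    nhanes = {
      tables <- lapply(config$nhanes_files, read_xpt_table)
      rec <- merge_and_harmonize(tables, config$variable_map)
      list(records = rec, interviewed = nrow(rec))
    }
  )
}

outcome_column <- c(any = "notch_any", bilateral = "notch_bilateral",
                    unilateral = "notch_unilateral")

# One table block: overall row + per-characteristic prevalence and OR rows
# within `stratum_domain` (logical over the design rows).
estimate_block <- function(data, design, config, stratum_label,
                           stratum_domain) {
  rows <- list()
  logs <- list()
  chars <- config$characteristics
  if (!is.null(config$stratify_by) && stratum_label != "overall") {
    chars <- chars[names(chars) != config$stratify_by]
  }
  for (oc in config$outcomes) {
    ycol <- outcome_column[[oc]]
    y <- data[[ycol]]
    dom_all <- stratum_domain & !is.na(y)
    prev <- svy_prevalence(ifelse(is.na(y), 0, y), design, dom_all,
                           label = stratum_label)
    rows[[length(rows) + 1]] <- data.frame(
      stratum = stratum_label, characteristic = "overall", level = "overall",
      outcome = oc, n = prev$n_unweighted, pct = prev$estimate,
      se = prev$se, weighted_count = prev$weighted_count,
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      referent = NA, stringsAsFactors = FALSE
    )
    for (ch in names(chars)) {
      f <- data[[ch]]
      if (is.null(f)) {
        stop(sprintf("characteristic '%s' not found in the data", ch),
             call. = FALSE)
      }
      f <- as.factor(f)
      referent <- chars[[ch]]
      if (!referent %in% levels(f)) {
        stop(sprintf(
          "config error: referent '%s' is not a level of characteristic '%s' (levels: %s)",
          referent, ch, paste(levels(f), collapse = ", ")
        ), call. = FALSE)
      }
      f <- stats::relevel(f, ref = referent)
      dom_fit <- dom_all & !is.na(f)
      fit_data <- data.frame(.y = ifelse(is.na(y), 0, y), .x = f)
      fit <- tryCatch(
        svy_logit(.y ~ .x, data = fit_data, design = design,
                  domain = dom_fit),
        error = function(e) {
          stop(sprintf("estimation failed for (%s, %s): %s",
                       ch, oc, conditionMessage(e)), call. = FALSE)
        }
      )
      ors <- odds_ratios(fit)
      ors$level <- sub("^\\.x", "", ors$level)
      logs[[length(logs) + 1]] <- list(
        stratum = stratum_label, outcome = oc, characteristic = ch,
        n_domain = sum(dom_fit), model = "svy_logit unadjusted",
        converged = fit$converged
      )
      for (i in seq_len(nrow(ors))) {
        lev <- ors$level[i]
        dom_lev <- dom_fit & f == lev
        prev_l <- svy_prevalence(ifelse(is.na(y), 0, y), design, dom_lev,
                                 label = paste(stratum_label, ch, lev))
        rows[[length(rows) + 1]] <- data.frame(
          stratum = stratum_label, characteristic = ch, level = lev,
          outcome = oc, n = prev_l$n_unweighted, pct = prev_l$estimate,
          se = prev_l$se, weighted_count = prev_l$weighted_count,
          or = ors$or[i], ci_low = ors$ci_low[i], ci_high = ors$ci_high[i],
          referent = ors$referent[i], stringsAsFactors = FALSE
        )
      }
    }
  }
  list(rows = do.call(rbind, rows), logs = logs)
}

#' Run the full analysis pipeline
#'
#' Loads (or generates) the cohort, classifies every audiogram with the
#' notch rule, applies the completeness inclusion filter, builds the
#' survey design over all age-eligible records (analytic exclusions are
#' handled as zero-weight domains, preserving the design structure for
#' variance), and produces the estimate table: for each outcome (any /
#' bilateral / unilateral notch) the overall prevalence and, per
#' characteristic, per-level prevalence % (SE) plus unadjusted
#' survey-weighted odds ratios with 95% CIs. With
#' `stratify_by = "exposure"` the whole block is repeated within each
#' exposure level (the Table-2 layout).
#'
#' Identical config and seed always give identical output. All stored
#' numbers are full precision; rounding happens in [render_table()].
#'
#' @param config An [analysis_config()].
#'
#' @return An object of class `notch_analysis`: a list with `table` (the
#'   estimate data.frame), `inclusion` (an `inclusion_report`), `log`
#'   (one record per fitted model), `design_df` (design degrees of
#'   freedom) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  input <- load_pipeline_input(config)
  filtered <- apply_inclusion_filters(input$records,
                                      interviewed = input$interviewed)
  # Keep every record in the design; analysis domains select the
  # classifiable subset.
  all_classified <- classify_audiograms(input$records)
  design <- survey_design(all_classified$weight, all_classified$stratum,
                          all_classified$psu,
                          lonely_psu = config$lonely_psu)
  analytic_domain <- all_classified$classifiable

  strata_spec <- list(overall = analytic_domain)
  if (!is.null(config$stratify_by)) {
    sv <- as.factor(all_classified[[config$stratify_by]])
    for (lev in levels(sv)) {
      strata_spec[[paste0(config$stratify_by, "=", lev)]] <-
        analytic_domain & !is.na(sv) & sv == lev
    }
  }

  rows <- list()
  logs <- list()
  for (sl in names(strata_spec)) {
    blk <- estimate_block(all_classified, design, config, sl,
                          strata_spec[[sl]])
    rows[[sl]] <- blk$rows
    logs <- c(logs, blk$logs)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  result <- structure(list(
    table = table, inclusion = filtered$report, log = logs,
    design_df = degf(design), config = config
  ), class = "notch_analysis")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    render_table(table[table$stratum == "overall", ],
                 file = file.path(config$out_dir, "table1.csv"))
    if (!is.null(config$stratify_by)) {
      render_table(table[table$stratum != "overall", ],
                   file = file.path(config$out_dir, "table2.csv"))
    }
    jsonlite::write_json(unclass(filtered$report),
                         file.path(config$out_dir, "inclusion.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(vapply(logs, function(l)
      as.character(jsonlite::toJSON(l, auto_unbox = TRUE)), character(1)),
      file.path(config$out_dir, "log.jsonl"))
  }
  result
}

#' @export
print.notch_analysis <- function(x, ...) {
  cat("Notch prevalence analysis\n")
  print(x$inclusion)
  cat(sprintf("design df = %d; %d estimate rows; %d fitted models\n",
              x$design_df, nrow(x$table), length(x$log)))
  ov <- x$table[x$table$stratum == "overall" &
                  x$table$characteristic == "overall", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-10s notch: %.1f%% (SE %.2f)\n",
                ov$outcome[i], ov$pct[i], ov$se[i]))
  }
  invisible(x)
}

#' Render an estimate table in publication style
#'
#' Formats a [run_pipeline()] table with the publication rounding rules:
#' prevalence and SE to one decimal, odds ratios and confidence bounds to
#' two decimals, referent rows showing `"Referent"` in the OR column and
#' overall rows an em-dash.
#'
#' @param table The `table` element of a `notch_analysis` (or a subset).
#' @param style `"csv"` for one formatted column per quantity, `"text"`
#'   for combined `% (SE)` / `OR (95% CI)` display columns.
#' @param file Optional path; the rendered table is written as CSV.
#'
#' @return The rendered data.frame (character columns), invisibly when
#'   `file` is given.
#' @export
render_table <- function(table, style = c("csv", "text"), file = NULL) {
  style <- match.arg(style)
  f1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
  f2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  or_cell <- function(or, lo, hi, ref) {
    ifelse(is.na(or), "—",
           ifelse(!is.na(ref) & ref, "Referent",
                  if (style == "text") {
                    sprintf("%s (%s–%s)", f2(or), f2(lo), f2(hi))
                  } else f2(or)))
  }
  out <- data.frame(
    stratum = table$stratum, characteristic = table$characteristic,
    level = table$level, outcome = table$outcome, n = table$n,
    stringsAsFactors = FALSE
  )
  if (style == "text") {
    out$pct_se <- sprintf("%s (%s)", f1(table$pct), f1(table$se))
    out$or_ci <- or_cell(table$or, table$ci_low, table$ci_high,
                         table$referent)
  } else {
    out$pct <- f1(table$pct)
    out$se <- f1(table$se)
    out$or <- or_cell(table$or, table$ci_low, table$ci_high,
                      table$referent)
    out$ci_low <- ifelse(!is.na(table$referent) & table$referent, "",
                         f2(table$ci_low))
    out$ci_high <- ifelse(!is.na(table$referent) & table$referent, "",
                          f2(table$ci_high))
    out$referent_flag <- ifelse(is.na(table$referent), "",
                                ifelse(table$referent, "1", "0"))
  }
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
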