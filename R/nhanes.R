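# Reading and harmonizing health-survey microdata: SAS XPORT (v5) reader,
# a minimal numeric XPORT writer (used to build test fixtures in code), a
# config-driven variable map, and the inclusion-filter chain.

#' Read a SAS XPORT (v5) table
#'
#' Thin, validated wrapper around [foreign::read.xport()]: materializes
#' all rows and columns of the first data set in the file, with SAS
#' numeric missing values mapped to `NA`.
#'
#' @param path Path to a `.XPT` file.
#' @return A data.frame.
#' @export
read_xpt_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  head <- readBin(path, "raw", 80)
  magic <- "HEADER RECORD*******LIBRARY HEADER RECORD!!!!!!!"
  if (length(head) < 80 ||
      !identical(rawToChar(head[seq_len(nchar(magic))]), magic)) {
    stop(sprintf("not a SAS XPORT (v5) file: %s", path), call. = FALSE)
  }
  out <- tryCatch(
    foreign::read.xport(path),
    error = function(e) {
      stop(sprintf("failed to parse XPORT file %s: %s",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  if (is.list(out) && !is.data.frame(out)) out <- out[[1]]
  as.data.frame(out)
}

# ---- minimal XPORT v5 writer (numeric variables only) ----------------------
# Enough of the SAS transport format to emit fixture files that
# foreign::read.xport parses: 80-byte records, member/namestr/obs headers,
# and IBM hexadecimal floating point for the data.

# Encode one double as an 8-byte IBM hex float. The mantissa of an IEEE
# double (53 bits) always fits the IBM 56-bit mantissa, so the encoding is
# exact and round-trips bit-for-bit. NA encodes as the SAS missing value
# ('.' then seven zero bytes).
ieee_to_ibm <- function(x) {
  if (is.na(x)) return(as.raw(c(0x2e, rep(0L, 7))))
  if (x == 0) return(raw(8))
  sign <- if (x < 0) 0x80 else 0x00
  a <- abs(x)
  e2 <- floor(log2(a)) + 1          # a = f * 2^e2 with f in [0.5, 1)
  f <- a / 2^e2
  while (f >= 1) { e2 <- e2 + 1; f <- a / 2^e2 }
  while (f < 0.5) { e2 <- e2 - 1; f <- a / 2^e2 }
  k <- ceiling(e2 / 4)              # a = m * 16^k with m in [1/16, 1)
  s <- 4 * k - e2                   # 0..3
  if (k + 64 < 0 || k + 64 > 127) {
    stop(sprintf("value %g outside IBM hex float exponent range", x),
         call. = FALSE)
  }
  M <- f * 2^(56 - s)               # exact: power-of-two scaling
  bytes <- integer(7)
  for (i in 7:1) {
    bytes[i] <- M %% 256
    M <- (M - bytes[i]) / 256
  }
  as.raw(c(bitwOr(as.integer(sign), as.integer(k + 64)), bytes))
}

pad80 <- function(s) {
  stopifnot(nchar(s) <= 80)
  sprintf("%-80s", s)
}

xpt_datetime <- function() {
  toupper(format(Sys.time(), "%d%b%y:%H:%M:%S"))
}

# Write a numeric-only data.frame as a SAS XPORT v5 file. Internal: exists
# to build test fixtures programmatically; real survey files come from the
# data provider.
write_xpt <- function(data, path, name = "DATA") {
  stopifnot(is.data.frame(data))
  if (!all(vapply(data, is.numeric, logical(1)))) {
    stop("write_xpt supports numeric variables only", call. = FALSE)
  }
  name <- toupper(substr(name, 1, 8))
  vnames <- toupper(substr(names(data), 1, 8))
  if (anyDuplicated(vnames)) {
    stop("variable names collide after truncation to 8 characters",
         call. = FALSE)
  }
  nvar <- ncol(data)
  dt <- xpt_datetime()

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeBin(charToRaw(pad80(s)), con)

  put(paste0("HEADER RECORD*******LIBRARY HEADER RECORD!!!!!!!",
             strrep("0", 30)))
  put(paste0(sprintf("%-8s%-8s%-8s%-8s%-8s", "SAS", "SAS", "SASLIB",
                     "9.4", "R"), strrep(" ", 24), dt))
  put(dt)
  put(paste0("HEADER RECORD*******MEMBER  HEADER RECORD!!!!!!!",
             strrep("0", 17), "1600000000140"))
  put(paste0("HEADER RECORD*******DSCRPTR HEADER RECORD!!!!!!!",
             strrep("0", 30)))
  put(paste0(sprintf("%-8s%-8s%-8s%-8s%-8s", "SAS", name, "SASDATA",
                     "9.4", "R"), strrep(" ", 24), dt))
  put(paste0(dt, strrep(" ", 64)))
  put(paste0("HEADER RECORD*******NAMESTR HEADER RECORD!!!!!!!",
             strrep("0", 6), sprintf("%04d", nvar), strrep("0", 20)))

  int2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "big")
  int4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  chr <- function(s, width) writeBin(charToRaw(sprintf("%-*s", width, s)), con)
  for (j in seq_len(nvar)) {
    int2(1)                 # ntype: numeric
    int2(0)                 # nhfun
    int2(8)                 # nlng
    int2(j)                 # nvar0
    chr(vnames[j], 8)       # nname
    chr("", 40)             # nlabel
    chr("", 8)              # nform
    int2(0); int2(0); int2(0)  # nfl, nfd, nfj
    chr("", 2)              # nfill
    chr("", 8)              # niform
    int2(0); int2(0)        # nifl, nifd
    int4((j - 1) * 8)       # npos
    chr("", 52)             # remainder of the 140-byte namestr
  }
  namestr_bytes <- nvar * 140
  pad <- (80 - namestr_bytes %% 80) %% 80
  if (pad > 0) chr("", pad)

  put(paste0("HEADER RECORD*******OBS     HEADER RECORD!!!!!!!",
             strrep("0", 30)))
  for (i in seq_len(nrow(data))) {
    for (j in seq_len(nvar)) {
      writeBin(ieee_to_ibm(as.numeric(data[i, j])), con)
    }
  }
  data_bytes <- nrow(data) * nvar * 8
  pad <- (80 - data_bytes %% 80) %% 80
  if (pad > 0) chr("", pad)
  invisible(path)
}

# ---- variable map ----------------------------------------------------------

#' Read a variable map from YAML
#'
#' A variable map tells the harmonizer which columns of the source files
#' carry each analysis variable and how raw codes collapse into analysis
#' categories. No source variable name is hard-coded in the package; the
#' shipped default map (`default_variable_map()`) encodes one reading of
#' the NHANES 2011-2012 codebooks and can be replaced wholesale.
#'
#' The YAML schema has blocks `id`, `demographics` (`age`, `sex`, `race`,
#' `education`, `pir`), `design` (`weight`, `stratum`, `psu`),
#' `questionnaire` (`exposure`, `hearing`) and `audiometry` (`right` and
#' `left` frequency-to-column maps in Hz, optional `retest_1k` with
#' `policy` one of `primary`, `best`, `mean`, and optional
#' `missing_codes`). Coded variables give a `codes` mapping from raw code
#' to category label; the label `.na` marks codes (refused, don't know)
#' that become missing. A raw value absent from `codes` is an error, never
#' a silent drop.
#'
#' @param path Path to the YAML file.
#' @return An object of class `variable_map`.
#' @export
read_variable_map <- function(path) {
  m <- yaml::read_yaml(path)
  required <- c("id", "demographics", "design", "questionnaire", "audiometry")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    stop("variable map missing block(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (blk in c("age", "sex", "race", "education", "pir")) {
    if (is.null(m$demographics[[blk]])) {
      stop("variable map demographics block missing: ", blk, call. = FALSE)
    }
  }
  for (blk in c("weight", "stratum", "psu")) {
    if (is.null(m$design[[blk]])) {
      stop("variable map design block missing: ", blk, call. = FALSE)
    }
  }
  for (side in c("right", "left")) {
    cols <- m$audiometry[[side]]
    need <- as.character(RULE_FREQS * 1000)
    if (is.null(cols) || !all(need %in% names(cols))) {
      stop(sprintf("audiometry map for %s ear must cover %s Hz",
                   side, paste(need, collapse = ", ")), call. = FALSE)
    }
  }
  class(m) <- "variable_map"
  m
}

#' @rdname read_variable_map
#' @export
default_variable_map <- function() {
  read_variable_map(system.file("extdata", "nhanes_2011_2012_map.yaml",
                                package = "notchsurv", mustWork = TRUE))
}

# Collapse raw codes into category labels per the map; unmapped non-missing
# codes are an explicit error.
apply_codes <- function(x, codes, varname) {
  labels <- vapply(codes, function(v) as.character(v)[1], character(1))
  raw <- as.character(as.vector(x))
  out <- rep(NA_character_, length(x))
  present <- !is.na(x)
  bad <- present & !raw %in% names(labels)
  if (any(bad)) {
    stop(sprintf("unmapped code '%s' for variable '%s'",
                 raw[which(bad)[1]], varname), call. = FALSE)
  }
  out[present] <- labels[raw[present]]
  out[out == ".na"] <- NA_character_
  out
}

#' Merge source tables and harmonize to analysis variables
#'
#' Left-joins every table onto the first (the demographics table) by the
#' map's participant id, applies the category collapses of the
#' [read_variable_map()], derives the poverty-income-ratio category
#' (`<=1`, `>1 to <5`, `>=5` — both cut points inclusive outward, so PIR
#' 1.0 is `<=1` and 5.0 is `>=5`), reconciles the 1 kHz retest per the
#' map's policy, and drops participants outside ages 20-69 (count logged
#' as attribute `n_dropped_age` and message).
#'
#' @param tables Named list of data.frames; the first must be the
#'   demographics table carrying the id of every interviewed participant.
#' @param map A [read_variable_map()].
#'
#' @return A data.frame of participant records in the generic analysis
#'   layout (`id`, demographics, design columns, `l_500` ... `r_8000`),
#'   with attribute `n_input` (rows before the age filter) and
#'   `n_dropped_age`.
#' @export
merge_and_harmonize <- function(tables, map) {
  stopifnot(inherits(map, "variable_map"), is.list(tables),
            length(tables) >= 1)
  id <- map$id
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (!id %in% names(tab)) {
      stop(sprintf("id column '%s' missing from table '%s'", id, nm),
           call. = FALSE)
    }
    if (anyDuplicated(tab[[id]])) {
      stop(sprintf("duplicate ids in table '%s'", nm), call. = FALSE)
    }
  }
  merged <- tables[[1]]
  for (nm in names(tables)[-1]) {
    merged <- merge(merged, tables[[nm]], by = id, all.x = TRUE,
                    sort = TRUE)
  }

  getcol <- function(column, context) {
    if (!column %in% names(merged)) {
      stop(sprintf("mapped column '%s' (%s) not found in supplied tables",
                   column, context), call. = FALSE)
    }
    merged[[column]]
  }

  dm <- map$demographics
  age <- as.numeric(getcol(dm$age, "age"))
  out <- data.frame(id = merged[[id]], age = age)
  out$sex <- apply_codes(getcol(dm$sex$column, "sex"), dm$sex$codes, "sex")
  out$race <- apply_codes(getcol(dm$race$column, "race"), dm$race$codes,
                          "race")
  out$education <- apply_codes(getcol(dm$education$column, "education"),
                               dm$education$codes, "education")
  pir_val <- as.numeric(getcol(dm$pir$column, "pir"))
  out$pir <- ifelse(is.na(pir_val), NA_character_,
             ifelse(pir_val <= 1, "<=1",
             ifelse(pir_val >= 5, ">=5", ">1 to <5")))

  qn <- map$questionnaire
  out$exposure <- apply_codes(getcol(qn$exposure$column, "exposure"),
                              qn$exposure$codes, "exposure")
  out$hearing <- apply_codes(getcol(qn$hearing$column, "hearing"),
                             qn$hearing$codes, "hearing")

  out$weight <- as.numeric(getcol(map$design$weight, "weight"))
  out$stratum <- getcol(map$design$stratum, "stratum")
  out$psu <- getcol(map$design$psu, "psu")

  miss_codes <- as.numeric(map$audiometry$missing_codes)
  clean <- function(v) {
    v <- as.numeric(v)
    if (length(miss_codes) > 0) v[v %in% miss_codes] <- NA_real_
    v
  }
  for (side in c("right", "left")) {
    pre <- if (side == "right") "r_" else "l_"
    cols <- map$audiometry[[side]]
    for (hz in names(cols)) {
      out[[paste0(pre, hz)]] <- clean(getcol(cols[[hz]],
                                             paste(side, hz, "Hz")))
    }
    rt <- map$audiometry$retest_1k
    if (!is.null(rt) && !is.null(rt[[side]]) &&
        rt[[side]] %in% names(merged)) {
      retest <- clean(merged[[rt[[side]]]])
      primary <- out[[paste0(pre, "1000")]]
      policy <- if (is.null(rt$policy)) "primary" else rt$policy
      out[[paste0(pre, "1000")]] <- switch(policy,
        primary = ifelse(is.na(primary), retest, primary),
        best = pmin(primary, retest, na.rm = TRUE),
        mean = ifelse(is.na(primary), retest,
               ifelse(is.na(retest), primary, (primary + retest) / 2)),
        stop(sprintf("unknown retest policy '%s'", policy), call. = FALSE)
      )
    }
  }

  n_input <- nrow(out)
  keep <- !is.na(out$age) & out$age >= 20 & out$age <= 69
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("dropped %d participant(s) outside ages 20-69", dropped))
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- n_input
  attr(out, "n_dropped_age") <- dropped
  out
}

#' Apply the analytic inclusion filters
#'
#' Restricts harmonized records to participants with complete audiometric
#' data — both ears classifiable under the notch rule (all of 0.5, 1, 3,
#' 4, 6, 8 kHz present in each ear) — and reports the counts at every
#' step plus the response rate, defined as 100 x analytic n / interviewed
#' n within the age range.
#'
#' @param records Harmonized records from [merge_and_harmonize()] (or any
#'   data.frame in the generic audiogram layout).
#' @param interviewed Number of age-eligible interviewed participants the
#'   response rate is computed against; defaults to `nrow(records)`.
#'
#' @return A list with `records` (the analytic subset, classified — see
#'   [classify_audiograms()]) and `report`, an `inclusion_report` with
#'   fields `interviewed`, `examined`, `complete_audiometry`,
#'   `analytic_n`, `response_rate`.
#' @export
apply_inclusion_filters <- function(records, interviewed = nrow(records)) {
  classified <- classify_audiograms(records)
  th_cols <- as.vector(outer(c("l", "r"), RULE_FREQS * 1000, paste,
                             sep = "_"))
  examined <- rowSums(!is.na(classified[th_cols])) > 0
  complete <- classified$classifiable
  analytic <- classified[complete, , drop = FALSE]
  rownames(analytic) <- NULL
  report <- structure(list(
    interviewed = as.integer(interviewed),
    examined = as.integer(sum(examined)),
    complete_audiometry = as.integer(sum(complete)),
    analytic_n = as.integer(nrow(analytic)),
    response_rate = 100 * nrow(analytic) / interviewed
  ), class = "inclusion_report")
  stopifnot(report$analytic_n <= report$complete_audiometry,
            report$complete_audiometry <= report$interviewed ||
              report$interviewed == nrow(records))
  list(records = analytic, report = report)
}

#' @export
print.inclusion_report <- function(x, ...) {
  cat("Inclusion report\n")
  cat(sprintf("  interviewed (age-eligible): %d\n", x$interviewed))
  cat(sprintf("  examined (any audiometry):  %d\n", x$examined))
  cat(sprintf("  complete audiometric data:  %d\n", x$complete_audiometry))
  cat(sprintf("  analytic n:                 %d\n", x$analytic_n))
  cat(sprintf("  response rate:              %.1f%%\n", x$response_rate))
  invisible(x)
}
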