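# Audiogram data model and the high-frequency notch classification rule.

# Frequencies (kHz) carried by the data model. 2 kHz is recorded but plays no
# part in the notch rule.
AUDIOMETRIC_FREQS <- c(0.5, 1, 2, 3, 4, 6, 8)
# Frequencies the rule requires to be present before an ear is classifiable.
RULE_FREQS <- c(0.5, 1, 3, 4, 6, 8)
# High frequencies where the notch may sit.
NOTCH_FREQS <- c(3, 4, 6)
# Notch criteria: depth of at least 15 dB over the low-frequency baseline,
# with the 8 kHz threshold at least 5 dB better than the worst high frequency.
NOTCH_DEPTH_DB <- 15
NOTCH_RECOVERY_DB <- 5
THRESHOLD_RANGE <- c(-10, 120)

#' Construct a single-ear audiogram
#'
#' An ear audiogram holds pure-tone air-conduction hearing thresholds
#' (dB HL) at up to seven standard frequencies: 0.5, 1, 2, 3, 4, 6 and
#' 8 kHz. Missing frequencies are permitted (simply omit them); an ear
#' missing any of the six frequencies used by the notch rule is reported
#' as unclassifiable by [classify_ear_notch()].
#'
#' @param thresholds Named numeric vector of thresholds in dB HL. Names are
#'   frequencies in kHz and must be drawn from
#'   \code{c(0.5, 1, 2, 3, 4, 6, 8)}. Values must lie in \[-10, 120\].
#'   Clinical audiometers step in 5 dB; a threshold that is not a multiple
#'   of 5 is accepted with a warning (some instruments report 1 dB steps).
#' @param side `"right"` or `"left"`.
#'
#' @return An object of class `ear_audiogram`: a list with elements `side`
#'   and `thresholds` (named by frequency in kHz).
#'
#' @examples
#' ear <- ear_audiogram(c("0.5" = 10, "1" = 10, "3" = 10, "4" = 30,
#'                        "6" = 15, "8" = 20))
#' classify_ear_notch(ear)
#' @export
ear_audiogram <- function(thresholds, side = c("right", "left")) {
  side <- match.arg(side)
  if (length(thresholds) == 0L) {
    stop("`thresholds` must contain at least one frequency", call. = FALSE)
  }
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    stop("`thresholds` must be named by frequency in kHz", call. = FALSE)
  }
  freq <- suppressWarnings(as.numeric(names(thresholds)))
  bad <- is.na(freq) | !freq %in% AUDIOMETRIC_FREQS
  if (any(bad)) {
    stop(sprintf(
      "invalid frequency key(s): %s (allowed: %s kHz)",
      paste(names(thresholds)[bad], collapse = ", "),
      paste(AUDIOMETRIC_FREQS, collapse = ", ")
    ), call. = FALSE)
  }
  if (anyDuplicated(freq)) {
    stop("duplicate frequency keys in `thresholds`", call. = FALSE)
  }
  val <- as.numeric(thresholds)
  present <- !is.na(val)
  out_of_range <- present &
    (val < THRESHOLD_RANGE[1] | val > THRESHOLD_RANGE[2])
  if (any(out_of_range)) {
    stop(sprintf(
      "threshold at %s kHz (%g dB HL) outside [%d, %d]",
      names(thresholds)[out_of_range][1], val[out_of_range][1],
      THRESHOLD_RANGE[1], THRESHOLD_RANGE[2]
    ), call. = FALSE)
  }
  off_grid <- present & (val %% 5 != 0)
  if (any(off_grid)) {
    warning(sprintf(
      "threshold at %s kHz (%g dB HL) is not a multiple of 5 dB",
      names(thresholds)[off_grid][1], val[off_grid][1]
    ), call. = FALSE)
  }
  th <- val[present]
  names(th) <- as.character(freq[present])
  structure(list(side = side, thresholds = th), class = "ear_audiogram")
}

#' @export
print.ear_audiogram <- function(x, ...) {
  cat(sprintf("<ear_audiogram: %s ear>\n", x$side))
  print(x$thresholds)
  invisible(x)
}

# Vectorized notch rule. All arguments are equal-length numeric vectors of
# thresholds (dB HL); NAs mark missing frequencies. Returns a data.frame of
# diagnostics; this single core backs classify_ear_notch(), the grid audit
# and whole-cohort classification.
notch_rule <- function(t500, t1000, t3000, t4000, t6000, t8000) {
  classifiable <- !(is.na(t500) | is.na(t1000) | is.na(t3000) |
                      is.na(t4000) | is.na(t6000) | is.na(t8000))
  baseline <- (t500 + t1000) / 2
  max_high <- pmax(t3000, t4000, t6000)
  depth <- max_high - baseline
  recovery <- max_high - t8000
  notch <- classifiable & depth >= NOTCH_DEPTH_DB & recovery >= NOTCH_RECOVERY_DB
  baseline[!classifiable] <- NA_real_
  max_high[!classifiable] <- NA_real_
  depth[!classifiable] <- NA_real_
  recovery[!classifiable] <- NA_real_
  data.frame(
    classifiable = classifiable,
    notch_present = notch,
    baseline_low_freq = baseline,
    max_high_freq = max_high,
    notch_depth = depth,
    recovery_margin = recovery
  )
}

#' Classify one ear for a high-frequency audiometric notch
#'
#' Applies the notch rule: a notch is present when any threshold at 3, 4 or
#' 6 kHz exceeds the average of the 0.5 and 1 kHz thresholds by at least
#' 15 dB HL, and the 8 kHz threshold is at least 5 dB HL lower (better)
#' than the maximum threshold at 3, 4 and 6 kHz. Both comparisons are
#' inclusive. An ear missing any of the six frequencies the rule uses
#' (0.5, 1, 3, 4, 6, 8 kHz) is unclassifiable; 2 kHz is never consulted.
#'
#' Because "any of 3, 4, 6 kHz exceeds the baseline by >= 15" is equivalent
#' to "the maximum of 3, 4, 6 kHz exceeds the baseline by >= 15", the
#' reported `notch_depth` is the depth at the worst high frequency.
#'
#' @param ear An [ear_audiogram()].
#'
#' @return An object of class `ear_notch_result`: a list with elements
#'   `classifiable`, `notch_present`, `baseline_low_freq` (dB HL, mean of
#'   0.5 and 1 kHz), `max_high_freq` (dB HL, max of 3/4/6 kHz),
#'   `notch_depth` (dB, `max_high_freq - baseline_low_freq`) and
#'   `recovery_margin` (dB, `max_high_freq` minus the 8 kHz threshold).
#'   Diagnostics are `NA` when the ear is unclassifiable.
#'
#' @seealso [classify_participant()], [audit_notch_rule()],
#'   [classify_audiograms()] for whole-table classification.
#' @export
classify_ear_notch <- function(ear) {
  if (!inherits(ear, "ear_audiogram")) {
    stop("`ear` must be an ear_audiogram object", call. = FALSE)
  }
  th <- ear$thresholds
  g <- function(f) if (as.character(f) %in% names(th)) th[[as.character(f)]] else NA_real_
  res <- notch_rule(g(0.5), g(1), g(3), g(4), g(6), g(8))
  structure(c(as.list(res), list(side = ear$side)), class = "ear_notch_result")
}

#' @export
print.ear_notch_result <- function(x, ...) {
  if (!x$classifiable) {
    cat("<ear_notch_result: unclassifiable (missing rule frequency)>\n")
  } else {
    cat(sprintf(
      "<ear_notch_result: notch %s | baseline %.1f dB HL, worst high freq %.1f, depth %.1f, 8 kHz recovery %.1f>\n",
      if (x$notch_present) "PRESENT" else "absent",
      x$baseline_low_freq, x$max_high_freq, x$notch_depth, x$recovery_margin
    ))
  }
  invisible(x)
}

#' Combine per-ear notch results into a participant-level category
#'
#' A participant with both ears classifiable is `"bilateral"` (both ears
#' notched), `"unilateral"` (exactly one), or `"none"`; if either ear is
#' unclassifiable the participant is `"unclassifiable"` and is excluded
#' from analysis upstream.
#'
#' @param left,right `ear_notch_result` objects from [classify_ear_notch()].
#'
#' @return An object of class `participant_notch_status`: a list with
#'   `category` (one of `"none"`, `"unilateral"`, `"bilateral"`,
#'   `"unclassifiable"`) and the two ear results.
#' @export
classify_participant <- function(left, right) {
  if (!inherits(left, "ear_notch_result") || !inherits(right, "ear_notch_result")) {
    stop("`left` and `right` must be ear_notch_result objects", call. = FALSE)
  }
  category <- if (!left$classifiable || !right$classifiable) {
    "unclassifiable"
  } else if (left$notch_present && right$notch_present) {
    "bilateral"
  } else if (left$notch_present || right$notch_present) {
    "unilateral"
  } else {
    "none"
  }
  structure(list(category = category, left = left, right = right),
            class = "participant_notch_status")
}

#' @export
print.participant_notch_status <- function(x, ...) {
  cat(sprintf("<participant_notch_status: %s>\n", x$category))
  invisible(x)
}

#' Classify every audiogram in a participant table
#'
#' Operates on the generic audiogram layout: one row per participant with
#' threshold columns named `<side>_<freq>` where side is `l` or `r` and
#' freq is in Hz (`l_500`, `l_1000`, `l_2000`, `l_3000`, `l_4000`,
#' `l_6000`, `l_8000`, and the same with `r_`). Empty/NA cells are missing
#' thresholds. The 2 kHz columns may be absent; the rule never uses them.
#'
#' @param data A data.frame with the threshold columns above.
#'
#' @return `data` with columns appended: `notch_left`, `notch_right`
#'   (logical, NA when the ear is unclassifiable), `classifiable`
#'   (both ears classifiable), `notch_category` (factor: none, unilateral,
#'   bilateral, unclassifiable), and indicator columns `notch_any`,
#'   `notch_bilateral`, `notch_unilateral` (0/1, NA when unclassifiable).
#' @export
classify_audiograms <- function(data) {
  need <- as.vector(outer(c("l", "r"), RULE_FREQS * 1000, paste, sep = "_"))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("missing threshold column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  col <- function(nm) as.numeric(data[[nm]])
  rng <- range(unlist(lapply(need, col)), na.rm = TRUE)
  if (rng[1] < THRESHOLD_RANGE[1] || rng[2] > THRESHOLD_RANGE[2]) {
    stop(sprintf("threshold outside [%d, %d] dB HL in audiogram table",
                 THRESHOLD_RANGE[1], THRESHOLD_RANGE[2]), call. = FALSE)
  }
  left <- notch_rule(col("l_500"), col("l_1000"), col("l_3000"),
                     col("l_4000"), col("l_6000"), col("l_8000"))
  right <- notch_rule(col("r_500"), col("r_1000"), col("r_3000"),
                      col("r_4000"), col("r_6000"), col("r_8000"))
  classifiable <- left$classifiable & right$classifiable
  category <- ifelse(!classifiable, "unclassifiable",
              ifelse(left$notch_present & right$notch_present, "bilateral",
              ifelse(left$notch_present | right$notch_present, "unilateral",
                     "none")))
  data$notch_left <- ifelse(left$classifiable, left$notch_present, NA)
  data$notch_right <- ifelse(right$classifiable, right$notch_present, NA)
  data$classifiable <- classifiable
  data$notch_category <- factor(category,
    levels = c("none", "unilateral", "bilateral", "unclassifiable"))
  data$notch_any <- ifelse(classifiable,
                           as.integer(category %in% c("unilateral", "bilateral")),
                           NA_integer_)
  data$notch_bilateral <- ifelse(classifiable,
                                 as.integer(category == "bilateral"), NA_integer_)
  data$notch_unilateral <- ifelse(classifiable,
                                  as.integer(category == "unilateral"), NA_integer_)
  data
}

#' Enumerate and classify audiograms on a threshold grid
#'
#' Builds the full Cartesian product of candidate thresholds at the six
#' rule frequencies and classifies every combination. Intended for
#' exhaustive equivalence testing of the notch rule against independent
#' transcriptions of it.
#'
#' @param grid Named list giving the candidate thresholds (dB HL) at each
#'   of the six rule frequencies; names are kHz: `"0.5"`, `"1"`, `"3"`,
#'   `"4"`, `"6"`, `"8"`. Any frequency omitted defaults to `c(0, 20)`.
#' @param cap Maximum number of combinations enumerated; the grid is
#'   refused (with the size estimate) beyond this.
#'
#' @return A data.frame with one row per audiogram: columns `t500`,
#'   `t1000`, `t3000`, `t4000`, `t6000`, `t8000` plus the
#'   [classify_ear_notch()] diagnostics.
#' @export
audit_notch_rule <- function(grid = list(), cap = 2e6) {
  default <- c(0, 20)
  gnames <- as.character(RULE_FREQS)
  unknown <- setdiff(names(grid), gnames)
  if (length(unknown) > 0) {
    stop("unknown grid frequency: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full <- lapply(gnames, function(f) {
    v <- if (f %in% names(grid)) as.numeric(grid[[f]]) else default
    if (any(v < THRESHOLD_RANGE[1] | v > THRESHOLD_RANGE[2])) {
      stop(sprintf("grid thresholds at %s kHz outside [%d, %d]",
                   f, THRESHOLD_RANGE[1], THRESHOLD_RANGE[2]), call. = FALSE)
    }
    v
  })
  size <- prod(vapply(full, length, numeric(1)))
  if (size > cap) {
    stop(sprintf("grid enumerates %.3g audiograms, above the cap of %.3g",
                 size, cap), call. = FALSE)
  }
  names(full) <- c("t500", "t1000", "t3000", "t4000", "t6000", "t8000")
  g <- expand.grid(full, KEEP.OUT.ATTRS = FALSE)
  cbind(g, notch_rule(g$t500, g$t1000, g$t3000, g$t4000, g$t6000, g$t8000))
}
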