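# Complex survey design: weight / stratum / PSU triples and the
# stratified with-replacement variance machinery shared by all estimators.

#' Describe a complex survey design
#'
#' Captures the design variables used for design-based estimation: one
#' sampling weight, stratum label and primary sampling unit (PSU) label per
#' analysis row. Variance estimation treats first-stage PSU sampling as
#' with replacement within strata (the standard approximation for
#' masked-variance public-use designs), so it needs at least two PSUs per
#' stratum; strata with a single ("lonely") PSU are an error by default or
#' can be collapsed pairwise into the neighbouring stratum.
#'
#' @param weight Positive numeric sampling weights.
#' @param stratum Stratum labels (coerced to factor).
#' @param psu PSU labels, nested within stratum (labels may repeat across
#'   strata; PSUs are identified by the stratum/PSU pair).
#' @param lonely_psu `"error"` (default) to refuse variance estimation when
#'   a stratum has a single PSU, or `"collapse"` to merge each lonely
#'   stratum with the next stratum in sort order.
#'
#' @return An object of class `svy_design`: a list with the validated
#'   design vectors, the per-row stratum/PSU factors actually used for
#'   variance (after any collapsing), and `n`.
#'
#' @examples
#' d <- survey_design(weight = rep(1, 6),
#'                    stratum = rep(1:3, each = 2),
#'                    psu = rep(1:2, times = 3))
#' degf(d)
#' @export
survey_design <- function(weight, stratum, psu,
                          lonely_psu = c("error", "collapse")) {
  lonely_psu <- match.arg(lonely_psu)
  n <- length(weight)
  if (length(stratum) != n || length(psu) != n) {
    stop("`weight`, `stratum` and `psu` must have equal length", call. = FALSE)
  }
  weight <- as.numeric(weight)
  if (anyNA(weight) || any(weight <= 0)) {
    stop("all weights must be positive and non-missing", call. = FALSE)
  }
  if (anyNA(stratum) || anyNA(psu)) {
    stop("stratum and psu labels must be non-missing", call. = FALSE)
  }
  stratum <- factor(stratum)
  # PSUs are nested: identify clusters by the stratum x psu pair.
  psu <- factor(paste(as.character(stratum), as.character(psu), sep = "//"))

  psu_per_stratum <- rowSums(table(stratum, psu) > 0)
  lonely <- names(psu_per_stratum)[psu_per_stratum < 2]
  if (length(lonely) > 0 && lonely_psu == "collapse") {
    lev <- levels(stratum)
    if (length(lev) < 2) {
      stop("cannot collapse: design has a single stratum with one PSU",
           call. = FALSE)
    }
    # Merge each lonely stratum with its successor (predecessor for the last).
    map <- stats::setNames(lev, lev)
    for (s in lonely) {
      i <- match(s, lev)
      partner <- if (i < length(lev)) lev[i + 1] else lev[i - 1]
      map[s] <- map[partner]
    }
    stratum <- factor(map[as.character(stratum)])
    psu_per_stratum <- rowSums(table(stratum, psu) > 0)
    lonely <- names(psu_per_stratum)[psu_per_stratum < 2]
  }
  if (length(lonely) > 0) {
    stop(sprintf(
      "stratum %s has a single PSU; variance needs >= 2 PSUs per stratum (see `lonely_psu = \"collapse\"`)",
      paste(lonely, collapse = ", ")
    ), call. = FALSE)
  }
  structure(list(weight = weight, stratum = droplevels(stratum),
                 psu = droplevels(psu), n = n),
            class = "svy_design")
}

#' @export
print.svy_design <- function(x, ...) {
  cat(sprintf(
    "<svy_design: %d rows, %d strata, %d PSUs, design df = %d>\n",
    x$n, nlevels(x$stratum), nlevels(x$psu), degf(x)
  ))
  invisible(x)
}

#' Design degrees of freedom
#'
#' Number of PSUs minus number of strata — the degrees of freedom used for
#' t-based confidence intervals and as the denominator reference of the
#' design-based Wald test.
#'
#' @param design An object describing a survey design.
#' @return Integer degrees of freedom.
#' @export
degf <- function(design) UseMethod("degf")

#' @export
degf.svy_design <- function(design) {
  nlevels(design$psu) - nlevels(design$stratum)
}

# Stratified with-replacement variance of a total from linearized scores.
# `u` is an n x p matrix (or n-vector) of per-row score contributions,
# already weighted. Returns the p x p covariance: for each stratum h with
# n_h PSUs, sum n_h/(n_h - 1) * crossprod of PSU totals centred on the
# stratum mean, summed over strata.
cluster_variance <- function(u, design) {
  u <- as.matrix(u)
  p <- ncol(u)
  # PSU totals: one row per PSU.
  psu_tot <- rowsum(u, design$psu, reorder = TRUE)
  psu_strat <- design$stratum[match(rownames(psu_tot),
                                    as.character(design$psu))]
  V <- matrix(0, p, p)
  for (h in levels(psu_strat)) {
    idx <- which(psu_strat == h)
    nh <- length(idx)
    th <- psu_tot[idx, , drop = FALSE]
    centered <- sweep(th, 2, colMeans(th))
    V <- V + nh / (nh - 1) * crossprod(centered)
  }
  V
}

# Normalize a domain argument: NULL means everyone; otherwise a logical
# vector aligned with the design rows. Out-of-domain rows stay in the
# variance computation with zero contribution (design-correct subpopulation
# estimation), so we never subset the design itself.
resolve_domain <- function(domain, design) {
  if (is.null(domain)) return(rep(TRUE, design$n))
  if (!is.logical(domain) || length(domain) != design$n) {
    stop("`domain` must be NULL or a logical vector matching the design rows",
         call. = FALSE)
  }
  if (anyNA(domain)) stop("`domain` must not contain NA", call. = FALSE)
  if (!any(domain)) stop("empty domain: no rows selected", call. = FALSE)
  domain
}
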