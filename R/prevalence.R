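# Design-based prevalence (Hajek ratio) and population totals with
# Taylor-linearized standard errors.

#' Design-based prevalence of a binary indicator
#'
#' Estimates the population prevalence of `x` over a subpopulation
#' (domain) as the Hajek ratio \eqn{100 \sum w_i x_i / \sum w_i} using the
#' survey weights, with a Taylor-linearization standard error under
#' stratified with-replacement first-stage PSU sampling. Out-of-domain
#' rows are retained in the variance computation with zero weight rather
#' than dropped, which is the design-correct treatment of subpopulations.
#'
#' @param x Numeric 0/1 indicator (or logical), one value per design row.
#'   May be `NA` outside the domain.
#' @param design A [survey_design()] whose rows align one-to-one with `x`.
#' @param domain Optional logical vector selecting the subpopulation;
#'   `NULL` means all rows.
#' @param label Optional domain label carried into the result.
#'
#' @return An object of class `svy_prevalence`: a list with `estimate`
#'   (percent), `se` (percent), `weighted_count` (estimated population
#'   count with the indicator), `n_unweighted` (rows in the domain),
#'   `domain_label` and `df` (design degrees of freedom).
#'
#' @examples
#' d <- survey_design(weight = c(2, 1, 1),
#'                    stratum = c(1, 1, 1), psu = c(1, 2, 3))
#' svy_prevalence(c(1, 0, 1), d)  # 75%
#' @export
svy_prevalence <- function(x, design, domain = NULL, label = "overall") {
  stopifnot(inherits(design, "svy_design"))
  domain <- resolve_domain(domain, design)
  x <- as.numeric(x)
  if (length(x) != design$n) {
    stop("`x` must align with the design rows", call. = FALSE)
  }
  if (anyNA(x[domain])) {
    stop("indicator contains NA inside the domain", call. = FALSE)
  }
  w <- design$weight * domain
  x0 <- ifelse(domain, x, 0)
  W <- sum(w)
  X <- sum(w * x0)
  p <- X / W
  # Linearized variate of the ratio estimator; zero off-domain.
  u <- w * (x0 - p) / W
  v <- cluster_variance(u, design)[1, 1]
  structure(list(
    estimate = 100 * p,
    se = 100 * sqrt(v),
    weighted_count = X,
    n_unweighted = sum(domain),
    domain_label = label,
    df = degf(design)
  ), class = "svy_prevalence")
}

#' @export
print.svy_prevalence <- function(x, ...) {
  cat(sprintf(
    "<svy_prevalence [%s]: %.1f%% (SE %.2f), weighted count %.3g, n = %d>\n",
    x$domain_label, x$estimate, x$se, x$weighted_count, x$n_unweighted
  ))
  invisible(x)
}

#' Design-based population total of an indicator
#'
#' Weighted sum of `x` over the domain — an estimate of the number of
#' people in the population with the attribute — with its
#' Taylor-linearized standard error.
#'
#' @inheritParams svy_prevalence
#' @param millions If `TRUE`, report the total (and SE) in millions,
#'   rounded to one decimal.
#'
#' @return A list with `total`, `se`, `n_unweighted` and `df`.
#' @export
svy_total <- function(x, design, domain = NULL, millions = FALSE) {
  stopifnot(inherits(design, "svy_design"))
  domain <- resolve_domain(domain, design)
  x <- as.numeric(x)
  if (length(x) != design$n) {
    stop("`x` must align with the design rows", call. = FALSE)
  }
  if (anyNA(x[domain])) {
    stop("indicator contains NA inside the domain", call. = FALSE)
  }
  u <- design$weight * domain * ifelse(domain, x, 0)
  total <- sum(u)
  v <- cluster_variance(u, design)[1, 1]
  se <- sqrt(v)
  if (millions) {
    total <- round(total / 1e6, 1)
    se <- round(se / 1e6, 1)
  }
  list(total = total, se = se, n_unweighted = sum(domain), df = degf(design))
}
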