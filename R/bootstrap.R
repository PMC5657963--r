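# Stratified PSU bootstrap (Rao-Wu rescaling) — the replication-based
# cross-check for the Taylor-linearized standard errors.

#' Stratified-bootstrap standard error of a survey statistic
#'
#' Rao-Wu rescaling bootstrap for stratified with-replacement designs:
#' in each stratum with \eqn{n_h} PSUs, each replicate draws
#' \eqn{n_h - 1} PSUs with replacement and multiplies the weights of a
#' PSU drawn \eqn{r} times by \eqn{r \, n_h / (n_h - 1)}. The statistic is
#' recomputed with each replicate weight vector and its standard deviation
#' across replicates is returned. Used as an independent check on
#' Taylor-linearized variances.
#'
#' @param statistic Function of one argument, a weight vector of the same
#'   length as the design rows, returning a numeric scalar (or vector).
#' @param design A [survey_design()].
#' @param replicates Number of bootstrap replicates.
#'
#' @return A list with `se` (bootstrap standard error, per statistic
#'   component), `replicates`, and `estimates` (the replicate-by-component
#'   matrix).
#'
#' @examples
#' d <- survey_design(weight = runif(40, 1, 3),
#'                    stratum = rep(1:5, each = 8),
#'                    psu = rep(rep(1:2, each = 4), times = 5))
#' x <- rbinom(40, 1, 0.3)
#' boot <- svy_bootstrap_se(function(w) sum(w * x) / sum(w), d,
#'                          replicates = 200)
#' boot$se
#' @export
svy_bootstrap_se <- function(statistic, design, replicates = 500) {
  stopifnot(inherits(design, "svy_design"), is.function(statistic))
  psu_of_row <- design$psu
  strat_of_psu <- design$stratum[match(levels(psu_of_row),
                                       as.character(psu_of_row))]
  psu_levels <- levels(psu_of_row)
  row_psu_idx <- as.integer(psu_of_row)

  by_stratum <- split(seq_along(psu_levels), strat_of_psu)
  est <- NULL
  for (r in seq_len(replicates)) {
    mult <- numeric(length(psu_levels))
    for (ids in by_stratum) {
      nh <- length(ids)
      draw <- sample(ids, nh - 1, replace = TRUE)
      counts <- tabulate(match(draw, ids), nbins = nh)
      mult[ids] <- counts * nh / (nh - 1)
    }
    wrep <- design$weight * mult[row_psu_idx]
    val <- statistic(wrep)
    if (is.null(est)) est <- matrix(NA_real_, replicates, length(val))
    est[r, ] <- val
  }
  list(se = apply(est, 2, stats::sd), replicates = replicates,
       estimates = est)
}
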