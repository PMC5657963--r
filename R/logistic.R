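# Survey-weighted logistic regression: pseudo-maximum-likelihood fit via
# iteratively reweighted least squares, with a Taylor-linearized (clustered
# sandwich) covariance respecting strata and PSUs.

#' Fit a survey-weighted logistic regression
#'
#' Maximizes the weighted (pseudo) log-likelihood
#' \eqn{\sum_i w_i [y_i \eta_i - \log(1 + e^{\eta_i})]} by iteratively
#' reweighted least squares, then estimates the covariance of the
#' coefficients with the design-based sandwich
#' \eqn{A^{-1} B A^{-1}}, where \eqn{A = X' \Lambda X} is the weighted
#' information and \eqn{B} is the stratified between-PSU covariance of the
#' weighted score contributions \eqn{w_i (y_i - \mu_i) x_i}. Confidence
#' intervals use a t reference with design degrees of freedom
#' (PSUs minus strata).
#'
#' Estimates are invariant to rescaling all weights by a constant; weights
#' are normalized to mean one internally for numerical stability.
#'
#' Out-of-domain rows are kept in the design with zero weight, so
#' subpopulation fits retain the full PSU structure in the variance.
#'
#' @param formula Model formula; the response must be a 0/1 (or logical)
#'   outcome. Categorical predictors should be factors whose first level is
#'   the referent (use [stats::relevel()] to choose it).
#' @param data Data frame holding the model variables, one row per design
#'   row.
#' @param design A [survey_design()] aligned with `data`.
#' @param domain Optional logical subpopulation selector.
#' @param maxit,tol IRLS iteration cap and convergence tolerance:
#'   iteration stops when the largest absolute (normalized-weight) score
#'   component is below `tol` or the largest relative coefficient change is
#'   below `tol`.
#'
#' @return An object of class `svy_logit` with components `coefficients`,
#'   `vcov`, `df` (design df), `n` (rows used), `fitted` (probabilities on
#'   domain rows), `converged`, `iterations`, `formula`, `xlevels`, and the
#'   usual accessors: [coef()], [vcov()], [confint()], [summary()],
#'   [predict()], plus [odds_ratios()] for Table-style odds ratios.
#'
#' @examples
#' set.seed(1)
#' n <- 200
#' x <- rbinom(n, 1, 0.5)
#' y <- rbinom(n, 1, plogis(-1 + log(2) * x))
#' d <- survey_design(weight = rep(1, n), stratum = rep(1:10, each = 20),
#'                    psu = rep(1:2, times = 100))
#' fit <- svy_logit(y ~ factor(x), data = data.frame(y, x), design = d)
#' exp(coef(fit))
#' @export
svy_logit <- function(formula, data, design, domain = NULL,
                      maxit = 100, tol = 1e-10) {
  stopifnot(inherits(design, "svy_design"))
  if (nrow(data) != design$n) {
    stop("`data` must align with the design rows", call. = FALSE)
  }
  domain <- resolve_domain(domain, design)

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) y <- as.numeric(y) - 1
  X <- stats::model.matrix(stats::terms(mf), mf)
  if (anyNA(y[domain]) || anyNA(X[domain, ])) {
    stop("model variables contain NA inside the domain", call. = FALSE)
  }
  bad_y <- domain & !(y %in% c(0, 1) | is.na(y))
  if (any(bad_y)) stop("outcome must be 0/1 within the domain", call. = FALSE)
  if (all(y[domain] == 0) || all(y[domain] == 1)) {
    stop("outcome is constant within the domain", call. = FALSE)
  }

  # Separation check: a factor level whose domain outcomes are all 0 or
  # all 1 makes the MLE infinite; name the offending level.
  for (v in all.vars(formula)[-1]) {
    if (v %in% names(data) && (is.factor(data[[v]]) || is.character(data[[v]]))) {
      f <- as.factor(data[[v]])
      for (lev in levels(droplevels(f[domain]))) {
        sel <- domain & f == lev
        if (sum(sel) > 0 && (all(y[sel] == 0) || all(y[sel] == 1))) {
          stop(sprintf(
            "separation: outcome is constant (%d) for level '%s' of '%s'",
            y[which(sel)[1]], lev, v
          ), call. = FALSE)
        }
      }
    }
  }

  # Zero weight off-domain; normalize to mean 1 over the domain for
  # scale-invariant convergence checks.
  w_raw <- design$weight * domain
  w <- w_raw / mean(w_raw[domain])
  y0 <- ifelse(domain, y, 0)

  p <- ncol(X)
  qrX <- qr(X[domain, , drop = FALSE])
  if (qrX$rank < p) {
    stop("rank-deficient model matrix within the domain", call. = FALSE)
  }

  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- crossprod(X, w * (y0 - mu))
    lambda <- w * mu * (1 - mu)
    A <- crossprod(X, X * lambda)
    step <- tryCatch(solve(A, score), error = function(e) {
      stop("singular weighted information matrix in IRLS", call. = FALSE)
    })
    beta_new <- beta + drop(step)
    rel <- max(abs(beta_new - beta) / pmax(abs(beta), 1))
    beta <- beta_new
    if (max(abs(score)) < tol || rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (max(abs(beta)) > 30) {
    stop("coefficients diverging (|beta| > 30); quasi-separation likely",
         call. = FALSE)
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  lambda <- w * mu * (1 - mu)
  A <- crossprod(X, X * lambda)
  Ainv <- solve(A)
  # Weighted score contributions, clustered by PSU within stratum.
  U <- X * (w * (y0 - mu))
  B <- cluster_variance(U, design)
  V <- Ainv %*% B %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(list(
    coefficients = beta,
    vcov = V,
    df = degf(design),
    n = sum(domain),
    fitted = mu[domain],
    converged = converged,
    iterations = iter,
    formula = formula,
    xlevels = stats::.getXlevels(stats::terms(mf), mf),
    call = match.call()
  ), class = "svy_logit")
}

#' @export
coef.svy_logit <- function(object, ...) object$coefficients

#' @export
vcov.svy_logit <- function(object, ...) object$vcov

#' @export
confint.svy_logit <- function(object, parm, level = 0.95, ...) {
  cf <- coef(object)
  if (missing(parm)) parm <- names(cf)
  se <- sqrt(diag(vcov(object)))[parm]
  tq <- stats::qt(1 - (1 - level) / 2, df = object$df)
  out <- cbind(cf[parm] - tq * se, cf[parm] + tq * se)
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  rownames(out) <- parm
  out
}

#' @export
print.svy_logit <- function(x, ...) {
  cat("Survey-weighted logistic regression\n")
  cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("n = %d, design df = %d, converged in %d iterations\n",
              x$n, x$df, x$iterations))
  print(coef(x))
  invisible(x)
}

#' @export
summary.svy_logit <- function(object, ...) {
  cf <- coef(object)
  se <- sqrt(diag(vcov(object)))
  tval <- cf / se
  pval <- 2 * stats::pt(abs(tval), df = object$df, lower.tail = FALSE)
  tab <- cbind(Estimate = cf, `Std. Error` = se, `t value` = tval,
               `Pr(>|t|)` = pval)
  out <- list(call = object$call, coefficients = tab, df = object$df,
              n = object$n, converged = object$converged)
  class(out) <- "summary.svy_logit"
  out
}

#' @export
print.summary.svy_logit <- function(x, ...) {
  cat("Survey-weighted logistic regression\n")
  cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("n = %d, design df = %d\n\n", x$n, x$df))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
predict.svy_logit <- function(object, newdata = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    mu <- object$fitted
    return(if (type == "response") mu else stats::qlogis(mu))
  }
  tt <- stats::delete.response(stats::terms(object$formula))
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  eta <- drop(X %*% coef(object))
  if (type == "response") stats::plogis(eta) else eta
}

#' Odds ratios with design-based confidence intervals
#'
#' Exponentiates the coefficients of a [svy_logit()] fit for one
#' categorical predictor into a Table-style block of odds ratios: one row
#' per level, the referent level first with OR fixed at 1 and no interval.
#' Intervals are computed on the log-odds scale with a t reference at the
#' design degrees of freedom, then exponentiated.
#'
#' @param fit A [svy_logit()] whose right-hand side is a single factor.
#' @param level Confidence level (default 0.95).
#'
#' @return A data.frame with columns `level`, `or`, `ci_low`, `ci_high`,
#'   `referent`.
#' @export
odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "svy_logit"))
  if (length(fit$xlevels) != 1) {
    stop("odds_ratios() expects a fit with a single categorical predictor",
         call. = FALSE)
  }
  var <- names(fit$xlevels)[1]
  levs <- fit$xlevels[[1]]
  cf <- coef(fit)
  ci <- confint(fit, level = level)
  out <- data.frame(
    level = levs,
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    referent = c(TRUE, rep(FALSE, length(levs) - 1)),
    stringsAsFactors = FALSE
  )
  out$or[1] <- 1
  for (i in seq_along(levs)[-1]) {
    nm <- paste0(var, levs[i])
    if (!nm %in% names(cf)) {
      stop(sprintf("coefficient for level '%s' not found", levs[i]),
           call. = FALSE)
    }
    out$or[i] <- exp(cf[nm])
    out$ci_low[i] <- exp(ci[nm, 1])
    out$ci_high[i] <- exp(ci[nm, 2])
  }
  out
}

#' Design-adjusted Wald test for a group of coefficients
#'
#' Tests that all coefficients belonging to one categorical predictor
#' (every non-referent level) are simultaneously zero, using the
#' design-based covariance. Because the covariance is itself estimated
#' from only \eqn{d} design degrees of freedom (PSUs minus strata), the
#' Wald chi-square \eqn{W = b' V^{-1} b} is given the Hotelling-type
#' small-sample scaling: \eqn{F = W (d - k + 1) / (k d)} referred to an F
#' distribution with \eqn{k} and \eqn{d - k + 1} degrees of freedom (the
#' adjusted Wald test standard in complex-survey analysis). For a single
#' coefficient this reduces to the squared t statistic on \eqn{F(1, d)}.
#'
#' @param fit A [svy_logit()] fit.
#' @param term Name of the model variable whose coefficients are tested;
#'   defaults to the fit's single categorical predictor.
#'
#' @return A list with `statistic` (F), `chisq` (Wald chi-square
#'   \eqn{b'V^{-1}b}), `df1`, `df2`, `p.value` and `term`.
#' @export
wald_group_test <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "svy_logit"))
  cf <- coef(fit)
  if (is.null(term)) {
    if (length(fit$xlevels) != 1) {
      stop("specify `term`: the fit has no unique categorical predictor",
           call. = FALSE)
    }
    term <- names(fit$xlevels)[1]
  }
  idx <- which(startsWith(names(cf), term) & names(cf) != "(Intercept)")
  if (length(idx) == 0) {
    stop(sprintf("no coefficients found for term '%s'", term), call. = FALSE)
  }
  b <- cf[idx]
  V <- vcov(fit)[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e) {
    stop("singular covariance block in Wald test", call. = FALSE)
  })
  chisq <- drop(t(b) %*% Vi %*% b)
  k <- length(idx)
  d <- fit$df
  df2 <- max(d - k + 1, 1)
  Fstat <- chisq * df2 / (k * d)
  p <- stats::pf(Fstat, k, df2, lower.tail = FALSE)
  list(statistic = Fstat, chisq = chisq, df1 = k, df2 = df2,
       p.value = p, term = term)
}
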