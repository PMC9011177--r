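#' Dominant-model logistic regression fit
#'
#' Maximum-likelihood logistic regression of a binary outcome on carrier
#' status plus optional covariates, fitted by iteratively reweighted least
#' squares (binomial [stats::glm.fit()], relative deviance tolerance 1e-12,
#' at most 100 iterations). Categorical covariates are one-hot coded with
#' the first level as reference. Rows with missing values must be removed
#' beforehand. Complete separation in the carrier-by-outcome 2x2 table and
#' non-convergence are flagged on the result, not raised as errors.
#'
#' @param outcome Binary (0/1) outcome vector; both classes must be present.
#' @param carrier Logical or 0/1 carrier status vector.
#' @param covariates Optional data.frame of numeric or factor/character
#'   covariates (e.g. age, region).
#' @return A list of class `pv_logit`: `beta` (named coefficients,
#'   intercept first, carrier second), `se`, `vcov`, `loglik`, `converged`,
#'   `separated`, `n`, and the 2x2 `cells` (carrier x outcome counts).
#' @export
fit_logistic <- function(outcome, carrier, covariates = NULL) {
  outcome <- as.integer(outcome)
  carrier <- as.integer(as.logical(carrier))
  if (anyNA(outcome) || anyNA(carrier)) {
    stop("missing values in outcome or carrier; drop them first", call. = FALSE)
  }
  if (length(unique(outcome)) < 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  x <- cbind(`(Intercept)` = 1, carrier = carrier)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates)) stop("missing values in covariates; drop them first", call. = FALSE)
    mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    x <- cbind(x, mm)
  }
  cells <- table(factor(carrier, 0:1), factor(outcome, 0:1))
  separated <- any(cells == 0)
  fit <- suppressWarnings(stats::glm.fit(
    x, outcome, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  beta <- fit$coefficients
  # observed information from the final IRLS weights
  w <- fit$weights
  xtwx <- crossprod(x * sqrt(w))
  vcov <- tryCatch(solve(xtwx), error = function(e) {
    matrix(NA_real_, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  })
  eta <- drop(x %*% beta)
  loglik <- sum(outcome * eta - log1p(exp(eta)))
  structure(list(beta = beta, se = sqrt(diag(vcov)), vcov = vcov,
                 loglik = loglik, converged = fit$converged && !anyNA(vcov),
                 separated = separated, n = length(outcome), cells = cells),
            class = "pv_logit")
}

#' @export
print.pv_logit <- function(x, ...) {
  cat(sprintf("<pv_logit> n=%d, logLik=%.4f, converged=%s, separated=%s\n",
              x$n, x$loglik, x$converged, x$separated))
  est <- cbind(beta = x$beta, se = x$se)
  print(round(est, 4))
  invisible(x)
}

#' Wald summary for the carrier coefficient
#'
#' @param fit A `pv_logit`.
#' @param z Normal quantile for the confidence interval (1.959964 for 95%).
#' @return List with `beta`, `se`, `or`, `lo`, `hi`, `p` (two-sided Wald).
#' @export
wald_carrier <- function(fit, z = 1.959964) {
  b <- fit$beta[["carrier"]]
  s <- fit$se[["carrier"]]
  list(beta = b, se = s, or = exp(b),
       lo = exp(b - z * s), hi = exp(b + z * s),
       p = 2 * stats::pnorm(-abs(b / s)))
}
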