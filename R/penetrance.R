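check_bands <- function(inc, to_age = NULL) {
  inc <- inc[order(inc$age_lo), , drop = FALSE]
  if (nrow(inc) == 0) stop("empty incidence band set", call. = FALSE)
  if (any(inc$age_lo[-1] != inc$age_hi[-nrow(inc)])) {
    stop("age bands must be contiguous with no gaps or overlaps", call. = FALSE)
  }
  if (!is.null(to_age) && (inc$age_lo[1] > 0 || inc$age_hi[nrow(inc)] < to_age)) {
    stop(sprintf("age bands must cover [0, %g)", to_age), call. = FALSE)
  }
  if (any(inc$rate < 0)) stop("incidence rates must be >= 0", call. = FALSE)
  inc
}

#' Partition population incidence into carrier and noncarrier hazards
#'
#' Under a dominant model with carrier frequency p and relative risk rr
#' constant across age, the population rate in each band is the mixture
#' lambda_pop = p * rr * lambda_n + (1 - p) * lambda_n, so the noncarrier
#' hazard is lambda_n = lambda_pop / (1 + p * (rr - 1)) and the carrier
#' hazard lambda_c = rr * lambda_n; the mixture is conserved exactly by
#' construction. The odds ratio stands in for rr under the rare-disease
#' assumption.
#'
#' @param incidence data.frame of bands for one (cancer, sex): columns
#'   `age_lo`, `age_hi`, `rate` (population incidence per person-year).
#' @param p Carrier frequency, `0 <= p < 1`.
#' @param rr Relative risk (> 0).
#' @return The band table with added columns `rate_noncarrier`,
#'   `rate_carrier`.
#' @export
partition_hazard <- function(incidence, p, rr) {
  if (p < 0 || p >= 1) stop("carrier frequency p must satisfy 0 <= p < 1", call. = FALSE)
  if (rr <= 0) stop("relative risk must be > 0", call. = FALSE)
  inc <- check_bands(incidence)
  inc$rate_noncarrier <- inc$rate / (1 + p * (rr - 1))
  inc$rate_carrier <- rr * inc$rate_noncarrier
  inc
}

#' Cumulative risk from per-band hazards
#'
#' F(a) = 1 - prod over bands ending at or before a of exp(-lambda * width),
#' the discrete cumulative incidence ignoring competing mortality.
#'
#' @param bands data.frame with `age_lo`, `age_hi` and the hazard column
#'   named by `rate_col`; bands must be contiguous and cover `[0, to_age)`.
#' @param to_age Age the curve runs to (default 85).
#' @param rate_col Name of the hazard column (default `"rate"`).
#' @return data.frame `age` (band ends) and `cumulative_risk`.
#' @export
cumulative_risk <- function(bands, to_age = 85, rate_col = "rate") {
  bands <- check_bands(bands, to_age)
  bands <- bands[bands$age_lo < to_age, , drop = FALSE]
  width <- pmin(bands$age_hi, to_age) - bands$age_lo
  ch <- cumsum(bands[[rate_col]] * width)
  data.frame(age = pmin(bands$age_hi, to_age), cumulative_risk = 1 - exp(-ch))
}

#' Carrier / noncarrier risk curves from population incidence
#'
#' Combines [partition_hazard()] and [cumulative_risk()] into the full
#' per-band curve for one (cancer, sex).
#'
#' @inheritParams partition_hazard
#' @param to_age Upper age (default 85).
#' @return data.frame per band: `age_lo`, `age_hi`, `rate_pop`,
#'   `rate_noncarrier`, `rate_carrier`, `F_noncarrier`, `F_carrier`.
#' @export
risk_curve <- function(incidence, p, rr, to_age = 85) {
  part <- partition_hazard(incidence, p, rr)
  Fn <- cumulative_risk(part, to_age, "rate_noncarrier")
  Fc <- cumulative_risk(part, to_age, "rate_carrier")
  part <- part[part$age_lo < to_age, , drop = FALSE]
  data.frame(age_lo = part$age_lo, age_hi = pmin(part$age_hi, to_age),
             rate_pop = part$rate,
             rate_noncarrier = part$rate_noncarrier,
             rate_carrier = part$rate_carrier,
             F_noncarrier = Fn$cumulative_risk,
             F_carrier = Fc$cumulative_risk)
}

terminal_risk <- function(incidence, p, rr, to_age, rate_col) {
  part <- partition_hazard(incidence, p, rr)
  cr <- cumulative_risk(part, to_age, rate_col)
  cr$cumulative_risk[nrow(cr)]
}

#' Confidence interval for cumulative risk by simulating the log-OR
#'
#' Propagates the sampling uncertainty of the log odds ratio into the
#' cumulative risk: log-OR draws from Normal(beta, se^2) are pushed through
#' the hazard partition, and the primary interval is the normal
#' approximation on the risk scale, point estimate +/- 1.959964 * SD of the
#' draws. That construction can produce negative lower bounds for small
#' risks with wide ORs; a percentile interval (which cannot go negative)
#' is reported alongside.
#'
#' @param beta Log odds ratio (or a one-row association result data.frame
#'   with `beta`, `se`, `gated`, in which case gated input is an error).
#' @param se Standard error of `beta` (ignored when `beta` is a result row).
#' @param incidence Band table for one (cancer, sex): `age_lo`, `age_hi`,
#'   `rate`.
#' @param p Carrier frequency.
#' @param to_age Upper age (default 85).
#' @param n_draws Number of Monte Carlo draws (default 10000).
#' @param seed RNG seed for the draws.
#' @return List with `F_carrier`, `F_noncarrier` point estimates and, for
#'   each, `normal_lo`/`normal_hi` and `pct_lo`/`pct_hi` bounds.
#' @export
risk_ci <- function(beta, se = NULL, incidence, p, to_age = 85,
                    n_draws = 10000, seed = 1L) {
  if (is.data.frame(beta)) {
    if (isTRUE(beta$gated[1])) {
      stop("association result is gated; no risk estimate available", call. = FALSE)
    }
    se <- beta$se[1]
    beta <- beta$beta[1]
  }
  if (is.na(beta) || is.na(se) || se < 0) {
    stop("beta and se must be non-missing (se >= 0)", call. = FALSE)
  }
  fc_hat <- terminal_risk(incidence, p, exp(beta), to_age, "rate_carrier")
  fn_hat <- terminal_risk(incidence, p, exp(beta), to_age, "rate_noncarrier")
  if (se == 0) {
    return(list(F_carrier = fc_hat,
                carrier = list(normal_lo = fc_hat, normal_hi = fc_hat,
                               pct_lo = fc_hat, pct_hi = fc_hat),
                F_noncarrier = fn_hat,
                noncarrier = list(normal_lo = fn_hat, normal_hi = fn_hat,
                                  pct_lo = fn_hat, pct_hi = fn_hat)))
  }
  set.seed(seed)
  draws <- stats::rnorm(n_draws, beta, se)
  fc <- vapply(draws, function(b)
    terminal_risk(incidence, p, exp(b), to_age, "rate_carrier"), numeric(1))
  fn <- vapply(draws, function(b)
    terminal_risk(incidence, p, exp(b), to_age, "rate_noncarrier"), numeric(1))
  band <- function(hat, x) {
    q <- unname(stats::quantile(x, c(0.025, 0.975)))
    list(normal_lo = hat - Z95 * stats::sd(x), normal_hi = hat + Z95 * stats::sd(x),
         pct_lo = q[1], pct_hi = q[2])
  }
  list(F_carrier = fc_hat, carrier = band(fc_hat, fc),
       F_noncarrier = fn_hat, noncarrier = band(fn_hat, fn))
}

#' Penetrance estimates for a table of association results
#'
#' For each non-gated association row, partitions the matching (cancer,
#' sex) population incidence and reports cumulative risk to `to_age` for
#' carriers and noncarriers with both interval constructions.
#'
#' @param assoc Association results (rows from [run_association()]).
#' @param incidence Incidence table (`cancer`, `sex`, `age_lo`, `age_hi`,
#'   `rate`), as from [simulate_incidence_table()].
#' @param carrier_freq Named per-gene carrier frequencies (e.g. estimated
#'   from controls), or a single number.
#' @param to_age,n_draws,seed As in [risk_ci()].
#' @return data.frame, one row per usable association: gene, cancer, sex,
#'   `F_noncarrier`, `F_carrier` and the four CI bounds for the carrier
#'   risk.
#' @export
penetrance_table <- function(assoc, incidence, carrier_freq, to_age = 85,
                             n_draws = 10000, seed = 1L) {
  rows <- list()
  for (i in seq_len(nrow(assoc))) {
    r <- assoc[i, ]
    if (isTRUE(r$gated) || is.na(r$beta)) next
    p <- if (length(carrier_freq) == 1 && is.null(names(carrier_freq))) {
      carrier_freq
    } else {
      carrier_freq[[r$gene]]
    }
    sexes <- if (r$sex == "both") c("F", "M") else r$sex
    inc <- incidence[incidence$cancer == r$cancer & incidence$sex %in% sexes, ,
                     drop = FALSE]
    if (nrow(inc) == 0) next
    if (length(sexes) == 2) {
      # sex-averaged population incidence for cancers open to both sexes
      inc <- stats::aggregate(rate ~ age_lo + age_hi, inc, mean)
      inc$cancer <- r$cancer
    }
    ci <- risk_ci(r$beta, r$se, inc, p, to_age, n_draws, seed)
    rows[[length(rows) + 1]] <- data.frame(
      gene = r$gene, cancer = r$cancer, sex = r$sex, carrier_freq = p,
      or = r$or, F_noncarrier = ci$F_noncarrier, F_carrier = ci$F_carrier,
      normal_lo = ci$carrier$normal_lo, normal_hi = ci$carrier$normal_hi,
      pct_lo = ci$carrier$pct_lo, pct_hi = ci$carrier$pct_hi)
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(), cancer = character(),
                      sex = character(), carrier_freq = numeric(),
                      or = numeric(), F_noncarrier = numeric(),
                      F_carrier = numeric(), normal_lo = numeric(),
                      normal_hi = numeric(), pct_lo = numeric(),
                      pct_hi = numeric()))
  }
  do.call(rbind, rows)
}
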