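Z95 <- 1.959964 # normal quantile used throughout for 95% intervals

#' Recover a log-OR effect estimate from a printed OR and 95% CI
#'
#' Inverts the symmetric-on-log-scale Wald interval: theta = ln(OR),
#' SE = (ln hi - ln lo) / (2 * 1.959964).
#'
#' @param or Odds ratio (> 0).
#' @param lo,hi 95% confidence bounds, `lo < or < hi`.
#' @param label Optional label (e.g. the gene).
#' @return A one-row data.frame with `label`, `theta`, `se`.
#' @export
se_from_ci <- function(or, lo, hi, label = NA_character_) {
  if (any(c(or, lo, hi) <= 0)) {
    stop("or, lo and hi must all be positive", call. = FALSE)
  }
  if (!(lo < or && or < hi)) {
    stop(sprintf("confidence bounds must satisfy lo < or < hi (got %g, %g, %g)",
                 lo, or, hi), call. = FALSE)
  }
  data.frame(label = label, theta = log(or), se = (log(hi) - log(lo)) / (2 * Z95))
}

#' Cochran Q heterogeneity and random-effects pooling of effect estimates
#'
#' Fixed-effect inverse-variance weights w = 1/SE^2 give the weighted mean
#' theta-bar and Q = sum w (theta - theta-bar)^2 on k-1 degrees of freedom;
#' the heterogeneity p-value is the upper chi-square tail of Q. I-squared =
#' max(0, (Q - df)/Q) * 100, floored at zero. The between-study variance is
#' the DerSimonian-Laird moment estimator tau^2 = max(0, (Q - df) / C) with
#' C = sum(w) - sum(w^2)/sum(w), and the pooled random-effects estimate
#' uses weights 1/(SE^2 + tau^2).
#'
#' @param effects data.frame with columns `theta` (log-OR) and `se`
#'   (standard error, > 0), e.g. rows from [se_from_ci()]; at least 2 rows.
#' @return A list of class `het_result`: `k`, `Q`, `df`, `p`, `I2`
#'   (percent), `tau2`, `pooled` (log scale), `pooled_se`, `pooled_or`,
#'   `pooled_lo`, `pooled_hi`, and the fixed-effect counterparts
#'   `fixed_or`, `fixed_lo`, `fixed_hi`.
#' @export
heterogeneity <- function(effects) {
  if (!is.data.frame(effects) || !all(c("theta", "se") %in% names(effects))) {
    stop("effects must be a data.frame with columns theta, se", call. = FALSE)
  }
  k <- nrow(effects)
  if (k < 2) stop("heterogeneity needs at least 2 effect estimates", call. = FALSE)
  if (any(effects$se <= 0)) stop("standard errors must be > 0", call. = FALSE)
  th <- effects$theta
  w <- 1 / effects$se^2
  tb <- sum(w * th) / sum(w)
  Q <- sum(w * (th - tb)^2)
  df <- k - 1
  p <- stats::pchisq(Q, df, lower.tail = FALSE)
  I2 <- max(0, (Q - df) / Q) * 100
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  w_re <- 1 / (effects$se^2 + tau2)
  pooled <- sum(w_re * th) / sum(w_re)
  pooled_se <- sqrt(1 / sum(w_re))
  fixed_se <- sqrt(1 / sum(w))
  structure(list(
    k = k, Q = Q, df = df, p = p, I2 = I2, tau2 = tau2,
    pooled = pooled, pooled_se = pooled_se,
    pooled_or = exp(pooled),
    pooled_lo = exp(pooled - Z95 * pooled_se),
    pooled_hi = exp(pooled + Z95 * pooled_se),
    fixed_or = exp(tb),
    fixed_lo = exp(tb - Z95 * fixed_se),
    fixed_hi = exp(tb + Z95 * fixed_se)
  ), class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("<het_result> k=%d  Q=%.3f (df=%d, p=%.3g)  I2=%.1f%%  tau2=%.4f\n",
              x$k, x$Q, x$df, x$p, x$I2, x$tau2))
  cat(sprintf("  random-effects OR %.2f (%.2f-%.2f)\n",
              x$pooled_or, x$pooled_lo, x$pooled_hi))
  invisible(x)
}

#' Between-gene heterogeneity for every cancer type in an OR-pair table
#'
#' For each cancer with at least two (gene, OR, CI) rows, inverts the
#' printed intervals with [se_from_ci()] and computes [heterogeneity()].
#' Cancers with fewer than two rows are reported with `NA` statistics
#' (mirroring suppressed entries in published association tables).
#'
#' @param pairs data.frame with columns `cancer`, `gene`, `or`, `lo`, `hi`.
#' @return data.frame, one row per cancer: `k`, `Q`, `df`, `p_het`, `I2`
#'   (1-decimal, floored at 0), `tau2`, pooled random-effects OR and CI.
#' @export
heterogeneity_pairs <- function(pairs) {
  need <- c("cancer", "gene", "or", "lo", "hi")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0) {
    stop(sprintf("pairs table lacks columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  pairs <- pairs[stats::complete.cases(pairs[, c("or", "lo", "hi")]), , drop = FALSE]
  out <- lapply(sort(unique(pairs$cancer)), function(cc) {
    sub <- pairs[pairs$cancer == cc, , drop = FALSE]
    if (nrow(sub) < 2) {
      return(data.frame(cancer = cc, k = nrow(sub), Q = NA_real_,
                        df = NA_integer_, p_het = NA_real_, I2 = NA_real_,
                        tau2 = NA_real_, pooled_or = NA_real_,
                        pooled_lo = NA_real_, pooled_hi = NA_real_))
    }
    eff <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
      se_from_ci(sub$or[i], sub$lo[i], sub$hi[i], sub$gene[i])
    }))
    h <- heterogeneity(eff)
    data.frame(cancer = cc, k = h$k, Q = h$Q, df = h$df, p_het = h$p,
               I2 = round(h$I2, 1), tau2 = h$tau2, pooled_or = h$pooled_or,
               pooled_lo = h$pooled_lo, pooled_hi = h$pooled_hi)
  })
  do.call(rbind, out)
}

#' Published odds-ratio pairs fixture
#'
#' The odds ratios and 95% confidence intervals reported by a nationwide
#' biobank case-control study for the two hereditary breast/ovarian cancer
#' genes, for the eight cancer types where both gene-specific estimates
#' were available; shipped so the heterogeneity computation can be
#' exercised and checked against the published I-squared values.
#'
#' @return data.frame with columns `cancer`, `gene`, `or`, `lo`, `hi`.
#' @export
published_or_pairs <- function() {
  path <- system.file("extdata", "published_or_pairs.tsv", package = "pvburden")
  read_tsv_table(path)
}
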