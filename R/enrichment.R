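#' Regional carrier-frequency breakdown with founder attribution
#'
#' Tallies carriers of one gene per region among patients (or any subset),
#' distinguishing individuals who would remain carriers after removing
#' founder-flagged variants from those whose carrier status rests solely on
#' a founder variant.
#'
#' @param cohort Cohort data.frame.
#' @param carriers A `carrier_table`.
#' @param calls Variant call data.frame with `founder` column (needed for
#'   founder attribution / exclusion).
#' @param gene Gene label.
#' @param subset Which individuals to tally: `"case"` (default; patients),
#'   `"control"`, or `"all"`.
#' @return data.frame of class `regional_breakdown`: per region `n`,
#'   `carriers`, `prop`, `carriers_nonfounder`, `prop_nonfounder`; with
#'   attributes `gene` and `fold_difference` (max/min proportion among
#'   regions with carriers).
#' @export
regional_breakdown <- function(cohort, carriers, calls, gene, subset = "case") {
  d <- if (subset == "all") cohort else cohort[cohort$status == subset, , drop = FALSE]
  if (nrow(d) == 0) stop("empty subset for regional breakdown", call. = FALSE)
  m <- match(d$individual_id, carriers$individual_id)
  flag <- carriers[[carrier_col(carriers, gene)]][m]
  founder_ids <- unique(calls$variant_id[isTRUE_vec(calls$founder)])
  qual <- calls[calls$gene == gene & calls$class %in% c("P", "LP") &
                  !calls$variant_id %in% founder_ids, , drop = FALSE]
  nonfounder <- d$individual_id %in% qual$individual_id
  regions <- sort(unique(d$region))
  out <- do.call(rbind, lapply(regions, function(r) {
    i <- d$region == r
    data.frame(region = r, n = sum(i), carriers = sum(flag[i]),
               prop = mean(flag[i]),
               carriers_nonfounder = sum(nonfounder[i]),
               prop_nonfounder = mean(nonfounder[i]))
  }))
  pos <- out$prop[out$prop > 0]
  fold <- if (length(pos) > 0) max(out$prop) / min(pos) else NA_real_
  structure(out, class = c("regional_breakdown", "data.frame"),
            gene = gene, fold_difference = fold)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Chi-square test of carrier-frequency heterogeneity across regions
#'
#' Pearson chi-square (no continuity correction) on the regions-by-
#' carrier/noncarrier contingency table. With `exclude_founders = TRUE`,
#' individuals whose carrier status rests solely on founder-flagged
#' variants are recounted as noncarriers, testing whether regional
#' differences persist beyond founder structure.
#'
#' @param breakdown A `regional_breakdown`.
#' @param exclude_founders Recount founder-only carriers as noncarriers.
#' @return List with `statistic`, `df`, `p`, and the table used.
#' @export
regional_chisq <- function(breakdown, exclude_founders = FALSE) {
  if (nrow(breakdown) < 2) stop("need at least 2 regions", call. = FALSE)
  if (any(breakdown$n == 0)) stop("every region must have at least one individual", call. = FALSE)
  carr <- if (exclude_founders) breakdown$carriers_nonfounder else breakdown$carriers
  tab <- cbind(carrier = carr, noncarrier = breakdown$n - carr)
  rownames(tab) <- breakdown$region
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Family-history profile over the associated cancer types
#'
#' Per individual, the number of distinct associated cancer types reported
#' in first/second-degree relatives, categorized none / 1 / 2 or more.
#'
#' @param cohort Cohort data.frame.
#' @param cancers Character vector of the associated cancer types.
#' @return data.frame `individual_id`, `fh_count`, `fh_category` (ordered
#'   factor `0`, `1`, `2+`).
#' @export
fh_profile <- function(cohort, cancers) {
  cols <- paste0("fh_", cancers)
  miss <- setdiff(cols, names(cohort))
  if (length(miss) > 0) {
    stop(sprintf("cohort lacks family-history columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  cnt <- rowSums(cohort[, cols, drop = FALSE])
  data.frame(individual_id = cohort$individual_id, fh_count = cnt,
             fh_category = factor(ifelse(cnt >= 2, "2+", as.character(cnt)),
                                  levels = c("0", "1", "2+"), ordered = TRUE))
}

#' Cochran-Armitage trend test of carrier status over family-history burden
#'
#' Signed trend statistic on the 2x3 carrier-by-category table with scores
#' 0, 1, 2 for none / 1 / 2-or-more reported cancer types in relatives:
#' Z = sum_i s_i (r_i - n_i R/N) / sqrt(R/N (1 - R/N) (sum s_i^2 n_i -
#' (sum s_i n_i)^2 / N)); two-sided p from the normal distribution.
#' Positive Z means carrier enrichment increases with family-history
#' burden. Empty categories are allowed; an all-empty table is an error.
#'
#' @param carrier Logical carrier flags for the analyzed cases.
#' @param category Ordered factor / vector with levels `0`, `1`, `2+`
#'   aligned with `carrier` (e.g. `fh_category` from [fh_profile()]).
#' @return List with `z`, `p`, and the 2x3 `table`.
#' @export
fh_trend <- function(carrier, category) {
  category <- factor(as.character(category), levels = c("0", "1", "2+"))
  if (length(carrier) == 0 || all(is.na(category))) {
    stop("empty family-history table", call. = FALSE)
  }
  n_i <- as.numeric(table(category))
  r_i <- as.numeric(tapply(as.logical(carrier), category, sum, default = 0))
  N <- sum(n_i); R <- sum(r_i)
  if (N == 0) stop("empty family-history table", call. = FALSE)
  s <- c(0, 1, 2)
  pbar <- R / N
  num <- sum(s * (r_i - n_i * pbar))
  den2 <- pbar * (1 - pbar) * (sum(s^2 * n_i) - sum(s * n_i)^2 / N)
  z <- if (den2 <= 0) 0 else num / sqrt(den2)
  tab <- rbind(carrier = r_i, noncarrier = n_i - r_i)
  colnames(tab) <- c("0", "1", "2+")
  list(z = z, p = 2 * stats::pnorm(-abs(z)), table = tab)
}

#' Carrier enrichment by reported family history of each cancer type
#'
#' For cases of each analyzed cancer type and each family-history cancer
#' type, the carrier proportion among cases reporting that family history,
#' with a Fisher exact test of the 2x2 (carrier x family history) table
#' and Bonferroni correction across the whole grid.
#'
#' @param cohort Cohort data.frame.
#' @param carriers A `carrier_table`.
#' @param gene Gene label.
#' @param case_cancers Cancer types whose cases are profiled.
#' @param fh_cancers Family-history cancer types forming the grid columns
#'   (defaults to `case_cancers`).
#' @return data.frame: `case_cancer`, `fh_cancer`, counts, carrier
#'   proportions among family-history-positive and -negative cases,
#'   `p_fisher`, `p_bonferroni`.
#' @export
fh_cross_tab <- function(cohort, carriers, gene, case_cancers,
                         fh_cancers = case_cancers) {
  ccol <- carrier_col(carriers, gene)
  rows <- list()
  for (cc in case_cancers) {
    d <- cohort[cohort[[paste0("case_", cc)]] == 1, , drop = FALSE]
    flag <- carriers[[ccol]][match(d$individual_id, carriers$individual_id)]
    for (fc in fh_cancers) {
      fh <- d[[paste0("fh_", fc)]] == 1
      tab <- matrix(c(sum(flag & fh), sum(!flag & fh),
                      sum(flag & !fh), sum(!flag & !fh)), 2, 2)
      p <- if (sum(tab) == 0) NA_real_ else stats::fisher.test(tab)$p.value
      rows[[length(rows) + 1]] <- data.frame(
        case_cancer = cc, fh_cancer = fc,
        n_fh = sum(fh), carriers_fh = sum(flag & fh),
        prop_fh = if (sum(fh) > 0) mean(flag[fh]) else NA_real_,
        n_nofh = sum(!fh), carriers_nofh = sum(flag & !fh),
        prop_nofh = if (sum(!fh) > 0) mean(flag[!fh]) else NA_real_,
        p_fisher = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_fisher * nrow(out))
  out
}

#' Cohort characteristics summary
#'
#' Deterministic aggregation in the style of a study's participants table:
#' per cancer type the case counts by sex, mean (SD) age at diagnosis and
#' percentage of cases reporting family history of the same cancer type;
#' overall patient/control counts, the fraction of patients with two or
#' more primary cancer types; and per-gene carrier proportions by 10-year
#' diagnosis-age band among patients. Percentages are reported to one
#' decimal; SD is missing when a group has fewer than two members.
#'
#' @param cohort Cohort data.frame.
#' @param carriers Optional `carrier_table` for the age-band carrier
#'   proportions.
#' @return List with data.frames `by_cancer`, `overall`, and (when
#'   `carriers` is given) `carriers_by_ageband`.
#' @export
summarize_cohort <- function(cohort, carriers = NULL) {
  case_cols <- grep("^case_", names(cohort), value = TRUE)
  cancers <- sub("^case_", "", case_cols)
  by_cancer <- do.call(rbind, lapply(cancers, function(cc) {
    i <- cohort[[paste0("case_", cc)]] == 1
    ages <- cohort[[paste0("agedx_", cc)]][i]
    ages <- ages[!is.na(ages)]
    data.frame(
      cancer = cc,
      n_female = sum(i & cohort$sex == "F"),
      n_male = sum(i & cohort$sex == "M"),
      n_total = sum(i),
      agedx_mean = if (length(ages) > 0) round(mean(ages), 1) else NA_real_,
      agedx_sd = if (length(ages) > 1) round(stats::sd(ages), 1) else NA_real_,
      pct_fh_same = if (sum(i) > 0) {
        round(100 * mean(cohort[[paste0("fh_", cc)]][i] == 1), 1)
      } else NA_real_)
  }))
  patients <- cohort$status == "case"
  overall <- data.frame(
    n_patients = sum(patients),
    n_cases = sum(cohort$n_cancer_types),
    n_controls = sum(cohort$status == "control"),
    n_excluded = sum(cohort$status == "excluded"),
    pct_multi_primary = if (sum(patients) > 0) {
      round(100 * mean(cohort$n_cancer_types[patients] >= 2), 1)
    } else NA_real_)
  out <- list(by_cancer = by_cancer, overall = overall)
  if (!is.null(carriers)) {
    genes <- attr(carriers, "genes")
    if (is.null(genes)) genes <- sub("^carrier_", "", grep("^carrier_", names(carriers), value = TRUE))
    genes <- setdiff(genes, "multiple")
    agedx_any <- suppressWarnings(apply(
      cohort[patients, paste0("agedx_", cancers), drop = FALSE], 1, min, na.rm = TRUE))
    band <- pmin(floor(agedx_any / 10) * 10, 80)
    m <- match(cohort$individual_id[patients], carriers$individual_id)
    ab <- do.call(rbind, lapply(genes, function(g) {
      flag <- carriers[[paste0("carrier_", g)]][m]
      do.call(rbind, lapply(sort(unique(band)), function(b) {
        i <- band == b
        data.frame(gene = g, age_band = sprintf("%d-%d", b, b + 9),
                   n = sum(i), carriers = sum(flag[i]),
                   prop = mean(flag[i]))
      }))
    }))
    out$carriers_by_ageband <- ab
  }
  out
}
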