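DESIGNS <- c("all_patients", "no_family_history", "region_adjusted",
             "single_cancer_only")

# Assemble the analysis frame for one (gene, cancer, design): cases of the
# cancer vs registry controls, with the age covariate (diagnosis age for
# cases, registration age for controls) and design-specific case filters.
build_assoc_frame <- function(cohort, carriers, gene, cancer, design,
                              sex = "both", fh_scope = "any") {
  case_col <- paste0("case_", cancer)
  if (!case_col %in% names(cohort)) {
    stop(sprintf("unknown cancer '%s' in cohort table", cancer), call. = FALSE)
  }
  ccol <- carrier_col(carriers, gene)
  if (!design %in% DESIGNS) {
    stop(sprintf("unknown design '%s' (must be one of %s)", design,
                 paste(DESIGNS, collapse = ", ")), call. = FALSE)
  }
  d <- cohort
  if (sex != "both") d <- d[d$sex == sex, , drop = FALSE]
  cases <- d[d[[case_col]] == 1, , drop = FALSE]
  controls <- d[d$status == "control", , drop = FALSE]
  # controls are family-history-free by the registry's control definition,
  # so design filters act on cases only
  fh_cols <- grep("^fh_", names(d), value = TRUE)
  if (design %in% c("no_family_history", "region_adjusted", "single_cancer_only")) {
    keep <- if (fh_scope == "same") {
      cases[[paste0("fh_", cancer)]] == 0
    } else {
      rowSums(cases[, fh_cols, drop = FALSE]) == 0
    }
    cases <- cases[keep, , drop = FALSE]
  }
  if (design == "single_cancer_only") {
    cases <- cases[cases$n_cancer_types == 1, , drop = FALSE]
  }
  cases$.age <- cases[[paste0("agedx_", cancer)]]
  controls$.age <- controls$age_registration
  d <- rbind(cbind(cases, .y = 1L), cbind(controls, .y = 0L))
  d <- d[!is.na(d$.age), , drop = FALSE] # drop samples without age
  m <- match(d$individual_id, carriers$individual_id)
  if (anyNA(m)) {
    stop("cohort individuals missing from carrier table; collapse with a roster",
         call. = FALSE)
  }
  d$.carrier <- carriers[[ccol]][m]
  d
}

gated_result <- function(gene, cancer, design, sex, n_case, n_control,
                         car_case, car_control, reason) {
  data.frame(gene = gene, cancer = cancer, design = design, sex = sex,
             n_case = n_case, n_control = n_control,
             carriers_case = car_case, carriers_control = car_control,
             beta = NA_real_, se = NA_real_, or = NA_real_,
             lo = NA_real_, hi = NA_real_, p = NA_real_,
             gated = TRUE, gate_reason = reason,
             converged = NA, separated = NA)
}

#' Age-adjusted dominant-model burden association for one gene and cancer
#'
#' Logistic regression of case status on carrier status with age as a
#' covariate (diagnosis age for cases, registration age for controls),
#' under one of four designs:
#' \describe{
#'   \item{all_patients}{all cases vs controls; because unrestricted case
#'     recruitment biases the risk estimate, only the p-value is reported
#'     (estimates are withheld).}
#'   \item{no_family_history}{cases restricted to those reporting no family
#'     history (of any cancer by default, `fh_scope = "same"` for only the
#'     analyzed type); OR with 95% CI reported.}
#'   \item{region_adjusted}{as no_family_history, plus region as a
#'     categorical covariate (population-stratification sensitivity
#'     analysis).}
#'   \item{single_cancer_only}{as no_family_history, dropping patients with
#'     more than one primary cancer type.}
#' }
#' Any analysis with fewer than 3 carriers among cases or among controls is
#' gated: no estimates are produced and the reason is recorded. The burden
#' test is declared significant at p < 1e-4 (see
#' [run_all_associations()]).
#'
#' @param cohort Cohort data.frame from [simulate_cohort()] or
#'   [read_tsv_table()].
#' @param carriers A `carrier_table`.
#' @param gene Gene label.
#' @param cancer Cancer type label.
#' @param design One of `all_patients`, `no_family_history`,
#'   `region_adjusted`, `single_cancer_only`.
#' @param sex `"both"`, `"F"` or `"M"`; breast analyses are run separately
#'   per sex, sex-restricted cancers use the relevant sex.
#' @param fh_scope `"any"` (default) or `"same"`: which family-history
#'   flags the no-family-history case filter considers.
#' @return One-row data.frame (an association result): counts, `beta`,
#'   `se`, `or`, `lo`, `hi`, `p`, `gated`, `gate_reason`, `converged`,
#'   `separated`.
#' @export
run_association <- function(cohort, carriers, gene, cancer,
                            design = "no_family_history", sex = "both",
                            fh_scope = c("any", "same")) {
  fh_scope <- match.arg(fh_scope)
  d <- build_assoc_frame(cohort, carriers, gene, cancer, design, sex, fh_scope)
  n_case <- sum(d$.y == 1); n_control <- sum(d$.y == 0)
  car_case <- sum(d$.carrier[d$.y == 1]); car_control <- sum(d$.carrier[d$.y == 0])
  if (n_case == 0 || n_control == 0) {
    return(gated_result(gene, cancer, design, sex, n_case, n_control,
                        car_case, car_control, "empty case or control group"))
  }
  if (car_case < 3 || car_control < 3) {
    return(gated_result(gene, cancer, design, sex, n_case, n_control,
                        car_case, car_control, "carrier count < 3"))
  }
  covars <- data.frame(age = d$.age)
  if (design == "region_adjusted") covars$region <- factor(d$region)
  fit <- fit_logistic(d$.y, d$.carrier, covars)
  w <- wald_carrier(fit)
  res <- data.frame(gene = gene, cancer = cancer, design = design, sex = sex,
                    n_case = n_case, n_control = n_control,
                    carriers_case = car_case, carriers_control = car_control,
                    beta = w$beta, se = w$se, or = w$or, lo = w$lo, hi = w$hi,
                    p = w$p, gated = FALSE, gate_reason = "",
                    converged = fit$converged, separated = fit$separated)
  if (design == "all_patients") {
    # association testing only: withhold risk estimates
    res[c("beta", "se", "or", "lo", "hi")] <- NA_real_
  }
  res
}

#' Run the full gene-by-cancer association grid
#'
#' Applies [run_association()] over every (gene, cancer) pair, running
#' breast separately for females and males and restricting sex-specific
#' cancers to the relevant sex, then appends Bonferroni-adjusted p-values
#' across the grid and the burden-test significance flag at p < 1e-4.
#' Neither correction filters rows; both are reported as columns.
#'
#' @param cohort,carriers As in [run_association()].
#' @param genes Character vector of genes.
#' @param cancer_types data.frame with `cancer` and `sex_restrict`
#'   (as in a `sim_config`); breast (if present with `sex_restrict`
#'   `"both"` and named `"breast"`) is split by sex.
#' @param design,fh_scope As in [run_association()].
#' @param burden_alpha Burden-test significance threshold (default 1e-4).
#' @return data.frame of association results with `p_bonferroni` and
#'   `sig_burden` columns.
#' @export
run_all_associations <- function(cohort, carriers, genes, cancer_types,
                                 design = "no_family_history",
                                 fh_scope = "any", burden_alpha = 1e-4) {
  rows <- list()
  for (g in genes) {
    for (i in seq_len(nrow(cancer_types))) {
      cc <- cancer_types$cancer[i]
      restrict <- cancer_types$sex_restrict[i]
      sexes <- if (cc == "breast" && restrict == "both") c("F", "M")
               else if (restrict == "both") "both" else restrict
      for (s in sexes) {
        rows[[length(rows) + 1]] <-
          run_association(cohort, carriers, g, cc, design, s, fh_scope)
      }
    }
  }
  out <- do.call(rbind, rows)
  n_tests <- sum(!is.na(out$p))
  out$p_bonferroni <- pmin(1, out$p * n_tests)
  out$sig_burden <- !is.na(out$p) & out$p < burden_alpha
  out
}

#' Carrier-associated shift in age at diagnosis
#'
#' Difference in mean diagnosis age (carriers minus noncarriers) among
#' cases of one cancer type, estimated by linear regression of diagnosis
#' age on carrier status, with a Welch two-sample test as an alternative.
#' Gated (no estimates) when fewer than 3 carriers are among the cases.
#'
#' @param cohort,carriers,gene,cancer As in [run_association()].
#' @param sex Optional sex restriction.
#' @return One-row data.frame: carrier counts, `diff` (years), `lo`, `hi`,
#'   `p` (regression), `p_welch`, `gated`, `gate_reason`.
#' @export
age_at_diagnosis_shift <- function(cohort, carriers, gene, cancer, sex = "both") {
  case_col <- paste0("case_", cancer)
  if (!case_col %in% names(cohort)) {
    stop(sprintf("unknown cancer '%s' in cohort table", cancer), call. = FALSE)
  }
  d <- cohort[cohort[[case_col]] == 1, , drop = FALSE]
  if (sex != "both") d <- d[d$sex == sex, , drop = FALSE]
  d$.age <- d[[paste0("agedx_", cancer)]]
  d <- d[!is.na(d$.age), , drop = FALSE]
  m <- match(d$individual_id, carriers$individual_id)
  d$.carrier <- carriers[[carrier_col(carriers, gene)]][m]
  nc <- sum(d$.carrier)
  base <- data.frame(gene = gene, cancer = cancer, sex = sex,
                     n_cases = nrow(d), carriers = nc)
  if (nc < 3) {
    return(cbind(base, diff = NA_real_, lo = NA_real_, hi = NA_real_,
                 p = NA_real_, p_welch = NA_real_, gated = TRUE,
                 gate_reason = "carrier count < 3"))
  }
  fit <- stats::lm(.age ~ .carrier, data = d)
  # degenerate inputs (constant ages) legitimately yield a zero-variance fit
  ci <- suppressWarnings(stats::confint(fit)[".carrierTRUE", ])
  p <- suppressWarnings(summary(fit)$coefficients[".carrierTRUE", 4])
  pw <- tryCatch(stats::t.test(d$.age[d$.carrier], d$.age[!d$.carrier])$p.value,
                 error = function(e) NA_real_) # degenerate (constant) ages
  cbind(base, diff = unname(stats::coef(fit)[".carrierTRUE"]),
        lo = ci[[1]], hi = ci[[2]], p = p, p_welch = pw,
        gated = FALSE, gate_reason = "")
}
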