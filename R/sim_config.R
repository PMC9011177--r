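#' Age bands
#'
#' Contiguous half-open age bands `[lo, hi)` covering `[0, to)`, the grid on
#' which baseline hazards and population incidence are expressed.
#'
#' @param width Band width in years (default 5).
#' @param to Upper age limit (default 85).
#' @return A data.frame with columns `age_lo`, `age_hi`.
#' @export
age_bands <- function(width = 5, to = 85) {
  lo <- seq(0, to - width, by = width)
  data.frame(age_lo = lo, age_hi = lo + width)
}

#' Build a per-band baseline hazard table for one cancer type
#'
#' Converts a lifetime (to age `to`) cumulative risk into per-band hazards
#' (events per person-year), either constant over age or rising exponentially
#' with age as most adult solid tumours do.
#'
#' @param cancer Cancer type label.
#' @param sexes Character vector of sexes the hazard applies to
#'   (subset of `c("F","M")`).
#' @param lifetime_risk Cumulative risk to age `to` implied by the hazards,
#'   in `[0, 1)`.
#' @param shape `"constant"` or `"exponential"` (log-hazard linear in age).
#' @param k Log-hazard slope per decade for the exponential shape.
#' @param width,to Passed to [age_bands()].
#' @return A data.frame with columns `cancer`, `sex`, `age_lo`, `age_hi`,
#'   `rate`.
#' @export
hazard_table <- function(cancer, sexes, lifetime_risk, shape = c("exponential", "constant"),
                         k = 0.8, width = 5, to = 85) {
  shape <- match.arg(shape)
  stopifnot(lifetime_risk >= 0, lifetime_risk < 1)
  bands <- age_bands(width, to)
  target <- -log(1 - lifetime_risk) # total integrated hazard
  if (shape == "constant") {
    rate <- rep(target / to, nrow(bands))
  } else {
    mid <- (bands$age_lo + bands$age_hi) / 2
    raw <- exp(k * (mid - 60) / 10)
    rate <- raw * target / sum(raw * width)
  }
  out <- do.call(rbind, lapply(sexes, function(s) {
    data.frame(cancer = cancer, sex = s, bands, rate = rate)
  }))
  rownames(out) <- NULL
  out
}

#' Construct a cohort simulation configuration
#'
#' Defines the generative model for a synthetic biobank-style case-control
#' cohort: regional population structure with founder pathogenic variants,
#' per-gene background carrier frequencies, per-cancer age-band baseline
#' hazards, genotype relative risks under a dominant model, family-history
#' reporting, and multiple-primary frequency. All downstream stages can be
#' validated against the ground truth this configuration encodes.
#'
#' @param n Number of individuals (positive integer).
#' @param regions data.frame with columns `region`, `weight`; weights must
#'   sum to 1 (within 1e-9).
#' @param genes Character vector of gene labels.
#' @param background_rate Named numeric, per-gene carrier frequency of
#'   non-founder pathogenic variants (applied uniformly across regions).
#' @param founder_variants Optional data.frame with columns `gene`,
#'   `variant_id`, `region`, `freq`: founder pathogenic variants present at
#'   frequency `freq` in one region and absent elsewhere.
#' @param cancer_types data.frame with columns `cancer`, `sex_restrict`
#'   (one of `"F"`, `"M"`, `"both"`).
#' @param baseline_hazards data.frame as produced by [hazard_table()]
#'   (columns `cancer`, `sex`, `age_lo`, `age_hi`, `rate`), one row per
#'   (cancer, applicable sex, band).
#' @param true_or Optional data.frame with columns `gene`, `cancer`, `rr`:
#'   carrier hazard multipliers; pairs not listed default to 1. Carriers of
#'   several genes multiply their multipliers.
#' @param p_female Probability an individual is female.
#' @param fh_background_rate Named numeric, per-cancer probability a
#'   noncarrier reports family history of that cancer in first/second-degree
#'   relatives.
#' @param fh_carrier_multiplier Multiplier on the family-history reporting
#'   probability for pathogenic-variant carriers (capped so probabilities
#'   stay in `[0, 1]`).
#' @param multi_primary_target Target fraction of patients with more than
#'   one cancer type.
#' @param registration_age List with `mean`, `sd`, `min`, `max`: truncated
#'   normal distribution of age at registration.
#' @param decoy_rate Probability an individual carries a non-qualifying
#'   (VUS / likely benign / benign) call, exercising the collapsing rule.
#' @param seed RNG seed for the single global stream used in generation.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_incidence_table()], [demo_config()]
#' @export
sim_config <- function(n, regions, genes, background_rate, baseline_hazards,
                       cancer_types, founder_variants = NULL, true_or = NULL,
                       p_female = 0.44, fh_background_rate = NULL,
                       fh_carrier_multiplier = 2, multi_primary_target = 0,
                       registration_age = list(mean = 62, sd = 14.5, min = 20, max = 95),
                       decoy_rate = 0.03, seed = 1L) {
  if (is.null(fh_background_rate)) {
    fh_background_rate <- stats::setNames(rep(0.03, nrow(cancer_types)), cancer_types$cancer)
  }
  cfg <- structure(list(
    n = n, regions = regions, genes = genes,
    background_rate = background_rate,
    founder_variants = founder_variants,
    cancer_types = cancer_types,
    baseline_hazards = baseline_hazards,
    true_or = true_or,
    p_female = p_female,
    fh_background_rate = fh_background_rate,
    fh_carrier_multiplier = fh_carrier_multiplier,
    multi_primary_target = multi_primary_target,
    registration_age = registration_age,
    decoy_rate = decoy_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

config_error <- function(field, msg) {
  stop(sprintf("invalid simulation config: field '%s' %s", field, msg), call. = FALSE)
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant (probabilities in `[0,1]`, hazards
#' non-negative, relative risks positive, contiguous age bands covering
#' `[0, 85)`, region weights summing to 1) and fails naming the offending
#' field.
#'
#' @param cfg A `sim_config` object or plain list with the same fields.
#' @return The validated config, invisibly classed `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  if (!is.list(cfg)) config_error("(root)", "must be a list")
  if (is.null(cfg$n) || length(cfg$n) != 1 || is.na(cfg$n) || cfg$n <= 0 ||
      cfg$n != round(cfg$n)) {
    config_error("n", "must be a positive integer")
  }
  rg <- cfg$regions
  if (!is.data.frame(rg) || !all(c("region", "weight") %in% names(rg)) || nrow(rg) < 1) {
    config_error("regions", "must be a data.frame with columns region, weight")
  }
  if (any(rg$weight < 0) || abs(sum(rg$weight) - 1) > 1e-9) {
    config_error("regions", "weights must be non-negative and sum to 1 (within 1e-9)")
  }
  if (length(cfg$genes) < 1) config_error("genes", "must list at least one gene")
  bg <- cfg$background_rate
  if (is.null(names(bg)) || !all(cfg$genes %in% names(bg))) {
    config_error("background_rate", "must be named for every gene")
  }
  if (any(bg < 0 | bg > 1)) config_error("background_rate", "must lie in [0, 1]")
  fv <- cfg$founder_variants
  if (!is.null(fv) && nrow(fv) > 0) {
    if (!all(c("gene", "variant_id", "region", "freq") %in% names(fv))) {
      config_error("founder_variants", "needs columns gene, variant_id, region, freq")
    }
    if (!all(fv$gene %in% cfg$genes)) config_error("founder_variants", "references unknown gene")
    if (!all(fv$region %in% rg$region)) config_error("founder_variants", "references unknown region")
    if (any(fv$freq < 0 | fv$freq > 1)) config_error("founder_variants", "freq must lie in [0, 1]")
  }
  ct <- cfg$cancer_types
  if (!is.data.frame(ct) || !all(c("cancer", "sex_restrict") %in% names(ct)) ||
      nrow(ct) < 1 || anyDuplicated(ct$cancer)) {
    config_error("cancer_types", "must be a data.frame with unique cancer and sex_restrict columns")
  }
  if (!all(ct$sex_restrict %in% c("F", "M", "both"))) {
    config_error("cancer_types", "sex_restrict must be one of F, M, both")
  }
  bh <- cfg$baseline_hazards
  if (!is.data.frame(bh) ||
      !all(c("cancer", "sex", "age_lo", "age_hi", "rate") %in% names(bh))) {
    config_error("baseline_hazards", "needs columns cancer, sex, age_lo, age_hi, rate")
  }
  if (any(bh$rate < 0)) config_error("baseline_hazards", "rates must be >= 0")
  for (i in seq_len(nrow(ct))) {
    sexes <- switch(ct$sex_restrict[i], F = "F", M = "M", both = c("F", "M"))
    for (s in sexes) {
      sub <- bh[bh$cancer == ct$cancer[i] & bh$sex == s, , drop = FALSE]
      if (nrow(sub) == 0) {
        config_error("baseline_hazards",
                     sprintf("has no rows for cancer '%s', sex '%s'", ct$cancer[i], s))
      }
      sub <- sub[order(sub$age_lo), , drop = FALSE]
      if (sub$age_lo[1] != 0 || sub$age_hi[nrow(sub)] < 85 ||
          any(sub$age_lo[-1] != sub$age_hi[-nrow(sub)])) {
        config_error("baseline_hazards",
                     sprintf("bands for cancer '%s', sex '%s' must be contiguous and cover [0, 85)",
                             ct$cancer[i], s))
      }
    }
  }
  to <- cfg$true_or
  if (!is.null(to) && nrow(to) > 0) {
    if (!all(c("gene", "cancer", "rr") %in% names(to))) {
      config_error("true_or", "needs columns gene, cancer, rr")
    }
    if (!all(to$gene %in% cfg$genes)) config_error("true_or", "references unknown gene")
    if (!all(to$cancer %in% ct$cancer)) config_error("true_or", "references unknown cancer")
    if (any(to$rr <= 0)) config_error("true_or", "relative risks must be > 0")
  }
  if (cfg$p_female < 0 || cfg$p_female > 1) config_error("p_female", "must lie in [0, 1]")
  fh <- cfg$fh_background_rate
  if (!all(ct$cancer %in% names(fh))) {
    config_error("fh_background_rate", "must be named for every cancer type")
  }
  if (any(fh < 0 | fh > 1)) config_error("fh_background_rate", "must lie in [0, 1]")
  if (cfg$fh_carrier_multiplier < 0) config_error("fh_carrier_multiplier", "must be >= 0")
  if (cfg$multi_primary_target < 0 || cfg$multi_primary_target > 1) {
    config_error("multi_primary_target", "must lie in [0, 1]")
  }
  ra <- cfg$registration_age
  if (!all(c("mean", "sd", "min", "max") %in% names(ra)) || ra$sd <= 0 ||
      ra$min >= ra$max || ra$min < 0) {
    config_error("registration_age", "needs mean, sd > 0 and 0 <= min < max")
  }
  if (cfg$decoy_rate < 0 || cfg$decoy_rate > 1) config_error("decoy_rate", "must lie in [0, 1]")
  if (is.null(cfg$seed) || is.na(cfg$seed)) config_error("seed", "must be set")
  class(cfg) <- "sim_config"
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> n=%d, %d regions, genes: %s, %d cancer types, seed=%d\n",
              x$n, nrow(x$regions), paste(x$genes, collapse = "/"),
              nrow(x$cancer_types), x$seed))
  invisible(x)
}

# Region labels and rough population weights for the 7 hospital-service
# regions of a Japanese nationwide registry.
default_regions <- function() {
  data.frame(
    region = c("hokkaido", "tohoku", "kanto_koshinetsu", "tokai_hokuriku",
               "kinki", "kyushu", "okinawa"),
    weight = c(0.05, 0.07, 0.38, 0.14, 0.20, 0.13, 0.03)
  )
}

default_cancer_types <- function() {
  data.frame(
    cancer = c("biliary_tract", "breast", "cervical", "colorectal",
               "endometrial", "esophageal", "gastric", "liver", "lung",
               "lymphoma", "ovarian", "pancreatic", "prostate", "kidney"),
    sex_restrict = c("both", "both", "F", "both", "F", "both", "both", "both",
                     "both", "both", "F", "both", "M", "both")
  )
}

#' Demonstration configuration emulating a nationwide biobank study
#'
#' Fourteen cancer types with sex restrictions, seven regions with founder
#' pathogenic variants in two hereditary breast/ovarian cancer genes,
#' carrier frequencies in the 0.1--1.5% range, genotype relative risks set
#' to published burden odds ratios for the associated gene-cancer pairs,
#' family-history reporting enriched in carriers, and a 6.3% target for
#' patients with multiple primary cancer types. Lifetime baseline risks are
#' plausible East-Asian registry magnitudes; see the methods vignette for
#' the rationale behind each default.
#'
#' @param n Cohort size.
#' @param seed RNG seed.
#' @return A `sim_config`.
#' @export
demo_config <- function(n = 20000, seed = 1L) {
  ct <- default_cancer_types()
  lifetime <- c(biliary_tract = 0.013, breast = 0.055, cervical = 0.010,
                colorectal = 0.060, endometrial = 0.015, esophageal = 0.020,
                gastric = 0.055, liver = 0.022, lung = 0.048, lymphoma = 0.016,
                ovarian = 0.011, pancreatic = 0.024, prostate = 0.090,
                kidney = 0.010)
  bh <- do.call(rbind, lapply(seq_len(nrow(ct)), function(i) {
    sexes <- switch(ct$sex_restrict[i], F = "F", M = "M", both = c("F", "M"))
    hazard_table(ct$cancer[i], sexes, lifetime[[ct$cancer[i]]])
  }))
  founders <- data.frame(
    gene = c("BRCA1", "BRCA2", "BRCA2"),
    variant_id = c("BRCA1_fndr_tohoku", "BRCA2_fndr_kinki", "BRCA2_fndr_kanto"),
    region = c("tohoku", "kinki", "kanto_koshinetsu"),
    freq = c(0.0070, 0.0109, 0.0030)
  )
  true_or <- data.frame(
    gene = c(rep("BRCA1", 7), rep("BRCA2", 11)),
    cancer = c("ovarian", "breast", "biliary_tract", "gastric", "pancreatic",
               "lung", "lymphoma",
               "breast", "gastric", "ovarian", "pancreatic", "prostate",
               "esophageal", "cervical", "endometrial", "liver", "kidney",
               "colorectal"),
    rr = c(75.6, 16.1, 17.4, 5.2, 12.6, 3.7, 7.7,
           10.9, 4.7, 11.3, 10.7, 4.0, 5.6, 3.2, 4.0, 2.4, 4.5, 1.0)
  )
  fh <- c(biliary_tract = 0.01, breast = 0.06, cervical = 0.01,
          colorectal = 0.08, endometrial = 0.01, esophageal = 0.02,
          gastric = 0.12, liver = 0.04, lung = 0.06, lymphoma = 0.01,
          ovarian = 0.01, pancreatic = 0.02, prostate = 0.03, kidney = 0.01)
  sim_config(
    n = n,
    regions = default_regions(),
    genes = c("BRCA1", "BRCA2"),
    background_rate = c(BRCA1 = 0.0015, BRCA2 = 0.0028),
    founder_variants = founders,
    cancer_types = ct,
    baseline_hazards = bh,
    true_or = true_or,
    p_female = 0.44,
    fh_background_rate = fh,
    fh_carrier_multiplier = 2,
    multi_primary_target = 0.063,
    seed = seed
  )
}

#' Single-gene, single-cancer configuration for calibration experiments
#'
#' A deliberately minimal generative model (one gene, one cancer type open to
#' both sexes, constant hazard, no founder structure, no multiple-primary
#' injection) used for type-I-error, confidence-interval-coverage and
#' penetrance-recovery experiments where the estimand must equal the
#' configured relative risk as closely as the design allows.
#'
#' @param n Cohort size.
#' @param carrier_freq Carrier frequency of the single gene.
#' @param rr Carrier hazard multiplier for the single cancer.
#' @param lifetime_risk Baseline cumulative risk to age 85.
#' @param fh_carrier_multiplier Family-history enrichment in carriers
#'   (1 = complete null).
#' @param seed RNG seed.
#' @return A `sim_config`.
#' @export
calibration_config <- function(n, carrier_freq, rr, lifetime_risk,
                               fh_carrier_multiplier = 1, seed = 1L) {
  ct <- data.frame(cancer = "site1", sex_restrict = "both")
  sim_config(
    n = n,
    regions = data.frame(region = "all", weight = 1),
    genes = "gene1",
    background_rate = c(gene1 = carrier_freq),
    cancer_types = ct,
    baseline_hazards = hazard_table("site1", c("F", "M"), lifetime_risk,
                                    shape = "constant"),
    true_or = data.frame(gene = "gene1", cancer = "site1", rr = rr),
    fh_background_rate = c(site1 = 0.05),
    fh_carrier_multiplier = fh_carrier_multiplier,
    multi_primary_target = 0,
    decoy_rate = 0,
    seed = seed
  )
}
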