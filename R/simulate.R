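#' Overall carrier frequency implied by a configuration
#'
#' Per gene: within each region the carrier probability combines background
#' and founder variants as 1 - (1-bg) * prod(1-f); the population frequency
#' is the region-weight mixture of these.
#'
#' @param config A `sim_config`.
#' @return Named numeric, one entry per gene.
#' @export
overall_carrier_freq <- function(config) {
  config <- validate_sim_config(config)
  vapply(config$genes, function(g) {
    per_region <- vapply(config$regions$region, function(r) {
      f <- 1
      fv <- config$founder_variants
      if (!is.null(fv) && nrow(fv) > 0) {
        sub <- fv[fv$gene == g & fv$region == r, , drop = FALSE]
        if (nrow(sub) > 0) f <- prod(1 - sub$freq)
      }
      1 - (1 - config$background_rate[[g]]) * f
    }, numeric(1))
    sum(config$regions$weight * per_region)
  }, numeric(1))
}

# Truncated-normal registration ages, rounded to whole years.
draw_registration_age <- function(n, ra) {
  lo <- stats::pnorm(ra$min, ra$mean, ra$sd)
  hi <- stats::pnorm(ra$max, ra$mean, ra$sd)
  round(stats::qnorm(stats::runif(n, lo, hi), ra$mean, ra$sd))
}

# Sample discrete onset ages from per-band hazards for one hazard-multiplier
# group. rates: per-band baseline hazard; mult: scalar multiplier; k draws.
# Returns integer onset ages, NA when no onset occurs before the last band.
sample_onset_group <- function(rates, age_lo, width, mult, k) {
  h <- rates * mult
  p_surv_band <- exp(-h * width)
  s <- cumsum(c(0, -h * width))        # log survival at band starts
  surv_start <- exp(s[seq_along(h)])
  p_band <- surv_start * (1 - p_surv_band)
  cum <- cumsum(p_band)
  u <- stats::runif(k)
  band <- findInterval(u, cum) + 1L
  onset <- rep(NA_integer_, k)
  hit <- band <= length(h)
  if (any(hit)) {
    b <- band[hit]
    q <- 1 - exp(-h[b])                # per-year event probability in band
    v <- stats::runif(sum(hit))
    # inverse CDF of the geometric truncated to the band's width years
    tail_w <- (1 - q)^width[b]
    yr <- ceiling(log1p(-v * (1 - tail_w)) / log(1 - q)) - 1
    yr <- pmin(pmax(yr, 0), width[b] - 1)
    onset[hit] <- as.integer(age_lo[b] + yr)
  }
  onset
}

# Onset ages for all individuals of one (cancer, sex) stratum given each
# individual's hazard multiplier; groups identical multipliers for speed.
sample_onsets <- function(bh_rows, mult) {
  bh_rows <- bh_rows[order(bh_rows$age_lo), , drop = FALSE]
  width <- bh_rows$age_hi - bh_rows$age_lo
  onset <- rep(NA_integer_, length(mult))
  for (m in unique(mult)) {
    idx <- which(mult == m)
    onset[idx] <- sample_onset_group(bh_rows$rate, bh_rows$age_lo, width, m,
                                     length(idx))
  }
  onset
}

#' Simulate a biobank-style case-control cohort
#'
#' Generates individuals (sex, region, registration age), latent dominant
#' carrier status per gene from founder and background pathogenic variants,
#' cancer onsets from discrete per-band hazards with carrier hazard =
#' relative risk x baseline, family-history reporting, and the
#' registry-style status split: patients (>=1 observed cancer), controls
#' (cancer-free and family-history-free) and excluded individuals
#' (cancer-free but reporting family history). Variant calls include
#' benign/VUS decoys that must not confer carrier status. A fraction of
#' single-cancer patients may receive an additional independent primary to
#' meet `multi_primary_target`.
#'
#' Onsets after the registration age are censored: those individuals are
#' cancer-free at recruitment, mirroring registry enrolment.
#'
#' @param config A validated `sim_config`.
#' @return A list of class `pv_simulation` with elements:
#'   \describe{
#'     \item{cohort}{data.frame: `individual_id`, `sex`, `region`, `status`
#'       (`case`/`control`/`excluded`), `age_registration`,
#'       `n_cancer_types`, and per cancer `case_*`, `agedx_*`, `fh_*`.}
#'     \item{calls}{data.frame of variant calls: `individual_id`, `gene`,
#'       `variant_id`, `class` (P/LP/VUS/LB/B), `founder`.}
#'     \item{truth}{ground truth: latent carrier matrix, configured relative
#'       risks, realized per-region carrier frequencies, seed.}
#'   }
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n
  genes <- config$genes
  cancers <- config$cancer_types$cancer

  individual_id <- sprintf("I%07d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$p_female, "F", "M")
  region <- sample(config$regions$region, n, replace = TRUE,
                   prob = config$regions$weight)
  age_registration <- draw_registration_age(n, config$registration_age)

  # --- pathogenic variant carriers -------------------------------------
  # background pool: 25 distinct variant ids per gene, alternating P / LP
  call_list <- list()
  latent <- matrix(FALSE, n, length(genes), dimnames = list(NULL, genes))
  for (g in genes) {
    pool <- sprintf("%s_pv%03d", g, 1:25)
    pool_class <- rep(c("P", "LP"), length.out = 25)
    bg_idx <- which(stats::runif(n) < config$background_rate[[g]])
    if (length(bg_idx) > 0) {
      vix <- sample.int(25, length(bg_idx), replace = TRUE)
      call_list[[length(call_list) + 1]] <- data.frame(
        individual_id = individual_id[bg_idx], gene = g,
        variant_id = pool[vix], class = pool_class[vix], founder = FALSE)
      latent[bg_idx, g] <- TRUE
    }
    fv <- config$founder_variants
    if (!is.null(fv) && nrow(fv) > 0) {
      for (j in which(fv$gene == g)) {
        in_reg <- which(region == fv$region[j])
        hit <- in_reg[stats::runif(length(in_reg)) < fv$freq[j]]
        if (length(hit) > 0) {
          call_list[[length(call_list) + 1]] <- data.frame(
            individual_id = individual_id[hit], gene = g,
            variant_id = fv$variant_id[j], class = "P", founder = TRUE)
          latent[hit, g] <- TRUE
        }
      }
    }
  }

  # decoy non-qualifying calls; classification is a property of the variant
  # (ids 1-24 VUS, 25-32 LB, 33-40 B), so any VCF record stays consistent
  if (config$decoy_rate > 0) {
    d_idx <- which(stats::runif(n) < config$decoy_rate)
    if (length(d_idx) > 0) {
      decoy_class <- rep(c("VUS", "LB", "B"), c(24, 8, 8))
      dg <- sample(genes, length(d_idx), replace = TRUE)
      dv <- sample.int(40, length(d_idx), replace = TRUE)
      call_list[[length(call_list) + 1]] <- data.frame(
        individual_id = individual_id[d_idx], gene = dg,
        variant_id = sprintf("%s_vus%03d", dg, dv),
        class = decoy_class[dv],
        founder = FALSE)
    }
  }
  calls <- if (length(call_list) > 0) {
    do.call(rbind, call_list)
  } else {
    data.frame(individual_id = character(), gene = character(),
               variant_id = character(), class = character(),
               founder = logical())
  }
  rownames(calls) <- NULL

  # --- cancer onsets ----------------------------------------------------
  rr_of <- function(g, cc) {
    to <- config$true_or
    if (is.null(to)) return(1)
    hit <- to$rr[to$gene == g & to$cancer == cc]
    if (length(hit) == 0) 1 else hit[1]
  }
  case <- matrix(0L, n, length(cancers), dimnames = list(NULL, cancers))
  agedx <- matrix(NA_integer_, n, length(cancers), dimnames = list(NULL, cancers))
  for (ci in seq_along(cancers)) {
    cc <- cancers[ci]
    restrict <- config$cancer_types$sex_restrict[ci]
    mult <- rep(1, n)
    for (g in genes) {
      r <- rr_of(g, cc)
      if (r != 1) mult[latent[, g]] <- mult[latent[, g]] * r
    }
    for (s in c("F", "M")) {
      if (restrict != "both" && restrict != s) next
      rows <- which(sex == s)
      if (length(rows) == 0) next
      bh <- config$baseline_hazards
      bh_rows <- bh[bh$cancer == cc & bh$sex == s, , drop = FALSE]
      onset <- sample_onsets(bh_rows, mult[rows])
      obs <- !is.na(onset) & onset <= age_registration[rows]
      case[rows[obs], ci] <- 1L
      agedx[rows[obs], ci] <- onset[obs]
    }
  }

  # --- multiple-primary injection --------------------------------------
  n_types <- rowSums(case)
  patients <- which(n_types >= 1)
  if (config$multi_primary_target > 0 && length(patients) > 0) {
    needed <- round(config$multi_primary_target * length(patients) -
                      sum(n_types[patients] >= 2))
    if (needed < 0) {
      # natural co-occurrence overshoots the target: thin a random excess of
      # multi-primary patients down to their earliest diagnosis
      multis <- patients[n_types[patients] >= 2]
      thin <- if (length(multis) <= -needed) multis else sample(multis, -needed)
      for (i in thin) {
        have <- which(case[i, ] == 1L)
        keep <- have[which.min(agedx[i, have])]
        drop <- setdiff(have, keep)
        case[i, drop] <- 0L
        agedx[i, drop] <- NA_integer_
      }
    }
    if (needed > 0) {
      singles <- patients[n_types[patients] == 1]
      # only singles with at least one sex-compatible unaffected cancer type
      can_extend <- vapply(singles, function(i) {
        any(case[i, ] == 0L & (config$cancer_types$sex_restrict == "both" |
                                 config$cancer_types$sex_restrict == sex[i]))
      }, logical(1))
      pool <- singles[can_extend]
      boost <- if (length(pool) <= needed) pool else sample(pool, needed)
      for (i in boost) {
        eligible <- which(case[i, ] == 0L &
                          (config$cancer_types$sex_restrict == "both" |
                           config$cancer_types$sex_restrict == sex[i]))
        ci <- if (length(eligible) == 1) eligible else sample(eligible, 1)
        case[i, ci] <- 1L
        agedx[i, ci] <- as.integer(floor(stats::runif(
          1, min(25, age_registration[i]), age_registration[i] + 1)))
      }
    }
    n_types <- rowSums(case)
  }

  # --- family history ---------------------------------------------------
  any_carrier <- rowSums(latent) > 0
  fh <- matrix(0L, n, length(cancers), dimnames = list(NULL, cancers))
  for (ci in seq_along(cancers)) {
    p <- config$fh_background_rate[[cancers[ci]]]
    pi <- ifelse(any_carrier, pmin(1, p * config$fh_carrier_multiplier), p)
    fh[, ci] <- as.integer(stats::runif(n) < pi)
  }

  is_case <- rowSums(case) > 0
  status <- ifelse(is_case, "case",
                   ifelse(rowSums(fh) == 0, "control", "excluded"))

  cohort <- data.frame(individual_id, sex, region, status,
                       age_registration, n_cancer_types = rowSums(case))
  for (ci in seq_along(cancers)) {
    cohort[[paste0("case_", cancers[ci])]] <- case[, ci]
    cohort[[paste0("agedx_", cancers[ci])]] <- agedx[, ci]
    cohort[[paste0("fh_", cancers[ci])]] <- fh[, ci]
  }

  realized <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g, region = config$regions$region,
               freq = vapply(config$regions$region, function(r) {
                 mean(latent[region == r, g])
               }, numeric(1)))
  }))
  rownames(realized) <- NULL

  truth <- structure(list(
    carrier = data.frame(individual_id, as.data.frame(latent)),
    true_or = config$true_or,
    region_carrier_freq = realized,
    seed = config$seed
  ), class = "pv_ground_truth")

  structure(list(cohort = cohort, calls = calls, truth = truth,
                 config = config),
            class = "pv_simulation")
}

#' @export
print.pv_simulation <- function(x, ...) {
  st <- table(factor(x$cohort$status, c("case", "control", "excluded")))
  cat(sprintf("<pv_simulation> n=%d (%d cases, %d controls, %d excluded), %d variant calls\n",
              nrow(x$cohort), st[["case"]], st[["control"]], st[["excluded"]],
              nrow(x$calls)))
  invisible(x)
}

#' Population incidence table implied by a configuration
#'
#' Emits the exact genotype-mixture population incidence per (cancer, sex,
#' age band): with per-gene carrier frequency p_g and relative risk rr_g the
#' per-band rate is lambda_pop = lambda_0 * prod_g (1 + p_g * (rr_g - 1)).
#' For a single gene this is the familiar
#' lambda_pop = p * rr * lambda_0 + (1 - p) * lambda_0.
#'
#' @param config A `sim_config`.
#' @return A data.frame with columns `cancer`, `sex`, `age_lo`, `age_hi`,
#'   `rate`, covering every configured (cancer, applicable sex, band)
#'   exactly once.
#' @export
simulate_incidence_table <- function(config) {
  config <- validate_sim_config(config)
  p <- overall_carrier_freq(config)
  bh <- config$baseline_hazards
  rr_of <- function(g, cc) {
    to <- config$true_or
    if (is.null(to)) return(1)
    hit <- to$rr[to$gene == g & to$cancer == cc]
    if (length(hit) == 0) 1 else hit[1]
  }
  mult <- vapply(seq_len(nrow(bh)), function(i) {
    prod(vapply(config$genes, function(g) {
      1 + p[[g]] * (rr_of(g, bh$cancer[i]) - 1)
    }, numeric(1)))
  }, numeric(1))
  out <- bh
  out$rate <- bh$rate * mult
  out <- out[order(out$cancer, out$sex, out$age_lo), , drop = FALSE]
  rownames(out) <- NULL
  out
}
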