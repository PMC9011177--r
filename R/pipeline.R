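stage_stop <- function(stage, msg) {
  stop(sprintf("[stage %s] %s", stage, msg), call. = FALSE)
}

#' Run the full analysis pipeline on one configuration
#'
#' Orchestrates simulate -> collapse -> associate -> heterogeneity ->
#' penetrance -> report into a single run directory, with every numeric
#' output written unrounded as TSV/JSON and a manifest recording the seed,
#' a config digest and MD5 digests of every output file. Re-running with
#' the same configuration reproduces byte-identical numeric outputs.
#'
#' @param config A `sim_config`, or the path to a YAML/JSON config file.
#' @param out_dir Run directory (created if needed).
#' @param incidence_file Optional path to an external incidence TSV
#'   (`cancer`, `sex`, `age_lo`, `age_hi`, `rate`); by default the exact
#'   config-implied population incidence is used. A missing file is a
#'   configuration error naming the file.
#' @param designs Association designs to run (default the estimate-bearing
#'   `no_family_history` plus the test-only `all_patients`).
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, incidence_file = NULL,
                         designs = c("all_patients", "no_family_history"),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.character(config)) {
    if (!file.exists(config)) stage_stop("config", sprintf("config file not found: %s", config))
    config <- read_sim_config(config)
  }
  config <- validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(incidence_file) && !file.exists(incidence_file)) {
    stage_stop("penetrance", sprintf("incidence file not found: %s", incidence_file))
  }

  say("stage simulate: n=%d, seed=%d", config$n, config$seed)
  sim <- tryCatch(simulate_cohort(config),
                  error = function(e) stage_stop("simulate", conditionMessage(e)))
  write_tsv_table(sim$cohort, file.path(out_dir, "cohort.tsv"))
  write_tsv_table(sim$calls, file.path(out_dir, "calls.tsv"))

  say("stage collapse: %d calls", nrow(sim$calls))
  carriers <- tryCatch(
    collapse_carriers(sim$calls, config$genes, roster = sim$cohort$individual_id),
    error = function(e) stage_stop("collapse", conditionMessage(e)))
  write_carrier_table(carriers, file.path(out_dir, "carriers.tsv"))

  incidence <- if (is.null(incidence_file)) {
    simulate_incidence_table(config)
  } else {
    read_tsv_table(incidence_file)
  }
  write_tsv_table(incidence, file.path(out_dir, "incidence.tsv"))

  say("stage associate: %d designs x %d genes x %d cancers",
      length(designs), length(config$genes), nrow(config$cancer_types))
  assoc <- tryCatch(
    do.call(rbind, lapply(designs, function(dd) {
      run_all_associations(sim$cohort, carriers, config$genes,
                           config$cancer_types, design = dd)
    })),
    error = function(e) stage_stop("associate", conditionMessage(e)))
  write_tsv_table(assoc, file.path(out_dir, "associations.tsv"))

  say("stage heterogeneity")
  est <- assoc[assoc$design == "no_family_history" & !assoc$gated &
                 !is.na(assoc$or), , drop = FALSE]
  het <- tryCatch({
    pairs <- data.frame(cancer = paste0(est$cancer,
                                        ifelse(est$sex == "both", "",
                                               paste0("_", tolower(est$sex)))),
                        gene = est$gene, or = est$or, lo = est$lo, hi = est$hi)
    heterogeneity_pairs(pairs)
  }, error = function(e) stage_stop("heterogeneity", conditionMessage(e)))
  write_tsv_table(het, file.path(out_dir, "heterogeneity.tsv"))

  say("stage penetrance")
  controls <- sim$cohort[sim$cohort$status == "control", , drop = FALSE]
  m <- match(controls$individual_id, carriers$individual_id)
  pfreq <- vapply(config$genes, function(g) {
    mean(carriers[[paste0("carrier_", g)]][m])
  }, numeric(1))
  sig <- est[est$p < 1e-4, , drop = FALSE]
  pen <- tryCatch(
    penetrance_table(sig, incidence, pfreq, seed = config$seed),
    error = function(e) stage_stop("penetrance", conditionMessage(e)))
  write_tsv_table(pen, file.path(out_dir, "penetrance.tsv"))

  say("stage report")
  report <- tryCatch({
    summ <- summarize_cohort(sim$cohort, carriers)
    reg <- lapply(stats::setNames(config$genes, config$genes), function(g) {
      bd <- regional_breakdown(sim$cohort, carriers, sim$calls, g)
      res <- list(breakdown = as.data.frame(bd),
                  fold_difference = attr(bd, "fold_difference"))
      if (nrow(bd) >= 2 && all(bd$n > 0)) {
        all_t <- regional_chisq(bd)
        nf <- regional_chisq(bd, exclude_founders = TRUE)
        res$chisq <- list(statistic = all_t$statistic, df = all_t$df, p = all_t$p)
        res$chisq_nonfounder <- list(statistic = nf$statistic, df = nf$df, p = nf$p)
      }
      res
    })
    list(summary = summ, regional = reg,
         carrier_freq_controls = as.list(pfreq))
  }, error = function(e) stage_stop("report", conditionMessage(e)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_file <- file.path(out_dir, "config.json")
  write_sim_config(config, cfg_file)
  outputs <- c("cohort.tsv", "calls.tsv", "carriers.tsv", "incidence.tsv",
               "associations.tsv", "heterogeneity.tsv", "penetrance.tsv",
               "report.json", "config.json")
  digests <- tools::md5sum(file.path(out_dir, outputs))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pvburden")),
    seed = config$seed,
    config_digest = unname(tools::md5sum(cfg_file)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = c("simulate", "collapse", "associate", "heterogeneity",
               "penetrance", "report"),
    files = as.list(stats::setNames(unname(digests), outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: %s", out_dir)
  invisible(manifest)
}

#' Heterogeneity report for a table of published OR pairs
#'
#' Reads an OR-pair TSV (`cancer`, `gene`, `or`, `lo`, `hi`), computes
#' between-gene heterogeneity per cancer type with [heterogeneity_pairs()]
#' and optionally writes the result; output is sorted by cancer so row
#' order of the input does not matter.
#'
#' @param pairs_file Path to the pairs TSV; defaults to the shipped
#'   published-pairs fixture.
#' @param out Optional output TSV path.
#' @return The heterogeneity data.frame, invisibly when `out` is given.
#' @export
pairs_heterogeneity_report <- function(pairs_file = NULL, out = NULL) {
  pairs <- if (is.null(pairs_file)) published_or_pairs() else read_tsv_table(pairs_file)
  het <- heterogeneity_pairs(pairs)
  if (!is.null(out)) {
    write_tsv_table(het, out)
    return(invisible(het))
  }
  het
}
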