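#' Write / read tab-separated tables
#'
#' Plain TSV with a header row, no quoting, `NA` for missing values; the
#' interchange format for every table in the pipeline.
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `read_tsv_table` returns a data.frame; `write_tsv_table` returns
#'   `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a variant-call table
#'
#' Expects columns `individual_id`, `gene`, `variant_id`, `class` and
#' optionally `founder`; classification labels are validated downstream by
#' [collapse_carriers()].
#'
#' @param path TSV file path.
#' @return A data.frame of calls.
#' @export
read_variant_calls <- function(path) {
  x <- read_tsv_table(path)
  need <- c("individual_id", "gene", "variant_id", "class")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop(sprintf("variant call table %s lacks columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"founder" %in% names(x)) x$founder <- FALSE
  x
}

#' Write variant calls as a minimal VCF
#'
#' A deliberately small VCF dialect: one record per distinct variant,
#' `CLASS=` (one of P/LP/VUS/LB/B) and `FOUNDER=` in INFO, one sample column
#' per individual with GT `0/1` for individuals called with the variant and
#' `0/0` otherwise. Positions are synthetic ordinals (variant identity lives
#' in the ID column), since the call tables carry opaque variant ids rather
#' than genomic coordinates.
#'
#' @param calls Call data.frame (`individual_id`, `gene`, `variant_id`,
#'   `class`, optional `founder`).
#' @param path Output file.
#' @param individuals Sample ids to emit as columns; defaults to the
#'   individuals present in `calls`.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path, individuals = NULL) {
  if (is.null(individuals)) individuals <- sort(unique(calls$individual_id))
  if (!"founder" %in% names(calls)) calls$founder <- FALSE
  key <- paste(calls$gene, calls$variant_id, sep = "\r")
  variants <- !duplicated(key)
  vtab <- calls[variants, c("gene", "variant_id", "class", "founder")]
  vtab <- vtab[order(vtab$gene, vtab$variant_id), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Clinical classification: P, LP, VUS, LB or B\">",
    "##INFO=<ID=FOUNDER,Number=0,Type=Flag,Description=\"Regional founder variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individuals), collapse = "\t")
  ), con)
  sample_pos <- stats::setNames(seq_along(individuals), individuals)
  for (i in seq_len(nrow(vtab))) {
    g <- vtab$gene[i]; v <- vtab$variant_id[i]
    who <- calls$individual_id[calls$gene == g & calls$variant_id == v]
    gt <- rep("0/0", length(individuals))
    gt[sample_pos[unique(who)]] <- "0/1"
    info <- sprintf("GENE=%s;CLASS=%s%s", g, vtab$class[i],
                    if (isTRUE(vtab$founder[i])) ";FOUNDER" else "")
    writeLines(paste(c(g, i, v, "N", "<ALT>", ".", "PASS", info, "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read the minimal VCF dialect back into a call table
#'
#' @param path VCF file written by [write_variant_vcf()].
#' @return A call data.frame (`individual_id`, `gene`, `variant_id`,
#'   `class`, `founder`), one row per called (individual, variant).
#' @export
read_variant_vcf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("not a VCF: missing #CHROM header line", call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  individuals <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  out <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    info <- strsplit(f[8], ";")[[1]]
    kv <- strsplit(info, "=")
    keys <- vapply(kv, `[`, "", 1)
    val <- function(k) {
      i <- match(k, keys)
      if (is.na(i)) NA_character_ else kv[[i]][2]
    }
    carriers <- individuals[f[-(1:9)] != "0/0"]
    if (length(carriers) > 0) {
      out[[length(out) + 1]] <- data.frame(
        individual_id = carriers, gene = val("GENE"), variant_id = f[3],
        class = val("CLASS"), founder = "FOUNDER" %in% keys)
    }
  }
  if (length(out) == 0) {
    return(data.frame(individual_id = character(), gene = character(),
                      variant_id = character(), class = character(),
                      founder = logical()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Serializable plain-list view of a sim_config (data.frames become lists of
# column vectors so YAML/JSON round-trip cleanly).
config_to_list <- function(cfg) {
  df2l <- function(d) if (is.null(d)) NULL else as.list(d)
  list(
    n = cfg$n,
    regions = df2l(cfg$regions),
    genes = cfg$genes,
    background_rate = as.list(cfg$background_rate),
    founder_variants = df2l(cfg$founder_variants),
    cancer_types = df2l(cfg$cancer_types),
    baseline_hazards = df2l(cfg$baseline_hazards),
    true_or = df2l(cfg$true_or),
    p_female = cfg$p_female,
    fh_background_rate = as.list(cfg$fh_background_rate),
    fh_carrier_multiplier = cfg$fh_carrier_multiplier,
    multi_primary_target = cfg$multi_primary_target,
    registration_age = cfg$registration_age,
    decoy_rate = cfg$decoy_rate,
    seed = cfg$seed
  )
}

list_to_config <- function(x) {
  l2df <- function(l) if (is.null(l) || length(l) == 0) NULL else as.data.frame(l)
  sim_config(
    n = x$n,
    regions = l2df(x$regions),
    genes = unlist(x$genes),
    background_rate = unlist(x$background_rate),
    founder_variants = l2df(x$founder_variants),
    cancer_types = l2df(x$cancer_types),
    baseline_hazards = l2df(x$baseline_hazards),
    true_or = l2df(x$true_or),
    p_female = x$p_female,
    fh_background_rate = unlist(x$fh_background_rate),
    fh_carrier_multiplier = x$fh_carrier_multiplier,
    multi_primary_target = x$multi_primary_target,
    registration_age = x$registration_age,
    decoy_rate = x$decoy_rate,
    seed = x$seed
  )
}

#' Write / read a simulation configuration as YAML or JSON
#'
#' The format is chosen from the file extension (`.yaml`/`.yml` or
#' `.json`); the configuration is schema-validated on load, so malformed
#' files fail with an error naming the offending field.
#'
#' @param cfg A `sim_config`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_sim_config` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  cfg <- validate_sim_config(cfg)
  x <- config_to_list(cfg)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  }
  list_to_config(x)
}
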