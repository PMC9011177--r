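CLASS_LEVELS <- c("P", "LP", "VUS", "LB", "B") # most to least severe

#' Collapse classified variant calls to dominant-model carrier status
#'
#' An individual is a carrier of a gene if they have at least one call in
#' that gene classified Pathogenic or Likely Pathogenic; VUS, Likely benign
#' and Benign calls never confer carrier status. Duplicate calls on the same
#' (individual, gene, variant) are deduplicated keeping the most severe
#' classification (P > LP > VUS > LB > B). Individuals present in `roster`
#' but absent from the calls are treated as sequenced noncarriers unless
#' `strict = TRUE`, in which case they must appear in the calls file
#' explicitly.
#'
#' @param calls Data.frame with columns `individual_id`, `gene`,
#'   `variant_id`, `class`; unknown classification labels are an error
#'   citing the offending row.
#' @param genes Character vector of genes to collapse (non-empty).
#' @param roster Optional character vector of all sequenced individual ids;
#'   defaults to the individuals appearing in `calls`.
#' @param strict If `TRUE`, error when a roster individual has no call rows
#'   at all (explicit wild-type rows required).
#' @return A data.frame (class `carrier_table`) with `individual_id`, one
#'   logical `carrier_<gene>` column and one comma-separated
#'   `variants_<gene>` column of qualifying variant ids per gene, plus
#'   `carrier_multiple` flagging individuals carrying pathogenic variants
#'   in more than one gene.
#' @export
collapse_carriers <- function(calls, genes, roster = NULL, strict = FALSE) {
  if (length(genes) == 0) stop("genes must be non-empty", call. = FALSE)
  need <- c("individual_id", "gene", "variant_id", "class")
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0) {
    stop(sprintf("calls lack columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!calls$class %in% CLASS_LEVELS)
  if (length(bad) > 0) {
    stop(sprintf("unknown classification '%s' in call row %d (individual %s, %s %s)",
                 calls$class[bad[1]], bad[1], calls$individual_id[bad[1]],
                 calls$gene[bad[1]], calls$variant_id[bad[1]]), call. = FALSE)
  }
  if (is.null(roster)) roster <- sort(unique(calls$individual_id))
  if (strict) {
    absent <- setdiff(roster, calls$individual_id)
    if (length(absent) > 0) {
      stop(sprintf("strict mode: %d roster individuals have no call rows (first: %s)",
                   length(absent), absent[1]), call. = FALSE)
    }
  }
  # dedupe on (individual, gene, variant), keeping the most severe class
  sev <- match(calls$class, CLASS_LEVELS)
  o <- order(calls$individual_id, calls$gene, calls$variant_id, sev)
  calls <- calls[o, , drop = FALSE]
  key <- paste(calls$individual_id, calls$gene, calls$variant_id, sep = "\r")
  calls <- calls[!duplicated(key), , drop = FALSE]

  out <- data.frame(individual_id = roster, stringsAsFactors = FALSE)
  qual <- calls[calls$class %in% c("P", "LP"), , drop = FALSE]
  for (g in genes) {
    gq <- qual[qual$gene == g, , drop = FALSE]
    ids <- split(gq$variant_id, gq$individual_id)
    vstr <- vapply(ids, function(v) paste(sort(v), collapse = ","), "")
    m <- match(out$individual_id, names(vstr))
    out[[paste0("carrier_", g)]] <- !is.na(m)
    out[[paste0("variants_", g)]] <- ifelse(is.na(m), "", vstr[m])
  }
  flags <- as.matrix(out[, paste0("carrier_", genes), drop = FALSE])
  out$carrier_multiple <- rowSums(flags) > 1
  structure(out, class = c("carrier_table", "data.frame"), genes = genes)
}

#' Carrier proportion with exact binomial confidence interval
#'
#' Clopper-Pearson 95% interval via [stats::binom.test()].
#'
#' @param carrier Logical vector of carrier flags for the group, or a
#'   single count of carriers when `n` is given.
#' @param n Group size when `carrier` is a count.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `carriers`, `n`, `prop`, `lo`, `hi`.
#' @export
carrier_frequency <- function(carrier, n = NULL, conf_level = 0.95) {
  if (is.null(n)) {
    if (length(carrier) == 0) stop("empty group", call. = FALSE)
    x <- sum(carrier)
    n <- length(carrier)
  } else {
    if (n <= 0) stop("empty group", call. = FALSE)
    x <- carrier
  }
  ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
  list(carriers = x, n = n, prop = x / n, lo = ci[1], hi = ci[2])
}

#' Tally distinct variants by clinical classification
#'
#' Counts distinct (gene, variant) pairs per classification after
#' severity-dedup, and the fraction assigned pathogenic (P or LP), the
#' summary a curation effort reports for its classified variant set.
#'
#' @param calls Variant call data.frame.
#' @return A list with `n_variants`, `n_pathogenic`, `pct_pathogenic`
#'   (percent, 1 decimal) and the per-class count table `by_class`.
#' @export
variant_class_summary <- function(calls) {
  sev <- match(calls$class, CLASS_LEVELS)
  if (anyNA(sev)) stop("unknown classification label in calls", call. = FALSE)
  o <- order(calls$gene, calls$variant_id, sev)
  calls <- calls[o, , drop = FALSE]
  key <- paste(calls$gene, calls$variant_id, sep = "\r")
  v <- calls[!duplicated(key), , drop = FALSE]
  tab <- table(factor(v$class, CLASS_LEVELS))
  n_path <- sum(v$class %in% c("P", "LP"))
  list(n_variants = nrow(v), n_pathogenic = n_path,
       pct_pathogenic = round(100 * n_path / nrow(v), 1),
       by_class = tab)
}

carrier_col <- function(carriers, gene) {
  col <- paste0("carrier_", gene)
  if (!col %in% names(carriers)) {
    stop(sprintf("unknown gene '%s' in carrier table", gene), call. = FALSE)
  }
  col
}

#' Write / read a carrier table
#' @param carriers A `carrier_table`.
#' @param path File path.
#' @return `read_carrier_table` returns a `carrier_table`.
#' @export
write_carrier_table <- function(carriers, path) {
  write_tsv_table(as.data.frame(carriers), path)
}

#' @rdname write_carrier_table
#' @export
read_carrier_table <- function(path) {
  x <- read_tsv_table(path)
  genes <- sub("^carrier_", "", grep("^carrier_(?!multiple)", names(x),
                                     value = TRUE, perl = TRUE))
  vcols <- paste0("variants_", genes)
  x[vcols][is.na(x[vcols])] <- ""
  structure(x, class = c("carrier_table", "data.frame"), genes = genes)
}
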