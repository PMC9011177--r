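# Small generative configs and call-table builders shared across tests.

# Two regions, two genes (one founder variant confined to region "a"),
# two cancers (one female-restricted), modest n.
tiny_config <- function(n = 4000, seed = 1L, rr1 = 5, rr2 = 3,
                        multi_primary_target = 0, fh_mult = 2) {
  ct <- data.frame(cancer = c("siteA", "siteB"),
                   sex_restrict = c("both", "F"))
  bh <- rbind(hazard_table("siteA", c("F", "M"), 0.08, shape = "constant"),
              hazard_table("siteB", "F", 0.04, shape = "constant"))
  sim_config(
    n = n,
    regions = data.frame(region = c("a", "b"), weight = c(0.5, 0.5)),
    genes = c("g1", "g2"),
    background_rate = c(g1 = 0.004, g2 = 0.006),
    founder_variants = data.frame(gene = "g1", variant_id = "g1_fndrA",
                                  region = "a", freq = 0.01),
    cancer_types = ct,
    baseline_hazards = bh,
    true_or = data.frame(gene = c("g1", "g2"), cancer = c("siteA", "siteA"),
                         rr = c(rr1, rr2)),
    fh_background_rate = c(siteA = 0.05, siteB = 0.02),
    fh_carrier_multiplier = fh_mult,
    multi_primary_target = multi_primary_target,
    seed = seed
  )
}

# Call table from a compact spec: list of c(id, gene, variant, class)
make_calls <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(individual_id = r[1], gene = r[2], variant_id = r[3],
               class = r[4],
               founder = if (length(r) >= 5) as.logical(r[5]) else FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Constant-rate band table on [0, 85)
const_bands <- function(rate, width = 5) {
  b <- age_bands(width)
  b$rate <- rate
  b
}
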