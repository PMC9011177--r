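#!/usr/bin/env Rscript
# Stage 4: between-gene heterogeneity of the odds ratios, per cancer type.
# First on the published OR pairs shipped with the package (the desk-scale
# reference computation), then on the simulated cohort's own estimates.

library(pvburden)

out <- "results/run"

pub <- pairs_heterogeneity_report()
write_tsv_table(pub, file.path(out, "heterogeneity_published.tsv"))
cat("published OR pairs: Cochran Q / I2 per cancer type\n")
print(pub[, c("cancer", "Q", "p_het", "I2", "pooled_or")], digits = 3,
      row.names = FALSE)

assoc <- read_tsv_table(file.path(out, "associations.tsv"))
est <- assoc[assoc$design == "no_family_history" & !assoc$gated &
               !is.na(assoc$or), ]
pairs <- data.frame(
  cancer = paste0(est$cancer, ifelse(est$sex == "both", "",
                                     paste0("_", tolower(est$sex)))),
  gene = est$gene, or = est$or, lo = est$lo, hi = est$hi)
sim_het <- heterogeneity_pairs(pairs)
write_tsv_table(sim_het, file.path(out, "heterogeneity_simulated.tsv"))
both <- sim_het[sim_het$k >= 2, ]
cat(sprintf("\nsimulated cohort: %d cancer types with both gene estimates\n",
            nrow(both)))
if (nrow(both) > 0) {
  print(both[, c("cancer", "Q", "p_het", "I2")], digits = 3, row.names = FALSE)
}
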