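#!/usr/bin/env Rscript
# Treatment inference: block-random-effect mixed models for each structural
# response (treatment + log floral display fixed effects, interaction
# pruned when non-significant), the metric correlation matrix, and
# Kruskal-Wallis/Dunn tests of plant-species-visited for the ten most
# abundant visitor species.
library(bloomnet)

interactions <- read_interactions("results/interactions.csv")
metadata <- read_metadata("results/metadata.csv")
metrics <- read_metrics_table("results/metrics.csv")

eff <- effect_tables(metrics)
write.csv(eff, "results/effects.csv", row.names = FALSE)
cat("Mixed-model treatment contrasts (p < 0.05):\n")
sig <- eff[grepl("^C-", eff$contrast) & eff$p < 0.05, ]
if (nrow(sig)) print(sig[c("response", "contrast", "estimate", "t", "p",
                           "R2m", "R2c")], digits = 3) else cat("  (none)\n")

vars <- c("abundance", "insect_richness", "unweighted_degree",
          "weighted_degree", "connectance", "nodf", "nodfc", "modularity",
          "display_log")
cm <- correlation_matrix(metrics, vars)
rsig <- cm$r; rsig[!cm$significant] <- NA
write.csv(round(rsig, 3), "results/correlations.csv")
cat("\nSignificant Pearson correlations with connectance:\n")
cc <- rsig["connectance", ]
print(round(cc[!is.na(cc) & names(cc) != "connectance"], 2))

top <- top_visitor_tests(interactions, n_top = 10)
rows <- do.call(rbind, lapply(names(top), function(sp) {
  cbind(species = sp, top[[sp]]$contrasts)
}))
write.csv(rows, "results/top_visitors.csv", row.names = FALSE)
cat("\nTop-visitor contrasts with Bonferroni-adjusted p < 0.05:\n")
hits <- rows[!is.na(rows$p_adj) & rows$p_adj < 0.05, ]
if (nrow(hits)) print(hits, digits = 3) else cat("  (none)\n")
cat("\nWrote results/effects.csv, results/correlations.csv, results/top_visitors.csv\n")
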