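#!/usr/bin/env Rscript
# Standardize the observed network metrics against fixed-margin (Patefield)
# null ensembles: 500 null matrices per network, z-scores per metric, and
# the treatment-level "mean +/- sd excludes 0" null-departure summary.
library(bloomnet)

seed <- 20240601L
n_null <- 500L

interactions <- read_interactions("results/interactions.csv")
metadata <- read_metadata("results/metadata.csv")
networks <- build_all_networks(interactions, metadata)
metrics <- read_metrics_table("results/metrics.csv")
I_total <- length(unique(interactions$insect))

z <- z_score_table(networks, metrics, n_null = n_null, seed = seed,
                   I_total = I_total)
write.csv(z, "results/z_scores.csv", row.names = FALSE)

dep <- departure_summary(z, metadata)
write.csv(dep, "results/departures.csv", row.names = FALSE)

cat(sprintf("z-scores for %d networks against %d-draw null ensembles\n",
            nrow(z), n_null))
cat("\nTreatment-level departures from the null expectation:\n")
print(dep[dep$departure, c("treatment", "metric", "mean_z", "sd_z")],
      digits = 3)

zeff <- z_effect_tables(z, metadata)
write.csv(zeff, "results/z_effects.csv", row.names = FALSE)
sig <- zeff[grepl("^C-", zeff$contrast) & zeff$p < 0.05, ]
cat("\nTreatment-vs-control contrasts on z-scores with p < 0.05:\n")
if (nrow(sig)) print(sig[c("response", "contrast", "estimate", "t", "p")],
                     digits = 3) else cat("  (none)\n")
cat("\nWrote results/z_scores.csv, results/departures.csv, results/z_effects.csv\n")
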