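#!/usr/bin/env Rscript
# Hill-number diversity (orders 0, 1, 2) and estimated sample coverage for
# the pooled visitor abundances of each treatment, plus interpolated
# rarefaction curves.
library(bloomnet)

interactions <- read_interactions("results/interactions.csv")

div <- diversity_summary(interactions)
write.csv(div, "results/diversity.csv", row.names = FALSE)
cat("Per-treatment Hill numbers and sample coverage:\n")
print(cbind(div[c("treatment", "n")], round(div[c("q0", "q1", "q2")], 1),
            coverage = sprintf("%.1f%%", 100 * div$coverage)))

curves <- do.call(rbind, lapply(sort(unique(interactions$treatment)),
  function(trt) {
    sub <- interactions[interactions$treatment == trt, ]
    ab <- tapply(sub$count, sub$insect, sum)
    sizes <- unique(round(seq(1, sum(ab), length.out = 30)))
    do.call(rbind, lapply(c(0, 1, 2), function(q) {
      cbind(treatment = trt, q = q, rarefaction_curve(ab, sizes, q = q))
    }))
  }))
write.csv(curves, "results/rarefaction.csv", row.names = FALSE)
cat(sprintf("\nMinimum sample coverage across treatments: %.1f%%\n",
            100 * min(div$coverage)))
cat("Wrote results/diversity.csv and results/rarefaction.csv\n")
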