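#!/usr/bin/env Rscript
# HSA synergy scoring of a two-drug viability matrix on the study's dose
# grid: OLA at 0.6/1/2 uM crossed with the LIG1 inhibitor L82-G17 at
# 10/20/30 uM. The viability matrix here is synthetic (a drug-interaction
# surface with a uniform 15-point excess over the best single agent);
# replace it with plate quantifications to score real data.

suppressPackageStartupMessages(library(screenkit))

out <- "results/synergy"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

doses_ola <- c(0, 0.6, 1, 2)    # uM
doses_l82 <- c(0, 10, 20, 30)   # uM
v <- matrix(100, 4, 4)
v[, 1] <- c(100, 80, 65, 45)    # OLA alone
v[1, ] <- c(100, 85, 70, 55)    # L82-G17 alone
for (i in 2:4) for (j in 2:4) v[i, j] <- min(v[i, 1], v[1, j]) - 15

m <- dose_matrix(doses_ola, doses_l82, v, drug_a = "OLA", drug_b = "L82-G17")
res <- hsa_score(m)
cat(sprintf("HSA synergy score: %.1f (%s)\n", res$score, res$classification))
write.csv(res$excess, file.path(out, "hsa_excess_synthetic.csv"))
cat("excess matrix written to", file.path(out, "hsa_excess_synthetic.csv"), "\n")
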