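#!/usr/bin/env Rscript
# Score every (cell line, contrast) with the NTC-resampling pipeline:
# essentials excluded and NTC guides aggregated into random 4-guide
# pseudogenes, 100 repetitions, averaged normZ with BH FDR per tail.
# The fitness contrast (DMSO vs T0) keeps the essentials so their dropout
# anchors the normZ scale. Reads results/screens/, writes results/scores/.

suppressPackageStartupMessages(library(screenkit))

seed <- 20260102
ind <- "results/screens"
out <- "results/scores"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lib <- read_library(file.path(ind, "library.tsv"))
contrasts <- list(
  list(label = "DMSO_vs_T0", control = "T0", treated = "DMSO", exclude = character(0)),
  list(label = "OLA_vs_DMSO", control = "DMSO", treated = "OLA", exclude = "essential"),
  list(label = "TALA_vs_DMSO", control = "DMSO", treated = "TALA", exclude = "essential"))

for (cl in c("LINE_A", "LINE_B")) {
  tab <- read_count_table(file.path(ind, sprintf("counts_%s.tsv", cl)), lib,
                          read_sample_sheet(file.path(ind, sprintf("samples_%s.tsv", cl))))
  for (ci in seq_along(contrasts)) {
    cc <- contrasts[[ci]]
    avg <- resampled_scores(
      tab, contrast_spec(cc$label, cc$control, cc$treated), engine_params(),
      resampling_params(n_rep = 100, seed = child_seed(seed, 100 * ci + match(cl, c("LINE_A", "LINE_B"))),
                        excluded_categories = cc$exclude))
    write_averaged_scores(avg, file.path(out, sprintf("scores_%s_%s.tsv", cl, cc$label)))
    cat(sprintf("%s %s: %d genes, NTC pseudogene normZ mean %+.3f, top gene %s (%.2f)\n",
                cl, cc$label, nrow(avg$scores), mean(avg$ntc$mean_normZ),
                avg$scores$gene[1], avg$scores$mean_normZ[1]))
  }
}
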