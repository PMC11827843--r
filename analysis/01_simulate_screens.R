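#!/usr/bin/env Rscript
# Simulate the study-scale screens: the 2,000-guide custom library (356
# target + 63 essential genes at 4 sgRNAs/gene, 324 NTC) in two cell lines,
# arms T0 / DMSO / OLA / TALA, 15 population doublings, 300x coverage.
# 20 target genes are planted as PARPi sensitizers (s = -0.5 log2/doubling)
# and every essential gene drops out at f = -0.5. Writes count tables,
# sample sheets, and truth labels under results/screens/.

suppressPackageStartupMessages(library(screenkit))

seed <- 20260101
out <- "results/screens"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lib <- compose_library(356, 63, 324, 4)
write_library(lib, file.path(out, "library.tsv"))

sens_genes <- sprintf("TGT%04d", 1:20)
ess_genes <- unique(lib$gene[lib$category == "essential"])
model <- effect_model(
  fitness = setNames(rep(-0.5, length(ess_genes)), ess_genes),
  sensitization = list(
    OLA = setNames(rep(-0.5, 20), sens_genes),
    TALA = setNames(rep(-0.5, 20), sens_genes)),
  doublings = c(DMSO = 15, OLA = 15, TALA = 15))

for (i in seq_along(cl <- c("LINE_A", "LINE_B"))) {
  sim <- simulate_screen(lib, model, seed = child_seed(seed, i),
                         cell_line = cl[i])
  write_count_table(sim$table, file.path(out, sprintf("counts_%s.tsv", cl[i])))
  write_sample_sheet(sim$samples, file.path(out, sprintf("samples_%s.tsv", cl[i])))
  if (i == 1) {
    write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  rep <- validate_screen(sim$table, sim$samples)
  cat(sprintf("%s: %d guides x %d samples, %d validation violations\n",
              cl[i], nrow(sim$table), length(count_samples(sim$table)),
              nrow(rep)))
}
cat("planted sensitizers:", paste(sens_genes[1:5], collapse = ", "), "...\n")
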