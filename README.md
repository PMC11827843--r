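# screenkit

Analysis toolkit for pooled CRISPR/Cas9 knockout dropout screens run with and
without drug treatment, built for the common chemogenetic design: a custom
sgRNA library over a focused gene panel (here, DNA repair genes), positive
controls (essential genes), a large bank of non-targeting controls (NTC), and
arms T0 / vehicle / drug grown for ~15 population doublings. Its target users
are functional-genomics analysts who need drug-sensitizer calls with an
honest, control-anchored null — plus a highest-single-agent (HSA) synergy
scorer for follow-up two-drug viability matrices.

## The statistics

**Guide and gene scoring (normZ).** For a contrast (e.g. olaparib vs DMSO),
counts in each sample are normalized to `c' = p + c * S / sum(c)` (pseudocount
`p = 5`, scale `S = 10^7`) and every guide gets a log2 fold change
`fc = log2(c'_trt / c'_ctrl)`. Guides are ranked by normalized control count
and each guide's fold change is standardized by the empirical-Bayes standard
deviation of the fold changes in a ±w rank window around it
(`w = min(500, max(50, floor(n/4)))`), giving `z = fc / sd_w`. Per gene g with
guide observations `z_1..z_k`:

    sumZ_g  = sum(z_i),    raw_g = sumZ_g / sqrt(k)
    normZ_g = (raw_g - mean(raw)) / sd(raw)        (over all scored units)

One-tailed p-values come from the standard normal (left tail = depletion =
sensitizer; right tail = enrichment), with Benjamini–Hochberg FDR per tail.

**NTC-pseudogene resampling null.** For a custom library the gene panel is
biased, so the null is anchored on the NTCs: essential genes are excluded from
the count table, the NTC guides are randomly aggregated into 4-guide
pseudogenes scored like genes, and the whole scoring run is repeated over
n = 100 random aggregations. Each real gene's normZ is the average over the
100 repetitions; p-values are taken from the averaged z and BH-corrected over
real genes. NTC pseudogenes are reported per repetition as diagnostics.

**Hit nomination.** A gene is a sensitizer hit when its fitness normZ
(vehicle vs T0) lies in [−1, +1] in every cell line measured and its drug
normZ (drug vs vehicle) is below −1 in at least one (cell line, drug);
FDR < 0.1 annotates (optionally gates) the call. The fitness contrast is
scored with essentials retained so their dropout anchors the normZ scale.

**HSA synergy.** For a viability matrix over two dose ladders, the excess in
each combination cell is `I(a,b) − max(I(a,0), I(0,b))` with `I = 100 −
viability`; the synergy score is the mean excess in percentage points
(> +10 synergistic, < −10 antagonistic).

A seeded synthetic-screen generator (lognormal library skew, Beta guide
efficiency, exponential growth with compositional closure, gamma–Poisson
sequencing noise) provides screens with known truth labels for validation.

## Worked example

The numbered drivers under `analysis/` run the whole workflow at study scale
(2,000-guide library, two cell lines, arms T0/DMSO/OLA/TALA, 100 resampling
repetitions, ~1 min total):

```sh
Rscript analysis/01_simulate_screens.R
Rscript analysis/02_score_contrasts.R
Rscript analysis/03_nominate_hits.R
Rscript analysis/04_synergy.R
```

which prints:

```
LINE_A: 2000 guides x 4 samples, 0 validation violations
...
LINE_A DMSO_vs_T0: 419 genes, NTC pseudogene normZ mean +0.376, top gene ESS0049 (-3.45)
LINE_A OLA_vs_DMSO: 356 genes, NTC pseudogene normZ mean +0.230, top gene TGT0013 (-5.52)
...
nominated 20 genes; 20 of the 20 planted sensitizers recovered; 0 false
HSA synergy score: 15.0 (synergistic)
```

Read: the essential-gene controls drop out hard in the fitness contrast
(normZ ≈ −3.5) while NTC pseudogenes sit near 0; the 20 genes planted as
drug sensitizers (additional −0.5 log2/doubling under drug) reach drug
normZ ≈ −5 and all pass the nomination rule, with no neutral gene falsely
nominated. The same steps are available as one call on a YAML config:

```r
library(screenkit)
res <- run_screen_analysis(system.file("extdata", "demo_config.yaml",
                                       package = "screenkit"),
                           output_dir = "demo_run")
head(res$hits[res$hits$nominated, c("gene", "criteria_met")])
```

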