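---
title: "Methods: normZ scoring, NTC-resampling null, and hit nomination for chemogenetic CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normZ scoring, NTC-resampling null, and hit nomination for chemogenetic CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model implemented by screenkit, the
meaning and defaults of every tuning parameter, the numerical conventions that
make results bit-reproducible, and the modeling decisions that were left to
the implementation — with the rationale for each. It is a methods reference;
for a runnable walk-through see the `analysis/` drivers and the README.

## 1. Screen design and data model

The package targets pooled CRISPR/Cas9 knockout screens with a custom library:
a focused panel of target genes, a set of core-essential genes as
positive controls for dropout, and a large bank of non-targeting control
(NTC) sgRNAs, each targeting gene covered by a fixed number of guides
(default 4). Cells are split into arms — a T0 baseline, a vehicle arm
(e.g. DMSO), and one or more drug arms — and grown for a known number of
population doublings before sgRNA sequencing.

The data objects are deliberately plain:

* a **library** (`compose_library`, `read_library`): guide → gene → category
  (`target` / `essential` / `ntc`; each NTC guide is its own "gene"),
* a **count table** (`count_table`, `read_count_table`): one row per guide,
  one integer column per sample,
* a **sample sheet** (`sample_sheet`): sample → arm / cell line / drug /
  replicate,
* a **contrast** (`contrast_spec`): a label plus control and treated sample
  sets, optionally paired.

`validate_screen` reports structural violations (duplicate guides, unknown or
missing samples, inconsistent categories, all-zero guides) as a data frame
rather than failing, so QC can be logged.

## 2. Guide and gene scoring (normZ)

For each contrast the engine proceeds in four steps.

**Normalization.** Each sample's counts are scaled to a fixed sequencing
depth and shifted by a pseudocount:

$$c' = p + c \cdot S \,/\, \textstyle\sum_j c_j$$

with pseudocount $p = 5$ and scale $S = 10^7$ (`engine_params`). The
pseudocount regularizes log fold changes of low-count guides; the scale makes
$c'$ comparable across libraries of any depth (gene-level results are exactly
invariant to multiplying all counts in a sample by a constant — this is
tested).

**Fold changes.** Every guide gets $\mathrm{fc} = \log_2(c'_\text{trt} /
c'_\text{ctrl})$. With multiple samples per side, paired contrasts use the
matched sample pairs; unpaired contrasts use all control × treated pairs,
each pair contributing an observation.

**Empirical-Bayes standardization.** Fold-change variance depends strongly on
abundance, so guides are sorted by normalized control count (descending, ties
broken deterministically by guide id) and each guide's fold change is divided
by the sample standard deviation of the fold changes in a rank window of
half-width $w$ around it:

$$z_i = \mathrm{fc}_i \,/\, \mathrm{sd}\{\mathrm{fc}_{i-w} \ldots
\mathrm{fc}_{i+w}\}.$$

The window adapts to library size, $w = \min(500, \max(50, \lfloor n/4
\rfloor))$, and is truncated at the ends of the ranking. The sd is floored at
`min_std = 1e-6` to avoid division blow-ups in degenerate windows. The
rolling sd is computed from cumulative sums in $O(n)$; the variance is
clamped at zero before the square root to absorb floating-point cancellation.

**Gene aggregation.** For gene $g$ with guide observations $z_1 \ldots z_k$:

$$\mathrm{sumZ}_g = \sum_i z_i, \qquad \mathrm{raw}_g =
\mathrm{sumZ}_g/\sqrt{k}, \qquad \mathrm{normZ}_g =
\frac{\mathrm{raw}_g - \overline{\mathrm{raw}}}{\mathrm{sd}(\mathrm{raw})}$$

where the re-standardization runs over all scored units, so normZ is a
z-score relative to the screened panel. One-tailed p-values are
$p_\text{left} = \Phi(\mathrm{normZ})$ (depletion; sensitizers) and
$p_\text{right} = 1 - p_\text{left}$ (enrichment), each Benjamini–Hochberg
adjusted per tail. If $\mathrm{sd}(\mathrm{raw}) = 0$ (a degenerate screen
with no signal variation), all normZ are set to 0 and all p-values to 0.5
rather than producing NaN. $\Phi$ values are clamped to
$[10^{-300},\, 1 - 10^{-16}]$ so both tails stay strictly inside $(0, 1)$.

The engine is verified against an independent straight-line oracle
implementation to $10^{-9}$ and is invariant to row permutations of the
input.

## 3. NTC-pseudogene resampling null

A focused library violates the usual assumption that most genes are null, so
anchoring significance on the panel itself is biased. Instead the null is
built from the NTCs (`resampled_scores`):

1. essential-gene guides are removed from the count table
   (`excluded_categories = "essential"` by default) so positive-control
   dropout does not distort the drug-contrast normZ scale;
2. the NTC guides are randomly shuffled and cut into consecutive blocks of
   `group_size = 4`, forming pseudogenes `NTC_PG_0001…`; a remainder smaller
   than the group size is dropped with a warning (324 NTCs → 81 pseudogenes,
   none dropped);
3. the full normZ engine runs on real genes + pseudogenes;
4. steps 2–3 repeat `n_rep = 100` times with counter-based child seeds;
5. each real gene's score is the **mean normZ across repetitions**, its
   p-values are $\Phi(\overline{\mathrm{normZ}})$ with BH correction over
   real genes only, and the NTC pseudogenes are reported per repetition as
   diagnostics (mean, sd, 5th/95th percentiles, fraction beyond ±1.645).

Defaults: `group_size = 4` matches the guides-per-gene of the library so
pseudogenes are statistically exchangeable with real genes; `n_rep = 100`
makes the Monte-Carlo error of the averaged normZ small relative to its
scale (repetitions differ only through the pseudogene aggregation, so
between-repetition sd of a real gene's normZ is a few percent of 1); a cell
budget (`max_cells = 5e8`, guides × samples × repetitions) guards against
accidental huge jobs with a classed error instead of an OOM.

## 4. Hit nomination

`nominate_hits` implements a two-axis rule over averaged scores from multiple
cell lines (`nomination_criteria`):

* **fitness-neutral**: fitness normZ (vehicle vs T0) within the closed
  interval $[-1, +1]$ in **every** cell line in which the gene was measured —
  sensitization must not be explained by generic fitness loss;
* **drug-depleted**: drug normZ (drug vs vehicle) strictly below $-1$ in at
  least `min_cell_lines = 1` (cell line, drug) combination;
* **FDR**: left-tail FDR < `fdr_max = 0.1` for that drug contrast is recorded
  as `fdr_pass` and, with `require_fdr = TRUE`, gates the call. The default
  annotates rather than gates because with 100-fold averaged z the p-values
  are conservative and the two-axis effect-size rule is the primary filter.

Genes with no fitness score are marked `unevaluable` and never nominated.
`guide_concordance` reports, per nominated gene, the fraction of guides whose
individual z agrees in sign, and `annotate_known` flags literature-known
sensitizers (case-insensitive).

## 5. Synthetic screens with known truth

`simulate_screen` generates screens for validation, emulating the main noise
sources of a real pooled screen:

* guide efficiency $u \sim \mathrm{Beta}(\alpha = 5, \beta = 1)$ — most
  guides cut well, a tail does not;
* baseline abundance $b \sim \mathrm{LogNormal}(0, \sigma = 0.5)$ — cloning
  skew; initial proportions $p_0 \propto b$;
* per-arm growth: guide log2 fold effect $e = u \cdot (f_g + s_{g,\text{drug}}
  \cdot [\text{drug}])$, where $f_g$ is fitness (log2 per doubling) and
  $s_{g,\text{drug}}$ drug sensitization; after $D$ doublings the proportions
  $p \propto p_0 \cdot 2^{D e}$ are renormalized — **compositional closure**,
  so strong dropouts inflate everything else, as in real sequencing;
* counts $\sim \mathrm{NB}(\mu = \text{coverage} \cdot n \cdot p,\,
  \text{size} = \theta)$ — gamma–Poisson sequencing/PCR noise.

Defaults: $D = 15$ doublings, coverage $= 300\times$ per guide, dispersion
$\theta = 100$ (counts at 300× have sd ≈ 11% of the mean). The seed is
mandatory and the draw order is fixed (efficiencies, baselines, T0, then
arms in declared order), so a seed pins the dataset bit-for-bit.

What the generator does **not** emulate: copy-number artifacts, double-strand
break toxicity, guide off-targets, jackpot PCR clones, batch effects between
arms, or cell-line-specific baseline differences beyond independent seeds.
Validation results on it are therefore necessary, not sufficient, evidence.

## 6. HSA synergy

For a two-drug viability matrix whose first row/column are the single agents
(dose ladders must start at 0 and increase strictly; replicates are averaged
by `dose_matrix`), inhibition is $I = 100 - V$ (no clamping — values outside
[0, 100] propagate visibly rather than being silently truncated) and the
highest-single-agent excess in each combination cell is

$$\mathrm{excess}(a, b) = I(a, b) - \max\{I(a, 0),\, I(0, b)\}.$$

`hsa_score` averages the excess over all combination cells; scores above
+10 percentage points classify as synergistic, below −10 as antagonistic,
otherwise additive.

## 7. Reproducibility conventions

* All randomness flows from a single seed through the exported counter-based
  rule `child_seed(seed, k)` = $(|s| \bmod M \cdot 69069 + k \cdot
  663608941) \bmod M$, $M = 2^{31}-1$ — exact in doubles, independent of
  evaluation order, so adding a contrast does not change another contrast's
  draws. `with_seed` saves and restores `.Random.seed`.
* Every sort uses `method = "radix"` with explicit tie-breaks (guide id,
  unit name) for locale-independent, deterministic ordering.
* `run_screen_analysis` writes a `manifest.yaml` with all seeds, parameters,
  captured warnings, per-step timings, and md5 digests of every output, and
  reruns are byte-identical (tested).

## 8. Decisions left to the implementation

* **Essentials retained in the fitness contrast.** Because normZ is
  re-standardized to sd 1 over scored units, the fitness normZ scale is only
  meaningful relative to the spread of the screen. With essentials excluded,
  typical fitness-neutral genes spread across roughly $\pm 1.5$ and the
  $[-1, +1]$ window misclassifies many of them; with essentials retained,
  their dropout dominates the spread, fitness-neutral genes concentrate well
  inside the window, and the window does what it is meant to do.
  `run_screen_analysis` therefore defaults to `excluded_categories =
  character(0)` for the fitness-role contrast and `"essential"` for drug
  contrasts; both are overridable per contrast.
* **BH family.** FDR is corrected over real genes only (per tail, per
  contrast); NTC pseudogenes are diagnostics, not hypotheses.
* **P-values from averaged z are conservative.** Averaging normZ over
  repetitions shrinks extreme values slightly, so $\Phi(\bar z)$ understates
  significance a little; this errs in the safe direction, and the default
  nomination rule uses effect sizes as the primary gate.
* **Doublings** default to 15 per arm and are settable per arm, since drug
  arms can grow slower.
* **No minimum-count prefilter.** Low-abundance guides are handled by the
  pseudocount and the abundance-matched EB window rather than dropped; users
  can filter upstream if a library has failed guides.
* The problem sizes used throughout (2,000 guides = 356 + 63 genes × 4 +
  324 NTC; 100 repetitions; 300× coverage) are the package's reference
  configuration for testing and examples; nothing in the code depends on
  them.

## 9. Limitations

normZ assumes fold-change noise depends on abundance only; chromatin or
copy-number covariates are not modeled. The NTC null assumes NTC guides
carry no phenotype (cutting-toxicity controls would be better where
available). Hit nomination treats cell lines as exchangeable and uses hard
thresholds; borderline genes should be inspected via `guide_concordance` and
the normZ scatter. HSA is the weakest synergy reference (no dose-response
model); Bliss or Loewe analyses need the full response surfaces and are out
of scope.
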