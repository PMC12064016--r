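# crossconcord

Cross-platform concordance analysis of baseline gene expression between a
**targeted sequencing platform** (probe-based counts from cell lysates,
with possibly several probes per gene) and a **whole-transcriptome
reference platform** (RNA-seq-style expression-per-million values). The
package answers three questions a lab faces before combining such data:

1. Is the targeted platform reproducible across sequencing runs at
   different read depths?
2. Which genes do the two platforms disagree on systematically, and how
   many genes must be removed before the platform factor stops dominating
   the multivariate structure?
3. Can a normalization remove the platform signal *without* removing
   genes?

It is aimed at transcriptomics analysts who have gene- or probe-level
expression tables for the same cell lines (or samples) on two platforms
and want a quantified, reproducible concordance report rather than a
one-off script.

## Methods at a glance

* **Harmonization** — probe collapse by per-sample maximum; per-sample
  normalization to EPM, `EPM_gs = x_gs / Σ_g x_gs × 10⁶`; transform
  `y = log2(EPM + 1)`; replicate averaging; reduction of both platforms
  to the shared gene universe with rescaling to 10⁶ per sample.
* **Replicate QC** — pairwise Pearson correlations with group means and
  95% t-intervals.
* **Variance attribution** — PCA (centered, unscaled), sequential
  (Type-I) ANOVA on single components, and PERMANOVA on Euclidean
  distances over all PCs: term SS = tr(H_k G) − tr(H_{k−1} G) on the
  Gower-centered matrix G, pseudo-F, and seeded permutation p-values
  `(1 + #{F_perm ≥ F}) / (n_perm + 1)`; plus a multivariate dispersion
  test (distance to group centroid in PCoA space) and PCoA itself.
* **Non-concordance determination** — iterate percentile pairs (10, 90),
  (11, 89), … of the per-gene difference Δ = y_targeted − y_reference;
  average per-cell-line percentiles into cutoffs; remove expressed genes
  (gate: mean ≥ 5 EPM on either platform) whose mean Δ falls outside;
  stop when the platform PERMANOVA R² drops below 0.10.
* **Ratio-RLE correction** — divide each gene's log2(EPM+1) by its
  cross-cell-line average within the platform: `RLE_gc = y_gc / mean_c'
  y_gc'` (a ratio, not the usual log-difference RLE); per-gene
  multiplicative platform effects cancel exactly, removing the divergence
  with no gene removal.
* **Gene-set concordance** — per signature, the 2×2 odds ratio
  `OR = (a/b)/(c/d)` of non-concordant vs concordant membership within
  the expressed universe, two-sided Fisher exact p, BH-FDR over the
  signatures that have ≥ 10 genes and ≥ 50% of their members in the
  universe.
* **Synthetic truth** — a dual-platform count generator with per-gene
  planted platform biases (realized as platform-specific capture loss),
  shared cell-line signatures, replicate noise, library-size variation,
  multi-probe genes and unexpressed genes, returning the ground truth
  needed to score recovery.

The methods vignette (`vignettes/cross-platform-concordance.Rmd`)
documents the models, conventions and design decisions in detail.

## Worked example

```r
library(crossconcord)

cfg <- sim_config(n_genes = 800, n_cell_lines = 8, seed = 7)
sim <- generate_dual_platform(cfg)
rep <- run_tvr(sim$targeted, sim$reference, sim$annotation,
               n_perm = 999, seed = 1)

rep$permanova
#>       term df       ss        r2 statistic     p
#> 1 platform  1 12606.85 0.4844436  13.15513 0.001
#> 2 Residual 14 13416.51 0.5155564        NA    NA
#> 3    Total 15 26023.36 1.0000000        NA    NA

rep$classification
#> <concordance_classification> 800 genes; cutoffs (-0.725, 0.548) at
#> percentiles (10, 90); 144 removed; platform R2 = 0.0035
#>
#>         concordant_expressed    concordant_low_expression
#>                          576                           80
#>  nonconcordant_high_targeted nonconcordant_high_reference
#>                           72                           72
```

Reading this: on the log2 data the platform factor explains 48% of the
multivariate variance (PERMANOVA p = 0.001). The iterative procedure
removes 144 genes whose mean cross-platform difference falls outside the
averaged 10th/90th-percentile cutoffs (−0.725, 0.548 log2), which drops
the platform R² to 0.0035 — below the 0.10 target at the first iteration.
The 800-gene universe partitions into 576 concordant expressed genes, 80
below the 5-EPM expression gate (both platforms agree they are off), and
72 + 72 non-concordant genes higher on the targeted and reference
platform respectively — exactly the planted 144:

```r
pa <- rep$rle$permanova
pa$r2[pa$term == "platform"]
#> 1.07e-16        # ratio-RLE removes the divergence without removing genes

called <- nonconcordant_genes(rep$classification)
length(intersect(called, sim$truth$biased_gene_ids)) /
  length(sim$truth$biased_gene_ids)
#> 1               # planted-gene recall
```

## The analysis workflow

The `analysis/` scripts run the two study designs end to end on generated
data, writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates both designs as TSV + truth JSON |
| `02_phase_reproducibility.R` | phase-vs-phase replication QC and variance attribution |
| `03_platform_concordance.R` | platform comparison, non-concordant genes, ratio-RLE |
| `04_geneset_enrichment.R` | odds-ratio signature enrichment on the classification |

Run them in order with `Rscript analysis/01_simulate.R`, etc.

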