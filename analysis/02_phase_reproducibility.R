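#!/usr/bin/env Rscript
## Phase-vs-phase reproducibility of the targeted platform.
##
## Reads the probe-level counts written by 01_simulate.R, collapses probes
## to genes, normalizes to CPM and log2(CPM+1), and asks whether samples
## group by cell line or by sequencing phase: replicate Pearson
## correlations, PCA with per-PC1 sequential ANOVA (~ cell_line + phase),
## PERMANOVA on Euclidean distances over all PCs (999 permutations), a
## dispersion test, and PCoA.

suppressPackageStartupMessages(library(crossconcord))

data_dir <- "results/data"
out <- "results/tvt"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20240502L

manifest <- read_probe_manifest(file.path(data_dir, "tvt_probe_manifest.tsv"))
phases <- lapply(1:2, function(p) {
  counts <- read_expression_table(
    file.path(data_dir, sprintf("tvt_phase%d_counts.tsv", p)),
    unit = "counts", id_column = "probe_id", allow_duplicate_ids = TRUE)
  probe_counts(counts, manifest)
})
ann <- read_annotation(file.path(data_dir, "tvt_annotation.tsv"))

rep <- run_tvt(phases, ann, n_perm = 999, seed = seed)

write_tsv <- function(df, name)
  utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
write_tsv(rep$correlations, "replicate_correlations.tsv")
write_tsv(rep$anova_pc1, "anova_pc1.tsv")
write_tsv(rep$permanova, "permanova.tsv")
write_expression_table(rep$pca$scores, file.path(out, "pca_scores.tsv"),
                       id_name = "sample_id")
write_expression_table(rep$pcoa$points, file.path(out, "pcoa_points.tsv"),
                       id_name = "sample_id")
hl <- high_loading_genes(rep$pca, component = 1, threshold = 0.02)
write_tsv(hl, "pc1_high_loading_genes.tsv")

pa <- rep$permanova
cat(sprintf(paste0(
  "Phase reproducibility: between-phase Pearson %.3f; cell line explains ",
  "%.1f%% of multivariate variance (p = %.3f), phase %.2f%% (p = %.3f); ",
  "phase dispersion p = %.2f; %d genes load |rotation| > 0.02 on PC1.\n"),
  rep$correlations$mean_r[rep$correlations$group == "between"],
  100 * pa$r2[pa$term == "cell_line"], pa$p[pa$term == "cell_line"],
  100 * pa$r2[pa$term == "phase"], pa$p[pa$term == "phase"],
  rep$dispersion_phase$p, nrow(hl)))
cat("Conclusion: phases group by cell line, not sequencing phase;",
    "they can be combined for the platform comparison.\n")
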