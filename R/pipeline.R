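## End-to-end drivers for the two study designs:
##  - run_tvt: replicate reproducibility across sequencing phases of the
##    targeted platform (phase-vs-phase).
##  - run_tvr: targeted vs reference platform across cell lines, including
##    non-concordance determination, RLE correction and optional gene-set
##    enrichment.

#' Phase-vs-phase replicate comparison (targeted platform)
#'
#' Collapses probes, normalizes to CPM, log2-transforms, computes
#' within-phase and between-phase replicate correlations, and attributes
#' multivariate variance to cell line and phase by per-PC1 ANOVA and
#' PERMANOVA (with dispersion test and PCoA).
#'
#' @param phases list of [probe_counts()] objects, one per phase.
#' @param annotation [sample_annotation()] covering every sample of every
#'   phase (with phase labels).
#' @param n_perm,seed PERMANOVA settings.
#' @return a report list: `log2`, `correlations`, `pca`, `anova_pc1`,
#'   `permanova`, `dispersion_phase`, `dispersion_cell_line`, `pcoa`,
#'   `gene_counts`.
#' @export
run_tvt <- function(phases, annotation, n_perm = 999, seed = NULL) {
  if (length(phases) < 2) stop("need >= 2 phases")
  collapsed <- lapply(phases, collapse_probes)
  g0 <- rownames(collapsed[[1]])
  for (m in collapsed[-1])
    if (!identical(rownames(m), g0))
      stop("phases disagree on the gene universe after probe collapse")
  counts <- do.call(cbind, lapply(collapsed, unclass))
  counts <- expr_matrix(counts, unit = "counts",
                        symbols = attr(collapsed[[1]], "symbols",
                                       exact = TRUE))
  annotation <- sample_annotation(annotation, sample_ids = colnames(counts))
  ann <- annotation[match(colnames(counts), annotation$sample_id), ,
                    drop = FALSE]
  lg <- log2p1(epm_normalize(counts))
  corr <- replicate_correlation_summary(lg, ann, within = "phase",
                                        match_on = "cell_line")
  ord <- pca_ordination(lg)
  d <- sample_distances(ord)
  model <- data.frame(cell_line = ann$cell_line, phase = ann$phase)
  list(log2 = lg, annotation = ann,
       correlations = corr,
       pca = ord,
       anova_pc1 = anova_on_component(ord$scores[, 1], model),
       permanova = permanova(d, model, n_perm = n_perm, seed = seed),
       dispersion_phase = dispersion_test(d, ann$phase),
       dispersion_cell_line = dispersion_test(d, ann$cell_line),
       pcoa = pcoa(d),
       gene_counts = list(n_probes = sum(vapply(phases,
                                                function(p) nrow(p$counts),
                                                integer(1))) /
                            length(phases),
                          n_genes = nrow(lg)))
}

#' Harmonize targeted probe counts and a reference EPM table
#'
#' Shared first half of the platform comparison: probe collapse, CPM,
#' replicate averaging per cell line (both platforms), restriction to the
#' shared cell lines and shared gene universe with rescaling to one
#' million, and the log2(EPM + 1) transform.
#'
#' @param targeted [probe_counts()] with replicate-level counts.
#' @param reference [expr_matrix()] in EPM.
#' @param annotation [sample_annotation()] covering the targeted samples
#'   (and the reference samples, when their columns are sample ids rather
#'   than cell lines).
#' @return list with `t_epm`, `r_epm`, `t_log2`, `r_log2` (columns = the
#'   shared cell lines), `cells`, and the intersection `report`.
#' @export
harmonize_platforms <- function(targeted, reference, annotation) {
  check_unit(reference, "EPM")
  collapsed <- collapse_probes(targeted)
  annotation <- sample_annotation(annotation,
                                  sample_ids = colnames(collapsed))
  t_epm_rep <- epm_normalize(collapsed)
  avg <- average_replicates(t_epm_rep, annotation, by = "cell_line")
  t_epm <- epm_normalize(avg$expr)        # re-close after averaging
  if (all(colnames(reference) %in% annotation$sample_id)) {
    ravg <- average_replicates(reference, annotation, by = "cell_line")
    reference <- epm_normalize(ravg$expr)
  }
  cells <- intersect(colnames(t_epm), colnames(reference))
  if (length(cells) < 2)
    stop("fewer than 2 shared cell lines between the platforms")
  t_epm <- t_epm[, cells, drop = FALSE]
  r_epm0 <- reference[, cells, drop = FALSE]
  harm <- intersect_and_rescale(t_epm, r_epm0)
  list(t_epm = harm$a, r_epm = harm$b,
       t_log2 = log2p1(harm$a), r_log2 = log2p1(harm$b),
       cells = cells, report = harm$report,
       n_genes_targeted = nrow(collapsed),
       n_genes_reference = nrow(reference))
}

#' Targeted-vs-reference platform comparison
#'
#' Full pipeline: probe collapse, CPM, replicate averaging per cell line,
#' gene-universe intersection and rescaling against the reference EPM
#' table, log2 transform, cross-platform correlations, PCA / per-PC1
#' ANOVA / PERMANOVA / dispersion / PCoA for the platform factor,
#' difference-profile statistics, iterative non-concordant gene
#' determination, RLE correction with repeated ordination analyses, and
#' (when gene sets are supplied) odds-ratio enrichment of non-concordant
#' vs concordant genes.
#'
#' @param targeted [probe_counts()] with replicate-level counts.
#' @param reference [expr_matrix()] in EPM, one column per cell line (or
#'   replicated with an annotation).
#' @param annotation [sample_annotation()] covering targeted samples (the
#'   reference columns are matched to cell lines by column name when not
#'   annotated).
#' @param gate_threshold,r2_target,start,step concordance parameters, see
#'   [find_nonconcordant()].
#' @param n_perm,seed PERMANOVA settings (one seed drives every stage).
#' @param gene_sets optional named list of gene-set vectors for the
#'   enrichment stage (skipped, with a warning, when absent).
#' @param min_genes,min_frac enrichment inclusion criteria.
#' @return a report list; see the elements of the returned object.
#' @export
run_tvr <- function(targeted, reference, annotation,
                    gate_threshold = 5, r2_target = 0.10,
                    start = c(10, 90), step = 1,
                    n_perm = 999, seed = NULL,
                    gene_sets = NULL, min_genes = 10, min_frac = 0.5) {
  h <- harmonize_platforms(targeted, reference, annotation)
  t_epm <- h$t_epm; r_epm <- h$r_epm
  t_log2 <- h$t_log2; r_log2 <- h$r_log2
  cells <- h$cells

  r <- pearson_matrix(t_log2, r_log2)
  match_idx <- diag(length(cells)) == 1
  corr <- summarize_correlations(
    as.vector(r), ifelse(as.vector(match_idx), "matching", "non_matching"))

  combined <- cbind(unclass(t_log2), unclass(r_log2))
  colnames(combined) <- c(paste0(cells, "_T"), paste0(cells, "_R"))
  combined <- expr_matrix(combined, unit = "log2EPM1")
  model <- data.frame(platform = rep(c("TARGETED", "REFERENCE"),
                                     each = length(cells)))
  ord <- pca_ordination(combined)
  d <- sample_distances(ord)
  pa <- permanova(d, model, n_perm = n_perm, seed = seed)

  cls <- find_nonconcordant(t_log2, r_log2, t_epm, r_epm,
                            start = start, step = step,
                            r2_target = r2_target,
                            gate_threshold = gate_threshold,
                            n_perm = n_perm, seed = seed)

  rle <- rle_pipeline_rerun(t_log2, r_log2, n_perm = n_perm, seed = seed)

  enrichment <- NULL
  if (is.null(gene_sets)) {
    warning("no gene sets supplied; enrichment stage skipped")
  } else {
    gated <- names(cls$gate)[cls$gate]
    nc <- nonconcordant_genes(cls)
    conc <- setdiff(gated, nc)
    enrichment <- enrich_genesets(gene_sets, nc, conc,
                                  min_genes = min_genes,
                                  min_frac = min_frac)
  }

  list(t_log2 = t_log2, r_log2 = r_log2, t_epm = t_epm, r_epm = r_epm,
       correlations = corr,
       pca = ord,
       anova_pc1 = anova_on_component(ord$scores[, 1], model),
       permanova = pa,
       dispersion = dispersion_test(d, model$platform),
       pcoa = pcoa(d),
       diff = cls$diff,
       average_median_diff = average_median_diff(cls$diff),
       fold_difference_all = fold_difference_summary(t_log2, r_log2),
       classification = cls,
       rle = rle,
       enrichment = enrichment,
       gene_counts = list(
         n_probes = nrow(targeted$counts),
         n_genes_targeted = h$n_genes_targeted,
         n_genes_reference = h$n_genes_reference,
         n_shared = h$report$n_shared,
         n_gated = sum(cls$gate),
         n_removed = cls$n_removed,
         n_concordant = sum(!grepl("^nonconcordant", cls$category))))
}
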