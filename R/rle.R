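## Ratio-based relative log expression (RLE) normalization.
##
## RLE(g, c) = log2(EPM(g, c) + 1) / mean over cell lines of
## log2(EPM(g, .) + 1), computed within each platform separately. Note
## this is a ratio of log2 values, not the conventional subtract-the-
## reference log-difference that shares the RLE name. A per-gene
## multiplicative platform bias on the log2 scale cancels identically in
## the ratio, which is what removes systematic platform divergence.

#' Relative log expression (ratio) normalization
#'
#' Divides each gene's log2(EPM + 1) value by that gene's average
#' log2(EPM + 1) across all cell lines of the same platform. Genes whose
#' values are all zero (zero denominator) are set to the neutral value 1
#' and flagged, keeping the gene universe intact.
#'
#' Because RLE destroys within-sample rank order, it must only be used to
#' compare the same gene across samples, never different genes within a
#' sample.
#'
#' @param m an [expr_matrix()] with unit `"log2EPM1"`; columns are cell
#'   lines of a single platform (>= 2). The averaging universe is exactly
#'   the columns of `m`: callers comparing platforms must pass each
#'   platform's full cell-line panel.
#' @param denominator `"log2"` (the ratio of log2 values, default) or
#'   `"linear"` (divide by the average of EPM + 1 instead; provided for
#'   auditability of the alternative reading of the defining ratio).
#' @param epm the EPM matrix, required only for `denominator = "linear"`.
#' @return an [expr_matrix()] with unit `"RLE"` carrying attributes
#'   `denominator_values` (per-gene averages) and `flagged` (all-zero
#'   genes mapped to 1).
#' @export
rle_normalize <- function(m, denominator = c("log2", "linear"),
                          epm = NULL) {
  check_unit(m, "log2EPM1")
  denominator <- match.arg(denominator)
  if (ncol(m) < 2)
    stop("RLE needs >= 2 cell lines (the denominator degenerates)")
  vals <- unclass(m)
  den <- if (denominator == "log2") {
    rowMeans(vals)
  } else {
    if (is.null(epm)) stop("denominator = 'linear' requires 'epm'")
    check_unit(epm, "EPM")
    rowMeans(unclass(epm) + 1)
  }
  zero <- den == 0
  out <- vals / ifelse(zero, 1, den)
  out[zero, ] <- 1
  res <- expr_matrix(out, unit = "RLE",
                     symbols = attr(m, "symbols", exact = TRUE))
  attr(res, "denominator_values") <- den
  attr(res, "flagged") <- rownames(vals)[zero]
  res
}

#' Re-run the ordination analyses on RLE-normalized data
#'
#' Normalizes each platform against its own cross-cell-line average,
#' combines the two RLE matrices, and repeats PCA, per-PC1 ANOVA,
#' PERMANOVA (`~ platform`), the dispersion test and PCoA, plus the
#' cross-platform Pearson correlations.
#'
#' @param t_log2,r_log2 matched log2(EPM + 1) matrices (one column per
#'   cell line).
#' @param n_perm,seed PERMANOVA settings.
#' @return list with `rle_targeted`, `rle_reference`, `pca`, `anova_pc1`,
#'   `permanova`, `dispersion`, `pcoa`, `correlations` (cross-platform r
#'   summary for matching and non-matching cell lines).
#' @export
rle_pipeline_rerun <- function(t_log2, r_log2, n_perm = 999, seed = NULL) {
  check_unit(t_log2, "log2EPM1"); check_unit(r_log2, "log2EPM1")
  if (!identical(rownames(t_log2), rownames(r_log2)) ||
      ncol(t_log2) != ncol(r_log2))
    stop("matrices must share genes and have matched cell lines")
  rle_t <- rle_normalize(t_log2)
  rle_r <- rle_normalize(r_log2)
  combined <- cbind(unclass(rle_t), unclass(rle_r))
  colnames(combined) <- c(paste0(colnames(t_log2), "_T"),
                          paste0(colnames(r_log2), "_R"))
  combined <- expr_matrix(combined, unit = "RLE")
  ann <- data.frame(platform = rep(c("TARGETED", "REFERENCE"),
                                   each = ncol(t_log2)))
  ord <- pca_ordination(combined)
  d <- sample_distances(ord)
  r <- pearson_matrix(rle_t, rle_r)
  match_idx <- diag(length(colnames(t_log2))) == 1
  corr <- summarize_correlations(
    as.vector(r), ifelse(as.vector(match_idx), "matching", "non_matching"))
  list(rle_targeted = rle_t, rle_reference = rle_r,
       pca = ord,
       anova_pc1 = anova_on_component(ord$scores[, 1], ann),
       permanova = permanova(d, ann, n_perm = n_perm, seed = seed),
       dispersion = dispersion_test(d, ann$platform),
       pcoa = pcoa(d),
       correlations = corr)
}
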