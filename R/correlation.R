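## Replicate and cross-platform QC via pairwise Pearson correlation.

#' Pairwise Pearson correlations between samples
#'
#' Correlates every sample (column) of `a` with every sample of `b` over
#' all genes. Both matrices must carry the same unit and identical gene
#' sets in identical order. Zero-variance samples yield `NA` entries and
#' are flagged rather than raising an error.
#'
#' @param a an [expr_matrix()] (unit `"log2EPM1"` or `"RLE"`).
#' @param b optional second matrix (same unit and genes); by default `a`
#'   is correlated against itself, giving a symmetric matrix.
#' @return correlation matrix (samples of `a` x samples of `b`) with an
#'   attribute `zero_variance` listing flagged samples.
#' @export
pearson_matrix <- function(a, b = NULL) {
  check_unit(a, c("log2EPM1", "RLE"))
  if (is.null(b)) b <- a
  check_unit(b, c("log2EPM1", "RLE"))
  if (expr_unit(a) != expr_unit(b))
    stop("both matrices must carry the same unit")
  if (!identical(rownames(a), rownames(b)))
    stop("gene sets/order differ between the two matrices")
  sd_a <- apply(a, 2, stats::sd)
  sd_b <- apply(b, 2, stats::sd)
  flagged <- unique(c(colnames(a)[sd_a == 0], colnames(b)[sd_b == 0]))
  r <- suppressWarnings(stats::cor(unclass(a), unclass(b),
                                   method = "pearson"))
  structure(r, zero_variance = flagged)
}

#' Summarize groups of correlation values
#'
#' Mean and 95% confidence interval per group. The interval is the
#' t-interval mean +/- t(0.975, n - 1) * sd / sqrt(n) on the raw r values,
#' clipped to \[-1, 1\]; with n = 1 the interval degenerates to the point.
#'
#' @param values numeric vector of correlations.
#' @param group optional grouping vector (same length); a single group
#'   labelled `"all"` by default.
#' @return data.frame with columns `group`, `n`, `mean_r`, `ci_lo`,
#'   `ci_hi`.
#' @export
summarize_correlations <- function(values, group = NULL) {
  if (is.null(group)) group <- rep("all", length(values))
  if (length(group) != length(values))
    stop("'group' must parallel 'values'")
  keep <- is.finite(values)
  values <- values[keep]; group <- as.character(group)[keep]
  if (length(values) == 0) stop("no finite correlation values")
  if (any(values < -1 - 1e-12 | values > 1 + 1e-12))
    stop("correlation values must lie in [-1, 1]")
  groups <- unique(group)
  rows <- lapply(groups, function(g) {
    v <- values[group == g]
    if (length(v) == 0) stop("empty group: ", g)
    m <- mean(v)
    if (length(v) == 1) {
      lo <- hi <- m
    } else {
      half <- stats::qt(0.975, length(v) - 1) * stats::sd(v) / sqrt(length(v))
      lo <- max(-1, m - half)
      hi <- min(1, m + half)
    }
    data.frame(group = g, n = length(v), mean_r = m, ci_lo = lo, ci_hi = hi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation summaries for a replicate design
#'
#' Convenience wrapper computing within-group and between-group correlation
#' summaries from a log2 (or RLE) matrix and its annotation, e.g. within
#' each sequencing phase and between phases for matching cell lines.
#'
#' @param m an [expr_matrix()] (`"log2EPM1"` or `"RLE"`).
#' @param ann annotation for the samples of `m`.
#' @param within annotation column defining replicate groups (pairs within
#'   the same level are "within"; pairs across levels with matching
#'   `match_on` are "between").
#' @param match_on annotation column that must agree for between-group
#'   pairs (default `"cell_line"`).
#' @return data.frame of summaries with groups `within:<level>` and
#'   `between`.
#' @export
replicate_correlation_summary <- function(m, ann, within = "phase",
                                          match_on = "cell_line") {
  ann <- sample_annotation(ann, sample_ids = colnames(m))
  ann <- ann[match(colnames(m), ann$sample_id), , drop = FALSE]
  r <- pearson_matrix(m)
  n <- ncol(m)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  lev <- ann[[within]]
  match_v <- ann[[match_on]]
  vals <- r[pairs]
  same_level <- lev[pairs[, 1]] == lev[pairs[, 2]]
  same_match <- match_v[pairs[, 1]] == match_v[pairs[, 2]]
  lab <- ifelse(same_level & same_match,
                paste0("within:", lev[pairs[, 1]]),
                ifelse(!same_level & same_match, "between", NA))
  keep <- !is.na(lab)
  summarize_correlations(vals[keep], lab[keep])
}
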