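## Per-gene cross-platform difference statistics and the iterative
## percentile-cutoff determination of non-concordant genes.

#' Cross-platform log2 difference profile
#'
#' Computes Delta(g, c) = targeted log2(EPM + 1) minus reference
#' log2(EPM + 1) per gene and cell line, per-cell-line quartiles and IQR
#' over genes (linear-interpolation quantiles), and per-gene mean Delta /
#' mean |Delta| across cell lines.
#'
#' @param t,r [expr_matrix()] objects with unit `"log2EPM1"`, identical
#'   genes (rows) and matched cell lines (columns, same order).
#' @return a `diff_profile` list: `delta` (genes x cell lines),
#'   `by_cell_line` (data.frame `cell_line`, `q1`, `median`, `q3`, `iqr`,
#'   sorted by IQR), `gene_mean` and `gene_mean_abs` (named vectors).
#' @export
diff_profile <- function(t, r) {
  check_unit(t, "log2EPM1"); check_unit(r, "log2EPM1")
  if (!identical(dim(t), dim(r)) || !identical(rownames(t), rownames(r)))
    stop("matrices must share genes and cell lines in the same order")
  delta <- unclass(t) - unclass(r)
  q <- apply(delta, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
             type = 7)
  by_cl <- data.frame(cell_line = colnames(delta),
                      q1 = q[1, ], median = q[2, ], q3 = q[3, ],
                      iqr = q[3, ] - q[1, ], row.names = NULL,
                      stringsAsFactors = FALSE)
  by_cl <- by_cl[order(by_cl$iqr), , drop = FALSE]
  structure(list(delta = delta, by_cell_line = by_cl,
                 gene_mean = rowMeans(delta),
                 gene_mean_abs = rowMeans(abs(delta))),
            class = "diff_profile")
}

#' Average across cell lines of the per-cell-line median difference
#'
#' A near-zero value indicates that the two platforms agree on average.
#'
#' @param dp a [diff_profile()].
#' @return numeric scalar (log2 units).
#' @export
average_median_diff <- function(dp) {
  stopifnot(inherits(dp, "diff_profile"))
  mean(dp$by_cell_line$median)
}

#' Minimum-expression gate
#'
#' A gene is considered expressed (and eligible to be called
#' non-concordant) if its cross-cell-line average is at least `threshold`
#' EPM on either platform. Genes failing the gate are effectively
#' concordant: both platforms agree they are not expressed.
#'
#' @param t_epm,r_epm matched [expr_matrix()] objects in EPM.
#' @param threshold EPM threshold (default 5).
#' @return named logical vector, `TRUE` for genes passing the gate.
#' @export
expression_gate <- function(t_epm, r_epm, threshold = 5) {
  check_unit(t_epm, "EPM"); check_unit(r_epm, "EPM")
  if (!identical(rownames(t_epm), rownames(r_epm)))
    stop("matrices must share genes in the same order")
  rowMeans(unclass(t_epm)) >= threshold |
    rowMeans(unclass(r_epm)) >= threshold
}

#' Percentile cutoffs of the difference distribution
#'
#' Per-cell-line percentiles of Delta over genes (linear-interpolation
#' quantiles), averaged across cell lines.
#'
#' @param dp a [diff_profile()].
#' @param p_low,p_high percentile pair in (0, 100), `p_low < p_high`.
#' @param scope `"all_genes"` (default; percentiles over the full gene
#'   universe) or `"gated_genes"` (restricted to genes passing the gate;
#'   requires `gate`).
#' @param gate logical vector from [expression_gate()] when
#'   `scope = "gated_genes"`.
#' @return numeric `c(lo, hi)` in log2 units.
#' @export
percentile_cutoffs <- function(dp, p_low, p_high,
                               scope = c("all_genes", "gated_genes"),
                               gate = NULL) {
  stopifnot(inherits(dp, "diff_profile"))
  scope <- match.arg(scope)
  if (!(p_low > 0 && p_high < 100 && p_low < p_high))
    stop("need 0 < p_low < p_high < 100")
  delta <- dp$delta
  if (scope == "gated_genes") {
    if (is.null(gate)) stop("scope 'gated_genes' requires 'gate'")
    delta <- delta[gate, , drop = FALSE]
  }
  q <- apply(delta, 2, stats::quantile, probs = c(p_low, p_high) / 100,
             type = 7)
  c(lo = mean(q[1, ]), hi = mean(q[2, ]))
}

#' Iterative non-concordant gene determination
#'
#' Starting from the percentile pair `start` (default 10th/87th...90th),
#' the procedure computes cross-cell-line averaged percentile cutoffs of
#' the per-gene difference distribution, marks expressed genes whose mean
#' difference falls strictly outside the cutoffs as candidate
#' non-concordant, removes them, and runs a PERMANOVA (`~ platform`) on
#' Euclidean distances of the remaining genes' log2 data. The percentile
#' pair is narrowed inward by `step` until the platform factor explains
#' less than `r2_target` of the multivariate variance.
#'
#' @param t_log2,r_log2 matched log2(EPM + 1) matrices (one column per
#'   cell line, replicate-averaged).
#' @param t_epm,r_epm matched EPM matrices for the expression gate.
#' @param start percentile pair `c(p_low, p_high)` for the first
#'   iteration.
#' @param step percentile increment per iteration.
#' @param r2_target stop once platform R-squared falls below this value
#'   (default 0.10).
#' @param gate_threshold EPM threshold for [expression_gate()].
#' @param scope percentile scope, see [percentile_cutoffs()].
#' @param n_perm,seed PERMANOVA permutations (the stopping rule uses only
#'   the permutation-free R-squared; the p-value is reported).
#' @return a `concordance_classification` list: `category` (named factor
#'   per gene: `concordant_expressed`, `concordant_low_expression`,
#'   `nonconcordant_high_targeted`, `nonconcordant_high_reference`),
#'   `cutoffs`, `percentiles`, `trace` (data.frame of every iteration),
#'   `platform_r2`, `platform_p`, `gate_threshold`, `n_removed`.
#' @export
find_nonconcordant <- function(t_log2, r_log2, t_epm, r_epm,
                               start = c(10, 90), step = 1,
                               r2_target = 0.10, gate_threshold = 5,
                               scope = c("all_genes", "gated_genes"),
                               n_perm = 999, seed = NULL) {
  scope <- match.arg(scope)
  dp <- diff_profile(t_log2, r_log2)
  gate <- expression_gate(t_epm, r_epm, threshold = gate_threshold)
  genes <- rownames(t_log2)
  n_cl <- ncol(t_log2)
  ann <- data.frame(platform = rep(c("TARGETED", "REFERENCE"),
                                   each = n_cl))
  trace <- list()
  i <- 0
  repeat {
    p_low <- start[1] + i * step
    p_high <- start[2] - i * step
    if (p_low >= p_high || p_low >= 49.5) {
      tr <- do.call(rbind, trace)
      stop("percentile narrowing reached (", p_low, ", ", p_high,
           ") without platform R2 < ", r2_target, "; trace:\n",
           paste(utils::capture.output(print(tr)), collapse = "\n"))
    }
    cut <- percentile_cutoffs(dp, p_low, p_high, scope = scope,
                              gate = gate)
    removed <- gate & (dp$gene_mean < cut["lo"] | dp$gene_mean > cut["hi"])
    keep <- !removed
    combined <- cbind(unclass(t_log2)[keep, , drop = FALSE],
                      unclass(r_log2)[keep, , drop = FALSE])
    colnames(combined) <- c(paste0(colnames(t_log2), "_T"),
                            paste0(colnames(r_log2), "_R"))
    pa <- permanova(stats::dist(t(combined)), ann, n_perm = n_perm,
                    seed = seed)
    r2 <- pa$r2[pa$term == "platform"]
    pval <- pa$p[pa$term == "platform"]
    i <- i + 1
    trace[[i]] <- data.frame(p_low = p_low, p_high = p_high,
                             lo = unname(cut["lo"]), hi = unname(cut["hi"]),
                             n_removed = sum(removed),
                             platform_r2 = r2, platform_p = pval)
    if (r2 < r2_target) {
      category <- ifelse(!gate, "concordant_low_expression",
                         ifelse(removed & dp$gene_mean > cut["hi"],
                                "nonconcordant_high_targeted",
                                ifelse(removed, "nonconcordant_high_reference",
                                       "concordant_expressed")))
      category <- factor(category,
                         levels = c("concordant_expressed",
                                    "concordant_low_expression",
                                    "nonconcordant_high_targeted",
                                    "nonconcordant_high_reference"))
      names(category) <- genes
      return(structure(list(category = category,
                            cutoffs = cut,
                            percentiles = c(p_low = p_low, p_high = p_high),
                            trace = do.call(rbind, trace),
                            platform_r2 = r2, platform_p = pval,
                            gate_threshold = gate_threshold,
                            n_removed = sum(removed),
                            diff = dp, gate = gate),
                       class = "concordance_classification"))
    }
  }
}

#' @export
print.concordance_classification <- function(x, ...) {
  cat(sprintf(paste0("<concordance_classification> %d genes; cutoffs ",
                     "(%.3f, %.3f) at percentiles (%g, %g); %d removed; ",
                     "platform R2 = %.4f\n"),
              length(x$category), x$cutoffs["lo"], x$cutoffs["hi"],
              x$percentiles["p_low"], x$percentiles["p_high"],
              x$n_removed, x$platform_r2))
  print(table(x$category))
  invisible(x)
}

#' Non-concordant gene ids of a classification
#' @param cls a `concordance_classification`.
#' @return character vector of gene ids.
#' @export
nonconcordant_genes <- function(cls) {
  names(cls$category)[grepl("^nonconcordant", cls$category)]
}

#' Average fold difference between platforms
#'
#' Per observation (gene x cell line) the fold is 2^|Delta|; the mean and
#' its 95% t-interval are reported, with the direction given separately as
#' the sign of the mean Delta.
#'
#' @param t_log2,r_log2 matched log2(EPM + 1) matrices.
#' @param genes optional gene subset.
#' @return list `mean_fold`, `ci_lo`, `ci_hi`, `direction` (+1 when the
#'   targeted platform trends higher, -1 otherwise, 0 on exact balance).
#' @export
fold_difference_summary <- function(t_log2, r_log2, genes = NULL) {
  check_unit(t_log2, "log2EPM1"); check_unit(r_log2, "log2EPM1")
  if (!identical(dim(t_log2), dim(r_log2)))
    stop("matrices must be matched")
  delta <- unclass(t_log2) - unclass(r_log2)
  if (!is.null(genes)) delta <- delta[genes, , drop = FALSE]
  fold <- 2^abs(as.vector(delta))
  n <- length(fold)
  m <- mean(fold)
  half <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(fold) / sqrt(n)
          else 0
  list(mean_fold = m, ci_lo = m - half, ci_hi = m + half,
       direction = sign(mean(delta)))
}

#' Counts of genes exceeding absolute-difference thresholds
#'
#' @param dp a [diff_profile()].
#' @param thresholds numeric vector of log2 thresholds.
#' @param gene_lists optional named list of gene-id vectors; for each list
#'   the overlap with the exceeding genes is tallied.
#' @return data.frame with one row per threshold: `threshold`, `n_genes`,
#'   and one overlap column per supplied list.
#' @export
threshold_counts <- function(dp, thresholds, gene_lists = NULL) {
  stopifnot(inherits(dp, "diff_profile"))
  rows <- lapply(thresholds, function(th) {
    hits <- names(dp$gene_mean_abs)[dp$gene_mean_abs > th]
    row <- data.frame(threshold = th, n_genes = length(hits))
    for (nm in names(gene_lists))
      row[[paste0("n_", nm)]] <- length(intersect(hits, gene_lists[[nm]]))
    row
  })
  do.call(rbind, rows)
}
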