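## Odds-ratio gene-set enrichment of non-concordant vs concordant genes
## within the expressed universe, with Fisher exact p-values and FDR
## control.

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then members, tab-separated.
#' Members are de-duplicated within a set.
#'
#' @param path GMT file.
#' @return named list of character vectors with attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nm[i] <- f[1]
    desc[i] <- f[2]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop(sprintf("GMT line %d (%s) has no members", i, f[1]))
    sets[[i]] <- members
  }
  if (anyDuplicated(nm)) stop("duplicated set names in GMT")
  names(sets) <- nm
  names(desc) <- nm
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors (optionally with a
#'   `descriptions` attribute).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions", exact = TRUE)
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)),
                                             names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Signature inclusion filter
#'
#' A signature is included if at least `min_genes` of its members lie in
#' the analysis universe and those members represent at least `min_frac`
#' of the full signature.
#'
#' @param sets named list of gene-id vectors.
#' @param universe character vector of analysis genes.
#' @param min_genes minimum members in the universe (default 10).
#' @param min_frac minimum fraction of the signature in the universe
#'   (default 0.5).
#' @return data.frame `signature`, `n_genes`, `n_in_universe`,
#'   `pct_in_universe` (integer percent, round-half-even), `included`.
#' @export
filter_signatures <- function(sets, universe, min_genes = 10,
                              min_frac = 0.5) {
  if (length(universe) == 0) stop("universe is empty")
  n_full <- lengths(sets)
  n_in <- vapply(sets, function(s) length(intersect(s, universe)),
                 integer(1))
  frac <- n_in / n_full
  data.frame(signature = names(sets), n_genes = unname(n_full),
             n_in_universe = unname(n_in),
             pct_in_universe = round(100 * unname(frac)),
             included = unname(n_in >= min_genes & frac >= min_frac),
             stringsAsFactors = FALSE)
}

#' 2x2 counts and odds ratio for one signature
#'
#' Within the expressed universe partitioned into non-concordant and
#' concordant genes: a = signature genes that are non-concordant, b =
#' non-concordant genes outside the signature, c = signature genes that
#' are concordant, d = concordant genes outside the signature;
#' OR = (a/b) / (c/d). Signature membership is counted after intersection
#' with the universe, so a + c equals the signature's genes in the
#' analysis.
#'
#' Zero cells: OR is `Inf` when b*c = 0 with a*d > 0, 0 when a*d = 0 with
#' b*c > 0, and `NaN` when both products vanish; a Haldane-Anscombe
#' (+0.5 to every cell) OR is reported alongside for ranking.
#'
#' @param set character vector of signature gene ids.
#' @param nonconcordant,concordant character vectors partitioning the
#'   universe.
#' @return list `a`, `b`, `c`, `d`, `or`, `or_haldane`.
#' @export
odds_ratio_counts <- function(set, nonconcordant, concordant) {
  if (length(intersect(nonconcordant, concordant)))
    stop("non-concordant and concordant sets overlap")
  a <- length(intersect(set, nonconcordant))
  b <- length(nonconcordant) - a
  cc <- length(intersect(set, concordant))
  d <- length(concordant) - cc
  or <- if (a * d == 0 && b * cc == 0) NaN
        else if (b * cc == 0) Inf
        else if (a * d == 0) 0
        else (a / b) / (cc / d)
  or_h <- ((a + 0.5) / (b + 0.5)) / ((cc + 0.5) / (d + 0.5))
  list(a = a, b = b, c = cc, d = d, or = or, or_haldane = or_h)
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Exact p from the hypergeometric distribution on the fixed-margin 2x2
#' table; a chi-square variant (without continuity correction) is
#' available.
#'
#' @param a,b,c,d non-negative integer cell counts (layout as in
#'   [odds_ratio_counts()]).
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return p-value.
#' @export
enrichment_p <- function(a, b, c, d, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (method == "fisher")
    stats::fisher.test(tab)$p.value
  else
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sort p ascending, multiply by m/i, take the running
#' minimum from the largest rank, cap at 1, and restore input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-set enrichment of non-concordant vs concordant genes
#'
#' Applies the inclusion filter, builds the 2x2 table for every signature,
#' computes odds ratios, exact p-values and BH-adjusted p-values
#' (adjustment over the included signatures only), and reports the
#' reciprocal OR for depleted signatures.
#'
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param nonconcordant,concordant gene-id vectors partitioning the
#'   expressed universe.
#' @param min_genes,min_frac inclusion criteria, see
#'   [filter_signatures()].
#' @param method p-value method, see [enrichment_p()].
#' @return data.frame with one row per signature: `signature`, `n_genes`,
#'   `n_in_universe`, `pct_in_universe`, `included`, `a`, `b`, `c`, `d`,
#'   `or`, `or_haldane`, `reciprocal_or`, `p`, `fdr` (NA for excluded
#'   signatures), sorted by `fdr` then `p` among included rows first.
#' @export
enrich_genesets <- function(sets, nonconcordant, concordant,
                            min_genes = 10, min_frac = 0.5,
                            method = "fisher") {
  universe <- c(nonconcordant, concordant)
  if (anyDuplicated(universe))
    stop("non-concordant and concordant sets must partition the universe")
  flt <- filter_signatures(sets, universe, min_genes, min_frac)
  tab <- lapply(names(sets), function(nm) {
    oc <- odds_ratio_counts(sets[[nm]], nonconcordant, concordant)
    data.frame(signature = nm, a = oc$a, b = oc$b, c = oc$c, d = oc$d,
               or = oc$or, or_haldane = oc$or_haldane,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  out <- merge(flt, tab, by = "signature", sort = FALSE)
  out$reciprocal_or <- ifelse(is.finite(out$or) & out$or > 0 & out$or < 1,
                              1 / out$or, NA_real_)
  out$p <- mapply(enrichment_p, out$a, out$b, out$c, out$d,
                  MoreArgs = list(method = method))
  out$fdr <- NA_real_
  out$fdr[out$included] <- bh_fdr(out$p[out$included])
  ord <- order(!out$included, out$fdr, out$p)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
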