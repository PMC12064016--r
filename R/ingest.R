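## Ingestion and normalization: probe collapse, expression-per-million,
## log2(EPM + 1), replicate averaging, and harmonization of two platforms
## onto a shared, rescaled gene universe.

#' Collapse probe-level counts to gene-level counts
#'
#' Where several probes interrogate the same gene, the gene value is the
#' maximum probe count, computed per sample independently. Genes whose
#' probes are all zero are kept with value 0.
#'
#' @param pm a [probe_counts()] object.
#' @return an [expr_matrix()] with unit `"counts"`, one row per distinct
#'   gene id.
#' @export
collapse_probes <- function(pm) {
  stopifnot(inherits(pm, "probe_counts"))
  if (nrow(pm$counts) == 0) stop("probe matrix is empty")
  gene_id <- pm$probe_info$gene_id
  genes <- unique(gene_id)
  idx <- split(seq_along(gene_id), factor(gene_id, levels = genes))
  ns <- ncol(pm$counts)
  out <- matrix(0, nrow = length(genes), ncol = ns,
                dimnames = list(genes, colnames(pm$counts)))
  single <- lengths(idx) == 1L
  if (any(single))
    out[single, ] <- pm$counts[unlist(idx[single]), , drop = FALSE]
  for (g in which(!single)) {
    rows <- idx[[g]]
    out[g, ] <- do.call(pmax, asplit(pm$counts[rows, , drop = FALSE], 1))
  }
  symbols <- NULL
  if ("symbol" %in% names(pm$probe_info))
    symbols <- pm$probe_info$symbol[match(genes, gene_id)]
  expr_matrix(out, unit = "counts", symbols = symbols)
}

#' Normalize each sample to expression per million
#'
#' Rescales every sample column so it sums to one million. Applies to raw
#' counts or to already-EPM values whose gene universe has been reduced
#' (renormalization).
#'
#' @param m an [expr_matrix()] with unit `"counts"` or `"EPM"`.
#' @return an [expr_matrix()] with unit `"EPM"`.
#' @export
epm_normalize <- function(m) {
  check_unit(m, c("counts", "EPM"))
  tot <- colSums(m)
  zero <- colnames(m)[tot <= 0]
  if (length(zero))
    stop("sample(s) with zero total, cannot normalize: ",
         paste(utils::head(zero, 5), collapse = ", "))
  out <- sweep(unclass(m), 2, tot, "/") * 1e6
  expr_matrix(out, unit = "EPM", symbols = attr(m, "symbols", exact = TRUE))
}

#' log2(EPM + 1) transform
#'
#' The pseudocount of one maps zero expression to zero rather than to
#' negative infinity.
#'
#' @param m an [expr_matrix()] with unit `"EPM"`.
#' @return an [expr_matrix()] with unit `"log2EPM1"`.
#' @export
log2p1 <- function(m) {
  check_unit(m, "EPM")
  if (any(m < 0)) stop("negative EPM values are not valid")
  expr_matrix(log2(unclass(m) + 1), unit = "log2EPM1",
              symbols = attr(m, "symbols", exact = TRUE))
}

#' Average replicate samples within groups
#'
#' Computes the per-gene arithmetic mean over the samples of each group
#' (all replicates weighted equally). Group keys are combinations of
#' annotation columns, typically `"cell_line"` or
#' `c("cell_line", "phase")`.
#'
#' @param m an [expr_matrix()] (any unit; averaging EPM is the standard
#'   use).
#' @param ann annotation covering every sample of `m` (see
#'   [sample_annotation()]).
#' @param by character vector of annotation columns defining the groups.
#' @return list with `expr` (one column per group, named by the group key)
#'   and `annotation` (one row per group).
#' @export
average_replicates <- function(m, ann, by = "cell_line") {
  ann <- sample_annotation(ann, sample_ids = colnames(m))
  bad <- setdiff(by, names(ann))
  if (length(bad))
    stop("grouping key(s) absent from annotation: ",
         paste(bad, collapse = ", "))
  ann <- ann[match(colnames(m), ann$sample_id), , drop = FALSE]
  key <- do.call(paste, c(ann[by], sep = "."))
  groups <- unique(key)
  out <- vapply(groups,
                function(g) rowMeans(m[, key == g, drop = FALSE]),
                numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), groups)
  uniq_or <- function(v, fallback) {
    u <- unique(v)
    if (length(u) == 1) u else fallback
  }
  new_ann <- do.call(rbind, lapply(groups, function(g) {
    rows <- ann[key == g, , drop = FALSE]
    data.frame(sample_id = g,
               cell_line = uniq_or(rows$cell_line, g),
               platform = uniq_or(rows$platform, "TARGETED"),
               phase = uniq_or(rows$phase, "none"),
               replicate = "avg", stringsAsFactors = FALSE)
  }))
  list(expr = expr_matrix(out, unit = expr_unit(m),
                          symbols = attr(m, "symbols", exact = TRUE)),
       annotation = sample_annotation(new_ann))
}

#' Reduce two EPM matrices to their shared gene universe and rescale
#'
#' Both matrices are restricted to the genes present in both (in a common
#' order) and every sample is renormalized to one million, so downstream
#' log2 values are comparable across platforms.
#'
#' @param a,b [expr_matrix()] objects with unit `"EPM"`.
#' @return list with `a`, `b` (harmonized EPM matrices) and `report`
#'   (`n_a_only`, `n_b_only`, `n_shared`).
#' @export
intersect_and_rescale <- function(a, b) {
  check_unit(a, "EPM"); check_unit(b, "EPM")
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) == 0) stop("the two matrices share no genes")
  report <- list(n_a_only = nrow(a) - length(shared),
                 n_b_only = nrow(b) - length(shared),
                 n_shared = length(shared))
  a2 <- epm_normalize(a[shared, , drop = FALSE])
  b2 <- epm_normalize(b[shared, , drop = FALSE])
  list(a = a2, b = b2, report = report)
}

## ---- delimited-text I/O -------------------------------------------------

read_table_any <- function(path, sheet = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading xlsx requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path, sheet = sheet),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
}

#' Read an expression table from TSV (or XLSX)
#'
#' @param path tab-delimited file with a header row (or an `.xlsx` file if
#'   the readxl package is available).
#' @param unit declared unit of the values (see [expr_matrix()]).
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`;
#'   never inferred from the file.
#' @param id_column name or index of the identifier column.
#' @param allow_duplicate_ids keep duplicated row ids (probe-level input
#'   only); duplicated ids are otherwise rejected.
#' @param sheet sheet name/index for xlsx input.
#' @return an [expr_matrix()] (or, with `allow_duplicate_ids = TRUE`, a
#'   plain numeric matrix).
#' @export
read_expression_table <- function(path, unit,
                                  orientation = c("genes_in_rows",
                                                  "samples_in_rows"),
                                  id_column = 1,
                                  allow_duplicate_ids = FALSE,
                                  sheet = NULL) {
  orientation <- match.arg(orientation)
  df <- read_table_any(path, sheet)
  if (is.character(id_column)) {
    if (!id_column %in% names(df))
      stop("id column '", id_column, "' not found in ", path)
    id_column <- match(id_column, names(df))
  }
  ids <- as.character(df[[id_column]])
  if (anyNA(ids) || any(ids == ""))
    stop("missing ids in rows: ",
         paste(utils::head(which(is.na(ids) | ids == ""), 5), collapse = ", "))
  vals <- df[, -id_column, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                     names(vals)[j], bad[1], v[bad[1]]))
      v <- num
    }
    vals[[j]] <- v
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  if (orientation == "samples_in_rows") mat <- t(mat)
  if (anyDuplicated(rownames(mat)) && !allow_duplicate_ids)
    stop("duplicated ids: ",
         paste(utils::head(unique(rownames(mat)[duplicated(rownames(mat))]), 5),
               collapse = ", "))
  if (allow_duplicate_ids) return(mat)
  expr_matrix(mat, unit = unit)
}

#' Write an expression (or any genes-x-samples) matrix as TSV
#'
#' @param m matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param id_name header of the identifier column.
#' @export
write_expression_table <- function(m, path, id_name = "gene_id") {
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation TSV
#' @param path tab-delimited file with the columns of [sample_annotation()].
#' @return a validated annotation data.frame.
#' @export
read_annotation <- function(path) {
  sample_annotation(read_table_any(path))
}

#' Read a probe manifest TSV (probe id, gene id, optional symbol)
#' @param path tab-delimited file with columns `probe_id`, `gene_id`
#'   and optionally `symbol`.
#' @return data.frame usable as `probe_info` in [probe_counts()].
#' @export
read_probe_manifest <- function(path) {
  df <- read_table_any(path)
  req <- c("probe_id", "gene_id")
  if (!all(req %in% names(df)))
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("duplicated probe ids in manifest")
  df
}
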