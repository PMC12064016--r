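#' @keywords internal
"_PACKAGE"

## Lightweight S3 containers. The pipeline operates on plain numeric
## matrices (genes x samples) carrying a unit tag, so that every stage can
## refuse input in the wrong state (e.g. RLE applied twice).

#' Expression matrix with a unit tag
#'
#' Wraps a genes x samples numeric matrix together with the unit its values
#' are expressed in. The unit tag is checked by every downstream operation:
#' `"counts"` (non-negative integers), `"EPM"` (expression per million; each
#' sample column sums to 1e6), `"log2EPM1"` (log2(EPM + 1)) or `"RLE"`
#' (ratio of log2(EPM + 1) to the per-gene cross-sample average).
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param unit one of `"counts"`, `"EPM"`, `"log2EPM1"`, `"RLE"`.
#' @param symbols optional character vector of gene symbols, parallel to the
#'   rows of `values`.
#' @return an `expr_matrix` object.
#' @export
expr_matrix <- function(values, unit = c("counts", "EPM", "log2EPM1", "RLE"),
                        symbols = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("'values' must have unique rownames (gene ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("'values' must have unique colnames (sample ids)")
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (unit %in% c("counts", "EPM", "log2EPM1") && any(values < 0))
    stop(sprintf("negative values are not valid for unit '%s'", unit))
  if (!is.null(symbols)) {
    if (length(symbols) != nrow(values))
      stop("'symbols' must have one entry per gene")
    symbols <- as.character(symbols)
  }
  structure(values, unit = unit, symbols = symbols,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, unit = %s\n",
              nrow(x), ncol(x), expr_unit(x)))
  invisible(x)
}

#' Unit tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return character scalar.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit", exact = TRUE)
  if (is.null(u)) stop("matrix has no unit tag; wrap it with expr_matrix()")
  u
}

## Subset while keeping the class, unit and symbols in sync.
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (!is.matrix(out)) return(out)
  sym <- attr(x, "symbols", exact = TRUE)
  if (!is.null(sym) && !missing(i)) {
    names(sym) <- rownames(unclass(x))
    sym <- unname(sym[rownames(out)])
  }
  expr_matrix(out, unit = expr_unit(x), symbols = sym)
}

check_unit <- function(x, expected, arg = deparse(substitute(x))) {
  u <- expr_unit(x)
  if (!u %in% expected)
    stop(sprintf("'%s' has unit '%s'; expected %s", arg, u,
                 paste(sQuote(expected), collapse = " or ")))
  invisible(x)
}

#' Probe-level count matrix for the targeted platform
#'
#' @param counts non-negative integer matrix, probes x samples; rownames are
#'   probe ids.
#' @param probe_info data.frame with columns `probe_id`, `gene_id`
#'   (primary identifier used for probe collapse and gene intersection) and
#'   optionally `symbol`. Every probe in `counts` must appear exactly once.
#' @return a `probe_counts` object (list with elements `counts`,
#'   `probe_info`).
#' @export
probe_counts <- function(counts, probe_info) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("probe counts must be non-negative integers")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("'counts' must have unique probe ids as rownames")
  if (anyDuplicated(colnames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have unique sample ids as colnames")
  req <- c("probe_id", "gene_id")
  if (!is.data.frame(probe_info) || !all(req %in% names(probe_info)))
    stop("'probe_info' must be a data.frame with columns probe_id, gene_id")
  missing_ids <- setdiff(rownames(counts), probe_info$probe_id)
  if (length(missing_ids))
    stop("probes missing from the manifest: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  bad <- probe_info$probe_id[is.na(probe_info$gene_id) |
                               probe_info$gene_id == ""]
  if (length(bad))
    stop("probes without a gene id: ",
         paste(utils::head(bad, 5), collapse = ", "))
  probe_info <- probe_info[match(rownames(counts), probe_info$probe_id), ,
                           drop = FALSE]
  rownames(probe_info) <- NULL
  structure(list(counts = counts, probe_info = probe_info),
            class = "probe_counts")
}

#' @export
print.probe_counts <- function(x, ...) {
  cat(sprintf("<probe_counts> %d probes (%d genes) x %d samples\n",
              nrow(x$counts), length(unique(x$probe_info$gene_id)),
              ncol(x$counts)))
  invisible(x)
}

#' Validate a sample annotation table
#'
#' @param ann data.frame with columns `sample_id`, `cell_line`, `platform`
#'   (`"TARGETED"` or `"REFERENCE"`), `phase` (integer or `"none"`) and
#'   `replicate`.
#' @param sample_ids optional character vector of matrix sample ids that
#'   must all be annotated.
#' @return the annotation, with `phase` and `replicate` as character.
#' @export
sample_annotation <- function(ann, sample_ids = NULL) {
  req <- c("sample_id", "cell_line", "platform", "phase", "replicate")
  if (!is.data.frame(ann) || !all(req %in% names(ann)))
    stop("annotation needs columns: ", paste(req, collapse = ", "))
  ann$sample_id <- as.character(ann$sample_id)
  ann$cell_line <- as.character(ann$cell_line)
  ann$platform <- as.character(ann$platform)
  ann$phase <- as.character(ann$phase)
  ann$replicate <- as.character(ann$replicate)
  if (!all(ann$platform %in% c("TARGETED", "REFERENCE")))
    stop("platform must be 'TARGETED' or 'REFERENCE'")
  if (anyDuplicated(ann$sample_id))
    stop("duplicated sample ids in annotation")
  key <- do.call(paste, c(ann[c("cell_line", "platform", "phase",
                                "replicate")], sep = "\r"))
  if (anyDuplicated(key))
    stop("(cell_line, platform, phase, replicate) must be unique")
  if (!is.null(sample_ids)) {
    missing_s <- setdiff(sample_ids, ann$sample_id)
    if (length(missing_s))
      stop("samples missing from annotation: ",
           paste(utils::head(missing_s, 5), collapse = ", "))
  }
  ann[req]
}

## Run a block with a locally-seeded RNG, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.finite(seed)) stop("'seed' must be a finite integer")
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
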