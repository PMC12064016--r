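## Synthetic dual-platform generator.
##
## Two platforms measure the same genes. On the log2 scale the expected
## targeted-minus-reference difference of gene g is bias(g) for the planted
## subset and 0 otherwise; the bias is realized as platform-specific capture
## loss (negative bias suppresses the gene on the targeted platform,
## positive bias suppresses it on the reference platform), emulating
## probe-efficiency and library-preparation losses without shifting the
## overall library composition.
## Replicates add Gaussian noise on the log2 scale; values are exponentiated
## and converted to integer counts at a drawn library size. The targeted
## platform emits 1..probes_per_gene_max probe rows per gene; the probe
## carrying the gene-level count is planted so that max-collapse recovers it
## exactly.

#' Configuration for the dual-platform simulator
#'
#' @param n_genes number of genes in the shared universe (>= 10).
#' @param n_cell_lines number of cell lines.
#' @param n_replicates_per_platform technical replicates per cell line on
#'   the targeted platform (the reference platform emits one averaged
#'   profile per cell line, as public whole-transcriptome compendia do).
#' @param frac_platform_biased fraction of expressed genes given a planted
#'   platform-specific log2 bias.
#' @param bias_log2_range interval of planted |bias| magnitudes (log2
#'   units); signs alternate up/down across planted genes.
#' @param frac_unexpressed fraction of genes that are all-zero on both
#'   platforms.
#' @param baseline_log2_mean_range interval of per-gene baseline log2
#'   abundances.
#' @param cell_line_effect_sd sd (log2) of i.i.d. gene x cell-line effects
#'   shared by both platforms.
#' @param replicate_noise_sd sd (log2) of per-replicate Gaussian noise.
#' @param library_size_range interval of total counts per sample.
#' @param probes_per_gene_max maximum probes per gene on the targeted
#'   platform (each gene gets 1..max, uniformly).
#' @param marker_frac fraction of expressed genes acting as cell-type
#'   markers with larger cell-line effects (drives cell-line separation in
#'   ordinations).
#' @param marker_effect_sd sd (log2) of marker-gene cell-line effects.
#' @param seed integer seed; identical configs produce identical output.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cell_lines = 12,
                       n_replicates_per_platform = 3,
                       frac_platform_biased = 0.2,
                       bias_log2_range = c(2, 8),
                       frac_unexpressed = 0.1,
                       baseline_log2_mean_range = c(3, 10),
                       cell_line_effect_sd = 1,
                       replicate_noise_sd = 0.25,
                       library_size_range = c(4.5e6, 6e6),
                       probes_per_gene_max = 3,
                       marker_frac = 0.05,
                       marker_effect_sd = 3,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, n_cell_lines = n_cell_lines,
              n_replicates_per_platform = n_replicates_per_platform,
              frac_platform_biased = frac_platform_biased,
              bias_log2_range = bias_log2_range,
              frac_unexpressed = frac_unexpressed,
              baseline_log2_mean_range = baseline_log2_mean_range,
              cell_line_effect_sd = cell_line_effect_sd,
              replicate_noise_sd = replicate_noise_sd,
              library_size_range = library_size_range,
              probes_per_gene_max = probes_per_gene_max,
              marker_frac = marker_frac,
              marker_effect_sd = marker_effect_sd,
              seed = seed)
  for (f in names(cfg)) {
    v <- cfg[[f]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop(sprintf("config field '%s' must be finite numeric", f))
  }
  for (f in c("frac_platform_biased", "frac_unexpressed", "marker_frac"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("config field '%s' must lie in [0, 1]", f))
  for (f in c("bias_log2_range", "baseline_log2_mean_range",
              "library_size_range")) {
    if (length(cfg[[f]]) != 2 || cfg[[f]][1] > cfg[[f]][2])
      stop(sprintf("config field '%s' must be an interval c(low, high)", f))
  }
  for (f in c("n_genes", "n_cell_lines", "n_replicates_per_platform",
              "probes_per_gene_max")) {
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop(sprintf("config field '%s' must be a positive integer", f))
  }
  if (cfg$n_genes < 10) stop("config field 'n_genes' must be >= 10")
  for (f in c("cell_line_effect_sd", "replicate_noise_sd",
              "marker_effect_sd"))
    if (cfg[[f]] < 0) stop(sprintf("config field '%s' must be >= 0", f))
  if (cfg$library_size_range[1] <= 0)
    stop("config field 'library_size_range' must be positive")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

## Draw the shared generative structure (everything except replicate noise
## and library sizes). Called under the config seed.
draw_truth <- function(config) {
  ng <- config$n_genes
  nc <- config$n_cell_lines
  gene_ids <- sprintf("G%05d", seq_len(ng))
  symbols <- sprintf("SYM%05d", seq_len(ng))
  cell_lines <- sprintf("CL%02d", seq_len(nc))

  n_unexp <- round(config$frac_unexpressed * ng)
  unexpressed <- sort(sample(ng, n_unexp))
  expressed <- setdiff(seq_len(ng), unexpressed)

  baseline <- rep(NA_real_, ng)
  baseline[expressed] <- stats::runif(length(expressed),
                                      config$baseline_log2_mean_range[1],
                                      config$baseline_log2_mean_range[2])

  n_marker <- round(config$marker_frac * length(expressed))
  markers <- sort(sample(expressed, n_marker))
  effect_sd <- rep(0, ng)
  effect_sd[expressed] <- config$cell_line_effect_sd
  effect_sd[markers] <- config$marker_effect_sd
  cell_effects <- matrix(stats::rnorm(ng * nc, sd = rep(effect_sd, nc)),
                         nrow = ng, ncol = nc,
                         dimnames = list(gene_ids, cell_lines))
  cell_effects[unexpressed, ] <- 0

  n_biased <- round(config$frac_platform_biased * length(expressed))
  biased <- sort(sample(expressed, n_biased))
  bias <- rep(0, ng)
  if (n_biased > 0) {
    magnitude <- stats::runif(n_biased, config$bias_log2_range[1],
                              config$bias_log2_range[2])
    sign <- sample(rep(c(1, -1), length.out = n_biased))
    bias[biased] <- sign * magnitude
  }

  n_probes <- sample.int(config$probes_per_gene_max, ng, replace = TRUE)
  max_probe <- vapply(n_probes, function(k) sample.int(k, 1L), integer(1))

  structure(list(
    gene_ids = gene_ids, symbols = symbols, cell_lines = cell_lines,
    unexpressed_gene_ids = gene_ids[unexpressed],
    biased_gene_ids = gene_ids[biased],
    bias = stats::setNames(bias, gene_ids),
    baseline = stats::setNames(baseline, gene_ids),
    cell_effects = cell_effects,
    marker_gene_ids = gene_ids[markers],
    n_probes = stats::setNames(n_probes, gene_ids),
    max_probe = stats::setNames(max_probe, gene_ids),
    seed = config$seed), class = "sim_truth")
}

## Integer gene-level counts for one sample: log-normal noise around the
## expected log2 abundance, renormalized to the drawn library size.
synth_sample <- function(mu_log2, noise_sd, lib_size) {
  x <- mu_log2 + stats::rnorm(length(mu_log2), sd = noise_sd)
  lin <- ifelse(is.na(mu_log2), 0, 2^x)
  tot <- sum(lin)
  if (tot == 0) return(rep(0, length(mu_log2)))
  round(lin / tot * lib_size)
}

## Expand gene-level counts into probe rows. Non-max probes draw uniform
## integers in [0, gene count]; the planted max probe carries the gene count.
expand_probes <- function(gene_counts, truth) {
  ng <- nrow(gene_counts)
  ns <- ncol(gene_counts)
  gene_idx <- rep(seq_len(ng), truth$n_probes)
  probe_rank <- sequence(truth$n_probes)
  probe_ids <- sprintf("%s_P%d", truth$gene_ids[gene_idx], probe_rank)
  is_max <- probe_rank == truth$max_probe[gene_idx]
  counts <- gene_counts[gene_idx, , drop = FALSE]
  nm <- which(!is_max)
  if (length(nm)) {
    u <- matrix(stats::runif(length(nm) * ns), nrow = length(nm))
    drawn <- floor(u * (counts[nm, , drop = FALSE] + 1))
    counts[nm, ] <- pmin(drawn, counts[nm, , drop = FALSE])
  }
  rownames(counts) <- probe_ids
  probe_counts(counts,
               data.frame(probe_id = probe_ids,
                          gene_id = truth$gene_ids[gene_idx],
                          symbol = truth$symbols[gene_idx],
                          stringsAsFactors = FALSE))
}

#' Generate matched targeted and reference platform data
#'
#' Produces probe-level counts for the targeted platform (replicated), an
#' EPM expression matrix for the reference platform (one profile per cell
#' line), a sample annotation table, and the ground-truth object recording
#' the planted structure.
#'
#' @param config a [sim_config()].
#' @return list with elements `targeted` ([probe_counts()]), `reference`
#'   ([expr_matrix()] in EPM), `annotation` (see [sample_annotation()]) and
#'   `truth`.
#' @export
generate_dual_platform <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    truth <- draw_truth(config)
    nc <- config$n_cell_lines
    nr <- config$n_replicates_per_platform
    ## Planted bias = platform-specific capture loss: a gene with negative
    ## bias is suppressed on the targeted platform, one with positive bias
    ## on the reference platform. The signed targeted-minus-reference log2
    ## difference equals the bias either way, but libraries stay
    ## mass-balanced so no global compositional offset is induced.
    mu <- truth$baseline + truth$cell_effects          # recycled by column
    mu_t <- mu + pmin(truth$bias, 0)
    mu_r <- mu - pmax(truth$bias, 0)

    t_ids <- as.vector(t(outer(truth$cell_lines, seq_len(nr),
                               function(c, r) sprintf("%s_T_r%d", c, r))))
    gene_counts_t <- matrix(0, nrow = config$n_genes, ncol = nc * nr,
                            dimnames = list(truth$gene_ids, t_ids))
    k <- 0
    for (c in seq_len(nc)) for (r in seq_len(nr)) {
      k <- k + 1
      lib <- stats::runif(1, config$library_size_range[1],
                          config$library_size_range[2])
      gene_counts_t[, k] <- synth_sample(mu_t[, c],
                                         config$replicate_noise_sd, lib)
    }
    targeted <- expand_probes(gene_counts_t, truth)

    r_ids <- sprintf("%s_R", truth$cell_lines)
    gene_counts_r <- matrix(0, nrow = config$n_genes, ncol = nc,
                            dimnames = list(truth$gene_ids, r_ids))
    for (c in seq_len(nc)) {
      lib <- stats::runif(1, config$library_size_range[1],
                          config$library_size_range[2])
      gene_counts_r[, c] <- synth_sample(mu_r[, c],
                                         config$replicate_noise_sd, lib)
    }
    tot <- colSums(gene_counts_r)
    epm <- sweep(gene_counts_r, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
    reference <- expr_matrix(epm, unit = "EPM", symbols = truth$symbols)

    annotation <- sample_annotation(data.frame(
      sample_id = c(t_ids, r_ids),
      cell_line = c(rep(truth$cell_lines, each = nr), truth$cell_lines),
      platform = c(rep("TARGETED", nc * nr), rep("REFERENCE", nc)),
      phase = "none",
      replicate = c(rep(seq_len(nr), nc), rep(1L, nc)),
      stringsAsFactors = FALSE))

    truth$targeted_gene_counts <- gene_counts_t
    list(targeted = targeted, reference = reference,
         annotation = annotation, truth = truth)
  })
}

#' Generate multi-phase replicate data for the targeted platform
#'
#' Phases share all generative parameters; they differ only in total library
#' size (scaled per phase by `depth_factors`) and fresh replicate noise
#' draws, emulating sequencing runs performed months apart at different
#' target read depths.
#'
#' @param config a [sim_config()].
#' @param n_phases number of phases (>= 2).
#' @param depth_factors positive multiplier on library size, one per phase.
#' @return list with `phases` (list of [probe_counts()], one per phase),
#'   `annotation`, and `truth`.
#' @export
generate_replicate_phases <- function(config, n_phases = 2,
                                      depth_factors = c(1.0, 0.75)) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_phases) || n_phases < 2 || n_phases != round(n_phases))
    stop("'n_phases' must be an integer >= 2")
  if (length(depth_factors) != n_phases)
    stop("need one depth factor per phase")
  if (any(!is.finite(depth_factors)) || any(depth_factors <= 0))
    stop("depth factors must be positive and finite")
  local_seed(config$seed, {
    truth <- draw_truth(config)
    nc <- config$n_cell_lines
    nr <- config$n_replicates_per_platform
    mu_t <- truth$baseline + truth$cell_effects + pmin(truth$bias, 0)

    phases <- vector("list", n_phases)
    ann <- list()
    for (p in seq_len(n_phases)) {
      ids <- as.vector(t(outer(truth$cell_lines, seq_len(nr),
                               function(c, r) sprintf("%s_P%d_r%d", c, p, r))))
      gene_counts <- matrix(0, nrow = config$n_genes, ncol = nc * nr,
                            dimnames = list(truth$gene_ids, ids))
      k <- 0
      for (c in seq_len(nc)) for (r in seq_len(nr)) {
        k <- k + 1
        lib <- stats::runif(1, config$library_size_range[1],
                            config$library_size_range[2]) * depth_factors[p]
        gene_counts[, k] <- synth_sample(mu_t[, c],
                                         config$replicate_noise_sd, lib)
      }
      phases[[p]] <- expand_probes(gene_counts, truth)
      ann[[p]] <- data.frame(sample_id = ids,
                             cell_line = rep(truth$cell_lines, each = nr),
                             platform = "TARGETED",
                             phase = as.character(p),
                             replicate = rep(seq_len(nr), nc),
                             stringsAsFactors = FALSE)
    }
    annotation <- sample_annotation(do.call(rbind, ann))
    list(phases = phases, annotation = annotation, truth = truth)
  })
}
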