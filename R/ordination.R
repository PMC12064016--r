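## Ordination and variance attribution: PCA, sequential ANOVA on single
## components, Euclidean distances, PERMANOVA (from its definition, with
## seeded permutation p-values), multivariate dispersion test, PCoA.

#' Principal component analysis of an expression matrix
#'
#' Samples are the observations and genes the variables. Data are centered
#' but not scaled (all inputs share a unit), via singular value
#' decomposition.
#'
#' @param m an [expr_matrix()]; any unit.
#' @param center,scale passed to [stats::prcomp()].
#' @return an `ordination` list: `scores` (samples x components),
#'   `rotation` (genes x components), `eigenvalues`, `var_fraction`,
#'   `center`.
#' @export
pca_ordination <- function(m, center = TRUE, scale = FALSE) {
  if (ncol(m) < 2) stop("PCA needs at least 2 samples")
  p <- stats::prcomp(t(unclass(m)), center = center, scale. = scale)
  ev <- p$sdev^2
  tot <- sum(ev)
  structure(list(scores = p$x, rotation = p$rotation, eigenvalues = ev,
                 var_fraction = if (tot > 0) ev / tot else rep(0, length(ev)),
                 center = p$center),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d samples, %d components; top var fractions: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(signif(utils::head(x$var_fraction, 3), 3),
                    collapse = ", ")))
  invisible(x)
}

attribution_frame <- function(term, df, ss, statistic, p, ss_total,
                              n_perm = NA_integer_) {
  out <- data.frame(term = term, df = df, ss = ss,
                    r2 = ss / ss_total, statistic = statistic, p = p,
                    stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- n_perm
  attr(out, "ss_total") <- ss_total
  class(out) <- c("variance_attribution", "data.frame")
  out
}

#' Sequential ANOVA on a single ordination component
#'
#' Fits the component scores against an ordered set of factors with
#' sequential (Type-I) sums of squares, reporting per-term R-squared
#' (SS / SS_total), the F statistic against the residual mean square and
#' its parametric p-value. A saturated model (zero residual df) reports
#' R-squared with F and p flagged `NA`.
#'
#' @param scores numeric vector of component scores (one per sample).
#' @param data data.frame of factors, one row per sample.
#' @param terms ordered term names (columns of `data`); defaults to all.
#' @return a `variance_attribution` data.frame with one row per term plus
#'   `Residual` and `Total`.
#' @export
anova_on_component <- function(scores, data, terms = names(data)) {
  if (length(scores) != nrow(data))
    stop("'scores' and 'data' must cover the same samples")
  bad <- setdiff(terms, names(data))
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  df <- data.frame(lapply(data[terms], factor))
  df$.y <- as.numeric(scores)
  fml <- stats::reformulate(terms, response = ".y")
  fit <- stats::lm(fml, data = df)
  ## perfect fits trigger a reliability warning from anova.lm; degenerate
  ## F/p are flagged NA below instead
  a <- suppressWarnings(stats::anova(fit))
  ss <- a[["Sum Sq"]]
  dfs <- a[["Df"]]
  ss_total <- sum(ss)
  n_terms <- length(terms)
  res_df <- dfs[n_terms + 1]
  stat <- a[["F value"]][seq_len(n_terms)]
  p <- a[["Pr(>F)"]][seq_len(n_terms)]
  if (res_df == 0) { stat[] <- NA_real_; p[] <- NA_real_ }
  attribution_frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs[seq_len(n_terms)], res_df, sum(dfs)),
    ss = c(ss[seq_len(n_terms)], ss[n_terms + 1], ss_total),
    statistic = c(stat, NA, NA), p = c(p, NA, NA), ss_total = ss_total)
}

#' Euclidean distances between samples
#'
#' @param x an [expr_matrix()] (distances between its sample columns), an
#'   `ordination` (distances between score rows) or a plain samples x
#'   variables matrix.
#' @return a [stats::dist] object.
#' @export
sample_distances <- function(x) {
  if (inherits(x, "ordination")) return(stats::dist(x$scores))
  if (inherits(x, "expr_matrix")) return(stats::dist(t(unclass(x))))
  stats::dist(x)
}

check_distance_matrix <- function(d) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-10,
                                              check.attributes = FALSE)))
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(D)) > 1e-10)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distance matrix has negative entries")
  D
}

## Gower-centered inner-product matrix G = C (-1/2 D o D) C.
gower_center <- function(D) {
  A <- -0.5 * D^2
  rm <- rowMeans(A)
  A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), rm) + mean(A)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Eigendecomposition of the Gower double-centered matrix of squared
#' distances. For Euclidean distances the coordinates reproduce PCA scores
#' up to sign/rotation.
#'
#' @param d a [stats::dist] or symmetric square matrix with zero diagonal.
#' @return list with `points` (coordinates on positive-eigenvalue axes),
#'   `eigenvalues` (all, nonincreasing), `rel_eigenvalues` (relative to the
#'   positive total).
#' @export
pcoa <- function(d) {
  D <- check_distance_matrix(d)
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev), 0) * 1e-8
  pos <- which(ev > tol)
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]),
                                                 length(pos))
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("Axis", seq_along(pos))
  list(points = pts, eigenvalues = ev,
       rel_eigenvalues = if (sum(ev[pos]) > 0) ev / sum(ev[pos]) else ev)
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance with sequential
#' (Type-I) term sums of squares. Term SS are traces of the Gower-centered
#' inner-product matrix projected onto nested dummy-coded design spaces;
#' R-squared = SS / total SS is permutation-free, while p-values come from
#' whole-row label permutation of the distance matrix with a seeded
#' generator: p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1).
#'
#' @param d distances between samples ([stats::dist] or square matrix).
#' @param data data.frame of factors, one row per sample, in distance
#'   order.
#' @param terms ordered term names; defaults to all columns of `data`.
#' @param n_perm number of permutations (999 by default).
#' @param seed integer seed for the permutations (optional).
#' @return a `variance_attribution` data.frame (terms + `Residual` +
#'   `Total`) with pseudo-F statistics and permutation p-values.
#' @export
permanova <- function(d, data, terms = names(data), n_perm = 999,
                      seed = NULL) {
  D <- check_distance_matrix(d)
  n <- nrow(D)
  if (nrow(data) != n) stop("'data' must have one row per sample")
  bad <- setdiff(terms, names(data))
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  fac <- data.frame(lapply(data[terms], factor))
  for (t in terms)
    if (nlevels(fac[[t]]) < 2)
      stop(sprintf("term '%s' has fewer than 2 levels", t))

  G <- gower_center(D)
  ss_total <- sum(diag(G))
  hats <- vector("list", length(terms))
  ranks <- integer(length(terms))
  for (k in seq_along(terms)) {
    X <- stats::model.matrix(stats::reformulate(terms[seq_len(k)]), fac)
    q <- qr(X)
    ranks[k] <- q$rank
    hats[[k]] <- hat_matrix(X)
  }
  tr_seq <- vapply(hats, function(H) sum(H * G), numeric(1))
  ss_terms <- diff(c(0, tr_seq))          # intercept trace is 0 (G centered)
  df_terms <- diff(c(1, ranks))
  df_res <- n - ranks[length(ranks)]
  ss_res <- ss_total - tr_seq[length(tr_seq)]
  if (df_res <= 0) stop("saturated design: no residual degrees of freedom")
  ms_res <- ss_res / df_res
  f_obs <- (ss_terms / df_terms) / ms_res

  p <- rep(NA_real_, length(terms))
  if (n_perm > 0) {
    exceed <- numeric(length(terms))
    local_seed(seed, {
      for (i in seq_len(n_perm)) {
        pm <- sample.int(n)
        Gp <- G[pm, pm]
        trp <- vapply(hats, function(H) sum(H * Gp), numeric(1))
        ssp <- diff(c(0, trp))
        ssrp <- ss_total - trp[length(trp)]
        fp <- (ssp / df_terms) / (ssrp / df_res)
        exceed <- exceed + (fp >= f_obs - 1e-12)
      }
    })
    p <- (1 + exceed) / (n_perm + 1)
  }
  attribution_frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    ss = c(ss_terms, ss_res, ss_total),
    statistic = c(f_obs, NA, NA), p = c(p, NA, NA),
    ss_total = ss_total, n_perm = n_perm)
}

weiszfeld_median <- function(X, tol = 1e-8, max_iter = 200) {
  m <- colMeans(X)
  for (i in seq_len(max_iter)) {
    dd <- sqrt(rowSums(sweep(X, 2, m)^2))
    if (any(dd < tol)) return(m)
    w <- 1 / dd
    m_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the samples by PCoA (keeping negative-eigenvalue axes, whose
#' squared contributions are subtracted), computes each sample's distance
#' to its group center (centroid by default, spatial median optional), and
#' tests equality of mean distances across groups with a one-way ANOVA F
#' test (optionally also a seeded permutation p obtained by shuffling the
#' distances across groups).
#'
#' @param d distances between samples.
#' @param group grouping vector (one per sample, >= 2 groups).
#' @param center `"centroid"` (closed form) or `"spatial_median"`
#'   (Weiszfeld iteration on the real axes).
#' @param n_perm permutations for the optional permutation p (0 = skip).
#' @param seed seed for the permutation p.
#' @return list with `distances`, `group`, `group_means`, `statistic`
#'   (F), `p` (parametric), `perm_p`, `flagged` (singleton groups), and
#'   `center`.
#' @export
dispersion_test <- function(d, group, center = c("centroid",
                                                 "spatial_median"),
                            n_perm = 0, seed = NULL) {
  center <- match.arg(center)
  D <- check_distance_matrix(d)
  group <- factor(group)
  if (length(group) != nrow(D)) stop("'group' must cover every sample")
  if (nlevels(group) < 2) stop("need at least 2 groups")
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values), 0) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  Xp <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  Xn <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(abs(e$values[neg])), sum(neg))

  dists <- numeric(nrow(D))
  flagged <- character(0)
  for (g in levels(group)) {
    idx <- which(group == g)
    if (length(idx) == 1) {
      dists[idx] <- 0
      flagged <- c(flagged, g)
      next
    }
    cp <- if (center == "centroid") colMeans(Xp[idx, , drop = FALSE])
          else weiszfeld_median(Xp[idx, , drop = FALSE])
    d2 <- rowSums(sweep(Xp[idx, , drop = FALSE], 2, cp)^2)
    if (ncol(Xn) > 0) {
      cn <- if (center == "centroid") colMeans(Xn[idx, , drop = FALSE])
            else weiszfeld_median(Xn[idx, , drop = FALSE])
      d2 <- d2 - rowSums(sweep(Xn[idx, , drop = FALSE], 2, cn)^2)
    }
    dists[idx] <- sqrt(pmax(d2, 0))
  }
  names(dists) <- rownames(D)
  group_means <- tapply(dists, group, mean)
  if (stats::var(dists) == 0) {
    f <- NA_real_; p <- NA_real_
  } else {
    a <- stats::anova(stats::lm(dists ~ group))
    f <- a[["F value"]][1]; p <- a[["Pr(>F)"]][1]
  }
  perm_p <- NA_real_
  if (n_perm > 0 && is.finite(f)) {
    exceed <- 0
    local_seed(seed, {
      for (i in seq_len(n_perm)) {
        dp <- dists[sample.int(length(dists))]
        ap <- stats::anova(stats::lm(dp ~ group))
        if (ap[["F value"]][1] >= f - 1e-12) exceed <- exceed + 1
      }
    })
    perm_p <- (1 + exceed) / (n_perm + 1)
  }
  list(distances = dists, group = group, group_means = group_means,
       statistic = f, p = p, perm_p = perm_p, flagged = flagged,
       center = center)
}

#' Genes with high absolute loadings on a component
#'
#' @param ord an `ordination` from [pca_ordination()].
#' @param component component index (default 1).
#' @param threshold absolute-loading cutoff (default 0.02).
#' @return data.frame `gene`, `loading`, sorted by decreasing |loading|.
#' @export
high_loading_genes <- function(ord, component = 1, threshold = 0.02) {
  if (component > ncol(ord$rotation)) stop("component does not exist")
  l <- ord$rotation[, component]
  keep <- abs(l) > threshold
  out <- data.frame(gene = names(l)[keep], loading = unname(l[keep]),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$loading)), , drop = FALSE]
}
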