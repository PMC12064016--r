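## Independent oracles and small fixture builders shared across tests.

## All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

## Exhaustive-permutation PERMANOVA for a single factor: returns the exact
## permutation p (proportion of permutations with F >= observed, identity
## included) computed by brute force from first principles.
exhaustive_permanova_p <- function(D, group) {
  n <- nrow(D)
  A <- -0.5 * D^2
  rm <- rowMeans(A)
  G <- A - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(A)
  f_stat <- function(g) {
    g <- factor(g)
    X <- stats::model.matrix(~g)
    q <- qr(X)
    H <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    ss_b <- sum(H * G)
    ss_t <- sum(diag(G))
    df_b <- nlevels(g) - 1
    df_r <- n - nlevels(g)
    (ss_b / df_b) / ((ss_t - ss_b) / df_r)
  }
  f_obs <- f_stat(group)
  fs <- vapply(all_perms(n), function(p) f_stat(group[p]), numeric(1))
  mean(fs >= f_obs - 1e-12)
}

## Direct centroid decomposition of a Euclidean distance design:
## R^2 = SSB / SST computed from the raw coordinates.
centroid_r2 <- function(X, group) {
  group <- factor(group)
  grand <- colMeans(X)
  sst <- sum(sweep(X, 2, grand)^2)
  ssb <- 0
  for (g in levels(group)) {
    idx <- group == g
    cg <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * sum((cg - grand)^2)
  }
  ssb / sst
}

## Independent BH step-up reimplementation.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
## the fixed-margin 2x2 family (a varies; probabilities from dhyper).
fisher_p_oracle <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c
  lo <- max(0, col1 - row2); hi <- min(col1, row1)
  k <- lo:hi
  probs <- stats::dhyper(k, row1, row2, col1)
  p_obs <- stats::dhyper(a, row1, row2, col1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Tiny expression fixture: genes x samples with known values.
make_expr <- function(values, unit = "log2EPM1", genes = NULL,
                      samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes))
    genes <- if (!is.null(rownames(m))) rownames(m)
             else sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples))
    samples <- if (!is.null(colnames(m))) colnames(m)
               else sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expr_matrix(m, unit = unit)
}

## Log2 matrices for a known per-gene targeted-minus-reference difference.
make_diff_pair <- function(delta, base = 5) {
  r <- make_expr(matrix(base, nrow = nrow(delta), ncol = ncol(delta),
                        dimnames = dimnames(delta)))
  t <- make_expr(unclass(r) + delta)
  list(t = t, r = r)
}
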