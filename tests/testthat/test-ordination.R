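random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  make_expr(matrix(stats::rnorm(n_genes * n_samples, 8, 2),
                   nrow = n_genes))
}

test_that("PCA satisfies the SVD identities", {
  m <- random_expr(50, 6)
  ord <- pca_ordination(m)
  centered <- t(unclass(m)) - rep(colMeans(t(unclass(m))),
                                  each = ncol(m))
  ## reconstruction
  expect_equal(ord$scores %*% t(ord$rotation), centered,
               tolerance = 1e-8, ignore_attr = TRUE)
  ## isometry of scores
  expect_equal(as.matrix(stats::dist(ord$scores)),
               as.matrix(stats::dist(centered)),
               tolerance = 1e-8, ignore_attr = TRUE)
  ## eigenvalues nonincreasing, fractions sum to 1, scores orthogonal
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))
  expect_equal(sum(ord$var_fraction), 1, tolerance = 1e-8)
  cp <- crossprod(ord$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
})

test_that("rank-1 data puts everything on PC1", {
  vals <- matrix(5, nrow = 4, ncol = 2,
                 dimnames = list(sprintf("g%d", 1:4), c("s1", "s2")))
  vals["g2", 2] <- 9
  ord <- pca_ordination(expr_matrix(vals, unit = "log2EPM1"))
  expect_equal(ord$var_fraction[1], 1)
  expect_equal(abs(ord$rotation["g2", 1]), 1, tolerance = 1e-10)
})

test_that("a constant matrix yields all-zero eigenvalues", {
  vals <- matrix(3, nrow = 5, ncol = 4,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:4)))
  ord <- pca_ordination(expr_matrix(vals, unit = "log2EPM1"))
  expect_true(all(ord$eigenvalues < 1e-12))
})

test_that("sequential ANOVA matches hand-computed sums of squares", {
  ## y = (1,2,3,4), A = (a,a,b,b), B = (x,y,x,y):
  ## SS_A = 4, SS_B = 1 (projection of the within-A residuals on B),
  ## residual 0 with 1 df (an exact but unsaturated fit).
  y <- c(1, 2, 3, 4)
  dat <- data.frame(A = c("a", "a", "b", "b"), B = c("x", "y", "x", "y"))
  att <- suppressWarnings(anova_on_component(y, dat, terms = c("A", "B")))
  expect_equal(att$ss[att$term == "A"], 4)
  expect_equal(att$ss[att$term == "B"], 1)
  expect_equal(att$ss[att$term == "Residual"], 0)
  expect_equal(att$r2[att$term == "A"], 0.8)
  expect_equal(att$r2[att$term == "B"], 0.2)
  ## a truly saturated model (0 residual df) flags F and p
  sat <- anova_on_component(c(1, 2), data.frame(A = c("a", "b")))
  expect_true(is.na(sat$statistic[sat$term == "A"]))
  expect_equal(sat$r2[sat$term == "A"], 1)
})

test_that("single-factor ANOVA reproduces SSB + SSW = SST and extremes", {
  ## perfect two-group separation
  att <- suppressWarnings(
    anova_on_component(c(1, 1, 2, 2), data.frame(g = c("a", "a", "b", "b"))))
  expect_equal(att$r2[att$term == "g"], 1)
  ## factor orthogonal to the response
  att0 <- anova_on_component(c(1, 2, 1, 2),
                             data.frame(g = c("a", "a", "b", "b")))
  expect_lt(att0$r2[att0$term == "g"], 1e-10)
  ## classical decomposition on random data
  set.seed(2)
  yy <- stats::rnorm(12)
  g <- rep(c("a", "b", "c"), each = 4)
  a <- anova_on_component(yy, data.frame(g = g))
  ssb <- sum(4 * (tapply(yy, g, mean) - mean(yy))^2)
  ssw <- sum((yy - ave(yy, g))^2)
  expect_equal(a$ss[a$term == "g"], ssb, tolerance = 1e-10)
  expect_equal(a$ss[a$term == "Residual"], ssw, tolerance = 1e-10)
  expect_equal(a$ss[a$term == "Total"], ssb + ssw, tolerance = 1e-10)
})

test_that("PCoA recovers 1-D geometry and rejects bad input", {
  D <- as.matrix(stats::dist(c(0, 3, 5)))
  p <- pcoa(D)
  coords <- p$points[, 1]
  expect_equal(as.matrix(stats::dist(coords)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  bad <- D; bad[1, 2] <- -1; bad[2, 1] <- -1
  expect_error(pcoa(bad), "negative")
  asym <- D; asym[1, 2] <- 99
  expect_error(pcoa(asym), "symmetric")
})

test_that("PCoA of Euclidean distances matches PCA eigenvalues", {
  m <- random_expr(40, 7, seed = 5)
  ord <- pca_ordination(m)
  p <- pcoa(stats::dist(ord$scores))
  n <- ncol(m)
  keep <- ord$eigenvalues > 1e-8
  expect_equal(p$eigenvalues[seq_len(sum(keep))],
               (n - 1) * ord$eigenvalues[keep], tolerance = 1e-6)
})

test_that("PERMANOVA matches the exhaustive-permutation oracle (n = 6)", {
  set.seed(11)
  X <- matrix(stats::rnorm(12), nrow = 6)
  X[4:6, ] <- X[4:6, ] + 1.2
  D <- as.matrix(stats::dist(X))
  g <- rep(c("a", "b"), each = 3)
  exact <- exhaustive_permanova_p(D, g)
  pa <- permanova(D, data.frame(g = g), n_perm = 999, seed = 42)
  mc_sd <- sqrt(exact * (1 - exact) / 999)
  expect_lt(abs(pa$p[1] - exact), 2 * mc_sd + 2 / 1000)
  ## R2 equals the direct centroid SSB/SST decomposition
  expect_equal(pa$r2[1], centroid_r2(X, g), tolerance = 1e-8)
})

test_that("PERMANOVA R2 is permutation-free and groups-identical data give 0", {
  X <- matrix(c(0, 0, 1, 1, 2, 2, 0, 0, 1, 1, 2, 2), ncol = 2)
  D <- as.matrix(stats::dist(X))
  g <- rep(c("a", "b"), times = 3)      # identical multisets per group
  pa <- permanova(D, data.frame(g = g), n_perm = 199, seed = 1)
  expect_lt(abs(pa$ss[1]), 1e-10)
  expect_lt(abs(pa$r2[1]), 1e-10)
  expect_gt(pa$p[1], 0.5)
  ## R2 identical across seeds
  pb <- permanova(D, data.frame(g = g), n_perm = 199, seed = 99)
  expect_identical(pa$r2, pb$r2)
})

test_that("PERMANOVA agrees with vegan::adonis2 term-by-term", {
  skip_if_not_installed("vegan")
  set.seed(21)
  X <- matrix(stats::rnorm(60), nrow = 12)
  grp <- data.frame(f1 = rep(c("a", "b"), each = 6),
                    f2 = rep(c("u", "v", "w"), 4))
  D <- stats::dist(X)
  pa <- permanova(D, grp, terms = c("f1", "f2"), n_perm = 99, seed = 2)
  va <- vegan::adonis2(D ~ f1 + f2, data = grp, permutations = 99,
                       by = "terms")
  expect_equal(pa$ss[1:2], va$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(pa$r2[1:2], va$R2[1:2], tolerance = 1e-8)
  expect_equal(pa$statistic[1:2], va$F[1:2], tolerance = 1e-8)
})

test_that("PERMANOVA is isometric: centered data vs full PCA scores", {
  m <- random_expr(30, 9, seed = 9)
  grp <- data.frame(g = rep(c("a", "b", "c"), each = 3))
  ord <- pca_ordination(m)
  d_scores <- stats::dist(ord$scores)
  d_raw <- stats::dist(t(unclass(m)) -
                         rep(rowMeans(unclass(m)), each = ncol(m)))
  pa <- permanova(d_scores, grp, n_perm = 0)
  pb <- permanova(d_raw, grp, n_perm = 0)
  expect_equal(pa$ss, pb$ss, tolerance = 1e-8)
  expect_equal(pa$r2, pb$r2, tolerance = 1e-8)
})

test_that("PERMANOVA rejects degenerate terms", {
  D <- as.matrix(stats::dist(matrix(stats::rnorm(8), ncol = 2)))
  expect_error(permanova(D, data.frame(g = rep("a", 4))), "levels")
})

test_that("dispersion test: equal-shape groups and scaled groups", {
  ## mirror-image groups: identical shape, so between-group SS of the
  ## distances is exactly zero (radii vary within groups)
  A <- matrix(c(1, 0, -2, 0, 0, 3, 0, -1), ncol = 2, byrow = TRUE)
  X <- rbind(A, -A + 10)
  D <- stats::dist(X)
  g <- rep(c("a", "b"), each = 4)
  dt <- dispersion_test(D, g)
  expect_lt(dt$statistic, 1e-10)
  expect_gt(dt$p, 0.99)
  ## group scaled x3 about its centroid: mean distance ratio ~ 3
  set.seed(8)
  B0 <- matrix(stats::rnorm(20), ncol = 2)
  B0 <- sweep(B0, 2, colMeans(B0))
  X2 <- rbind(B0, 3 * B0 + 5)
  dt2 <- dispersion_test(stats::dist(X2), rep(c("a", "b"), each = 10))
  expect_equal(unname(dt2$group_means["b"] / dt2$group_means["a"]), 3,
               tolerance = 1e-6)
  expect_lt(dt2$p, 0.01)
})

test_that("dispersion distances match vegan::betadisper centroids", {
  skip_if_not_installed("vegan")
  set.seed(13)
  X <- matrix(stats::rnorm(36), ncol = 3)
  g <- rep(c("a", "b"), each = 6)
  D <- stats::dist(X)
  dt <- dispersion_test(D, g)
  bd <- vegan::betadisper(D, g, type = "centroid")
  expect_equal(unname(dt$distances), unname(bd$distances),
               tolerance = 1e-8)
})

test_that("coincident points flag an undefined dispersion F", {
  D <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  dt <- dispersion_test(D, rep(c("a", "b"), each = 3))
  expect_true(all(dt$distances == 0))
  expect_true(is.na(dt$statistic))
  ## singleton groups are flagged
  dt1 <- dispersion_test(stats::dist(matrix(stats::rnorm(8), ncol = 2)),
                         c("a", "a", "a", "b"))
  expect_equal(dt1$flagged, "b")
})

test_that("high-loading extraction equals the brute-force filter", {
  m <- random_expr(40, 6, seed = 31)
  ord <- pca_ordination(m)
  hl <- high_loading_genes(ord, 1, threshold = 0.02)
  brute <- rownames(ord$rotation)[abs(ord$rotation[, 1]) > 0.02]
  expect_setequal(hl$gene, brute)
  expect_true(all(diff(abs(hl$loading)) <= 1e-12))
  expect_equal(nrow(high_loading_genes(ord, 1, threshold = 10)), 0)
  vals <- matrix(c(0.5, -0.5, 0.001), ncol = 1)
  fake <- list(rotation = matrix(vals, dimnames = list(c("gA", "gB", "gC"),
                                                       "PC1")))
  class(fake) <- "ordination"
  expect_equal(high_loading_genes(fake, 1)$gene, c("gA", "gB"))
})
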