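make_probes <- function() {
  counts <- matrix(c(5, 9, 3,
                     2, 1, 7,
                     0, 4, 4), nrow = 3, byrow = TRUE,
                   dimnames = list(c("p1", "p2", "p3"),
                                   c("s1", "s2", "s3")))
  probe_counts(counts,
               data.frame(probe_id = c("p1", "p2", "p3"),
                          gene_id = c("gA", "gA", "gB"),
                          symbol = c("A", "A", "B")))
}

test_that("probe collapse takes the per-sample maximum", {
  m <- collapse_probes(make_probes())
  expect_equal(expr_unit(m), "counts")
  expect_equal(unclass(m)["gA", ], c(s1 = 5, s2 = 9, s3 = 7))
  expect_equal(unclass(m)["gB", ], c(s1 = 0, s2 = 4, s3 = 4))
})

test_that("collapse is the identity when every probe has its own gene", {
  counts <- matrix(1:6, nrow = 3,
                   dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  pm <- probe_counts(counts,
                     data.frame(probe_id = c("p1", "p2", "p3"),
                                gene_id = c("g1", "g2", "g3")))
  m <- collapse_probes(pm)
  expect_equal(unname(unclass(m)), unname(counts), ignore_attr = TRUE)
})

test_that("probes without a gene id are rejected by name", {
  counts <- matrix(1:4, nrow = 2,
                   dimnames = list(c("p1", "p2"), c("s1", "s2")))
  expect_error(probe_counts(counts,
                            data.frame(probe_id = c("p1", "p2"),
                                       gene_id = c("g1", ""))),
               "p2")
})

test_that("EPM normalization scales proportionally and sums to one million", {
  m <- make_expr(matrix(c(2, 8), ncol = 1), unit = "counts")
  e <- epm_normalize(m)
  expect_equal(unname(unclass(e)[, 1]), c(200000, 800000))
  set.seed(1)
  r <- make_expr(matrix(stats::rexp(60), nrow = 20, ncol = 3),
                 unit = "counts")
  e2 <- epm_normalize(r)
  expect_true(all(abs(colSums(e2) - 1e6) < 0.01))
  ## renormalization after removing half the mass doubles what remains
  half <- e2[1:10, , drop = FALSE]
  mass <- colSums(half)
  e3 <- epm_normalize(half)
  expect_equal(unclass(e3), sweep(unclass(half), 2, 1e6 / mass, "*"),
               tolerance = 1e-12)
  ## idempotence
  expect_equal(unclass(epm_normalize(e2)), unclass(e2), tolerance = 1e-12)
})

test_that("an all-zero sample is rejected by name", {
  m <- make_expr(matrix(c(1, 2, 0, 0), nrow = 2), unit = "counts",
                 samples = c("ok", "empty"))
  expect_error(epm_normalize(m), "empty")
})

test_that("log2(EPM+1) maps anchor points correctly and is monotone", {
  ## single-gene sample: EPM is 1e6, log2(1e6 + 1) ~ 19.93
  one <- log2p1(epm_normalize(make_expr(matrix(5, 1, 1), unit = "counts")))
  expect_equal(unclass(one)[1, 1], log2(1e6 + 1))
  col <- c(0, 1, 3, 1e6 - 4)
  m <- make_expr(matrix(col, ncol = 1), unit = "EPM")
  lg <- log2p1(m)
  expect_equal(expr_unit(lg), "log2EPM1")
  expect_equal(unname(unclass(lg)[1:3, 1]), c(0, 1, 2))
  ## strictly monotone
  x <- sort(stats::runif(50, 0, 100))
  lx <- log2(x + 1)
  expect_true(all(diff(lx) > 0))
  expect_error(log2p1(make_expr(matrix(1, 1, 1), unit = "counts")),
               "unit")
})

test_that("replicate averaging is the per-gene arithmetic mean", {
  m <- make_expr(matrix(c(10, 20, 30,
                          1, 2, 3), nrow = 2, byrow = TRUE),
                 unit = "EPM", samples = c("a_r1", "a_r2", "a_r3"))
  ann <- data.frame(sample_id = colnames(m), cell_line = "a",
                    platform = "TARGETED", phase = "none",
                    replicate = 1:3)
  avg <- average_replicates(m, ann, by = "cell_line")
  expect_equal(unname(unclass(avg$expr)[, 1]), c(20, 2))
  expect_equal(avg$annotation$sample_id, "a")
  ## single replicate is unchanged
  one <- m[, 1, drop = FALSE]
  avg1 <- average_replicates(one, ann[1, ], by = "cell_line")
  expect_equal(unname(unclass(avg1$expr)), unname(unclass(one)))
})

test_that("balanced phases: grand mean equals mean of phase means", {
  set.seed(42)
  vals <- matrix(stats::runif(36, 1, 100), nrow = 6)
  colnames(vals) <- sprintf("a_p%d_r%d", rep(1:2, each = 3), rep(1:3, 2))
  rownames(vals) <- sprintf("g%d", 1:6)
  m <- expr_matrix(vals, unit = "EPM")
  ann <- data.frame(sample_id = colnames(vals), cell_line = "a",
                    platform = "TARGETED",
                    phase = rep(1:2, each = 3), replicate = rep(1:3, 2))
  all6 <- average_replicates(m, ann, by = "cell_line")
  by_phase <- average_replicates(m, ann, by = c("cell_line", "phase"))
  expect_equal(unname(unclass(all6$expr)[, 1]),
               unname(rowMeans(unclass(by_phase$expr))))
})

test_that("averaging rejects unknown grouping keys", {
  m <- make_expr(matrix(1:4, nrow = 2), unit = "EPM",
                 samples = c("x", "y"))
  ann <- data.frame(sample_id = c("x", "y"), cell_line = "a",
                    platform = "TARGETED", phase = "none", replicate = 1:2)
  expect_error(average_replicates(m, ann, by = "tissue"), "tissue")
})

test_that("intersect_and_rescale harmonizes gene universes", {
  a <- make_expr(matrix(c(10, 20, 70), ncol = 1), unit = "counts",
                 genes = c("g1", "g2", "g3"))
  b <- make_expr(matrix(c(30, 30, 40), ncol = 1), unit = "counts",
                 genes = c("g2", "g3", "g4"))
  ab <- intersect_and_rescale(epm_normalize(a), epm_normalize(b))
  expect_equal(rownames(ab$a), c("g2", "g3"))
  expect_equal(rownames(ab$b), c("g2", "g3"))
  expect_equal(ab$report,
               list(n_a_only = 1, n_b_only = 1, n_shared = 2))
  expect_true(all(abs(colSums(ab$a) - 1e6) < 0.01))
  expect_true(all(abs(colSums(ab$b) - 1e6) < 0.01))
  ## identical universes leave already-normalized values unchanged
  e <- epm_normalize(a)
  same <- intersect_and_rescale(e, e)
  expect_equal(unclass(same$a), unclass(e), tolerance = 1e-12)
  ## disjoint universes are rejected
  expect_error(intersect_and_rescale(
    epm_normalize(make_expr(matrix(1, 1, 1), unit = "counts",
                            genes = "gX")),
    epm_normalize(make_expr(matrix(1, 1, 1), unit = "counts",
                            genes = "gY"))),
    "share no genes")
})

test_that("rescaling preserves within-sample rank order of shared genes", {
  set.seed(7)
  a <- make_expr(matrix(stats::runif(40, 1, 1000), nrow = 20), unit = "counts")
  b <- make_expr(matrix(stats::runif(30, 1, 1000), nrow = 15), unit = "counts",
                 genes = sprintf("g%02d", 4:18))
  ab <- intersect_and_rescale(epm_normalize(a), epm_normalize(b))
  shared <- rownames(ab$a)
  for (j in seq_len(ncol(a)))
    expect_equal(order(unclass(ab$a)[, j]),
                 order(unclass(epm_normalize(a))[shared, j]))
})

test_that("collapse then normalize commutes with sample subsetting", {
  pm <- make_probes()
  full <- epm_normalize(collapse_probes(pm))
  sub <- probe_counts(pm$counts[, c("s1", "s3")], pm$probe_info)
  expect_equal(unclass(epm_normalize(collapse_probes(sub))),
               unclass(full[, c("s1", "s3")]))
})

test_that("TSV round trip preserves an expression table", {
  m <- make_expr(matrix(c(1.5, 2, 0, 7.25, 3, 9), nrow = 3),
                 unit = "EPM")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(m, path)
  back <- read_expression_table(path, unit = "EPM")
  expect_equal(unclass(back), unclass(m))
})

test_that("reader errors carry row/column context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\ttwo", "g2\t3\t4"), path)
  expect_error(read_expression_table(path, unit = "counts"), "s2")
  writeLines(c("gene_id\ts1", "g1\t1", "g1\t2"), path)
  expect_error(read_expression_table(path, unit = "counts"), "duplicated")
  ann_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcell_line\tplatform\tphase\treplicate",
               "s1\ta\tTARGETED\tnone\t1"), ann_path)
  ann <- read_annotation(ann_path)
  m <- make_expr(matrix(1:4, nrow = 2), unit = "counts",
                 samples = c("s1", "s2"))
  expect_error(sample_annotation(ann, sample_ids = colnames(m)), "s2")
})
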