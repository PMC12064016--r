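Package: crossconcord
Title: Cross-Platform Baseline Gene Expression Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for assessing the concordance of baseline gene
    expression between a targeted sequencing platform (probe-based counts,
    TempO-seq-like) and a whole-transcriptome reference platform
    (RNA-seq-like). Provides probe-to-gene collapse, expression-per-million
    normalization, log2 transformation, replicate averaging and
    cross-platform gene-universe harmonization; replicate quality control by
    Pearson correlation; PCA with per-component sequential ANOVA, PERMANOVA
    on Euclidean distance matrices with permutation p-values, multivariate
    dispersion tests and principal coordinates analysis; an iterative
    percentile-cutoff procedure that identifies non-concordant genes until
    the platform factor explains less than a target share of multivariate
    variance; ratio-based relative log expression (RLE) normalization that
    removes systematic platform divergence; and odds-ratio gene-set
    enrichment of non-concordant versus concordant genes with Fisher exact
    p-values and false discovery rate control. Includes a synthetic
    dual-platform count generator with planted platform biases and ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    readxl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
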