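#!/usr/bin/env Rscript
## Odds-ratio gene-set enrichment of non-concordant vs concordant genes.
##
## Builds a synthetic gene-set collection around the classification from
## 03_platform_concordance.R: one signature drawn entirely from the
## planted biased genes (the analogue of a histone/ribosome family), one
## signature of concordant genes, several random background signatures,
## and one deliberately too small to pass the inclusion filter. Each
## signature's 2x2 odds ratio within the expressed universe is tested with
## a two-sided Fisher exact test and BH-FDR corrected.

suppressPackageStartupMessages(library(crossconcord))

out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(20240504L)

cls <- utils::read.delim("results/tvr/classification.tsv")
universe <- cls$gene_id[cls$passes_gate]
nonconc <- cls$gene_id[grepl("^nonconcordant", cls$category)]
conc <- setdiff(universe, nonconc)

sets <- c(
  list(PLANTED_FAMILY = sample(nonconc, 30),
       CONCORDANT_STRUCTURE = sample(conc, 40),
       TOO_SMALL = sample(universe, 5)),
  stats::setNames(lapply(1:20, function(i)
    sample(cls$gene_id, sample(15:80, 1))),
    sprintf("RANDOM_%02d", 1:20)))
write_gmt(sets, file.path(out, "signatures.gmt"))
sets <- read_gmt(file.path(out, "signatures.gmt"))

tab <- enrich_genesets(sets, nonconc, conc)
utils::write.table(tab, file.path(out, "enrichment_full.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
sig <- tab[!is.na(tab$fdr) & tab$fdr < 0.05, ]
utils::write.table(sig, file.path(out, "enrichment_significant.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(paste0(
  "Universe: %d expressed genes (%d non-concordant, %d concordant); %d of ",
  "%d signatures pass the inclusion filter (>= 10 genes and >= 50%% in ",
  "universe); %d reach FDR < 0.05.\n"),
  length(universe), length(nonconc), length(conc),
  sum(tab$included), nrow(tab), nrow(sig)))
pl <- tab[tab$signature == "PLANTED_FAMILY", ]
cat(sprintf(
  "PLANTED_FAMILY: a=%d b=%d c=%d d=%d, OR = %s (FDR = %.2g) — enriched for non-concordance, as planted.\n",
  pl$a, pl$b, pl$c, pl$d, format(pl$or, digits = 3), pl$fdr))
cs <- tab[tab$signature == "CONCORDANT_STRUCTURE", ]
cat(sprintf(
  "CONCORDANT_STRUCTURE: OR = %.2f (Haldane OR = %.3f, FDR = %.2g) — depleted.\n",
  cs$or, cs$or_haldane, cs$fdr))
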