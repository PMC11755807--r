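#!/usr/bin/env Rscript
## Differential expression with the NB Wald test for the two contrasts the
## analysis is built around: MDS vs CTR (FDR < 0.05) and LR-MDS vs HR-MDS
## (FDR < 0.001), for TEs, piRNAs and protein-coding genes. Size factors
## are anchored on each library's stable majority (PCGs for the RNA-seq
## library, miRNAs for the small-RNA library).

suppressMessages(library(piRatio))

counts <- list(te = read_count_tsv("results/cohort/te_counts.tsv"),
               pirna = read_count_tsv("results/cohort/pirna_counts.tsv"),
               pcg = read_count_tsv("results/cohort/pcg_counts.tsv"))
anchors <- list(te = read_count_tsv("results/cohort/pcg_counts.tsv"),
                pirna = read_count_tsv("results/cohort/mirna_counts.tsv"),
                pcg = NULL)
clin <- read.table("results/cohort/clinical.tsv", header = TRUE, sep = "\t")
is_mds <- clin$group != "CTR"
dir.create("results/dea", showWarnings = FALSE, recursive = TRUE)

contrasts <- list(
  mds_ctr = list(sel = rep(TRUE, nrow(clin)),
                 g = factor(ifelse(is_mds, "MDS", "CTR"), c("CTR", "MDS")),
                 fdr = 0.05),
  lr_hr = list(sel = is_mds,
               g = factor(ifelse(is_mds, clin$group, NA), c("LR", "HR")),
               fdr = 0.001))

for (cn in names(contrasts)) {
  ct <- contrasts[[cn]]
  for (kind in names(counts)) {
    cm <- counts[[kind]][, ct$sel, drop = FALSE]
    cm <- cm[rowSums(cm) > 0, , drop = FALSE]
    sf <- if (is.null(anchors[[kind]])) size_factors(cm)
    else size_factors(rbind(anchors[[kind]][, ct$sel], cm))
    dea <- nb_wald_test(cm, ct$g[ct$sel], factors = sf)
    sig <- call_significant(dea, ct$fdr)
    write.table(dea, sprintf("results/dea/dea_%s_%s.tsv", kind, cn),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("%-5s %-7s: %3d/%4d significant at FDR < %g (%d up, %d down)\n",
                kind, cn, nrow(sig), nrow(dea), ct$fdr,
                sum(sig$direction == "up"), sum(sig$direction == "down")))
  }
}
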