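#!/usr/bin/env Rscript
## Gene-set enrichment on the TE:piRNA-ratio contrast: protein-coding genes
## are ranked by the signed Wald z of low- vs high-ratio differential
## expression, GSEA (gene-label permutation) runs against the simulated
## piRNA-program set plus random sets, and each network module's PCG list
## is tested by hypergeometric over-representation.

suppressMessages(library(piRatio))

pcg <- read_count_tsv("results/cohort/pcg_counts.tsv")
tot <- read.table("results/aggstats/sample_totals.tsv", header = TRUE,
                  sep = "\t")
dir.create("results/enrich", showWarnings = FALSE, recursive = TRUE)

strat <- factor(tot$ratio_stratum, c("low", "high"))
pcg <- pcg[rowSums(pcg) > 0, tot$sample]
dea <- nb_wald_test(pcg, strat)
z <- qnorm(pmax(dea$p / 2, 1e-300), lower.tail = FALSE) * sign(dea$log2FC)
scores <- setNames(z, dea$feature)

## the simulated piRNA-program genes sit right after PIWIL2/PIWIL4 in the
## identifier order; random sets calibrate the background
set.seed(1)
sets <- c(list(PIRNA_PROGRAM = sprintf("PCG_%05d", 3:52)),
          setNames(lapply(1:20, function(i) sample(dea$feature, 25)),
                   sprintf("RANDOM_SET_%02d", 1:20)))

gsea <- gsea_significance(scores, sets, n_perm = 1000, seed = 1)
write.table(gsea, "results/enrich/gsea_ratio_contrast.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("GSEA: %d/%d sets at FDR < 0.2\n",
            sum(gsea$fdr < 0.2, na.rm = TRUE), nrow(gsea)))
print(head(gsea[, c("set", "size", "es", "nes", "pval", "fdr")], 3))

members <- list.files("results/network", pattern = "_members\\.tsv$",
                      full.names = TRUE)
for (mf in members) {
  mem <- read.table(mf, header = TRUE, sep = "\t")
  mg <- intersect(mem$name, dea$feature)
  if (length(mg) < 2) next
  ora <- ora_hypergeom(mg, dea$feature, sets)
  out <- sub("_members\\.tsv$", "_ora.tsv", mf)
  write.table(ora, sub("network", "enrich", out), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("ORA %s: top set %s (p = %.3g, overlap %d)\n",
              basename(mf), ora$set[1], ora$pval[1], ora$overlap[1]))
}
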