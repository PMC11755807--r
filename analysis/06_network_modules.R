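#!/usr/bin/env Rscript
## Seed-centered correlation modules over the combined PCG + TE + piRNA
## panel: complete Pearson graph on log2(x+1) normalized values of the most
## variable molecules of each kind (PIWIL2 always included), top-k
## neighbor/neighbor-of-neighbor membership, Q3 edge filtering, and
## GraphML/SIF export for Cytoscape-style viewers.

suppressMessages(library(piRatio))

te <- read_count_tsv("results/cohort/te_counts.tsv")
pirna <- read_count_tsv("results/cohort/pirna_counts.tsv")
pcg <- read_count_tsv("results/cohort/pcg_counts.tsv")
mirna <- read_count_tsv("results/cohort/mirna_counts.tsv")

top_var <- function(nm, n) {
  v <- apply(log2(nm + 1), 1, var)
  nm[order(-v)[seq_len(min(n, nrow(nm)))], , drop = FALSE]
}
pcg_n <- library_normalize(pcg)
panel <- rbind(top_var(pcg_n, 40),
               top_var(library_normalize(te, pcg), 40),
               top_var(library_normalize(pirna, mirna), 40))
if (!"PIWIL2" %in% rownames(panel)) panel <- rbind(PIWIL2 = pcg_n["PIWIL2", ],
                                                   panel)
kind <- setNames(ifelse(grepl("^TE", rownames(panel)), "TE",
                 ifelse(grepl("^piR", rownames(panel)), "piRNA", "PCG")),
                 rownames(panel))

graph <- build_correlation_graph(panel, kind)
print(graph)

## seeds: PIWIL2 plus the strongest LR-vs-HR TE and piRNA
pick_top <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  d$feature[which.min(d$FDR)]
}
seeds <- unique(c("PIWIL2", pick_top("results/dea/dea_te_lr_hr.tsv"),
                  pick_top("results/dea/dea_pirna_lr_hr.tsv")))
seeds <- intersect(seeds, rownames(graph$cor))

for (sd in seeds) {
  mod <- filter_module_edges(extract_module(graph, sd, k = 10), graph)
  print(mod)
  export_module(mod, graph, "results/network")
  mem_kind <- table(kind[mod$members])
  cat(sprintf("  composition: %s\n",
              paste(names(mem_kind), mem_kind, sep = "=", collapse = ", ")))
}
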