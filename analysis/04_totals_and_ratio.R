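#!/usr/bin/env Rscript
## Total TE and piRNA levels, TE class composition, the TE:piRNA ratio, the
## Pearson correlation between the totals, Welch group comparisons, and the
## control-extremum cutoff stratifications (minimum TE, maximum piRNA,
## minimum ratio observed in controls).

suppressMessages(library(piRatio))

te <- read_count_tsv("results/cohort/te_counts.tsv")
pirna <- read_count_tsv("results/cohort/pirna_counts.tsv")
pcg <- read_count_tsv("results/cohort/pcg_counts.tsv")
mirna <- read_count_tsv("results/cohort/mirna_counts.tsv")
ann <- read.table("results/cohort/feature_annotation.tsv", header = TRUE,
                  sep = "\t")
clin <- read.table("results/cohort/clinical.tsv", header = TRUE, sep = "\t")
dir.create("results/aggstats", showWarnings = FALSE, recursive = TRUE)

te_norm <- library_normalize(te, pcg)
pirna_norm <- library_normalize(pirna, mirna)
tot <- sample_totals(te_norm, pirna_norm, setNames(clin$group, clin$sample))

comp <- te_composition(te_norm, setNames(ann$class[ann$kind == "TE"],
                                         ann$id[ann$kind == "TE"]))
cat("TE class composition (cohort mean):\n")
print(round(comp$cohort_mean, 3))

pc <- pearson_cor(tot$total_te, tot$total_pirna)
cat(sprintf("total TE vs total piRNA: Pearson r = %.3f, p = %.3g\n",
            pc$r, pc$p))

hr <- tot$group == "HR"; lr <- tot$group == "LR"
for (v in c("total_te", "total_pirna", "ratio"))
  cat(sprintf("Welch t, HR vs LR, %s: p = %.3g\n", v,
              welch_t(tot[[v]][hr], tot[[v]][lr])$p))
cat(sprintf("Welch ANOVA across CTR/LR/HR, ratio: p = %.3g\n",
            welch_anova(tot$ratio, tot$group)$p))

is_ctrl <- tot$group == "CTR"
rules <- list(te = control_cutoff(tot$total_te, is_ctrl, "control-minimum",
                                  "total_te"),
              pirna = control_cutoff(tot$total_pirna, is_ctrl,
                                     "control-maximum", "total_pirna"),
              ratio = control_cutoff(tot$ratio, is_ctrl, "control-minimum",
                                     "ratio"))
tot$te_stratum <- apply_cutoff(rules$te, tot$total_te)
tot$pirna_stratum <- apply_cutoff(rules$pirna, tot$total_pirna)
tot$ratio_stratum <- apply_cutoff(rules$ratio, tot$ratio)
for (rn in names(rules)) print(rules[[rn]])
cat("low-ratio group by risk:\n")
print(table(tot$ratio_stratum, tot$group)["low", c("LR", "HR")])

write.table(tot, "results/aggstats/sample_totals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(class = names(comp$cohort_mean),
                       mean_fraction = comp$cohort_mean),
            "results/aggstats/te_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
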