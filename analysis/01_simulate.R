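#!/usr/bin/env Rscript
## Simulate the default synthetic MDS cohort (17 CTR / 45 LR-MDS / 35 HR-MDS;
## 687 TEs, 300 piRNAs, 1000 PCGs, 300 background miRNAs) and write its
## tables under results/cohort/. Everything downstream reads from there.

suppressMessages(library(piRatio))

cfg <- cohort_config(seed = 1)
print(cfg)
cohort <- generate_cohort(cfg)
paths <- write_cohort(cohort, "results/cohort")

cat(sprintf("wrote %d files under results/cohort\n", length(paths)))
cat(sprintf("MDS patients: %d, controls: %d\n",
            sum(cohort$clinical$group != "CTR"),
            sum(cohort$clinical$group == "CTR")))
cat(sprintf("OS events among MDS patients: %d/%d\n",
            sum(cohort$survival$event[cohort$survival$endpoint == "OS"]),
            sum(cohort$survival$endpoint == "OS")))
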