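#!/usr/bin/env Rscript
## Survival analyses for both endpoints: Kaplan-Meier curves and log-rank
## tests for each control-cutoff stratification (with the univariate Cox
## hazard ratio for the risk side), then a multivariate Cox model over
## age, sex, the IPSS-R ordinal clinical covariates and the low-ratio
## indicator, reduced by stepwise selection.

suppressMessages(library(piRatio))

tot <- read.table("results/aggstats/sample_totals.tsv", header = TRUE,
                  sep = "\t")
surv <- read.table("results/cohort/survival.tsv", header = TRUE, sep = "\t")
clin <- read.table("results/cohort/clinical.tsv", header = TRUE, sep = "\t")
dir.create("results/survival", showWarnings = FALSE, recursive = TRUE)

risk_side <- c(te_stratum = "low", pirna_stratum = "high",
               ratio_stratum = "low")

for (ep in c("OS", "PFS")) {
  cat(sprintf("== %s ==\n", ep))
  sv <- merge(surv[surv$endpoint == ep, ], tot, by = "sample")
  sv <- sv[sv$group != "CTR", ]
  for (st in names(risk_side)) {
    lab <- factor(sv[[st]], c("low", "high"))
    if (nlevels(droplevels(lab)) < 2) next
    lt <- logrank_test(sv$time, sv$event, lab)
    uni <- cox_fit(sv$time, sv$event,
                   matrix(as.integer(lab == risk_side[[st]]),
                          dimnames = list(NULL, risk_side[[st]])))
    med <- tapply(seq_len(nrow(sv)), lab, function(ix)
      km_curve(sv$time[ix], sv$event[ix])$median)
    cat(sprintf("  %-14s log-rank p = %.4g; HR(%s) = %.2f [%.2f, %.2f]; median %s: low %.1f / high %.1f months\n",
                st, lt$p, risk_side[[st]], uni$table$HR, uni$table$ci_low,
                uni$table$ci_high, ep,
                ifelse(is.na(med["low"]), Inf, med["low"]),
                ifelse(is.na(med["high"]), Inf, med["high"])))
  }
  cl <- clin[match(sv$sample, clin$sample), ]
  X <- cbind(age = cl$age, female = cl$sex, ipssr_ordinalize(cl),
             ratio_low = as.integer(sv$ratio_stratum == "low"))
  sw <- stepwise_cox(sv$time, sv$event, X)
  cat("  stepwise multivariate model:\n")
  if (is.null(sw$model)) {
    cat("    <empty>\n")
  } else {
    print(sw$model)
    write.table(sw$model$table, sprintf("results/survival/mva_%s.tsv", ep),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
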