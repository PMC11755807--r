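# piRatio

Joint transposable-element (TE) and piRNA expression analysis for
myelodysplastic neoplasm (MDS) cohorts.

In CD34+ bone-marrow cells, TEs are silenced by PIWI-protein/piRNA
complexes. Higher-risk MDS shows suppressed total TE expression together
with elevated total piRNA levels, and the imbalance carries prognostic
information. piRatio implements the complete analysis chain for studying
that axis in a cohort of controls (CTR), lower-risk (LR-MDS) and
higher-risk (HR-MDS) patients:

* **piRNA quantification** from small-RNA reads: leftmost-adapter trimming
  with UMI extraction, a 24–34 nt insert filter, exact full-length matching
  to a piRNA reference (one substitution or one missing base disqualifies a
  read), and directional UMI deduplication.
* **Differential expression**: median-of-ratios size factors and a
  self-contained negative-binomial Wald test with a binned mean-dispersion
  trend and Benjamini–Hochberg FDR.
* **The TE:piRNA ratio**: per-sample totals of normalized TE and piRNA
  levels, their Pearson correlation, Welch group tests, and dichotomization
  at control-derived cutoffs — minimum TE, maximum piRNA, minimum ratio
  observed in controls. Low ratio = TE suppression with piRNA elevation.
* **Survival**: Kaplan–Meier / log-rank per stratification, and
  multivariate Cox proportional hazards (Breslow partial likelihood,
  Newton–Raphson) over age, sex, IPSS-R ordinal clinical covariates and the
  ratio stratum, reduced by stepwise selection.
* **Correlation-network modules**: seed-centered subgraphs of the complete
  Pearson graph over a mixed PCG/TE/piRNA panel (top-k neighbors and their
  neighbors), edge-filtered at the third quartile of all module-pair
  correlations, exported as GraphML/SIF.
* **Enrichment**: preranked GSEA (running-sum statistic, gene-label
  permutation, sign-stratified NES/FDR) and hypergeometric
  over-representation for module gene lists.

A synthetic cohort generator (`generate_cohort()`) with recorded ground
truth — negative-binomial counts with an HR-MDS TE suppression / piRNA
elevation confined to a responsive feature subset, a latent negative
TE–piRNA coupling, PIWIL2 tracking the piRNA signal, miRNA background for
small-RNA normalization, clinical covariates and exponential survival —
makes every stage testable without patient data. The methods vignette
(`vignettes/te-pirna-workflow.Rmd`) documents the model and every design
choice.

## Worked example

The `analysis/` directory is the workflow: numbered scripts that read and
write under `results/`.

```sh
Rscript analysis/01_simulate.R                # cohort tables
Rscript analysis/02_quantify.R                # read-level verification
Rscript analysis/03_differential_expression.R
Rscript analysis/04_totals_and_ratio.R
Rscript analysis/05_survival.R
Rscript analysis/06_network_modules.R
Rscript analysis/07_enrichment.R
```

`04_totals_and_ratio.R` prints, for the default cohort (seed 1):

```
TE class composition (cohort mean):
  ERV    L1  SINE
0.057 0.149 0.794
total TE vs total piRNA: Pearson r = -0.737, p = 7.25e-18
Welch t, HR vs LR, total_te: p = 9.76e-21
Welch t, HR vs LR, total_pirna: p = 5.05e-16
Welch t, HR vs LR, ratio: p = 2.95e-30
cutoff rule: ratio, control-minimum = 3.14546 (high side is control-like)
low-ratio group by risk:
LR HR
 0 34
```

SINEs carry ~79% of TE expression; total TE and total piRNA levels are
negatively correlated; HR-MDS samples are shifted on both totals; and the
patients falling below the control ratio minimum are almost exclusively
HR-MDS. `05_survival.R` then shows that this low-ratio group has worse
overall survival and that the stratum survives multivariate adjustment:

```
== OS ==
  ratio_stratum  log-rank p = 0.0001019; HR(low) = 3.37 [1.77, 6.41];
                 median OS: low 9.8 / high Inf months
  stepwise multivariate model:
  variable             HR    CI.lo    CI.hi          p
  ratio_low         3.426    1.779    6.598    0.00023
  hemoglobin_ord    1.925    1.229    3.014     0.0042
  age               1.071    1.018    1.126     0.0077
```

`06_network_modules.R` and `07_enrichment.R` close the loop: the PIWIL2
seed module is dominated by piRNAs and TEs plus the simulated
piRNA-program genes, and that program is the only gene set flagged by GSEA
on the ratio contrast (NES = −3.3, FDR = 0) and by module ORA
(p = 1.5e-06).

All of this is synthetic data whose generative truth is known — the point
is that every number above is produced by the same functions a real cohort
would be run through, and is verified against that truth by the test
suite.

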