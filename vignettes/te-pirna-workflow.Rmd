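---
title: "Joint TE and piRNA expression analysis for MDS cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint TE and piRNA expression analysis for MDS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piRatio)
```

# The analysis

Transposable elements (TEs) are repressed in the germ line and in stem-cell
compartments by PIWI-clade Argonaute proteins loaded with PIWI-interacting
RNAs (piRNAs, here 24–34 nt). In myelodysplastic neoplasms (MDS), loss of TE
expression together with elevated piRNA levels in CD34+ cells marks
higher-risk disease. piRatio packages the full chain of analyses needed to
study that axis in a cohort of controls (CTR), lower-risk (LR-MDS) and
higher-risk (HR-MDS) patients:

1. **piRNA quantification** from small-RNA reads under strict rules: exact
   full-length matching to a piRNA reference after a 24–34 nt insert filter,
   with directional UMI deduplication.
2. **Normalization and differential expression** — median-of-ratios size
   factors and a self-contained negative-binomial Wald test.
3. **Aggregate statistics** — per-sample total TE and piRNA levels, their
   ratio, Pearson correlation, Welch group tests, and dichotomization at
   control-derived cutoffs.
4. **Survival** — Kaplan–Meier curves, log-rank tests, Cox
   proportional-hazards regression with IPSS-R ordinal covariate coding and
   stepwise variable selection.
5. **Correlation-network modules** — seed-centered subgraphs of the complete
   Pearson graph over a mixed PCG/TE/piRNA panel, edge-filtered at the third
   quartile of module correlations.
6. **Enrichment** — preranked GSEA (running-sum statistic, gene-label
   permutation) and hypergeometric over-representation for module gene
   lists.

Because patient-level sequencing data cannot ship with a package, every
stage is exercised against a **synthetic cohort generator** whose ground
truth is recorded, so each claim the workflow makes is testable
end-to-end. The `analysis/` scripts run the whole chain over the default
synthetic cohort and write their tables under `results/`.

# The synthetic cohort model

`generate_cohort()` draws, for `n_ctr + n_lr + n_hr` samples
(default 17/45/35, the cohort shape the workflow targets):

* **Counts.** Feature $f$ in sample $i$ is negative binomial with mean
  $\mu_{fi} = b_f \, d_i \, 2^{\,r_f (\delta_{g(i)} + a_i)}$ and variance
  $\mu + \alpha\mu^2$ (default dispersion $\alpha = 0.2$; $\alpha = 0$
  gives Poisson). Here $b_f$ is a lognormal baseline, $d_i$ a per-library
  sequencing-depth factor (log2 SD 0.15, drawn separately for the RNA-seq
  and small-RNA libraries), $\delta_g$ the HR-MDS group shift, and $a_i$
  the per-sample latent factor.
* **Responsive subsets.** The indicator $r_f$ restricts the group shift and
  the latent factor to a minority of features (`responsive_frac = 0.4`).
  This is both biologically and statistically essential: in real cohorts
  only a minority of TEs is dysregulated while the aggregate level shifts,
  and median-of-ratios normalization anchors on the stable majority. A
  shift shared by *all* features of a matrix would be absorbed into the
  size factors and disappear — we verified exactly that failure mode with a
  fully-shared-shift generator before settling on this design. The
  per-feature shift is `te_hr_logfc / responsive_frac` so the mean shift
  across all features equals the configured value.
* **Latent coupling.** The TE factor $a_i$ and the piRNA factor $b_i$ are
  bivariate normal (SD 0.35 log2) with correlation `latent_rho = -0.4`,
  the generative counterpart of the observed negative correlation between
  total TE and total piRNA levels. The coupling acts on totals, not on
  individual feature pairs.
* **PIWIL2.** Its log2 mean follows the piRNA signal
  ($\delta + b_i$) with coefficient `piwil2_coupling = 2`, chosen so that
  the HR-vs-LR fold change is $2^{2 \times 0.5} = 2$ — a twofold increase —
  and the correlation with total piRNA lands near the strength reported for
  CD34+ cells. `n_pcg_coupled = 50` further protein-coding genes follow the
  same signal with unit coefficient; they are the "piRNA program" that the
  network and enrichment stages can recover. PIWIL4 is independent noise.
* **miRNA background.** The small-RNA library additionally carries
  `n_mirna = 300` unshifted miRNA features. Real small-RNA libraries are
  miRNA-dominated; normalizing the piRNA matrix against this background
  (`library_normalize()`) is what lets a genuine global piRNA elevation
  survive size-factor normalization. The TE matrix is normalized against
  the protein-coding genes of the same RNA-seq library for the same reason.
* **Clinical covariates** are simple parametric draws with group-dependent
  parameters (anemia, thrombocytopenia and neutropenia in MDS; marrow
  blasts > 5% enriched in HR-MDS; an ordered 0–4 cytogenetic code skewed
  toward higher risk in HR).
* **Survival.** Event times are exponential with
  $\log h_i = \log h_0 + \beta_{HR}\,\mathbb 1[\text{HR}] +
  0.05\,(\text{age}_i - 70) + 0.5\,\text{plt}^{ord}_i +
  0.4\,(b_i - a_i)/\sigma$, censored uniformly on
  $(0, \text{censor\_time\_max}]$ (default 72 months);
  $h_0 = 0.015$/month and $\beta_{HR} = \log 2.5$. The latent term ties
  poor outcome to the piRNA-high / TE-low state, so the TE:piRNA-ratio
  stratification carries real prognostic signal. Constant baseline hazard
  keeps parameter-recovery tests analytic; PFS uses a 1.5× hazard.
* **Reads.** `generate_reads()` emits a stranded library with layout
  insert + 3′ adapter + UMI, padded to 83 nt: one random 12-nt UMI per true
  molecule, `1 + Poisson(dup_rate)` reads per molecule reusing that UMI,
  and uniform per-base substitutions in the insert at `error_rate`. The
  default adapter `AACTGTAGGCACCATCAAT` reflects common miRNA library kits;
  both adapter and UMI length are configurable because kits differ.

Per-group variance parameters are not something a published cohort
reports directly; the defaults above were chosen once for realistic effect
sizes and test power and are not revisited.

What the generator does *not* emulate: piRNA-database sequence redundancy
at scale (the quantifier handles it, the generator emits unique
sequences), quality-score structure in reads, batch effects, non-exponential
hazards, and any real gene-gene covariance beyond the single latent
program. Passing tests therefore demonstrate correctness of the
*computations* under the stated model, not robustness to every artifact of
real libraries.

# Quantification rules

A read is counted only when, after locating the leftmost exact adapter
occurrence and taking the bases before it as the insert, (i) the insert is
24–34 nt inclusive, and (ii) it equals a reference sequence
character-for-character and length-for-length (U normalized to T). One
substitution, one missing base, or any N means the read is discarded; no
reverse-complement matching is attempted because the protocol is stranded.
Counts are keyed by unique sequence: piRNA databases carry many identifiers
for one sequence, and per-identifier counting would multiply one molecule
across entries. All identifiers sharing a sequence are reported, the
lexicographically smallest as representative.

Deduplication uses the directional network rule: within one sequence
group, a directed edge runs $u \to v$ when the UMIs differ at exactly one
position and $c(u) \ge 2c(v) - 1$; UMIs are visited in order of decreasing
count (ties lexicographic) and everything reachable is absorbed; the
molecule count is the number of visits. Traversal may pass through
already-claimed UMIs, matching the reference tool's cluster semantics; an
exhaustive-enumeration oracle in the test suite pins this down for groups
of up to six UMIs. An exact-duplicate mode (`method = "unique"`) is
available.

# Normalization and the NB test

Size factors follow the median-of-ratios definition: the pseudo-reference
is each feature's geometric mean across samples, and a sample's factor is
the median ratio over features with no zero anywhere. `library_normalize()`
computes the factors on the stacked anchor + target matrix — protein-coding
genes anchor the TE matrix, the miRNA background anchors the piRNA matrix —
then divides the target. Totals and ratios are computed on these normalized
values.

The two-group test is a deliberately self-contained negative-binomial Wald
test, not a re-implementation of any published tool's full machinery (no
shrinkage estimators, independent filtering, or outlier replacement):

* group means $m_1, m_2$ on the normalized scale;
* dispersion by method of moments pooled across the two groups, then
  **stabilized across features**: features are binned by abundance
  (≈25 per bin, at most 20 bins), the within-bin mean forms a
  mean-dispersion trend, and each feature uses the trend unless its own
  estimate exceeds twice the trend (hyper-variable features keep their
  larger, more conservative value). Floor $10^{-8}$.
* $\log_2\!\text{FC} = \log_2\frac{m_2 + 0.5}{m_1 + 0.5}$ (pseudocount 0.5
  for stability at low counts);
* Wald statistic = natural-log fold change over its delta-method SE
  $\sqrt{\sum_g (1/(n_g(m_g + 0.5)) + \alpha/n_g)}$, referred to Student
  $t_{n_1+n_2-2}$; Benjamini–Hochberg FDR.

The last two choices came out of a null-calibration study (NB counts,
10–30 samples per group) rather than first principles. Purely per-feature
dispersions made BH-level error control fail badly (empirical FDR ≈ 0.10
at a 0.05 cutoff), and even with the *true* dispersion plugged in, the
normal reference was ≈1.4× too light in the far tail that BH thresholds
probe. The trend-with-outlier-guard estimator plus the $t$ reference gives
a null rejection fraction of 0.03–0.05 at $p<0.05$, full sensitivity for
1.5-log2 planted effects at $n = 30$ per group, and empirical FDR ≈ 0.05.
Those operating characteristics are what the acceptance tests assert.

Significance calls use strict FDR < cutoff and partition by log2FC sign;
the workflow's two standard contrasts are MDS vs CTR at FDR < 0.05 and
LR vs HR at FDR < 0.001.

# Cutoffs, ratio and stratification

Totals dichotomize at control extrema: the minimum total TE, the maximum
total piRNA, and — for the TE:piRNA ratio, total TE over total piRNA — the
control minimum. Values exactly at a cutoff fall on the control-like side;
the sources describing this scheme do not state the boundary convention,
so we fixed one and test it. Stratification is invariant under strictly
monotone transforms of the statistic, which the suite checks. The ratio is
undefined (NA) when the piRNA total is zero.

# Survival methodology

`km_curve()` is the product-limit estimator with the median read off as the
smallest time with $S(t) \le 0.5$; `logrank_test()` sums observed-minus-
expected with the hypergeometric variance over event times. `cox_fit()`
maximizes the Breslow partial likelihood by Newton–Raphson with step
halving (tolerance $10^{-8}$ on the coefficient change, 50 iterations,
divergence beyond $|\beta| > 20$ reported as monotone likelihood); SEs come
from the inverse observed information and CIs are
$\exp(\hat\beta \pm 1.96\,\text{SE})$. Breslow tie handling keeps the
classical score-test identity with the log-rank statistic on tie-free
data, which the suite asserts to $10^{-6}$; the estimates are additionally
cross-checked against an independent reference implementation and a dense
grid search of the partial likelihood.

Clinical covariates enter multivariate models as IPSS-R ordinal codes:
hemoglobin (g/dL) <8 → 2, 8–<10 → 1, ≥10 → 0; platelets (×10⁹/L) <50 → 2,
50–<100 → 1, ≥100 → 0; neutrophils (×10⁹/L) <0.8 → 1, ≥0.8 → 0; blasts (%)
≤2 → 0, >2–<5 → 1, 5–10 → 2, >10 → 3; cytogenetic category as its 0–4
code. Age enters in years; sex as a female indicator.

`stepwise_cox()` is forward selection with backward checks at the
conventional thresholds `p_enter = 0.05`, `p_remove = 0.10` (both
configurable), deterministic tie-break by candidate order, singular or
non-convergent candidates skipped, and an empty final model allowed. Two
calibration facts shaped the tests: with $k$ pure-noise candidates
screened at 0.05 the empty-model probability is ≈ $0.95^k$, so the
80%-empty check uses two candidates (ten would cap it at 60% by
arithmetic, not by any defect of the selector); and the hazard ratios
attached to Kaplan–Meier stratifications are univariate Cox fits on the
risk-side indicator (low TE, high piRNA, low ratio respectively).

# Network modules

The panel stacks log2(x+1) normalized values of the most variable
molecules per kind (PIWIL2 always included); `build_correlation_graph()`
computes the complete Pearson graph (Spearman by option), dropping
zero-variance molecules with a warning. "Most strongly correlated
neighbors" is quantified as top-$k$ by $|r|$ with default $k = 10$ and ties
broken by ascending identifier, making extraction deterministic and
row-order invariant; members are the seed, its top-$k$ neighbors, and each
neighbor's top-$k$ neighbors. The edge filter computes the third quartile
(type-7, linear interpolation — conventions differ, so this is pinned) of
$|r|$ over **all** member pairs — the complete graph on module nodes, not
just recruiting edges — and keeps pairs with $|r|$ strictly above it.
Signed-$r$ thresholding is available for sensitivity checks. Exports are
GraphML (node attributes `kind`, `is_seed`; edge attribute `r`), SIF and a
members table.

# Enrichment

`gsea_es()` is the weighted Kolmogorov–Smirnov running sum: hits add
$|s|^p$ normalized over the set's hits (default $p = 1$; $p = 0$ is the
unweighted walk), misses subtract $1/(N - N_{hit})$, and the score is the
signed extremum, with the positive extremum winning exact ties.
Significance uses **gene-label permutation** (random same-size sets), not
phenotype permutation: re-fitting the differential expression inside the
permutation loop is out of desk scale, and the divergence is stated here
deliberately. NES divides by the mean same-sign null ES; the permutation p
is the add-one same-sign tail; FDR follows the sign-stratified
NES-comparison convention. The default ranking metric is the signed Wald z
of the differential-expression contrast. `ora_hypergeom()` is the
upper-tail hypergeometric test against a configurable universe (default:
all tested protein-coding genes) with BH correction.

# Problem sizes and degenerate inputs

The shipped analysis and test problem sizes — the 97-sample default cohort,
three re-quantified libraries at ≈20k reads each, 500–1000-feature test
matrices, 8-node oracle panels, 100–1000 permutations — were chosen so the
whole suite and the acceptance script run in minutes on a single core
while leaving every statistical check well-powered; all sizes are
parameters, and nothing in the code assumes them.

Degenerate inputs have defined behavior throughout: empty FASTQ gives zero
tallies, malformed FASTQ reports the failing record index, all-censored
strata give an undefined median, all-zero features are dropped and counted
before testing, zero-variance panel molecules are dropped with a warning,
an all-equal module correlation yields an empty edge set, and a cohort
configuration error names the offending field.

# Known limitations

* The NB test's calibration was tuned for 10–60 samples per group; very
  small designs (n = 2–3) will be conservative.
* Directional UMI deduplication occasionally merges distinct molecules
  whose random UMIs land within Hamming distance 1 with compatible counts;
  with 12-nt UMIs this is rare (the read-level verification typically
  reproduces ≥ 99.5% of features exactly under PCR duplication) and it is
  the deliberate behavior of the directional rule, not a defect.
* The Cox implementation handles Breslow ties only; Efron weighting and
  proportionality diagnostics are out of scope, as are time-dependent
  covariates and competing risks.
* Gene-label permutation GSEA understates between-gene correlation
  relative to phenotype permutation; treat module-level FDRs on real data
  accordingly.
* The synthetic cohort is a single-latent-factor world; it cannot stand in
  for the covariance structure of real CD34+ transcriptomes.
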