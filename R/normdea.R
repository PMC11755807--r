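#' Median-of-ratios size factors
#'
#' Per-sample scaling factors in the DESeq style: for each feature the
#' geometric mean across samples is the pseudo-reference; a sample's factor
#' is the median, over features whose geometric mean is positive (no zero
#' count in any sample), of count/geometric-mean.
#'
#' @param counts numeric matrix, features x samples.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable))
    stop("normalization error: no feature with all-positive counts", call. = FALSE)
  apply(counts, 2, function(col)
    exp(stats::median(log(col[usable]) - log_geo[usable])))
}

#' Divide counts by per-sample size factors
#'
#' @param counts numeric matrix, features x samples.
#' @param factors named vector covering every sample column.
#' @return real-valued normalized matrix, same dimnames and order.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  if (is.null(names(factors))) {
    if (length(factors) != ncol(counts))
      stop("size factors do not cover all samples", call. = FALSE)
  } else {
    miss <- setdiff(colnames(counts), names(factors))
    if (length(miss))
      stop("missing size factor for sample: ", miss[1], call. = FALSE)
    factors <- factors[colnames(counts)]
  }
  sweep(counts, 2, factors, "/")
}

#' Normalize a matrix with size factors anchored on its library
#'
#' Computes median-of-ratios size factors on the stacked anchor + target
#' matrix (one factor per sample, driven by the anchor when it dominates)
#' and divides the target counts by them. Used to normalize TE counts
#' against the whole RNA-seq library (protein-coding genes as anchor) and
#' piRNA counts against the whole small-RNA library (miRNA background as
#' anchor), so that genuine aggregate shifts of the target survive
#' normalization.
#'
#' @param target counts to normalize, features x samples.
#' @param anchor optional stable companion matrix over the same samples;
#'   NULL falls back to the target's own size factors.
#' @return normalized real-valued matrix.
#' @export
library_normalize <- function(target, anchor = NULL) {
  sf <- if (is.null(anchor)) size_factors(target)
  else size_factors(rbind(anchor[, colnames(target), drop = FALSE], target))
  normalize_counts(target, sf)
}

#' Negative-binomial Wald differential expression
#'
#' A self-contained two-group NB Wald test on median-of-ratios-normalized
#' counts. Per feature, group means are taken on the normalized scale; the
#' NB dispersion is estimated by method of moments pooled across the two
#' groups, then stabilized by sharing information across features: features
#' are binned by abundance, the within-bin mean dispersion forms a
#' mean-dispersion trend, and each feature uses the trend value unless its
#' own estimate exceeds twice the trend (an outlier guard that keeps
#' genuinely hyper-variable features conservative). The floor is 1e-8.
#' log2FC = log2((mean2 + 0.5)/(mean1 + 0.5)); the Wald statistic is the
#' natural-log fold change over its delta-method standard error from the NB
#' variance, referred to a Student t distribution with n1 + n2 - 2 degrees
#' of freedom (slightly heavier-tailed than the normal, which a null
#' calibration study showed is needed for empirical FDR control at
#' Benjamini-Hochberg cutoffs); FDR by Benjamini-Hochberg. Features with
#' all-zero counts are dropped before testing. This intentionally omits the
#' shrinkage estimators, independent filtering and outlier replacement of
#' full DESeq-class machinery.
#'
#' @param counts integer matrix, features x samples.
#' @param group two-level factor/character vector, one label per sample;
#'   log2FC is level2 over level1 (levels in factor order, or order of first
#'   appearance).
#' @param factors optional precomputed size factors.
#' @param pseudocount stabilizer added to normalized group means for the
#'   fold change.
#' @param dispersion_floor lower bound for the pooled dispersion.
#' @return data.frame (class \code{dea_result}): feature, baseMean1,
#'   baseMean2, log2FC, p, FDR; attribute \code{levels} and
#'   \code{n_dropped}.
#' @export
nb_wald_test <- function(counts, group, factors = NULL, pseudocount = 0.5,
                         dispersion_floor = 1e-8) {
  if (is.factor(group)) lev <- levels(droplevels(group)) else lev <- unique(group)
  if (length(lev) != 2)
    stop("design error: 'group' must have exactly two levels", call. = FALSE)
  g1 <- group == lev[1]; g2 <- group == lev[2]
  if (sum(g1) < 2 || sum(g2) < 2)
    stop("design error: each group needs >= 2 samples", call. = FALSE)
  if (is.null(factors)) factors <- size_factors(counts)
  norm <- normalize_counts(counts, factors)

  nonzero <- rowSums(counts) > 0
  n_dropped <- sum(!nonzero)
  norm <- norm[nonzero, , drop = FALSE]

  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  ## pooled method-of-moments dispersion: var = mu + a*mu^2 within each group
  a1 <- (v1 - m1) / m1^2
  a2 <- (v2 - m2) / m2^2
  a1[!is.finite(a1)] <- 0
  a2[!is.finite(a2)] <- 0
  alpha <- ((n1 - 1) * a1 + (n2 - 1) * a2) / (n1 + n2 - 2)
  ## mean-dispersion trend over abundance bins; per-feature estimate kept
  ## only when it exceeds twice the trend (hyper-variable outliers)
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  n_bins <- min(20, max(1, floor(length(mu) / 25)))
  bins <- if (n_bins >= 2) cut(rank(mu, ties.method = "first"), n_bins)
  else factor(rep(1L, length(mu)))
  trend <- tapply(alpha, bins, mean)[bins]
  alpha <- pmax(ifelse(alpha > 2 * trend, alpha, trend), dispersion_floor)

  lfc_nat <- log((m2 + pseudocount) / (m1 + pseudocount))
  se2 <- (1 / (n1 * (m1 + pseudocount)) + alpha / n1) +
    (1 / (n2 * (m2 + pseudocount)) + alpha / n2)
  z <- lfc_nat / sqrt(se2)
  p <- 2 * stats::pt(-abs(z), df = n1 + n2 - 2)

  res <- data.frame(feature = rownames(norm), baseMean1 = m1, baseMean2 = m2,
                    log2FC = lfc_nat / log(2), p = p,
                    FDR = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "levels") <- lev
  attr(res, "n_dropped") <- n_dropped
  class(res) <- c("dea_result", "data.frame")
  res
}

#' Call significant features at an FDR cutoff
#'
#' Features with FDR strictly below the cutoff, partitioned by the sign of
#' log2FC; significant features with exactly zero log2FC are reported as
#' unclassified.
#'
#' @param dea a [nb_wald_test()] result.
#' @param fdr_cutoff FDR threshold in (0, 1).
#' @return data.frame of significant rows with an added \code{direction}
#'   column (\code{up}/\code{down}/\code{unclassified}).
#' @export
call_significant <- function(dea, fdr_cutoff = 0.05) {
  if (!(fdr_cutoff > 0 && fdr_cutoff < 1))
    stop("fdr_cutoff must lie in (0, 1)", call. = FALSE)
  sig <- dea[!is.na(dea$FDR) & dea$FDR < fdr_cutoff, , drop = FALSE]
  sig$direction <- ifelse(sig$log2FC > 0, "up",
                          ifelse(sig$log2FC < 0, "down", "unclassified"))
  class(sig) <- "data.frame"
  rownames(sig) <- NULL
  sig
}
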