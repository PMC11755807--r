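#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set name, description, genes...).
#' @return named list of unique gene identifier vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

## Running-sum values at hit positions only (mathematically identical to the
## full walk; the extremum of the running sum is attained at a hit or just
## before one).
es_from_hits <- function(score_sorted, hit_idx, p = 1) {
  N <- length(score_sorted)
  k <- length(hit_idx)
  hit_idx <- sort(hit_idx)
  w <- abs(score_sorted[hit_idx])^p
  NR <- sum(w)
  if (NR == 0) w <- rep(1 / k, k) else w <- w / NR
  miss_step <- if (N - k > 0) 1 / (N - k) else 0
  cw <- cumsum(w)
  at_hit <- cw - (hit_idx - seq_len(k)) * miss_step
  before_hit <- c(0, cw[-k]) - (hit_idx - 1 - (seq_len(k) - 1)) * miss_step
  mx <- max(at_hit); mn <- min(c(before_hit, at_hit))
  if (mx + 1e-12 >= -mn) mx else mn   # positive extremum wins (near-)ties
}

#' GSEA enrichment score (weighted running sum)
#'
#' Walks the ranked list: genes in the set increment the running sum by
#' |score|^p normalized over the set's hits, genes outside it decrement by
#' 1/(N - N_hit); the enrichment score is the signed extremum.
#'
#' @param scores named numeric vector of ranking scores (any order; sorted
#'   decreasingly internally). Gene names must be unique.
#' @param gene_set character vector of gene identifiers.
#' @param p hit-weight exponent (1 = classical weighted statistic, 0 =
#'   unweighted Kolmogorov-Smirnov).
#' @return list: \code{es}, \code{running} (full running-sum vector),
#'   \code{hits} (logical over the ranked list), \code{leading_edge}
#'   (genes up to the extremum, for positive ES).
#' @export
gsea_es <- function(scores, gene_set, p = 1) {
  if (anyDuplicated(names(scores)))
    stop("ranked list must have unique gene names", call. = FALSE)
  ord <- order(-scores)
  s <- scores[ord]
  hits <- names(s) %in% gene_set
  if (!any(hits)) stop("gene set does not intersect the ranked list", call. = FALSE)
  N <- length(s); k <- sum(hits)
  w <- abs(s)^p
  w[!hits] <- 0
  NR <- sum(w)
  inc <- if (NR == 0) hits / k else w / NR
  dec <- if (N - k > 0) (!hits) / (N - k) else 0
  running <- cumsum(inc - dec)
  mx <- max(running); mn <- min(running)
  es <- if (mx + 1e-12 >= -mn) mx else mn   # positive extremum wins (near-)ties
  le <- if (es >= 0) names(s)[seq_len(which.max(running))][hits[seq_len(which.max(running))]]
  else names(s)[seq(which.min(running), N)][hits[seq(which.min(running), N)]]
  list(es = es, running = running, hits = hits, leading_edge = le)
}

#' GSEA with gene-label permutation significance
#'
#' For each set, the null distribution of the enrichment score is obtained
#' by drawing random gene sets of the same size from the ranked list
#' (gene-label permutation). NES = ES divided by the mean |null ES| of
#' matching sign; the permutation p is the add-one tail fraction among null
#' scores of matching sign; FDR follows the sign-stratified NES-comparison
#' convention (observed and pooled null NES of the same sign).
#'
#' @param scores named numeric ranking vector.
#' @param sets named list of gene sets.
#' @param n_perm number of permutations (>= 100).
#' @param seed random seed.
#' @param p hit-weight exponent.
#' @param min_size sets with fewer overlapping genes are skipped.
#' @return data.frame (class \code{enrichment_result}): set, size, es, nes,
#'   pval, fdr, leading_edge.
#' @export
gsea_significance <- function(scores, sets, n_perm = 1000, seed = 1, p = 1,
                              min_size = 2) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  set.seed(seed)
  ord <- order(-scores)
  s <- scores[ord]
  N <- length(s)
  keep <- vapply(sets, function(g) sum(names(s) %in% g) >= min_size, logical(1))
  sets <- sets[keep]
  if (!length(sets)) stop("no gene set overlaps the ranked list", call. = FALSE)

  obs <- vapply(sets, function(g) gsea_es(s, g, p)$es, numeric(1))
  sizes <- vapply(sets, function(g) sum(names(s) %in% g), integer(1))
  le <- vapply(sets, function(g)
    paste(gsea_es(s, g, p)$leading_edge, collapse = ","), character(1))

  usz <- sort(unique(sizes))
  null_by_size <- lapply(usz, function(k)
    vapply(seq_len(n_perm), function(i)
      es_from_hits(s, sample.int(N, k), p), numeric(1)))
  names(null_by_size) <- as.character(usz)

  nes <- numeric(length(sets)); pval <- numeric(length(sets))
  null_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    nul <- null_by_size[[as.character(sizes[i])]]
    pos <- nul[nul >= 0]; neg <- nul[nul < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    nes[i] <- if (obs[i] >= 0) obs[i] / mpos else obs[i] / mneg
    same <- if (obs[i] >= 0) pos else neg
    pval[i] <- (1 + sum(abs(same) >= abs(obs[i]))) / (1 + length(same))
    null_nes[[i]] <- c(if (length(pos)) pos / mpos,
                       if (length(neg)) -abs(neg) / mneg)
  }
  all_null_nes <- unlist(null_nes)
  fdr <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num_pool <- all_null_nes[all_null_nes >= 0]
      num <- if (length(num_pool)) mean(num_pool >= nes[i]) else 0
      den_pool <- nes[nes >= 0 & !is.na(nes)]
      den <- mean(den_pool >= nes[i])
    } else {
      num_pool <- all_null_nes[all_null_nes < 0]
      num <- if (length(num_pool)) mean(num_pool <= nes[i]) else 0
      den_pool <- nes[nes < 0 & !is.na(nes)]
      den <- mean(den_pool <= nes[i])
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  res <- data.frame(set = names(sets), size = sizes, es = unname(obs),
                    nes = nes, pval = pval, fdr = fdr, leading_edge = le,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$pval), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value for the overlap of a module gene list
#' with each set, conditioning on the universe, with BH FDR across sets.
#'
#' @param module_genes character vector (must be a subset of the universe).
#' @param universe character vector of all eligible genes.
#' @param sets named list of gene sets (clipped to the universe).
#' @return data.frame (class \code{enrichment_result}): set, set_size,
#'   overlap, pval, fdr, genes.
#' @export
ora_hypergeom <- function(module_genes, universe, sets) {
  universe <- unique(universe)
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% universe))
    stop("module genes must be a subset of the universe", call. = FALSE)
  Nu <- length(universe); nm <- length(module_genes)
  pv <- numeric(length(sets)); ov <- integer(length(sets))
  ks <- integer(length(sets)); genes <- character(length(sets))
  for (i in seq_along(sets)) {
    set_u <- intersect(sets[[i]], universe)
    hit <- intersect(module_genes, set_u)
    ks[i] <- length(set_u); ov[i] <- length(hit)
    genes[i] <- paste(sort(hit), collapse = ",")
    # P(X >= overlap), X ~ Hypergeom(|set|, |universe|-|set|, |module|)
    pv[i] <- stats::phyper(ov[i] - 1, ks[i], Nu - ks[i], nm,
                           lower.tail = FALSE)
  }
  res <- data.frame(set = names(sets), set_size = ks, overlap = ov,
                    pval = pv, fdr = stats::p.adjust(pv, "BH"), genes = genes,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$pval), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
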