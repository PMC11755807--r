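#' Per-sample total TE and piRNA levels and the TE:piRNA ratio
#'
#' Column sums of the normalized TE and piRNA matrices over the shared
#' sample set, and their ratio (total TE / total piRNA). The two totals come
#' from different libraries; no cross-library renormalization is attempted
#' beyond the per-library size factors. The ratio is NA (flagged) where the
#' piRNA total is zero.
#'
#' @param te_norm,pirna_norm normalized matrices, features x samples, over
#'   the same samples.
#' @param group optional per-sample group labels (named or in column order).
#' @return data.frame: sample, group, total_te, total_pirna, ratio.
#' @export
sample_totals <- function(te_norm, pirna_norm, group = NULL) {
  if (!identical(sort(colnames(te_norm)), sort(colnames(pirna_norm))))
    stop("TE and piRNA matrices must share the same sample set", call. = FALSE)
  pirna_norm <- pirna_norm[, colnames(te_norm), drop = FALSE]
  total_te <- colSums(te_norm)
  total_pirna <- colSums(pirna_norm)
  ratio <- ifelse(total_pirna > 0, total_te / total_pirna, NA_real_)
  if (!is.null(group) && !is.null(names(group)))
    group <- group[colnames(te_norm)]
  data.frame(sample = colnames(te_norm),
             group = if (is.null(group)) NA_character_ else as.character(group),
             total_te = total_te, total_pirna = total_pirna, ratio = ratio,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' TE class composition
#'
#' Fraction of the total TE level attributable to each TE class (SINE, L1,
#' ERV, ...), per sample and averaged over the cohort.
#'
#' @param te_norm normalized TE matrix, features x samples.
#' @param class character vector of class labels, one per TE feature (named
#'   by feature id or in row order).
#' @return list with \code{per_sample} (classes x samples matrix of
#'   fractions, each column summing to 1) and \code{cohort_mean} (named
#'   vector, mean of per-sample fractions).
#' @export
te_composition <- function(te_norm, class) {
  if (!is.null(names(class))) class <- class[rownames(te_norm)]
  if (length(class) != nrow(te_norm) || anyNA(class))
    stop("every TE feature must carry a class annotation", call. = FALSE)
  by_class <- rowsum(te_norm, class)
  per_sample <- sweep(by_class, 2, colSums(by_class), "/")
  list(per_sample = per_sample, cohort_mean = rowMeans(per_sample))
}

#' Control-extremum cutoff rule
#'
#' Dichotomizes a statistic at the extremum observed in the control group:
#' in \code{control-minimum} mode the cutoff is the control minimum and
#' samples strictly below it are \code{low}; in \code{control-maximum} mode
#' the cutoff is the control maximum and samples strictly above it are
#' \code{high}. Values exactly at the cutoff fall on the control-like side.
#'
#' @param values numeric vector of the statistic over all samples.
#' @param is_control logical vector marking control samples.
#' @param mode \code{"control-minimum"} or \code{"control-maximum"}.
#' @param statistic optional statistic name carried in the rule.
#' @return object of class \code{cutoff_rule} (list: statistic, mode,
#'   cutoff).
#' @export
control_cutoff <- function(values, is_control,
                           mode = c("control-minimum", "control-maximum"),
                           statistic = "value") {
  mode <- match.arg(mode)
  ctrl <- values[is_control]
  ctrl <- ctrl[!is.na(ctrl)]
  if (length(ctrl) < 1)
    stop("at least one control sample with a defined value is required",
         call. = FALSE)
  cutoff <- if (mode == "control-minimum") min(ctrl) else max(ctrl)
  structure(list(statistic = statistic, mode = mode, cutoff = cutoff),
            class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  cat(sprintf("cutoff rule: %s, %s = %g (%s side is control-like)\n",
              x$statistic, x$mode, x$cutoff,
              if (x$mode == "control-minimum") "high" else "low"))
  invisible(x)
}

#' Apply a control-extremum cutoff rule
#'
#' @param rule a [control_cutoff()] rule.
#' @param values numeric vector to stratify.
#' @return factor with levels \code{low}, \code{high} (NA preserved).
#' @export
apply_cutoff <- function(rule, values) {
  stopifnot(inherits(rule, "cutoff_rule"))
  lab <- if (rule$mode == "control-minimum") {
    ifelse(values < rule$cutoff, "low", "high")
  } else {
    ifelse(values > rule$cutoff, "high", "low")
  }
  factor(lab, levels = c("low", "high"))
}

#' Pearson correlation with two-sided p
#'
#' Product-moment correlation with the t-transform p-value on n - 2 degrees
#' of freedom; pairs with missing values are dropped.
#'
#' @param x,y paired numeric vectors.
#' @return list: r, p, n.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Welch two-sample t-test
#' @param a,b numeric vectors (each >= 2 values).
#' @return list: t, df, p.
#' @export
welch_t <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Welch's heteroscedastic one-way ANOVA
#' @param values numeric vector.
#' @param group factor/character of group labels (k >= 2 groups).
#' @return list: F, df1, df2, p.
#' @export
welch_anova <- function(values, group) {
  ow <- stats::oneway.test(values ~ factor(group), var.equal = FALSE)
  list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = ow$p.value)
}
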