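#' Kaplan-Meier product-limit curve
#'
#' S(t) is the product over event times up to t of (1 - d/n); the median is
#' the smallest time at which S drops to 0.5 or below, NA if S never reaches
#' 0.5.
#'
#' @param time positive follow-up times (months).
#' @param event event indicator (1 = event, 0 = censored).
#' @return object of class \code{km_curve}: data.frame \code{table} (time,
#'   n_risk, n_event, n_censor, surv) over distinct observed times, plus
#'   \code{median} and \code{n}.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  med <- ut[surv <= 0.5][1]
  structure(list(table = data.frame(time = ut, n_risk = n_risk,
                                    n_event = n_event, n_censor = n_censor,
                                    surv = surv),
                 median = if (is.na(med)) NA_real_ else med,
                 n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, sum(x$table$n_event),
              if (is.na(x$median)) "not reached" else sprintf("%.1f", x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic with the hypergeometric variance summed
#' over event times; p from chi-square with 1 df.
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level grouping.
#' @return list: chisq, p, observed and expected events per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2) stop("log-rank test needs exactly two strata", call. = FALSE)
  if (sum(event) < 1) stop("at least one event is required", call. = FALSE)
  g1 <- group == lev[1]
  ev_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chisq, df = 1, lower.tail = FALSE) else 1
  list(chisq = chisq, p = p,
       observed = stats::setNames(c(O, sum(event) - O), lev),
       expected = stats::setNames(c(E, sum(event) - E), lev))
}

## Breslow partial-likelihood pieces: log-likelihood, score, information.
## Risk-set sums are cumulative sums over samples ordered by descending time.
cox_derivs <- function(beta, time, event, X) {
  ord <- order(-time)
  t_o <- time[ord]; e_o <- event[ord]; X_o <- X[ord, , drop = FALSE]
  eta <- drop(X_o %*% beta)
  eta <- eta - max(eta)          # guard exp overflow; cancels in ratios
  w <- exp(eta)
  p <- ncol(X)
  S0 <- cumsum(w)
  S1 <- apply(X_o * w, 2, cumsum)
  if (p == 1) S1 <- matrix(S1, ncol = 1)
  ## ties (Breslow): every event at time t uses the full risk set {time >= t};
  ## with descending order that is the cumulative sum through the LAST index
  ## of the tie group
  last_of_tie <- rev(!duplicated(rev(t_o)))
  idx_full <- cumsum(last_of_tie)                # tie-group id (descending)
  grp_last <- which(last_of_tie)
  S0_at <- S0[grp_last][idx_full]
  S1_at <- S1[grp_last, , drop = FALSE][idx_full, , drop = FALSE]
  ev <- e_o == 1
  loglik <- sum(eta[ev]) - sum(log(S0_at[ev]))
  Xbar <- S1_at[ev, , drop = FALSE] / S0_at[ev]
  U <- colSums(X_o[ev, , drop = FALSE] - Xbar)
  ## information: sum over events of S2/S0 - (S1/S0)(S1/S0)'
  I <- matrix(0, p, p)
  for (a in seq_len(p)) {
    S2a <- apply(X_o * (X_o[, a] * w), 2, cumsum)
    if (p == 1) S2a <- matrix(S2a, ncol = 1)
    S2_at <- S2a[grp_last, , drop = FALSE][idx_full, , drop = FALSE]
    I[a, ] <- colSums(S2_at[ev, , drop = FALSE] / S0_at[ev] -
                        Xbar[, a] * Xbar)
  }
  list(loglik = loglik, U = U, I = I)
}

#' Cox proportional-hazards model (Breslow ties, Newton-Raphson)
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with step
#' halving (convergence at 1e-8 on the coefficient change, at most 50
#' iterations). Standard errors come from the inverse observed information;
#' 95% CIs are exp(coef +- 1.96 SE) and per-covariate p-values are Wald.
#'
#' @param time,event follow-up times and event indicators.
#' @param X covariate matrix (samples x covariates) or numeric vector.
#' @param tol convergence tolerance on max absolute coefficient change.
#' @param max_iter Newton-Raphson iteration cap.
#' @return object of class \code{cox_model}: data.frame \code{table}
#'   (variable, coef, HR, ci_low, ci_high, se, p), \code{loglik},
#'   \code{loglik_null}, \code{iterations}.
#' @export
cox_fit <- function(time, event, X, tol = 1e-8, max_iter = 50) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(event) < ncol(X))
    stop("fit error: fewer events than covariates", call. = FALSE)
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(const))
    stop("fit error: covariate constant across samples: ",
         colnames(X)[const][1], call. = FALSE)
  p <- ncol(X)
  beta <- rep(0, p)
  d0 <- cox_derivs(beta, time, event, X)
  ll_null <- d0$loglik
  ll <- ll_null; U <- d0$U; I <- d0$I
  it <- 0
  repeat {
    it <- it + 1
    step <- tryCatch(solve(I, U), error = function(e) NULL)
    if (is.null(step))
      stop("fit error: singular information matrix (covariate: ",
           colnames(X)[which.max(abs(U))], ")", call. = FALSE)
    ## step halving if the likelihood does not improve
    h <- 1
    repeat {
      cand <- beta + h * step
      dc <- cox_derivs(cand, time, event, X)
      if (dc$loglik >= ll - 1e-12 || h < 1e-4) break
      h <- h / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand; ll <- dc$loglik; U <- dc$U; I <- dc$I
    if (delta < tol) break
    if (it >= max_iter)
      stop("fit error: no convergence in ", max_iter,
           " iterations (covariate: ", colnames(X)[which.max(abs(beta))], ")",
           call. = FALSE)
    if (max(abs(beta)) > 20)
      stop("fit error: monotone likelihood, coefficient diverging (covariate: ",
           colnames(X)[which.max(abs(beta))], ")", call. = FALSE)
  }
  cov_beta <- solve(I)
  se <- sqrt(diag(cov_beta))
  z <- beta / se
  tab <- data.frame(variable = colnames(X), coef = beta, HR = exp(beta),
                    ci_low = exp(beta - 1.96 * se),
                    ci_high = exp(beta + 1.96 * se), se = se,
                    p = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, loglik = ll, loglik_null = ll_null,
                 iterations = it, vcov = cov_beta),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards model (%d covariates)\n",
              nrow(x$table)))
  if (nrow(x$table) == 0) {
    cat("  <empty model>\n")
    return(invisible(x))
  }
  tab <- x$table
  cat(sprintf("  %-14s %8s %8s %8s %10s\n", "variable", "HR", "CI.lo",
              "CI.hi", "p"))
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-14s %8.3f %8.3f %8.3f %10.2g\n", tab$variable[i],
                tab$HR[i], tab$ci_low[i], tab$ci_high[i], tab$p[i]))
  invisible(x)
}

#' Score test at beta = 0 for a single covariate
#'
#' U(0)^2 / I(0) from the Breslow partial likelihood; on tie-free data with
#' a binary covariate this equals the log-rank chi-square.
#'
#' @param time,event follow-up times and event indicators.
#' @param x single numeric covariate.
#' @return list: chisq, p.
#' @export
cox_score_test <- function(time, event, x) {
  d <- cox_derivs(0, time, event, as.matrix(x))
  chisq <- drop(d$U^2 / d$I)
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' IPSS-R ordinal transformation of clinical covariates
#'
#' Maps continuous clinical values to ordinal risk codes at the IPSS-R
#' cut-points: hemoglobin (g/dL) < 8 -> 2, 8 to < 10 -> 1, >= 10 -> 0;
#' platelets (x10^9/L) < 50 -> 2, 50 to < 100 -> 1, >= 100 -> 0;
#' neutrophils (x10^9/L) < 0.8 -> 1, >= 0.8 -> 0; marrow blasts (%)
#' <= 2 -> 0, > 2 to < 5 -> 1, 5 to 10 -> 2, > 10 -> 3. The cytogenetic
#' category is passed through as an ordered 0-4 code.
#'
#' @param clinical data.frame with columns hemoglobin, platelets,
#'   neutrophils, blasts, cytogenetics.
#' @return numeric matrix (samples x 5) of ordinal codes, rownames from a
#'   \code{sample} column when present.
#' @export
ipssr_ordinalize <- function(clinical) {
  need <- c("hemoglobin", "platelets", "neutrophils", "blasts", "cytogenetics")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop("missing clinical columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  hb <- ifelse(clinical$hemoglobin < 8, 2,
               ifelse(clinical$hemoglobin < 10, 1, 0))
  plt <- ifelse(clinical$platelets < 50, 2,
                ifelse(clinical$platelets < 100, 1, 0))
  anc <- ifelse(clinical$neutrophils < 0.8, 1, 0)
  bl <- ifelse(clinical$blasts <= 2, 0,
               ifelse(clinical$blasts < 5, 1,
                      ifelse(clinical$blasts <= 10, 2, 3)))
  m <- cbind(hemoglobin_ord = hb, platelets_ord = plt, neutrophils_ord = anc,
             blasts_ord = bl, cytogenetics_ord = clinical$cytogenetics)
  if ("sample" %in% names(clinical)) rownames(m) <- clinical$sample
  m
}

#' Stepwise Cox variable selection
#'
#' Forward selection with backward checks: repeatedly add the candidate with
#' the smallest Wald p-value below \code{p_enter}, then drop any included
#' covariate whose Wald p exceeds \code{p_remove}; stop when nothing
#' changes. Ties break on candidate order. Candidates whose addition makes
#' the fit singular or non-convergent are skipped. An empty final model is a
#' valid outcome.
#'
#' @param time,event follow-up times and event indicators.
#' @param X candidate covariate matrix (samples x candidates).
#' @param p_enter entry threshold on the Wald p-value.
#' @param p_remove removal threshold on the Wald p-value.
#' @return list: \code{model} (a [cox_fit()] result, or NULL when empty),
#'   \code{selected} (character vector in entry order), \code{trace}
#'   (data.frame of add/drop steps).
#' @export
stepwise_cox <- function(time, event, X, p_enter = 0.05, p_remove = 0.10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2) stop("need at least 2 candidate covariates", call. = FALSE)
  selected <- character(0)
  trace <- data.frame(step = character(), variable = character(),
                      p = numeric(), stringsAsFactors = FALSE)
  try_fit <- function(vars) {
    tryCatch(cox_fit(time, event, X[, vars, drop = FALSE]),
             error = function(e) NULL)
  }
  rounds <- 0
  repeat {
    rounds <- rounds + 1
    if (rounds > 4 * ncol(X) + 10) break   # cycle guard
    changed <- FALSE
    ## forward: best candidate by Wald p in the enlarged model
    cand <- setdiff(colnames(X), selected)
    best <- NULL; best_p <- Inf
    for (v in cand) {
      fit <- try_fit(c(selected, v))
      if (is.null(fit)) next
      pv <- fit$table$p[fit$table$variable == v]
      if (is.finite(pv) && pv < best_p - 1e-15) { best <- v; best_p <- pv }
    }
    if (!is.null(best) && best_p < p_enter) {
      selected <- c(selected, best)
      trace <- rbind(trace, data.frame(step = "add", variable = best,
                                       p = best_p))
      changed <- TRUE
    }
    ## backward: drop the worst included covariate above p_remove
    if (length(selected) > 0) {
      fit <- try_fit(selected)
      if (!is.null(fit)) {
        pv <- fit$table$p[match(selected, fit$table$variable)]
        worst <- which.max(pv)
        if (pv[worst] > p_remove) {
          trace <- rbind(trace, data.frame(step = "drop",
                                           variable = selected[worst],
                                           p = pv[worst]))
          selected <- selected[-worst]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  model <- if (length(selected)) try_fit(selected) else NULL
  list(model = model, selected = selected, trace = trace)
}
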