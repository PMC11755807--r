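test_that("product-limit estimate matches hand computation on toys", {
  ## three events: S = 2/3, 1/3, 0; median = 2
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  ## all censored: S = 1 throughout, median undefined
  km2 <- km_curve(c(2, 5, 7), c(0, 0, 0))
  expect_true(all(km2$table$surv == 1))
  expect_true(is.na(km2$median))
  ## six subjects, events at 2 and 4, censored at 3, 5, 5, 6:
  ## S(2) = 5/6, S(4) = 5/6 * 3/4 = 5/8
  km3 <- km_curve(c(2, 3, 4, 5, 5, 6), c(1, 0, 1, 0, 0, 0))
  tab <- km3$table
  expect_equal(tab$surv[tab$time == 2], 5 / 6)
  expect_equal(tab$surv[tab$time == 4], 5 / 8)
  expect_true(is.na(km3$median))
  ## monotone non-increasing, S(0) = 1 implicitly via first value <= 1
  expect_true(all(diff(tab$surv) <= 0))
})

test_that("km_curve agrees with the survival package on random data", {
  skip_if_not_installed("survival")
  s <- sim_surv(40, beta = 0.5, seed = 3)
  km <- km_curve(s$time, s$event)
  sf <- survival::survfit(survival::Surv(s$time, s$event) ~ 1)
  mine <- km$table$surv[km$table$n_event > 0]
  theirs <- sf$surv[sf$n.event > 0]
  expect_equal(mine, theirs, tolerance = 1e-12)
})

test_that("log-rank behaves on degenerate and closed-form cases", {
  ## identical strata (duplicated records): statistic 0, p = 1
  lt <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                     rep(c("A", "B"), each = 3))
  expect_equal(lt$chisq, 0, tolerance = 1e-12)
  expect_equal(lt$p, 1, tolerance = 1e-12)
  ## single event time: 2x2 hypergeometric closed form
  ## groups A: event at 1, B: censored later
  time <- c(1, 5, 6, 7)
  event <- c(1, 0, 0, 0)
  grp <- c("A", "A", "B", "B")
  lt2 <- logrank_test(time, event, grp)
  ## at t=1: n=4, n_A=2, d=1 -> E = 0.5, V = 1*(1/2)*(1/2)*(3/3) = 0.25
  expect_equal(lt2$chisq, (1 - 0.5)^2 / 0.25, tolerance = 1e-12)
  expect_error(logrank_test(1:3, c(1, 1, 0), c("A", "B", "C")), "two strata")
  expect_error(logrank_test(1:2, c(0, 0), c("A", "B")), "event")
})

test_that("log-rank is symmetric and time-scale invariant, matches survdiff", {
  skip_if_not_installed("survival")
  s <- sim_surv(60, beta = 0.7, seed = 9)
  g <- ifelse(s$x == 1, "hi", "lo")
  l1 <- logrank_test(s$time, s$event, g)
  l2 <- logrank_test(s$time, s$event, ifelse(s$x == 1, "lo", "hi"))
  expect_equal(l1$chisq, l2$chisq, tolerance = 1e-12)
  l3 <- logrank_test(s$time * 7.3, s$event, g)
  expect_equal(l1$chisq, l3$chisq, tolerance = 1e-12)
  sd_ <- survival::survdiff(survival::Surv(s$time, s$event) ~ g)
  expect_equal(l1$chisq, sd_$chisq, tolerance = 1e-9)
})

test_that("log-rank null rejection rate is calibrated", {
  set.seed(20)
  rej <- replicate(400, {
    n <- 40
    t0 <- rexp(n, 0.05); cn <- runif(n, 0, 40)
    logrank_test(pmin(t0, cn), as.integer(t0 <= cn),
                 rep(c("A", "B"), each = n / 2))$p < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Cox fit maximizes the partial likelihood (grid-search oracle)", {
  s <- sim_surv(60, beta = 0.8, seed = 5)
  time <- untie(s$time)
  fit <- cox_fit(time, s$event, matrix(s$x, ncol = 1))
  grid <- seq(fit$table$coef - 0.05, fit$table$coef + 0.05, by = 1e-5)
  pl <- vapply(grid, function(b)
    piRatio:::cox_derivs(b, time, s$event, matrix(s$x, ncol = 1))$loglik,
    numeric(1))
  expect_lt(abs(fit$table$coef - grid[which.max(pl)]), 1e-4)
  ## CI brackets the HR
  expect_true(fit$table$ci_low < fit$table$HR &&
                fit$table$HR < fit$table$ci_high)
})

test_that("Cox estimates agree with coxph on multivariate data", {
  skip_if_not_installed("survival")
  set.seed(6)
  n <- 120
  X <- cbind(age = rnorm(n, 60, 8), trt = rbinom(n, 1, 0.5))
  t0 <- rexp(n, 0.01 * exp(0.03 * (X[, 1] - 60) + 0.6 * X[, 2]))
  cn <- runif(n, 0, 80)
  time <- untie(pmin(t0, cn)); ev <- as.integer(t0 <= cn)
  fit <- cox_fit(time, ev, X)
  cp <- survival::coxph(survival::Surv(time, ev) ~ X, ties = "breslow")
  expect_equal(fit$table$coef, unname(coef(cp)), tolerance = 1e-6)
  expect_equal(fit$table$se, unname(sqrt(diag(vcov(cp)))), tolerance = 1e-6)
})

test_that("score test at zero equals the log-rank statistic (tie-free)", {
  s <- sim_surv(80, beta = 0.6, seed = 7)
  time <- untie(s$time)
  st <- cox_score_test(time, s$event, s$x)
  lr <- logrank_test(time, s$event, ifelse(s$x == 1, "hi", "lo"))
  expect_lt(abs(st$chisq - lr$chisq), 1e-6)
})

test_that("Cox guards degenerate designs", {
  s <- sim_surv(30, seed = 8)
  expect_error(cox_fit(s$time, s$event, matrix(1, 30, 1)), "constant")
  expect_error(cox_fit(s$time, rep(0L, 30), matrix(s$x, ncol = 1)),
               "fewer events")
  ## perfectly separating covariate diverges (monotone likelihood)
  ord <- order(s$time)
  xsep <- numeric(30); xsep[ord[1:15]] <- 1
  expect_error(cox_fit(s$time, rep(1L, 30), matrix(xsep, ncol = 1)),
               "fit error")
})

test_that("IPSS-R ordinal coding maps the boundary cases exactly", {
  cl <- data.frame(
    sample = paste0("P", 1:8),
    hemoglobin = c(7.9, 8.0, 9.9, 10.0, 12, 12, 12, 12),
    platelets = c(49, 50, 99, 100, 200, 200, 200, 200),
    neutrophils = c(0.79, 0.8, 1.5, 0.2, 1, 1, 1, 1),
    blasts = c(2.0, 2.1, 4.9, 5.0, 10.0, 10.1, 0, 15),
    cytogenetics = c(0, 1, 2, 3, 4, 0, 1, 2))
  ord <- ipssr_ordinalize(cl)
  expect_equal(unname(ord[, "hemoglobin_ord"]), c(2, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(ord[, "platelets_ord"]), c(2, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(ord[, "neutrophils_ord"]), c(1, 0, 0, 1, 0, 0, 0, 0))
  expect_equal(unname(ord[, "blasts_ord"]), c(0, 1, 1, 2, 2, 3, 0, 3))
  expect_equal(unname(ord[, "cytogenetics_ord"]), cl$cytogenetics)
  expect_error(ipssr_ordinalize(cl[, -2]), "hemoglobin")
})

test_that("stepwise selection keeps signal, drops noise, survives collinearity", {
  set.seed(10)
  n <- 250
  X <- cbind(true = rbinom(n, 1, 0.5),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  t0 <- rexp(n, 0.03 * exp(log(3) * X[, "true"]))
  cn <- runif(n, 0, 60)
  time <- pmin(t0, cn); ev <- as.integer(t0 <= cn)
  sw <- stepwise_cox(time, ev, X)
  expect_true("true" %in% sw$selected)
  ## duplicated column: only one copy can enter
  Xd <- cbind(X[, c("true", "true")], X[, c("n1", "n2")])
  colnames(Xd) <- c("a", "b", "n1", "n2")
  swd <- stepwise_cox(time, ev, Xd)
  expect_lte(sum(c("a", "b") %in% swd$selected), 1)
  expect_error(stepwise_cox(time, ev, X[, 1, drop = FALSE]), "2 candidate")
})
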