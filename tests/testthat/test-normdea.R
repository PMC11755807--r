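test_that("size factors follow the median-of-ratios definition", {
  ## identical columns: both factors 1
  cm <- cbind(A = c(10, 100), B = c(10, 100))
  expect_equal(unname(size_factors(cm)), c(1, 1))
  ## column B = 2 x column A: factors (1/sqrt(2), sqrt(2)), ratio exactly 2
  cm2 <- cbind(A = c(10, 100), B = c(20, 200))
  sf <- size_factors(cm2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  ## no feature positive everywhere
  expect_error(size_factors(cbind(c(0, 5), c(3, 0))), "normalization error")
})

test_that("scaling one column scales its factor exactly, others shift together", {
  set.seed(31)
  for (i in 1:5) {
    cm <- matrix(rpois(120, 60) + 1, 20, 6,
                 dimnames = list(NULL, paste0("S", 1:6)))
    sf0 <- size_factors(cm)
    c_mult <- sample(2:5, 1)
    cm2 <- cm
    cm2[, 3] <- cm2[, 3] * c_mult
    sf1 <- size_factors(cm2)
    ## brute-force expectation: scaled column x c, every column / c^(1/n)
    shift <- c_mult^(1 / 6)
    expect_equal(sf1[3], sf0[3] * c_mult / shift, tolerance = 1e-12)
    expect_equal(sf1[-3], sf0[-3] / shift, tolerance = 1e-12)
  }
})

test_that("normalization divides element-wise and round-trips", {
  cm <- matrix(c(4, 8, 6, 12), 2, 2, dimnames = list(c("f1", "f2"),
                                                     c("A", "B")))
  expect_equal(normalize_counts(cm, c(A = 1, B = 1)), cm)
  half <- normalize_counts(cm, c(A = 1, B = 2))
  expect_equal(half[, "B"], cm[, "B"] / 2)
  expect_error(normalize_counts(cm, c(A = 1)), "missing size factor")
  ## after normalization every sample has the same residual size factor
  ## (the geometric mean of the originals), i.e. relative scaling is gone
  set.seed(7)
  cm2 <- matrix(rpois(200, 80) + 1, 20, 10,
                dimnames = list(paste0("f", 1:20), paste0("S", 1:10)))
  sf <- size_factors(cm2)
  nm <- normalize_counts(cm2, sf)
  sf2 <- size_factors(nm)
  expect_equal(unname(sf2), rep(exp(mean(log(sf))), 10), tolerance = 1e-12)
})

test_that("identical groups give zero log2FC and p = 1", {
  cm <- rbind(flat = rep(50L, 8), other = c(10L, 60L, 30L, 45L, 20L, 55L,
                                            35L, 40L))
  colnames(cm) <- paste0("S", 1:8)
  cm["flat", ] <- rep(c(17L, 23L, 41L, 12L), 2)
  grp <- rep(c("A", "B"), each = 4)
  cm[, grp == "B"] <- cm[, grp == "A"]
  dea <- nb_wald_test(cm, grp, factors = rep(1, 8))
  expect_equal(dea$log2FC[dea$feature == "flat"], 0, tolerance = 1e-12)
  expect_equal(dea$p[dea$feature == "flat"], 1, tolerance = 1e-9)
})

test_that("design errors are rejected", {
  cm <- sim_counts(10, 3, 3, seed = 2)
  expect_error(nb_wald_test(cm, rep("A", 6)), "two levels")
  expect_error(nb_wald_test(cm, c("A", rep("B", 5))), ">= 2 samples")
})

test_that("Benjamini-Hochberg step-up matches the hand calculation", {
  ## independent oracle: hand-applied BH on (0.01, 0.02, 0.03, 0.5)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5))
})

test_that("label swap negates log2FC and preserves p", {
  cm <- sim_counts(50, 6, 6, seed = 5)
  grp <- rep(c("A", "B"), each = 6)
  d1 <- nb_wald_test(cm, factor(grp, c("A", "B")))
  d2 <- nb_wald_test(cm, factor(grp, c("B", "A")))
  expect_equal(d1$log2FC, -d2$log2FC, tolerance = 1e-12)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
})

test_that("scaled counts with scaled factors give the identical test", {
  cm <- sim_counts(40, 5, 5, seed = 6)
  grp <- rep(c("A", "B"), each = 5)
  sf <- size_factors(cm)
  d1 <- nb_wald_test(cm, grp, factors = sf)
  ## tripling the counts and the factors leaves the normalized matrix, and
  ## hence every statistic, bit-identical
  d2 <- nb_wald_test(cm * 3L, grp, factors = 3 * sf)
  expect_equal(d2$p, d1$p, tolerance = 1e-12)
  expect_equal(d2$log2FC, d1$log2FC, tolerance = 1e-12)
})

test_that("rescaling one sample is absorbed by its size factor", {
  ## the shared pseudo-reference shift c^(1/n) perturbs the count-scale
  ## pseudocount and dispersion terms slightly, so invariance is approximate
  cm <- sim_counts(200, 10, 10, seed = 8)
  grp <- rep(c("A", "B"), each = 10)
  d1 <- nb_wald_test(cm, grp)
  cm2 <- cm
  cm2[, 1] <- cm2[, 1] * 4L
  d2 <- nb_wald_test(cm2, grp)
  expect_lt(max(abs(d2$p - d1$p)), 0.02)
  expect_gt(cor(d1$p, d2$p), 0.999)
})

test_that("significance calls partition by sign and nest across cutoffs", {
  dea <- data.frame(feature = paste0("f", 1:6),
                    baseMean1 = 1, baseMean2 = 1,
                    log2FC = c(2, -1, 0.5, -0.2, 0, 1),
                    p = c(1e-5, 1e-4, 0.2, 0.004, 2e-5, 0.6))
  dea$FDR <- p.adjust(dea$p, "BH")
  class(dea) <- c("dea_result", "data.frame")
  sig05 <- call_significant(dea, 0.05)
  sig001 <- call_significant(dea, 0.001)
  expect_true(all(sig001$feature %in% sig05$feature))
  expect_setequal(sig05$direction[sig05$log2FC > 0], "up")
  expect_setequal(sig05$direction[sig05$log2FC < 0], "down")
  ## all FDR above the cutoff: empty
  expect_equal(nrow(call_significant(dea, 1e-9)), 0)
  expect_error(call_significant(dea, 1.2), "fdr_cutoff")
})

test_that("zero-log2FC significant features are reported unclassified", {
  dea <- data.frame(feature = "f1", baseMean1 = 1, baseMean2 = 1,
                    log2FC = 0, p = 1e-6, FDR = 1e-6)
  class(dea) <- c("dea_result", "data.frame")
  expect_equal(call_significant(dea, 0.05)$direction, "unclassified")
})
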