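make_panel <- function(n_mol, n_samp, seed = 1) {
  set.seed(seed)
  matrix(rexp(n_mol * n_samp, 0.05), n_mol, n_samp,
         dimnames = list(sprintf("M%02d", seq_len(n_mol)),
                         sprintf("S%02d", seq_len(n_samp))))
}

## independent oracle: enumerate the membership rule directly from the
## correlation matrix
oracle_members <- function(cm, seed, k) {
  topk <- function(node) {
    r <- cm[node, setdiff(rownames(cm), node)]
    names(sort(rank(-abs(r), ties.method = "first")))[seq_len(min(k, length(r)))]
  }
  ## rank with ties by identifier: order(-abs(r), names)
  topk <- function(node) {
    r <- cm[node, setdiff(rownames(cm), node)]
    nm <- names(r)[order(-abs(r), names(r))]
    nm[seq_len(min(k, length(nm)))]
  }
  nb <- topk(seed)
  sort(unique(c(seed, nb, unlist(lapply(nb, topk)))))
}

test_that("the graph is complete with brute-force Pearson weights", {
  panel <- make_panel(5, 12)
  g <- build_correlation_graph(panel)
  expect_equal(sum(upper.tri(g$cor)), 10)  # 5 choose 2
  bf <- cor(t(log2(panel + 1)))
  expect_equal(g$cor, bf, tolerance = 1e-12)
  ## perfectly proportional molecules get weight 1
  p2 <- rbind(a = c(1, 2, 4, 8), b = c(1, 2, 4, 8) * 3)
  colnames(p2) <- paste0("S", 1:4)
  expect_equal(build_correlation_graph(p2, log2_transform = FALSE)$cor["a", "b"], 1)
  ## zero-variance molecules dropped with a warning
  p3 <- rbind(a = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  colnames(p3) <- paste0("S", 1:4)
  expect_warning(build_correlation_graph(p3, log2_transform = FALSE),
                 "zero-variance")
})

test_that("module membership equals exhaustive enumeration", {
  set.seed(41)
  for (i in 1:100) {
    panel <- make_panel(8, 10, seed = 1000 + i)
    g <- build_correlation_graph(panel)
    seed_node <- sample(rownames(g$cor), 1)
    k <- sample(1:4, 1)
    mod <- extract_module(g, seed_node, k)
    expect_equal(mod$members, oracle_members(g$cor, seed_node, k))
  }
})

test_that("module extraction is deterministic and row-order invariant", {
  panel <- make_panel(10, 12, seed = 5)
  g1 <- build_correlation_graph(panel)
  g2 <- build_correlation_graph(panel[sample(1:10), ])
  m1 <- extract_module(g1, "M03", 3)
  m2 <- extract_module(g2, "M03", 3)
  expect_equal(m1$members, m2$members)
  ## k at least node count returns everything
  mall <- extract_module(g1, "M03", 50)
  expect_setequal(mall$members, rownames(g1$cor))
  expect_error(extract_module(g1, "nope", 2), "not in graph")
})

test_that("Q3 edge filtering is strict and matches the hand quantile", {
  ## 4 members, pairwise |r| = .9 .8 .7 .6 .5 .4 -> Q3 = 0.775, keep 2 edges
  cm <- diag(4)
  rownames(cm) <- colnames(cm) <- c("a", "b", "c", "d")
  vals <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  pairs <- combn(4, 2)
  for (j in 1:6) {
    cm[pairs[1, j], pairs[2, j]] <- vals[j]
    cm[pairs[2, j], pairs[1, j]] <- vals[j]
  }
  g <- structure(list(cor = cm, kind = NULL), class = "correlation_graph")
  mod <- structure(list(seed = "a", members = c("a", "b", "c", "d"), k = 3,
                        edges = NULL, threshold = NA_real_),
                   class = "seed_module")
  mod <- filter_module_edges(mod, g)
  expect_equal(mod$threshold, 0.775)
  expect_equal(nrow(mod$edges), 2)
  expect_setequal(mod$edges$r, c(0.9, 0.8))
  ## all correlations equal: nothing strictly exceeds Q3
  cm[upper.tri(cm)] <- 0.5
  cm[lower.tri(cm)] <- 0.5
  g2 <- structure(list(cor = cm, kind = NULL), class = "correlation_graph")
  mod2 <- filter_module_edges(structure(list(seed = "a",
                                             members = rownames(cm), k = 3,
                                             edges = NULL,
                                             threshold = NA_real_),
                                        class = "seed_module"), g2)
  expect_equal(nrow(mod2$edges), 0)
})

test_that("retained edges match brute force on random modules", {
  set.seed(43)
  for (i in 1:100) {
    panel <- make_panel(8, 9, seed = 2000 + i)
    g <- build_correlation_graph(panel)
    mod <- extract_module(g, "M01", 3)
    mod <- filter_module_edges(mod, g)
    ## brute force: all pairs, type-7 Q3 on |r|, strict threshold
    prs <- combn(mod$members, 2)
    rr <- g$cor[cbind(prs[1, ], prs[2, ])]
    thr <- unname(quantile(abs(rr), 0.75, type = 7))
    expect_equal(mod$threshold, thr)
    expect_equal(nrow(mod$edges), sum(abs(rr) > thr))
    ## invariants: strictness and membership closure
    if (nrow(mod$edges)) {
      expect_true(all(abs(mod$edges$r) > mod$threshold))
      expect_true(all(c(mod$edges$node1, mod$edges$node2) %in% mod$members))
    }
  }
})

test_that("a planted correlated block is recovered from inside", {
  hits <- sapply(1:50, function(s) {
    set.seed(300 + s)
    n <- 30; block <- 6; total <- 20
    z <- rnorm(n)
    panel <- rbind(
      t(sapply(seq_len(block), function(i) 40 + 12 * z + rnorm(n, 0, 4))),
      matrix(rexp((total - block) * n, 0.03), total - block, n))
    rownames(panel) <- sprintf("M%02d", 1:total)
    colnames(panel) <- sprintf("S%02d", 1:n)
    panel <- pmax(panel, 0)
    g <- build_correlation_graph(panel)
    mod <- extract_module(g, "M01", k = block)
    mean(sprintf("M%02d", 1:block) %in% mod$members)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("module export writes parseable GraphML and SIF", {
  skip_if_not_installed("xml2")
  panel <- make_panel(8, 10, seed = 6)
  g <- build_correlation_graph(panel)
  mod <- filter_module_edges(extract_module(g, "M02", 3), g)
  d <- file.path(tempdir(), "netexp")
  p <- export_module(mod, g, d)
  x <- xml2::read_xml(p[["graphml"]])
  nodes <- xml2::xml_find_all(x, ".//*[local-name()='node']")
  edges <- xml2::xml_find_all(x, ".//*[local-name()='edge']")
  expect_equal(length(nodes), length(mod$members))
  expect_equal(length(edges), nrow(mod$edges))
  expect_equal(length(readLines(p[["sif"]])), nrow(mod$edges))
  ## empty edge set still yields valid GraphML with isolated nodes
  cm <- g$cor
  cm[abs(cm) < 1] <- 0.3
  g2 <- structure(list(cor = cm, kind = NULL), class = "correlation_graph")
  mod2 <- filter_module_edges(structure(list(seed = "M02",
                                             members = mod$members, k = 3,
                                             edges = NULL,
                                             threshold = NA_real_),
                                        class = "seed_module"), g2)
  expect_equal(nrow(mod2$edges), 0)
  p2 <- export_module(mod2, g2, d)
  x2 <- xml2::read_xml(p2[["graphml"]])
  expect_equal(length(xml2::xml_find_all(x2, ".//*[local-name()='node']")),
               length(mod2$members))
  unlink(d, recursive = TRUE)
})
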