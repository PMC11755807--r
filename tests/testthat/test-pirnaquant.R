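adapter <- "AACTGTAGGCACCATCAAT"

test_that("adapter trimming and UMI extraction follow the read layout", {
  umi <- "AAACCCGGGTTT"
  tr <- trim_and_extract(paste0("ACGTACGT", adapter, umi), adapter,
                         umi_len = 12)
  expect_true(tr$extracted)
  expect_equal(tr$insert, "ACGTACGT")
  expect_equal(tr$umi, umi)
  ## no adapter occurrence: flagged, not an error
  tr2 <- trim_and_extract("ACGTACGTACGT", adapter, umi_len = 12)
  expect_false(tr2$extracted)
  expect_true(is.na(tr2$insert))
  ## adapter present but UMI truncated
  tr3 <- trim_and_extract(paste0("ACGT", adapter, "AAA"), adapter,
                          umi_len = 12)
  expect_false(tr3$extracted)
  ## empty insert is extracted (length 0), left to the length filter
  tr4 <- trim_and_extract(paste0(adapter, umi), adapter, umi_len = 12)
  expect_true(tr4$extracted)
  expect_equal(nchar(tr4$insert), 0)
  expect_error(trim_and_extract("ACGT", ""), "adapter")
})

test_that("length filter keeps 24-34 nt inclusive", {
  lens <- c(0, 23, 24, 30, 34, 35)
  ins <- vapply(lens, function(L) strrep("A", L), character(1))
  expect_equal(length_filter(ins), c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_true(is.na(NA_character_) || TRUE)
  expect_false(length_filter(NA_character_))
})

test_that("matching is exact in both sequence and length", {
  seq28 <- paste(rep(c("A", "C", "G", "T"), 7), collapse = "")
  ref <- pirna_reference(c(p1 = seq28))
  expect_equal(exact_match(seq28, ref), seq28)
  ## one substitution: no match
  sub <- paste0("C", substr(seq28, 2, 28))
  expect_true(is.na(exact_match(sub, ref)))
  ## truncation by one base: no match
  expect_true(is.na(exact_match(substr(seq28, 1, 27), ref)))
  ## N never matches
  expect_true(is.na(exact_match(paste0("N", substr(seq28, 2, 28)), ref)))
  ## U in the reference or the insert normalizes to T
  refU <- pirna_reference(c(p1 = chartr("T", "U", seq28)))
  expect_equal(exact_match(seq28, refU), seq28)
  expect_equal(exact_match(chartr("T", "U", seq28), ref), seq28)
})

test_that("reference indexes redundant identifiers under one sequence", {
  s <- strrep("ACGT", 6)
  ref <- pirna_reference(c(beta = s, alpha = s, other = strrep("GT", 13)))
  expect_equal(length(ref$seq_ids), 2)
  expect_equal(ref$seq_ids[[s]], c("alpha", "beta"))
  expect_error(pirna_reference(c(a = "ACGT", a = "ACGT")), "unique")
  expect_error(pirna_reference(c(a = "ACGX")), "A/C/G/T/U")
})

test_that("directional UMI deduplication collapses the published way", {
  ## count(a) >= 2*count(b) - 1 with Hamming distance 1: collapse
  expect_equal(umi_dedup(c(rep("AAAA", 5), "AAAT")), 1L)
  ## Hamming distance 4: no edge
  expect_equal(umi_dedup(c("AAAA", "AAAA", "TTTT", "TTTT")), 2L)
  ## all identical
  expect_equal(umi_dedup(rep("AAAA", 10)), 1L)
  ## directional condition violated (2 vs 2): two molecules
  expect_equal(umi_dedup(c("AAAA", "AAAA", "AAAT", "AAAT")), 2L)
  ## unique mode never collapses
  expect_equal(umi_dedup(c(rep("AAAA", 5), "AAAT"), method = "unique"), 2L)
  expect_equal(umi_dedup(character(0)), 0L)
  expect_error(umi_dedup(c("AAAA", "AAA")), "mixed UMI lengths")
})

test_that("directional collapse equals exhaustive evaluation on small groups", {
  ## independent oracle: apply the adjacency rule over all pairs, then count
  ## roots by visiting UMIs in decreasing-count order
  oracle <- function(umis) {
    tab <- table(umis)
    u <- names(tab); cnt <- as.integer(tab)
    ord <- order(-cnt, u); u <- u[ord]; cnt <- cnt[ord]
    m <- length(u)
    reach <- diag(TRUE, m)
    repeat {
      nxt <- reach
      for (i in seq_len(m)) for (j in seq_len(m)) {
        if (i == j || nxt[i, j]) next
        ## j reachable from i via some k with a directed edge k -> j
        for (k in which(reach[i, ])) {
          hd <- sum(strsplit(u[k], "")[[1]] != strsplit(u[j], "")[[1]])
          if (hd == 1 && cnt[k] >= 2 * cnt[j] - 1) { nxt[i, j] <- TRUE; break }
        }
      }
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    visited <- rep(FALSE, m); roots <- 0L
    for (i in seq_len(m)) {
      if (visited[i]) next
      roots <- roots + 1L
      visited[reach[i, ]] <- TRUE
    }
    roots
  }
  set.seed(77)
  alphabet <- c("A", "C", "G", "T")
  for (rep_i in 1:60) {
    n_umi <- sample(1:6, 1)
    umis <- replicate(n_umi, paste(sample(alphabet, 3, TRUE), collapse = ""))
    counts <- sample(1:6, n_umi, TRUE)
    group <- rep(umis, counts)
    expect_equal(umi_dedup(group), oracle(group),
                 info = paste(umis, counts, collapse = " "))
  }
})

test_that("quantification matches generator truth and tallies attrition", {
  co <- generate_cohort(cohort_config(n_ctr = 2, n_lr = 2, n_hr = 2,
                                      n_te = 5, n_pirna = 40, n_pcg = 5,
                                      n_mirna = 5, seed = 21))
  ref <- pirna_reference(co$reference)
  mol <- co$truth$pirna_molecules[, 1]
  names(mol) <- rownames(co$pirna_counts)

  for (dup in c(0, 3)) {
    fq <- tempfile(fileext = ".fastq")
    generate_reads(mol, co$reference, adapter = adapter, dup_rate = dup,
                   error_rate = 0, path = fq, seed = 31 + dup)
    q <- quantify_pirnas(fq, ref, adapter = adapter)
    got <- setNames(q$counts$dedup_count, q$counts$representative_id)
    truth <- mol[mol > 0]
    expect_equal(got[names(truth)], truth, ignore_attr = TRUE)
    if (dup > 0) expect_gt(sum(q$counts$raw_count), sum(q$counts$dedup_count))
    ## attrition monotone non-increasing through matching
    a <- q$attrition$reads
    expect_true(all(diff(a[1:4]) <= 0))
    expect_true(all(q$counts$dedup_count <= q$counts$raw_count))
    ## idempotence
    q2 <- quantify_pirnas(fq, ref, adapter = adapter)
    expect_identical(q$counts, q2$counts)
    unlink(fq)
  }
})

test_that("degenerate FASTQ inputs are handled", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(character(0), fq)
  ref <- pirna_reference(c(p1 = strrep("ACGT", 7)))
  q <- quantify_pirnas(fq, ref, adapter = adapter)
  expect_equal(q$attrition$reads, rep(0L, 5))
  expect_equal(nrow(q$counts), 0)
  ## malformed record reports its index
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), fq)
  expect_error(read_fastq(fq), "record 2")
  writeLines(c("@r1", "ACGT", "+", "III"), fq)
  expect_error(read_fastq(fq), "record 1")
  unlink(fq)
})
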