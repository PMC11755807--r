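## Shared fixtures built in code at test time.

## NB count matrix with optional planted log2 fold changes in group 2
sim_counts <- function(n_features, n1, n2, mu = 100, size = 10,
                       lfc = numeric(0), seed = 1) {
  set.seed(seed)
  m <- matrix(mu, n_features, n1 + n2)
  if (length(lfc))
    m[seq_along(lfc), (n1 + 1):(n1 + n2)] <- mu * 2^lfc
  cm <- matrix(rnbinom(length(m), mu = m, size = size), n_features,
               dimnames = list(sprintf("F%04d", seq_len(n_features)),
                               sprintf("S%03d", seq_len(n1 + n2))))
  storage.mode(cm) <- "integer"
  cm
}

## Exponential survival with a binary covariate (true log-HR = beta)
sim_surv <- function(n, beta = 0, base_rate = 0.03, cens_max = 60, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t0 <- rexp(n, base_rate * exp(beta * x))
  cn <- runif(n, 0.5, cens_max)
  list(time = pmin(t0, cn), event = as.integer(t0 <= cn), x = x)
}

## Jitter times to remove ties (for tie-free oracles)
untie <- function(time) time + seq_along(time) * 1e-6

write_fastq <- function(reads, path) {
  writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n",
                    strrep("I", nchar(reads))), path)
  path
}
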