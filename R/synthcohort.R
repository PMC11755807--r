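#' Synthetic MDS cohort configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. Defaults
#' mirror the cohort structure the workflow targets: 17 healthy controls
#' (CTR), 45 lower-risk (LR-MDS) and 35 higher-risk (HR-MDS) patients, with
#' TE expression suppressed and piRNA expression elevated in HR-MDS, a
#' negative latent correlation between per-sample total TE and total piRNA
#' levels, PIWIL2 coupled to the piRNA latent factor, and exponential
#' survival with a higher hazard in HR-MDS.
#'
#' @param n_ctr,n_lr,n_hr group sizes (controls, LR-MDS, HR-MDS).
#' @param n_te,n_pirna,n_pcg number of TE, piRNA and protein-coding features.
#' @param n_mirna number of background miRNA features in the small-RNA
#'   library (no group shift, no latent factor); they anchor small-RNA
#'   size-factor normalization the way miRNAs dominate real small-RNA
#'   libraries.
#' @param te_hr_logfc mean log2 shift of TE expression in HR-MDS
#'   (negative = suppression), averaged over all TE features; the
#'   responsive subset carries \code{te_hr_logfc / responsive_frac}.
#' @param pirna_hr_logfc mean log2 shift of piRNA expression in HR-MDS.
#' @param latent_rho target correlation of the two per-sample latent factors
#'   (total-TE and total-piRNA), in [-1, 1].
#' @param latent_sd standard deviation (log2 scale) of the latent factors.
#' @param responsive_frac fraction of TE and piRNA features that respond to
#'   the group shift and the latent factor (must be < 0.5 so that
#'   median-of-ratios normalization anchors on the stable majority).
#' @param depth_sd standard deviation (log2 scale) of the per-sample
#'   library-depth factor, drawn independently for the RNA-seq and
#'   small-RNA libraries; absorbed by size-factor normalization.
#' @param dispersion negative-binomial dispersion; variance = mu + dispersion
#'   * mu^2. Zero gives Poisson counts.
#' @param piwil2_coupling regression coefficient of PIWIL2 latent
#'   log2-expression on the piRNA signal (group shift + latent factor).
#' @param n_pcg_coupled number of protein-coding genes (beyond PIWIL2)
#'   whose latent log2 expression follows the piRNA signal with unit
#'   coefficient — a co-expression program that correlation-network and
#'   enrichment stages can recover.
#' @param baseline_hazard baseline event rate, events per month.
#' @param hr_group_loghr log hazard ratio of HR-MDS versus LR-MDS.
#' @param censor_time_max upper bound (months) of the uniform censoring time.
#' @param te_class_weights named numeric, expected share of total TE
#'   expression per TE class; must sum to 1.
#' @param seed integer random seed.
#' @return an object of class \code{cohort_config} (a validated list).
#' @export
cohort_config <- function(n_ctr = 17, n_lr = 45, n_hr = 35,
                          n_te = 687, n_pirna = 300, n_pcg = 1000,
                          n_mirna = 300,
                          te_hr_logfc = -0.5, pirna_hr_logfc = 0.5,
                          latent_rho = -0.4, latent_sd = 0.35,
                          responsive_frac = 0.4, depth_sd = 0.15,
                          dispersion = 0.2, piwil2_coupling = 2.0,
                          n_pcg_coupled = 50,
                          baseline_hazard = 0.015,
                          hr_group_loghr = log(2.5),
                          censor_time_max = 72,
                          te_class_weights = c(SINE = 0.79, L1 = 0.15, ERV = 0.06),
                          seed = 1L) {
  cfg <- list(n_ctr = n_ctr, n_lr = n_lr, n_hr = n_hr,
              n_te = n_te, n_pirna = n_pirna, n_pcg = n_pcg,
              n_mirna = n_mirna,
              te_hr_logfc = te_hr_logfc, pirna_hr_logfc = pirna_hr_logfc,
              latent_rho = latent_rho, latent_sd = latent_sd,
              responsive_frac = responsive_frac, depth_sd = depth_sd,
              dispersion = dispersion, piwil2_coupling = piwil2_coupling,
              n_pcg_coupled = n_pcg_coupled,
              baseline_hazard = baseline_hazard,
              hr_group_loghr = hr_group_loghr,
              censor_time_max = censor_time_max,
              te_class_weights = te_class_weights,
              seed = as.integer(seed))
  for (f in c("n_ctr", "n_lr", "n_hr", "n_te", "n_pirna", "n_pcg",
              "n_mirna")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      stop("invalid configuration: '", f, "' must be a positive integer", call. = FALSE)
  }
  for (f in c("latent_sd", "baseline_hazard", "censor_time_max")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop("invalid configuration: '", f, "' must be positive", call. = FALSE)
  }
  if (!is.numeric(cfg$dispersion) || cfg$dispersion < 0)
    stop("invalid configuration: 'dispersion' must be >= 0", call. = FALSE)
  if (abs(cfg$latent_rho) > 1)
    stop("invalid configuration: 'latent_rho' must lie in [-1, 1]", call. = FALSE)
  if (cfg$responsive_frac <= 0 || cfg$responsive_frac >= 0.5)
    stop("invalid configuration: 'responsive_frac' must lie in (0, 0.5)",
         call. = FALSE)
  if (cfg$depth_sd < 0)
    stop("invalid configuration: 'depth_sd' must be >= 0", call. = FALSE)
  if (cfg$n_pcg_coupled < 0)
    stop("invalid configuration: 'n_pcg_coupled' must be >= 0", call. = FALSE)
  cfg$n_pcg_coupled <- min(cfg$n_pcg_coupled, max(cfg$n_pcg - 2, 0))
  if (abs(sum(cfg$te_class_weights) - 1) > 1e-8 || any(cfg$te_class_weights < 0))
    stop("invalid configuration: 'te_class_weights' must be non-negative and sum to 1",
         call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic MDS cohort configuration\n")
  cat(sprintf("  samples: %d CTR / %d LR-MDS / %d HR-MDS\n", x$n_ctr, x$n_lr, x$n_hr))
  cat(sprintf("  features: %d TE, %d piRNA, %d PCG\n", x$n_te, x$n_pirna, x$n_pcg))
  cat(sprintf("  HR-MDS shifts: TE %+.2f log2, piRNA %+.2f log2\n",
              x$te_hr_logfc, x$pirna_hr_logfc))
  cat(sprintf("  latent rho = %.2f, dispersion = %.2f, seed = %d\n",
              x$latent_rho, x$dispersion, x$seed))
  invisible(x)
}

rnb <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic MDS cohort with ground truth
#'
#' Draws count matrices for TEs, piRNAs and protein-coding genes (PCGs),
#' clinical covariates, overall-/progression-free-survival records, a piRNA
#' reference of random sequences, and the latent ground truth used by the
#' generator.
#'
#' Counts are negative binomial with mean
#' \code{baseline * depth * 2^(group shift + latent factor)}, where the
#' group shift and latent factor act only on a responsive minority of
#' features (\code{responsive_frac}); the stable majority varies with
#' library depth alone, so median-of-ratios size factors absorb depth while
#' the shifts and the latent coupling survive in the normalized totals —
#' mirroring real cohorts, where a minority of TEs is dysregulated but the
#' aggregate level shifts. The two per-sample latent factors (one for TEs,
#' one for piRNAs) are bivariate normal with correlation \code{latent_rho},
#' so the induced negative coupling acts on per-sample totals, not on
#' individual feature pairs. PIWIL2's latent log2 mean follows the piRNA
#' signal (group shift + latent factor) scaled by \code{piwil2_coupling};
#' PIWIL4 is independent. Survival times are exponential with log hazard =
#' log(baseline_hazard) + \code{hr_group_loghr}·I(HR-MDS) + covariate and
#' latent terms, censored uniformly on (0, censor_time_max].
#'
#' @param config a [cohort_config()] object.
#' @return a list with elements \code{te_counts}, \code{pirna_counts},
#'   \code{pcg_counts}, \code{mirna_counts} (integer matrices, features x
#'   samples),
#'   \code{te_annotation} (data.frame: id, kind, class, clade),
#'   \code{clinical} (data.frame of covariates incl. group),
#'   \code{survival} (data.frame: sample, endpoint, time, event),
#'   \code{reference} (named character vector of piRNA sequences), and
#'   \code{truth} (latent factors, per-group true means, per-sample piRNA
#'   molecule counts, true log-hazards).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)

  n <- config$n_ctr + config$n_lr + config$n_hr
  samples <- sprintf("S%03d", seq_len(n))
  group <- rep(c("CTR", "LR", "HR"), c(config$n_ctr, config$n_lr, config$n_hr))
  is_hr <- group == "HR"
  is_mds <- group != "CTR"

  ## latent per-sample factors (log2 scale), bivariate normal
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  te_factor <- config$latent_sd * z1
  pirna_factor <- config$latent_sd *
    (config$latent_rho * z1 + sqrt(1 - config$latent_rho^2) * z2)

  ## TE features: class-weighted baselines so expected class shares match
  classes <- names(config$te_class_weights)
  te_class <- sample(classes, config$n_te, replace = TRUE,
                     prob = config$te_class_weights)
  clade_pool <- list(SINE = c("Alu", "MIR"), L1 = "L1",
                     ERV = c("ERV1", "ERV2", "ERV3"))
  te_clade <- vapply(te_class, function(cl) {
    pool <- clade_pool[[cl]]
    if (is.null(pool)) cl else sample(pool, 1)
  }, character(1))
  te_base_raw <- stats::rlnorm(config$n_te, meanlog = log(20), sdlog = 1)
  te_base <- te_base_raw
  total_target <- 50 * config$n_te
  for (cl in classes) {
    idx <- te_class == cl
    if (any(idx))
      te_base[idx] <- te_base_raw[idx] / sum(te_base_raw[idx]) *
        config$te_class_weights[[cl]] * total_target
  }
  te_ids <- sprintf("TE_%04d", seq_len(config$n_te))

  pirna_base <- stats::rlnorm(config$n_pirna, meanlog = log(15), sdlog = 1)
  pirna_ids <- sprintf("piR_%06d", seq_len(config$n_pirna))

  pcg_base <- stats::rlnorm(config$n_pcg, meanlog = log(100), sdlog = 1.2)
  pcg_ids <- sprintf("PCG_%05d", seq_len(config$n_pcg))
  pcg_ids[1:2] <- c("PIWIL2", "PIWIL4")
  pcg_base[1:2] <- c(120, 80)

  mirna_base <- stats::rlnorm(config$n_mirna, meanlog = log(40), sdlog = 1)
  mirna_ids <- sprintf("miR_%04d", seq_len(config$n_mirna))

  ## per-sample HR-MDS shift applied to the responsive feature subset; the
  ## per-feature shift is scaled so the mean over ALL features equals the
  ## configured value
  te_shift <- ifelse(is_hr, config$te_hr_logfc / config$responsive_frac, 0)
  pirna_shift <- ifelse(is_hr, config$pirna_hr_logfc / config$responsive_frac, 0)
  te_resp <- seq_len(config$n_te) <= round(config$responsive_frac * config$n_te)
  pirna_resp <- seq_len(config$n_pirna) <=
    round(config$responsive_frac * config$n_pirna)

  ## independent per-library depth factors (log2 scale)
  depth_rna <- 2^stats::rnorm(n, 0, config$depth_sd)
  depth_srna <- 2^stats::rnorm(n, 0, config$depth_sd)

  ## feature x sample mean matrices
  te_mu <- outer(te_base, depth_rna) *
    2^(outer(te_resp, te_shift + te_factor))
  pirna_mu <- outer(pirna_base, depth_srna) *
    2^(outer(pirna_resp, pirna_shift + pirna_factor))
  pcg_mu <- outer(pcg_base, depth_rna)
  pirna_signal <- ifelse(is_hr, config$pirna_hr_logfc, 0) + pirna_factor
  pcg_mu[1, ] <- pcg_base[1] * depth_rna *
    2^(config$piwil2_coupling * pirna_signal)
  pcg_coupled <- logical(config$n_pcg)
  if (config$n_pcg_coupled > 0) {
    pcg_coupled[seq(3, 2 + config$n_pcg_coupled)] <- TRUE
    pcg_mu[pcg_coupled, ] <- pcg_mu[pcg_coupled, , drop = FALSE] *
      rep(2^pirna_signal, each = config$n_pcg_coupled)
  }

  draw <- function(mu, ids) {
    m <- matrix(rnb(length(mu), as.vector(mu), config$dispersion),
                nrow = nrow(mu), dimnames = list(ids, samples))
    storage.mode(m) <- "integer"
    m
  }
  te_counts <- draw(te_mu, te_ids)
  pirna_counts <- draw(pirna_mu, pirna_ids)
  pcg_counts <- draw(pcg_mu, pcg_ids)
  mirna_counts <- draw(outer(mirna_base, depth_srna), mirna_ids)

  ## clinical covariates; blasts > 5% enriched in HR-MDS
  age <- pmin(pmax(round(stats::rnorm(n, 70, 8)), 25), 95)
  sex <- stats::rbinom(n, 1, 0.45)  # 1 = female
  hemoglobin <- ifelse(is_mds,
                       pmax(stats::rnorm(n, 9.5, 1.8), 4),
                       pmax(stats::rnorm(n, 14, 1), 11))
  platelets <- ifelse(is_mds,
                      stats::rlnorm(n, log(120), 0.6),
                      stats::rlnorm(n, log(250), 0.25))
  neutrophils <- ifelse(is_mds,
                        stats::rlnorm(n, log(1.2), 0.7),
                        stats::rlnorm(n, log(3.5), 0.3))
  blasts <- numeric(n)
  blasts[group == "CTR"] <- stats::runif(sum(group == "CTR"), 0, 2)
  blasts[group == "LR"] <- pmin(stats::rgamma(sum(group == "LR"), 2, scale = 1), 19)
  blasts[group == "HR"] <- pmin(4 + stats::rgamma(sum(group == "HR"), 2, scale = 2.5), 19)
  cyto <- integer(n)
  cyto[group == "LR"] <- sample(0:4, sum(group == "LR"), TRUE,
                                prob = c(.5, .3, .15, .04, .01))
  cyto[group == "HR"] <- sample(0:4, sum(group == "HR"), TRUE,
                                prob = c(.15, .25, .3, .2, .1))
  ipssr <- rep(NA_real_, n)
  ipssr[group == "LR"] <- round(stats::runif(sum(group == "LR"), 1, 3.5), 1)
  ipssr[group == "HR"] <- round(stats::runif(sum(group == "HR"), 4, 8), 1)

  clinical <- data.frame(sample = samples, group = group, age = age,
                         sex = sex, blasts = round(blasts, 1),
                         hemoglobin = round(hemoglobin, 1),
                         platelets = round(platelets, 1),
                         neutrophils = round(neutrophils, 2),
                         cytogenetics = cyto, ipssr = ipssr,
                         stringsAsFactors = FALSE)

  ## survival for MDS patients: exponential hazard with group, age,
  ## platelet-ordinal and latent (piRNA-high / TE-low) terms
  plt_ord <- ifelse(platelets < 50, 2, ifelse(platelets < 100, 1, 0))
  loghaz <- log(config$baseline_hazard) +
    config$hr_group_loghr * is_hr +
    0.05 * (age - 70) + 0.5 * plt_ord +
    0.4 * (pirna_factor - te_factor) / config$latent_sd
  surv_list <- lapply(c(OS = 1, PFS = 1.5), function(mult) {
    t_ev <- stats::rexp(n, rate = exp(loghaz) * mult)
    t_cn <- stats::runif(n, 0, config$censor_time_max)
    data.frame(sample = samples,
               time = round(pmax(pmin(t_ev, t_cn), 0.1), 2),
               event = as.integer(t_ev <= t_cn),
               stringsAsFactors = FALSE)
  })
  survival <- rbind(
    cbind(surv_list$OS, endpoint = "OS"),
    cbind(surv_list$PFS, endpoint = "PFS"))
  survival <- survival[survival$sample %in% samples[is_mds],
                       c("sample", "endpoint", "time", "event")]
  rownames(survival) <- NULL

  ## piRNA reference: unique random sequences, lengths 24-34 nt
  ref_len <- sample(24:34, config$n_pirna, replace = TRUE)
  reference <- vapply(ref_len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  while (anyDuplicated(reference)) {
    d <- which(duplicated(reference))
    reference[d] <- vapply(ref_len[d], function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  }
  names(reference) <- pirna_ids

  truth <- list(
    latent = data.frame(sample = samples, group = group,
                        te_factor = te_factor, pirna_factor = pirna_factor,
                        stringsAsFactors = FALSE),
    te_group_means = cbind(
      CTR = te_base, LR = te_base,
      HR = te_base * 2^(te_resp * config$te_hr_logfc / config$responsive_frac)),
    pirna_group_means = cbind(
      CTR = pirna_base, LR = pirna_base,
      HR = pirna_base *
        2^(pirna_resp * config$pirna_hr_logfc / config$responsive_frac)),
    te_responsive = te_resp, pirna_responsive = pirna_resp,
    pcg_coupled = pcg_ids[pcg_coupled],
    pirna_molecules = pirna_counts,   # molecule counts before PCR duplication
    loghaz = data.frame(sample = samples, loghaz = loghaz,
                        stringsAsFactors = FALSE))
  rownames(truth$te_group_means) <- te_ids
  rownames(truth$pirna_group_means) <- pirna_ids

  te_annotation <- data.frame(id = te_ids, kind = "TE", class = te_class,
                              clade = te_clade, stringsAsFactors = FALSE)

  list(te_counts = te_counts, pirna_counts = pirna_counts,
       pcg_counts = pcg_counts, mirna_counts = mirna_counts,
       te_annotation = te_annotation,
       clinical = clinical, survival = survival,
       reference = reference, truth = truth, config = config)
}

#' Generate a synthetic small-RNA FASTQ library
#'
#' Emulates a stranded small-RNA library with the layout
#' insert + 3' adapter + UMI, padded with random bases to a fixed read
#' length. Each true molecule receives one random UMI; PCR duplicates reuse
#' the molecule's UMI; sequencing errors are uniform per-base substitutions
#' applied to the insert.
#'
#' @param molecules named integer vector (or two-column data.frame
#'   feature/count) of true molecule counts per piRNA feature.
#' @param reference named character vector of piRNA sequences (the features
#'   in \code{molecules} must all be present).
#' @param adapter 3' adapter sequence.
#' @param umi_len UMI length in bases (>= 1).
#' @param dup_rate mean number of PCR duplicates per molecule (Poisson).
#' @param error_rate per-base substitution probability in the insert.
#' @param read_length reads shorter than this are padded with random bases.
#' @param path optional FASTQ output path (plain or .gz); written when given.
#' @param seed optional random seed.
#' @return invisibly, a data.frame with one row per read (read_id, feature,
#'   umi, sequence) and attribute \code{path} when a file was written.
#' @export
generate_reads <- function(molecules, reference,
                           adapter = "AACTGTAGGCACCATCAAT", umi_len = 12,
                           dup_rate = 0, error_rate = 0, read_length = 83,
                           path = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(molecules)) {
    m <- molecules[[2]]
    names(m) <- molecules[[1]]
    molecules <- m
  }
  if (umi_len < 1) stop("umi_len must be >= 1", call. = FALSE)
  molecules <- molecules[molecules > 0]
  unknown <- setdiff(names(molecules), names(reference))
  if (length(unknown))
    stop("molecules reference unknown sequences: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)

  feature <- rep(names(molecules), molecules)
  n_mol <- length(feature)
  if (n_mol == 0) {
    reads <- data.frame(read_id = character(), feature = character(),
                        umi = character(), sequence = character())
  } else {
    umi <- random_dna(n_mol, umi_len)
    n_reads <- 1L + stats::rpois(n_mol, dup_rate)
    feature <- rep(feature, n_reads)
    umi <- rep(umi, n_reads)
    insert <- unname(reference[feature])
    if (error_rate > 0) {
      ins_chars <- strsplit(insert, "", fixed = TRUE)
      insert <- vapply(ins_chars, function(ch) {
        hit <- stats::runif(length(ch)) < error_rate
        if (any(hit)) {
          ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        }
        paste(ch, collapse = "")
      }, character(1))
    }
    seq_full <- paste0(insert, adapter, umi)
    pad <- pmax(read_length - nchar(seq_full), 0)
    if (any(pad > 0)) {
      pads <- vapply(pad, function(k)
        if (k == 0) "" else paste(sample(c("A", "C", "G", "T"), k, TRUE),
                                  collapse = ""), character(1))
      seq_full <- paste0(seq_full, pads)
    }
    reads <- data.frame(read_id = sprintf("read_%06d", seq_along(seq_full)),
                        feature = feature, umi = umi, sequence = seq_full,
                        stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    if (nrow(reads)) {
      writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                        strrep("I", nchar(reads$sequence))), con)
    }
    attr(reads, "path") <- path
  }
  invisible(reads)
}

#' Write cohort tables to a directory
#'
#' Emits TSV count matrices (first column = feature id) with a companion
#' annotation table, clinical and survival TSVs, the piRNA reference FASTA,
#' the latent-truth TSV, and a YAML run manifest recording the seed.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(te_counts = file.path(dir, "te_counts.tsv"),
             mirna_counts = file.path(dir, "mirna_counts.tsv"),
             pirna_counts = file.path(dir, "pirna_counts.tsv"),
             pcg_counts = file.path(dir, "pcg_counts.tsv"),
             annotation = file.path(dir, "feature_annotation.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             survival = file.path(dir, "survival.tsv"),
             reference = file.path(dir, "pirna_reference.fasta"),
             truth = file.path(dir, "latent_truth.tsv"),
             manifest = file.path(dir, "manifest.yaml"))
  write_count_tsv(cohort$te_counts, paths["te_counts"])
  write_count_tsv(cohort$pirna_counts, paths["pirna_counts"])
  write_count_tsv(cohort$pcg_counts, paths["pcg_counts"])
  write_count_tsv(cohort$mirna_counts, paths["mirna_counts"])
  ann <- rbind(cohort$te_annotation,
               data.frame(id = rownames(cohort$pirna_counts), kind = "piRNA",
                          class = "piRNA", clade = "piRNA"),
               data.frame(id = rownames(cohort$pcg_counts), kind = "PCG",
                          class = "PCG", clade = "PCG"))
  utils::write.table(ann, paths["annotation"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$survival, paths["survival"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$reference),
                              paths["reference"])
  utils::write.table(cohort$truth$latent, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(seed = cohort$config$seed,
                        groups = list(CTR = cohort$config$n_ctr,
                                      LR = cohort$config$n_lr,
                                      HR = cohort$config$n_hr),
                        files = as.list(basename(paths))),
                   paths["manifest"])
  invisible(paths)
}

write_count_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a count matrix written by [write_cohort()]
#' @param path TSV path, first column = feature identifier.
#' @return integer matrix, features x samples.
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
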