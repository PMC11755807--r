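#' Pipeline run configuration
#'
#' Assembles stage toggles and parameters for [run_pipeline()]. With
#' \code{simulate = TRUE} the synthetic cohort supplies every input;
#' otherwise count matrices, clinical and survival tables are read from the
#' paths in \code{inputs} (TSV, as written by [write_cohort()]).
#'
#' @param out_dir output directory.
#' @param cohort a [cohort_config()] for the simulate stage.
#' @param stages character vector of stages to run, a subset of
#'   \code{c("simulate", "quantify", "dea", "aggstats", "survive",
#'   "network", "enrich")}.
#' @param inputs named list of file paths (te_counts, pirna_counts,
#'   pcg_counts, annotation, clinical, survival) used when \code{simulate}
#'   is disabled.
#' @param adapter,umi_len small-RNA read layout for the quantify stage.
#' @param quantify_samples number of samples whose libraries are simulated
#'   and re-quantified as a read-level verification.
#' @param dup_rate,error_rate PCR duplication and sequencing error rates for
#'   the simulated libraries.
#' @param fdr_mds_ctr,fdr_lr_hr FDR cutoffs for the two differential
#'   expression contrasts (MDS vs CTR; LR vs HR).
#' @param network_seeds molecules to use as module seeds; defaults to
#'   PIWIL2 plus the strongest LR-vs-HR differential TE and piRNA.
#' @param k neighbors followed per node in module extraction.
#' @param panel_size number of most-variable molecules per kind entering the
#'   correlation panel.
#' @param gene_sets optional GMT path for the enrichment stage; when NULL,
#'   sets are sampled from the simulated PCG universe.
#' @param n_perm GSEA permutations.
#' @param endpoint survival endpoint for stratified analyses
#'   (\code{"OS"} or \code{"PFS"}).
#' @param seed global seed recorded in the manifest and used for every
#'   stochastic stage.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_config(),
                            stages = c("simulate", "quantify", "dea",
                                       "aggstats", "survive", "network",
                                       "enrich"),
                            inputs = list(),
                            adapter = "AACTGTAGGCACCATCAAT", umi_len = 12,
                            quantify_samples = 2, dup_rate = 1,
                            error_rate = 0,
                            fdr_mds_ctr = 0.05, fdr_lr_hr = 0.001,
                            network_seeds = NULL, k = 10, panel_size = 40,
                            gene_sets = NULL, n_perm = 200,
                            endpoint = "OS", seed = 1L) {
  known <- c("simulate", "quantify", "dea", "aggstats", "survive", "network",
             "enrich")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("configuration error: unknown stage '", bad[1], "'", call. = FALSE)
  if (!endpoint %in% c("OS", "PFS"))
    stop("configuration error: endpoint must be OS or PFS", call. = FALSE)
  cfg <- as.list(environment())
  cfg$known <- NULL
  cfg$bad <- NULL
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(report, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  report$log <- c(report$log, sprintf("[%s] %s", stage, msg))
  report
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in order: cohort simulation, read-level piRNA
#' quantification (on a few sample libraries, verified against the
#' generator's truth), differential expression (TE and piRNA; MDS vs CTR and
#' LR vs HR), total levels / TE:piRNA ratio / control-cutoff stratification
#' with group tests, survival analyses (Kaplan-Meier + log-rank per
#' stratification; multivariate Cox with IPSS-R ordinals and stepwise
#' selection), seed-centered correlation modules, and enrichment (GSEA on
#' the ratio contrast plus per-module ORA). Writes stage outputs and a YAML
#' manifest under \code{out_dir}; any stage failure aborts with the stage
#' name, keeping partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return a report list: per-stage summaries, output paths, manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), log = character())
  stage <- "init"
  on_fail <- function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  withCallingHandlers({
    ## ---- simulate / load ----
    stage <- "simulate"
    if ("simulate" %in% config$stages) {
      cohort <- generate_cohort(config$cohort)
      paths <- write_cohort(cohort, file.path(config$out_dir, "cohort"))
      report <- stage_log(report, stage, "%d samples, %d TE / %d piRNA / %d PCG features",
                          ncol(cohort$te_counts), nrow(cohort$te_counts),
                          nrow(cohort$pirna_counts), nrow(cohort$pcg_counts))
      report$stages$simulate <- list(n_samples = ncol(cohort$te_counts),
                                     paths = paths)
    } else {
      ins <- config$inputs
      need <- c("te_counts", "pirna_counts", "pcg_counts", "clinical",
                "survival")
      miss <- setdiff(need, names(ins))
      if (length(miss))
        stop("inputs missing for disabled simulate stage: ",
             paste(miss, collapse = ", "))
      cohort <- list(
        te_counts = read_count_tsv(ins$te_counts),
        pirna_counts = read_count_tsv(ins$pirna_counts),
        pcg_counts = read_count_tsv(ins$pcg_counts),
        clinical = utils::read.table(ins$clinical, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE),
        survival = utils::read.table(ins$survival, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE),
        truth = NULL, reference = NULL)
      if (!is.null(ins$annotation))
        cohort$te_annotation <- utils::read.table(ins$annotation, header = TRUE,
                                                  sep = "\t",
                                                  stringsAsFactors = FALSE)
      if (!is.null(ins$mirna_counts))
        cohort$mirna_counts <- read_count_tsv(ins$mirna_counts)
      report <- stage_log(report, stage, "loaded inputs from files (%d samples)",
                          ncol(cohort$te_counts))
    }
    group <- stats::setNames(cohort$clinical$group, cohort$clinical$sample)
    is_mds <- group != "CTR"

    ## ---- quantify ----
    stage <- "quantify"
    if ("quantify" %in% config$stages) {
      if (is.null(cohort$reference))
        stop("quantify stage needs the simulated reference")
      ref <- pirna_reference(cohort$reference)
      qdir <- file.path(config$out_dir, "quantify")
      n_q <- min(config$quantify_samples, ncol(cohort$pirna_counts))
      agree <- logical(n_q)
      for (i in seq_len(n_q)) {
        mol <- cohort$truth$pirna_molecules[, i]
        fq <- file.path(tempdir(), sprintf("lib_%02d.fastq", i))
        generate_reads(stats::setNames(mol, rownames(cohort$pirna_counts)),
                       cohort$reference, adapter = config$adapter,
                       umi_len = config$umi_len, dup_rate = config$dup_rate,
                       error_rate = config$error_rate, path = fq,
                       seed = config$seed + i)
        q <- quantify_pirnas(fq, ref, adapter = config$adapter,
                             umi_len = config$umi_len)
        truth_tab <- mol[mol > 0]
        got <- stats::setNames(q$counts$dedup_count, q$counts$representative_id)
        got <- got[names(truth_tab)]
        got[is.na(got)] <- 0L
        agree[i] <- all(got == truth_tab)
        write_pirna_counts(q, file.path(qdir, sprintf("sample_%02d", i)))
        unlink(fq)
      }
      report <- stage_log(report, stage,
                          "%d libraries re-quantified, truth agreement in %d/%d",
                          n_q, sum(agree), n_q)
      report$stages$quantify <- list(n_libraries = n_q, agree = agree)
    }

    ## ---- differential expression ----
    stage <- "dea"
    if ("dea" %in% config$stages) {
      ddir <- file.path(config$out_dir, "dea")
      dir.create(ddir, showWarnings = FALSE, recursive = TRUE)
      contrasts <- list(
        mds_ctr = list(sel = rep(TRUE, length(group)),
                       g = factor(ifelse(is_mds, "MDS", "CTR"),
                                  c("CTR", "MDS")),
                       fdr = config$fdr_mds_ctr),
        lr_hr = list(sel = is_mds,
                     g = factor(ifelse(is_mds, group, NA), c("LR", "HR")),
                     fdr = config$fdr_lr_hr))
      anchors <- list(te = cohort$pcg_counts, pirna = cohort$mirna_counts,
                      pcg = NULL)
      dea_out <- list()
      for (cn in names(contrasts)) {
        ct <- contrasts[[cn]]
        for (kind in c("te", "pirna", "pcg")) {
          cm <- cohort[[paste0(kind, "_counts")]][, ct$sel, drop = FALSE]
          cm <- cm[rowSums(cm) > 0, , drop = FALSE]
          anc <- anchors[[kind]]
          sf <- if (is.null(anc)) size_factors(cm)
          else size_factors(rbind(anc[, ct$sel, drop = FALSE], cm))
          dea <- nb_wald_test(cm, ct$g[ct$sel], factors = sf)
          sig <- call_significant(dea, ct$fdr)
          utils::write.table(dea, file.path(ddir, sprintf("dea_%s_%s.tsv",
                                                          kind, cn)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          dea_out[[paste(kind, cn, sep = "_")]] <-
            list(dea = dea, sig = sig, fdr = ct$fdr)
          report <- stage_log(report, stage, "%s %s: %d/%d significant at FDR<%g",
                              kind, cn, nrow(sig), nrow(dea), ct$fdr)
        }
      }
      report$stages$dea <- lapply(dea_out, function(d)
        list(n_sig = nrow(d$sig), n_tested = nrow(d$dea)))
    }

    ## ---- aggregate statistics ----
    stage <- "aggstats"
    te_norm <- library_normalize(cohort$te_counts, cohort$pcg_counts)
    pirna_norm <- library_normalize(cohort$pirna_counts, cohort$mirna_counts)
    totals <- sample_totals(te_norm, pirna_norm, group)
    if ("aggstats" %in% config$stages) {
      adir <- file.path(config$out_dir, "aggstats")
      dir.create(adir, showWarnings = FALSE, recursive = TRUE)
      is_ctrl <- totals$group == "CTR"
      rules <- list(
        te = control_cutoff(totals$total_te, is_ctrl, "control-minimum",
                            "total_te"),
        pirna = control_cutoff(totals$total_pirna, is_ctrl, "control-maximum",
                               "total_pirna"),
        ratio = control_cutoff(totals$ratio, is_ctrl, "control-minimum",
                               "ratio"))
      totals$te_stratum <- apply_cutoff(rules$te, totals$total_te)
      totals$pirna_stratum <- apply_cutoff(rules$pirna, totals$total_pirna)
      totals$ratio_stratum <- apply_cutoff(rules$ratio, totals$ratio)

      cor_tp <- pearson_cor(totals$total_te, totals$total_pirna)
      lr <- totals$group == "LR"; hr <- totals$group == "HR"
      t_te <- welch_t(totals$total_te[hr], totals$total_te[lr])
      t_pi <- welch_t(totals$total_pirna[hr], totals$total_pirna[lr])
      t_ratio <- welch_t(totals$ratio[hr], totals$ratio[lr])
      comp <- if (!is.null(cohort$te_annotation))
        te_composition(te_norm, stats::setNames(cohort$te_annotation$class,
                                                cohort$te_annotation$id))
      else NULL

      utils::write.table(totals, file.path(adir, "sample_totals.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(comp))
        utils::write.table(data.frame(class = names(comp$cohort_mean),
                                      mean_fraction = comp$cohort_mean),
                           file.path(adir, "te_composition.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      report <- stage_log(report, stage,
                          "TE~piRNA r = %.3f (p = %.2g); HR-vs-LR Welch p: TE %.2g, piRNA %.2g, ratio %.2g",
                          cor_tp$r, cor_tp$p, t_te$p, t_pi$p, t_ratio$p)
      report$stages$aggstats <- list(pearson = cor_tp,
                                     welch = list(te = t_te, pirna = t_pi,
                                                  ratio = t_ratio),
                                     cutoffs = lapply(rules, `[[`, "cutoff"),
                                     composition = comp$cohort_mean,
                                     totals = totals)
    }

    ## ---- survival ----
    stage <- "survive"
    if ("survive" %in% config$stages) {
      sdir <- file.path(config$out_dir, "survival")
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      sv <- cohort$survival[cohort$survival$endpoint == config$endpoint, ]
      sv <- merge(sv, totals, by = "sample")
      sv <- sv[sv$group != "CTR", ]
      strat_res <- list()
      risk_side <- c(te_stratum = "low", pirna_stratum = "high",
                     ratio_stratum = "low")
      for (st in intersect(names(risk_side), names(sv))) {
        lab <- sv[[st]]
        if (nlevels(droplevels(lab)) == 2 && sum(sv$event) >= 1) {
          lt <- logrank_test(sv$time, sv$event, lab)
          uni <- cox_fit(sv$time, sv$event,
                         matrix(as.integer(lab == risk_side[[st]]),
                                dimnames = list(NULL,
                                                paste0(st, "_", risk_side[[st]]))))
          med <- tapply(seq_len(nrow(sv)), lab, function(ix)
            km_curve(sv$time[ix], sv$event[ix])$median)
          strat_res[[st]] <- list(logrank = lt, cox = uni$table,
                                  median = med)
          report <- stage_log(report, stage,
                              "%s %s: log-rank p = %.3g, HR(low) = %.2f",
                              config$endpoint, st, lt$p, uni$table$HR[1])
        }
      }
      ## multivariate Cox with IPSS-R ordinals + stepwise selection
      cl <- cohort$clinical[match(sv$sample, cohort$clinical$sample), ]
      ord <- ipssr_ordinalize(cl)
      Xmva <- cbind(age = cl$age, female = cl$sex, ord,
                    ratio_low = as.integer(sv$ratio_stratum == "low"))
      sw <- stepwise_cox(sv$time, sv$event, Xmva)
      if (!is.null(sw$model))
        utils::write.table(sw$model$table,
                           file.path(sdir, sprintf("mva_%s.tsv",
                                                   config$endpoint)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      report <- stage_log(report, stage, "stepwise MVA (%s) retained: %s",
                          config$endpoint,
                          if (length(sw$selected))
                            paste(sw$selected, collapse = ", ") else "<none>")
      report$stages$survive <- list(strata = strat_res, stepwise = sw,
                                    endpoint = config$endpoint)
    }

    ## ---- network ----
    stage <- "network"
    if ("network" %in% config$stages) {
      ndir <- file.path(config$out_dir, "network")
      top_var <- function(m, n) {
        nm <- normalize_counts(m)
        v <- apply(log2(nm + 1), 1, stats::var)
        nm[order(-v)[seq_len(min(n, nrow(nm)))], , drop = FALSE]
      }
      panel <- rbind(top_var(cohort$pcg_counts, config$panel_size),
                     top_var(cohort$te_counts, config$panel_size),
                     top_var(cohort$pirna_counts, config$panel_size))
      kind <- rep(c("PCG", "TE", "piRNA"),
                  c(min(config$panel_size, nrow(cohort$pcg_counts)),
                    min(config$panel_size, nrow(cohort$te_counts)),
                    min(config$panel_size, nrow(cohort$pirna_counts))))
      if (!"PIWIL2" %in% rownames(panel)) {
        panel <- rbind(normalize_counts(cohort$pcg_counts)["PIWIL2", ,
                                                           drop = FALSE],
                       panel)
        kind <- c("PCG", kind)
      }
      graph <- build_correlation_graph(panel,
                                       stats::setNames(kind, rownames(panel)))
      seeds <- config$network_seeds
      if (is.null(seeds)) seeds <- "PIWIL2"
      seeds <- intersect(seeds, rownames(graph$cor))
      mods <- list()
      for (sd in seeds) {
        mod <- extract_module(graph, sd, config$k)
        mod <- filter_module_edges(mod, graph)
        export_module(mod, graph, ndir)
        mods[[sd]] <- mod
        report <- stage_log(report, stage,
                            "seed %s: %d members, %d edges above Q3 = %.3f",
                            sd, length(mod$members), nrow(mod$edges),
                            mod$threshold)
      }
      report$stages$network <- list(modules = mods, graph_nodes = nrow(graph$cor))
    }

    ## ---- enrichment ----
    stage <- "enrich"
    if ("enrich" %in% config$stages) {
      edir <- file.path(config$out_dir, "enrich")
      dir.create(edir, showWarnings = FALSE, recursive = TRUE)
      ## rank PCGs by the Wald statistic of the ratio-stratum contrast
      strat <- totals$ratio_stratum
      if (is.null(strat)) {
        is_ctrl <- totals$group == "CTR"
        strat <- apply_cutoff(control_cutoff(totals$ratio, is_ctrl,
                                             "control-minimum", "ratio"),
                              totals$ratio)
      }
      sel <- !is.na(strat)
      pcg <- cohort$pcg_counts[rowSums(cohort$pcg_counts) > 0, sel,
                               drop = FALSE]
      dea <- nb_wald_test(pcg, factor(strat[sel], c("low", "high")))
      z <- stats::qnorm(pmax(dea$p / 2, 1e-300), lower.tail = FALSE) *
        sign(dea$log2FC)
      scores <- stats::setNames(z, dea$feature)
      sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
      else {
        set.seed(config$seed)
        rnd <- stats::setNames(lapply(1:20, function(i)
          sample(dea$feature, 25)), sprintf("RANDOM_SET_%02d", 1:20))
        if (!is.null(cohort$truth) && length(cohort$truth$pcg_coupled))
          c(list(PIRNA_PROGRAM = cohort$truth$pcg_coupled), rnd)
        else rnd
      }
      gsea <- gsea_significance(scores, sets, n_perm = config$n_perm,
                                seed = config$seed)
      utils::write.table(gsea, file.path(edir, "gsea_ratio_contrast.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report <- stage_log(report, stage, "GSEA: %d/%d sets at FDR < 0.2",
                          sum(gsea$fdr < 0.2, na.rm = TRUE), nrow(gsea))
      ora <- NULL
      if (!is.null(report$stages$network)) {
        universe <- dea$feature
        for (sd in names(report$stages$network$modules)) {
          mod <- report$stages$network$modules[[sd]]
          mg <- intersect(mod$members, universe)
          if (length(mg) >= 2) {
            ora <- ora_hypergeom(mg, universe, sets)
            utils::write.table(ora, file.path(edir, sprintf("ora_%s.tsv", sd)),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            report <- stage_log(report, stage, "ORA %s: top set %s (p = %.2g)",
                                sd, ora$set[1], ora$pval[1])
          }
        }
      }
      report$stages$enrich <- list(gsea = gsea, ora = ora)
    }
  }, error = on_fail)

  ## ---- manifest ----
  manifest <- list(
    seed = config$seed,
    stages_run = config$stages,
    endpoint = config$endpoint,
    counts = lapply(report$stages, function(s)
      if (!is.null(s$n_sig)) s$n_sig else NULL),
    log = report$log)
  mpath <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  report$manifest <- mpath
  report$manifest_hash <- unname(tools::md5sum(mpath))
  report
}
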