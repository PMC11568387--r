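#' @importFrom jsonlite write_json toJSON
#' @importFrom yaml read_yaml write_yaml
NULL

#' Default pipeline configuration
#'
#' A plain named list holding every stage threshold (with the defaults used
#' throughout the package), stage toggles and the global seed. Round-trips
#' through YAML ([readPipelineConfig()] / [writePipelineConfig()]).
#'
#' @param seed global integer seed; re-seeds the simulation and every
#'   randomized stage.
#' @param sim named list of [simConfig()] overrides.
#' @param ... scalar overrides of top-level entries (e.g. `peak_q = 0.01`,
#'   `stages = list(differential = FALSE)`).
#' @return named list.
#' @export
pipelineConfig <- function(seed = 1L, sim = list(), ...) {
  cfg <- list(
    seed = as.integer(seed),
    sim = sim,
    peak_q = 0.05, peak_min_fold = 2, peak_window = 500L,
    min_support = 2L, max_length = 10000L,
    presence_min_replicates = 1L,
    diff_q = 0.05,
    overlap_n_perm = 200L,
    assoc_q = 0.05, maf_min = 0.05, max_missing = 0.25, qual_min = 30,
    motif_sig = 1e-4, motif_ratio = 1.5,
    pbs_quantile = 0.95,
    stages = list(differential = TRUE, overlap = TRUE, association = TRUE,
                  pbs = TRUE, motifs = TRUE)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "stages") cfg$stages[names(dots$stages)] <- dots$stages
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  raw <- read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' @rdname pipelineConfig
#' @param config a pipeline configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  write_yaml(config, path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end synthetic analysis
#'
#' Executes the full chain on simulated data: genome + enhancer truths +
#' counts + variants, per-replicate peak calling, consensus construction,
#' activity quantification and population presence, gene assignment and
#' convergent-target classification, differential activity, region-overlap
#' permutation testing against the simulated conserved-element set, pooled
#' allele-frequency association, outgroup polarization, PBS with outlier
#' flagging, motif allele effects and the direction-of-effect test battery.
#' Every statistic, threshold and seed lands in the returned report; the
#' run is fully deterministic given the configuration.
#'
#' @param config a [pipelineConfig()] list, or a YAML path.
#' @return nested list report (serialize with [writeReport()]).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  sim_args <- config$sim
  sim_args$seed <- config$seed
  cfg <- do.call(simConfig, sim_args)
  study <- .stage("simulate", simulateStudy(cfg))
  truths <- study$truths

  peaks <- .stage("peaks", callPeaksAll(
    study$counts, q_threshold = config$peak_q,
    min_fold = config$peak_min_fold, window = config$peak_window))
  consensus <- .stage("consensus", buildConsensus(
    peaks, min_support = config$min_support, max_length = config$max_length))
  act <- .stage("activity", quantifyActivity(consensus, study$counts))
  presence <- .stage("presence", populationPresence(
    consensus, peaks, study$design,
    min_replicates = config$presence_min_replicates))

  recall <- if (length(truths)) mean(overlapsAny(truths, consensus)) else NA
  precision <- if (length(consensus)) mean(overlapsAny(consensus, truths))
  else NA

  assign_strict <- .stage("assignment", assignGenes(
    consensus, study$annotation, mode = "strict"))
  spec_sum <- specificitySummary(presence, assign_strict)
  conv <- convergentTargets(presence, assign_strict, study$design)

  report <- list(
    config = config[setdiff(names(config), "sim")],
    sim = list(n_truth_enhancers = length(truths),
               n_genes = sum(mcols(study$annotation)$type == "gene"),
               n_snps = nrow(study$variants$snps)),
    peaks = list(n_per_replicate = lengths(peaks)),
    consensus = list(n = length(consensus),
                     mean_width = if (length(consensus))
                       mean(width(consensus)) else NA,
                     recall = recall, precision = precision),
    presence = list(
      frac_conserved = if (nrow(presence)) mean(rowSums(presence) ==
                                                  ncol(presence)) else NA,
      frac_single = if (nrow(presence)) mean(rowSums(presence) == 1) else NA),
    genes = list(n_with_enhancer = nrow(spec_sum),
                 multi_enhancer_trend = multiEnhancerTrend(spec_sum),
                 n_social_only = sum(conv$convergence_class == "social_only"),
                 n_solitary_only = sum(conv$convergence_class ==
                                         "solitary_only"),
                 mechanism_table = table(conv$convergence_class,
                                         conv$mechanism))
  )

  diff_res <- NULL
  if (isTRUE(config$stages$differential)) {
    diff_res <- .stage("differential", fitDifferential(act, config$diff_q))
    bias_sets <- classifyBias(diff_res)
    # power over planted-bias truths (the detectable effect class); FDR
    # against anything class-differential in expectation, planted bias or
    # class-asymmetric activity pattern alike
    truth_planted <- truths[mcols(truths)$sociality_bias != "none"]
    truth_classdiff <- truths[abs(mcols(truths)$expected_class_diff) > 1e-9]
    sig <- diff_res$q_value < config$diff_q
    dae_power <- if (length(truth_planted))
      mean(overlapsAny(truth_planted, consensus[sig])) else NA
    dae_fdr <- if (any(sig))
      mean(!overlapsAny(consensus[sig], truth_classdiff)) else NA
    report$differential <- list(
      n_tested = nrow(diff_res), n_significant = sum(sig),
      n_social_biased = length(bias_sets$social),
      n_solitary_biased = length(bias_sets$solitary),
      power = dae_power, fdr = dae_fdr)
  }

  if (isTRUE(config$stages$overlap)) {
    genome <- setNames(rep(cfg@chrom_length, cfg@n_chromosomes),
                       paste0("chr", seq_len(cfg@n_chromosomes)))
    ov <- .stage("overlap", permutationOverlapTest(
      consensus, study$cnees, genome, n_perm = config$overlap_n_perm,
      seed = config$seed))
    ov$representation_factor_2dp <- round(ov$representation_factor, 2)
    report$overlap <- ov
  }

  assoc <- NULL
  snps_pol <- NULL
  if (isTRUE(config$stages$association) && nrow(study$variants$snps)) {
    snps <- .stage("variant_filter", filterVariants(
      study$variants$snps, maf_min = config$maf_min,
      max_missing = config$max_missing, qual_min = config$qual_min))
    assoc <- .stage("association", suppressWarnings(
      associateActivity(snps, act, consensus)))
    og <- study$variants$outgroup
    snps_pol <- polarize(snps, outgroup = og$allele[
      match(paste(snps$chrom, snps$pos),
            paste(og$chrom, og$pos))])
    assoc <- directionOfEffect(assoc, snps_pol)
    sig <- assoc$q_value < config$assoc_q
    causal <- snps$b[match(assoc$snp, snps$id)] != 0
    report$association <- list(
      n_filtered_snps = nrow(snps), n_tested = nrow(assoc),
      n_significant = sum(sig),
      power = if (any(causal)) mean(sig[causal]) else NA,
      fdr = if (any(sig)) mean(!causal[sig]) else NA,
      polarization_rate = mean(snps_pol$derived_allele != "unresolved"))
  }

  pbs_res <- NULL
  if (isTRUE(config$stages$pbs) && nrow(study$variants$snps)) {
    pbs_res <- .stage("pbs", computePbs(study$variants$genotypes,
                                        quantile_prob = config$pbs_quantile))
    sel <- study$variants$snps$selected[
      match(pbs_res$id, study$variants$snps$id)]
    enr <- if (any(pbs_res$outlier_social, na.rm = TRUE) && mean(sel) > 0)
      mean(sel[pbs_res$outlier_social], na.rm = TRUE) / mean(sel) else NA
    report$pbs <- list(n_sites = nrow(pbs_res),
                       mean_pbs_social = mean(pbs_res$pbs_social,
                                              na.rm = TRUE),
                       mean_pbs_solitary = mean(pbs_res$pbs_solitary,
                                                na.rm = TRUE),
                       n_outlier_social = sum(pbs_res$outlier_social,
                                              na.rm = TRUE),
                       selected_site_enrichment = enr)
  }

  if (isTRUE(config$stages$motifs)) {
    pwm <- Pwm("planted", matrix(c(
      0.97, 0.01, 0.01, 0.01,  0.01, 0.97, 0.01, 0.01,
      0.01, 0.01, 0.97, 0.01,  0.97, 0.01, 0.01, 0.01,
      0.01, 0.01, 0.01, 0.97,  0.01, 0.97, 0.01, 0.01,
      0.97, 0.01, 0.01, 0.01,  0.01, 0.01, 0.97, 0.01), 4))
    wins <- simulateAlleleWindows(pwm, n = 20L, seed = config$seed)
    eff <- .stage("motifs", do.call(rbind, lapply(seq_len(nrow(wins)),
      function(i) {
        d <- alleleEffect(wins$window_ref[i], wins$window_alt[i],
                          list(pwm), sig = config$motif_sig,
                          ratio_threshold = config$motif_ratio)
        d$snp <- wins$snp[i]; d$disrupting <- wins$disrupting[i]
        d
      })))
    report$motifs <- list(
      n_snps = nrow(wins),
      n_with_effect = sum(eff$effect != "none"),
      effect_recall = if (any(wins$disrupting))
        mean(eff$effect[eff$disrupting] != "none") else NA)
  }

  if (!is.null(diff_res) && !is.null(assoc) && !is.null(pbs_res) &&
      nrow(assoc)) {
    cls <- rep("non-DAE", nrow(assoc))
    bias <- diff_res$bias[match(assoc$enhancer, diff_res$enhancer)]
    cls[bias == "social"] <- "social-biased DAE"
    cls[bias == "solitary"] <- "solitary-biased DAE"
    sites <- data.frame(
      class = cls, derived_direction = assoc$derived_direction,
      pbs_social = pbs_res$pbs_social[match(assoc$snp, pbs_res$id)],
      pbs_solitary = pbs_res$pbs_solitary[match(assoc$snp, pbs_res$id)])
    sites <- sites[assoc$q_value < config$assoc_q, , drop = FALSE]
    if (sum(sites$derived_direction %in% c("increase", "decrease")) >= 5L)
      report$direction_tests <- .stage("direction_tests", {
        ct <- contingencyTests(sites)
        list(table = as.data.frame.matrix(ct$table),
             chisq = ct$chisq,
             binomial = lapply(ct$binomial, function(b)
               b[c("n", "frac_increase", "p_value")]),
             kruskal = ct$kruskal)
      })
  }
  report
}

#' Serialize a pipeline report
#'
#' Writes `report.json` (all statistics, thresholds and seeds; stable
#' across reruns of the same configuration) and a short Markdown summary
#' `report.md`.
#'
#' @param report output of [runPipeline()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_json(report, file.path(dir, "report.json"), auto_unbox = TRUE,
             digits = 10, force = TRUE, pretty = TRUE)
  md <- c("# STARR-seq analysis report", "",
          sprintf("- consensus enhancers: %s", report$consensus$n),
          sprintf("- planted-enhancer recall %.3f, precision %.3f",
                  report$consensus$recall, report$consensus$precision))
  if (!is.null(report$differential))
    md <- c(md, sprintf(
      "- differential enhancers (q < %s): %d (%d social-, %d solitary-biased)",
      report$config$diff_q, report$differential$n_significant,
      report$differential$n_social_biased,
      report$differential$n_solitary_biased))
  if (!is.null(report$overlap))
    md <- c(md, sprintf(
      "- conserved-element overlap: observed %d vs permuted mean %.1f (RF %.2f, p %.4g)",
      report$overlap$observed_overlap, report$overlap$perm_mean,
      report$overlap$representation_factor, report$overlap$empirical_p))
  if (!is.null(report$association))
    md <- c(md, sprintf(
      "- SNP-activity associations (q < %s): %d of %d tested",
      report$config$assoc_q, report$association$n_significant,
      report$association$n_tested))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
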