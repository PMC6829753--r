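## End-to-end orchestration: simulate -> segment -> features -> cluster ->
## DMR -> imprint/XCI -> mCH, with every stage's thresholds named once in
## the run configuration and a JSON summary for provenance.

#' Default pipeline configuration
#'
#' All analysis thresholds appear here once, named, at their conventional
#' values: PMDs are segments > 10 kb below 70% mean mCG; features are 100-kb
#' windows, 2-kb promoters and TSS +/- 500 bp regions; DMRs need >= 20 CpGs,
#' q < 0.01 and > 30% difference, and proximal genes lie within 5 kb; iDMR
#' bands are [0.25, 0.75]; XCI calls use male <= 10%, female 20-45%, escape
#' <= 5%; CG/CH coverage minima are 1 and 10; the expression pseudocount is
#' 0.01; ICA contributors need |loading| >= 5; hyper/hypo-DMR k-means use
#' k = 5 and k = 2; gene-set terms are filtered to 10-500 genes, reported at
#' p < 0.01 with >= 3 genes.
#'
#' @param seed master seed.
#' @param outdir output directory.
#' @param genome a [genome_config()].
#' @param design a cohort design data.frame.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("methylscape_run_"),
                            genome = genome_config(),
                            design = default_cohort_design()) {
  structure(list(
    seed = as.integer(seed), outdir = outdir,
    genome = genome, design = design,
    pmd_min_size = 10000, pmd_max_level = 0.70,
    segmentation_penalty = 1.0, segmentation_min_sites = 20,
    window_width = 1e5, promoter_upstream = 2000, tss_flank = 500,
    dmr_min_cpg = 20, dmr_max_q = 0.01, dmr_min_diff = 0.30,
    proximal_max_dist = 5000,
    idmr_hypo_max = 0.25, idmr_hyper_min = 0.75,
    xci_male_max = 0.10, xci_female_range = c(0.20, 0.45),
    xci_escape_max = 0.05, xci_min_sites = 5,
    cov_min_cg = 1, cov_min_ch = 10,
    expr_pseudocount = 0.01,
    ica_loading_threshold = 5,
    kmeans_k_hyper = 5, kmeans_k_hypo = 2,
    go_min_term = 10, go_max_term = 500, go_max_p = 0.01, go_min_overlap = 3
  ), class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the genome and cohort, segments each methylome and calls PMDs,
#' builds promoter feature matrices and runs the three clustering workflows,
#' calls iRPE-vs-nRPE DMRs with k-means and origin/fate classification,
#' summarizes iDMR status, XCI candidates and escape, and profiles mCH —
#' writing stage outputs and a JSON summary under `config$outdir`.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages to run (default all); earlier
#'   stages a later one depends on are always run.
#' @return list with the stage results and `summary` (the JSON-ready list).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "segment", "cluster", "dmr",
                                    "xci", "mch")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  summary <- list(seed = config$seed)

  genome <- generate_genome(config$genome, seed = config$seed)
  cohort <- simulate_cohort(genome, config$design, seed = config$seed)
  res$genome <- genome; res$cohort <- cohort
  write_genome_annotations(genome, file.path(config$outdir, "annotations"))
  write.table(cohort$manifest, file.path(config$outdir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  design <- cohort$manifest

  if ("segment" %in% stages) {
    pmds <- list(); pmd_mb <- numeric(0)
    for (s in names(cohort$samples)) {
      dom <- segment_methylome(cohort$samples[[s]],
                               penalty = config$segmentation_penalty,
                               min_sites = config$segmentation_min_sites)
      pm <- call_pmds(dom, config$pmd_min_size, config$pmd_max_level)
      pmds[[s]] <- pm
      pmd_mb[s] <- sum(pm$end - pm$start) / 1e6
      utils::write.table(mdl_table(dom),
                         file.path(config$outdir, paste0("mdl_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res$pmds <- pmds
    summary$pmd_mb <- as.list(round(pmd_mb, 3))
  }

  if ("cluster" %in% stages) {
    feats <- standard_features(genome, window_width = config$window_width,
                               promoter_upstream = config$promoter_upstream,
                               tss_flank = config$tss_flank)
    prom_auto <- autosomal_only(feats$promoters, genome$autosomes)
    fm <- feature_means(cohort$samples, prom_auto)
    res$promoter_matrix <- fm
    hc_raw <- cluster_raw(fm)
    ica <- run_ica(fm, seed = config$seed)
    pca <- run_pca(fm)
    hc_ica <- cluster_components(ica)
    hc_pca <- cluster_components(pca)
    res$clustering <- list(raw = hc_raw, ica = hc_ica, pca = hc_pca,
                           ica_dec = ica, pca_dec = pca)
    labels <- stats::setNames(design$state, design$sample_id)
    summary$clustering <- list(
      raw_clades = clades_recovered(hc_raw, labels),
      pca_clades = clades_recovered(hc_pca, labels),
      ica_clades = clades_recovered(hc_ica, labels)
    )
    rep_s <- design$sample_id[design$reprogrammed]
    non_s <- design$sample_id[!design$reprogrammed]
    if (length(rep_s) && length(non_s)) {
      dc <- discriminating_component(ica, rep_s, non_s)
      summary$clustering$reprogramming_component <- dc$component[1]
      summary$clustering$reprogramming_p <- dc$p_value[1]
    }
    for (nm in c("raw", "ica", "pca")) {
      write_newick(res$clustering[[nm]],
                   file.path(config$outdir, paste0("dendro_", nm, ".nwk")))
    }
  }

  if ("dmr" %in% stages) {
    irpe <- cohort$samples[design$sample_id[design$state == "iRPE"]]
    nrpe <- cohort$samples[design$sample_id[design$state == "nRPE"]]
    dmrs <- call_dmrs(irpe, nrpe, min_cpg = config$dmr_min_cpg,
                      max_q = config$dmr_max_q, min_diff = config$dmr_min_diff)
    res$dmrs <- dmrs
    summary$dmr <- list(n_hyper = sum(dmrs$direction == "hyper"),
                        n_hypo = sum(dmrs$direction == "hypo"),
                        mb_hyper = round(sum((dmrs$end - dmrs$start)[dmrs$direction == "hyper"]) / 1e6, 4),
                        mb_hypo = round(sum((dmrs$end - dmrs$start)[dmrs$direction == "hypo"]) / 1e6, 4))
    if (nrow(dmrs) > 0) {
      ## state means over DMR intervals (ESC reference simulated on demand)
      esc <- simulate_methylome(genome,
                                cell_state_params("ESC", genome = genome),
                                seed = child_seed(config$seed, "ESC_ref"))
      by_state <- split(design$sample_id, design$state)
      dgr <- dmrs_to_granges(dmrs)
      state_means <- sapply(c("Fibro", "iPSC", "iRPE", "xRPE", "cRPE", "nRPE"),
        function(st) {
          rowMeans(feature_means(cohort$samples[by_state[[st]]], dgr)$levels,
                   na.rm = TRUE)
        })
      state_means <- cbind(state_means,
                           esc = feature_means(list(esc = esc), dgr)$levels[, 1])
      colnames(state_means) <- c("fib", "ipsc", "irpe", "xrpe", "crpe",
                                 "nrpe", "esc")
      of <- classify_origin_fate(state_means, dmrs$direction)
      dmrs$origin <- of$origin; dmrs$fate <- of$fate
      prox <- proximal_genes(dmrs, genome$genes, config$proximal_max_dist)
      hyper_g <- unique(prox$gene_id[dmrs$direction[prox$dmr] == "hyper"])
      hypo_g <- unique(prox$gene_id[dmrs$direction[prox$dmr] == "hypo"])
      summary$dmr$proximal <- proximal_gene_summary(hyper_g, hypo_g)
      summary$dmr$origin <- as.list(table(dmrs$origin))
      res$dmrs <- dmrs
      write_dmrs(dmrs, file.path(config$outdir, "dmrs.bed"),
                 file.path(config$outdir, "dmrs.tsv"))
    }
  }

  if ("xci" %in% stages) {
    ist <- idmr_status(genome$idmrs, cohort$samples,
                       hypo_max = config$idmr_hypo_max,
                       hyper_min = config$idmr_hyper_min)
    summary$idmr <- idmr_summary(ist$status)
    res$idmr <- ist
    tss <- tss_regions(genome, config$tss_flank)
    x_tss <- tss[as.character(seqnames(tss)) == genome$x_chrom]
    nonrep <- design[!design$reprogrammed, ]
    fem <- cohort$samples[nonrep$sample_id[nonrep$sex == "F"]]
    mal <- cohort$samples[nonrep$sample_id[nonrep$sex == "M"]]
    if (length(fem) && length(mal)) {
      cand <- xci_candidates(x_tss, fem, mal,
                             male_max = config$xci_male_max,
                             female_range = config$xci_female_range,
                             min_sites = config$xci_min_sites)
      rep_f <- design$sample_id[design$reprogrammed & design$sex == "F"]
      esc <- NULL
      if (length(rep_f)) {
        rl <- feature_means(cohort$samples[rep_f], x_tss,
                            min_sites = config$xci_min_sites)$levels
        rownames(rl) <- mcols(x_tss)$gene_id
        esc <- xci_escape(cand, rl, max_level = config$xci_escape_max)
      }
      res$xci <- list(candidates = cand, escape = esc)
      summary$xci <- list(
        n_callable = attr(cand, "n_callable"),
        n_subject = sum(cand$status == "XCI-subject"),
        pct_subject = round(100 * attr(cand, "fraction_subject"), 1),
        n_escaped = if (!is.null(esc)) attr(esc, "n_escaped"),
        pct_escaped = if (!is.null(esc))
          round(100 * attr(esc, "fraction_escaped"), 1)
      )
    }
  }

  if ("mch" %in% stages) {
    profs <- lapply(cohort$samples, mch_levels, min_cov = config$cov_min_ch)
    res$mch <- profs
    summary$mch <- lapply(profs, function(p) {
      list(chg = round(p$chg, 4), chh = round(p$chh, 4),
           top_context = context_ranking(p)[1])
    })
    utils::write.table(mch_radar_table(profs),
                       file.path(config$outdir, "mch_contexts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$summary <- summary
  res
}
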