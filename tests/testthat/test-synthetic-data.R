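test_that("genome generation is deterministic and validates its invariants", {
  cfg <- small_genome_config()
  g1 <- generate_genome(cfg, seed = 3)
  g2 <- generate_genome(cfg, seed = 3)
  expect_identical(g1$cpg, g2$cpg)
  expect_identical(as.data.frame(g1$cgis), as.data.frame(g2$cgis))
  expect_identical(g1$xci_subject, g2$xci_subject)
  g3 <- generate_genome(cfg, seed = 4)
  expect_false(identical(g1$cpg, g3$cpg))

  ## same seed -> byte-identical annotation files
  d1 <- file.path(tempdir(), "ann1"); d2 <- file.path(tempdir(), "ann2")
  write_genome_annotations(g1, d1); write_genome_annotations(g2, d2)
  for (f in c("cgi.bed", "lad.bed", "idmr.bed", "genes.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  ## catalogue of exactly 50 disjoint imprinted DMRs
  expect_length(g1$idmrs, 50)
  expect_true(GenomicRanges::isDisjoint(g1$idmrs))

  ## every gene has exactly one TSS, all intervals within bounds
  expect_false(anyDuplicated(paste(GenomicRanges::seqnames(g1$genes),
                                   S4Vectors::mcols(g1$genes)$tss)) > 0)
  expect_silent(validate_genome(g1))
})

test_that("invalid genome configurations are rejected", {
  expect_error(genome_config(autosome_lengths = c(chr1 = 5e5)), "1 Mb")
  expect_error(genome_config(cgi_cpg_spacing = 200), "density")
  expect_error(genome_config(n_xci_escaped = 500, n_xci_subject = 394),
               "gene-set")
  expect_error(cell_state_params("Melanocyte"), "unknown cell state")
})

test_that("simulated methylomes converge to the planted probabilities", {
  g <- fx_small_genome()
  pr <- cell_state_params("Fibro", genome = g)
  st <- simulate_methylome(g, pr, seed = 21)
  probs <- site_probabilities(g, pr)

  ## fibroblast PMDs: mean mCG inside LADs lower than outside by ~ the
  ## planted depth (0.35)
  cg <- merge_symmetric_cpg(st[st$context == "CG", ])
  cg <- cg[cg$total > 0, ]
  cg_auto <- cg[cg$chrom != g$x_chrom, ]
  inlad <- IRanges::overlapsAny(
    GenomicRanges::GRanges(cg_auto$chrom, IRanges::IRanges(cg_auto$pos, width = 1)),
    g$lads)
  gap <- mean(cg_auto$meth[!inlad] / cg_auto$total[!inlad]) -
    mean(cg_auto$meth[inlad] / cg_auto$total[inlad])
  expect_gt(gap, 0.25)   # depressed by PMDs (CGIs etc. dilute the contrast)
  expect_lt(gap, 0.45)

  ## global site-level agreement with the planted truth within binomial error
  cg_df <- as.data.frame(cg)
  for (chrom in names(g$cpg)) {
    d <- cg_df[cg_df$chrom == chrom, ]
    truth <- probs$cpg[[chrom]]
    obs <- mean(d$meth / d$total)
    exp_mean <- mean(truth * (1 - pr$nonconversion) + (1 - truth) * pr$nonconversion)
    se <- sd(truth) / sqrt(length(truth)) + 0.002
    expect_lt(abs(obs - exp_mean), 3 * se + 0.01)
  }
})

test_that("non-conversion produces the expected error floor on unmethylated CH", {
  g <- fx_small_genome()
  pr <- cell_state_params("Fibro", genome = g,
                          mch_rates = setNames(rep(0, 12),
                                               names(cell_state_params("Fibro")$mch_rates)))
  st <- simulate_methylome(g, pr, seed = 5)
  p <- mch_levels(st)
  ## true mCH 0, non-conversion 0.005 -> observed ~ 0.005
  expect_lt(abs(mean(p$contexts, na.rm = TRUE) - 0.005), 0.0015)
})

test_that("cohort simulation enforces lineage memory and the 16-sample design", {
  g <- fx_small_genome()
  coh <- fx_small_cohort()
  expect_length(coh$samples, 16)
  expect_identical(sort(unique(coh$manifest$state)),
                   sort(c("Fibro", "iPSC", "iRPE", "xRPE", "cRPE", "nRPE")))

  ## reprogrammed samples of one patient share the same planted errors
  p <- coh$params
  expect_identical(p$iPSC1$cgi_errors, p$iRPE1$cgi_errors)
  expect_identical(p$iRPE1$cgi_errors, p$xRPE1$cgi_errors)
  expect_identical(p$iPSC1$idmr_hyper, p$xRPE1$idmr_hyper)
  expect_identical(p$iPSC1$xci_escaped, p$iRPE1$xci_escaped)
  ## ... and absent from non-reprogrammed cells
  for (s in c("Fibro1", "cRPE1", "nRPE1")) {
    expect_length(p[[s]]$cgi_errors, 0)
    expect_length(p[[s]]$idmr_hyper, 0)
  }
  ## patient 2 carries extra iDMR errors
  expect_gt(length(p$iPSC2$idmr_hyper), length(p$iPSC1$idmr_hyper))
  ## iRPE and xRPE of one patient share their PMD footprint
  expect_identical(p$iRPE1$pmd_lads, p$xRPE1$pmd_lads)

  ## determinism of the manifest; single-state design
  coh2 <- simulate_cohort(g, seed = 11)
  expect_identical(coh$manifest, coh2$manifest)
  one <- simulate_cohort(g, data.frame(sample_id = "s1", state = "nRPE",
                                       patient = "donor1", sex = "F"),
                         seed = 2)
  expect_length(one$samples, 1)
  expect_error(simulate_cohort(g, data.frame(sample_id = "s1", state = "HeLa",
                                             patient = "p", sex = "F")),
               "unknown states")
})

test_that("per-context mCH ranking matches the planted cell-state rates", {
  g <- fx_small_genome()
  nrpe <- simulate_methylome(g, cell_state_params("nRPE", genome = g), seed = 7)
  ipsc <- simulate_methylome(g, cell_state_params("iPSC", genome = g), seed = 7)
  expect_identical(context_ranking(mch_levels(nrpe))[1], "CAC")
  expect_identical(context_ranking(mch_levels(ipsc))[1], "CAG")
  ## nRPE: CAA/CAG/CAT/CTC occupy the next ranks after CAC
  expect_setequal(context_ranking(mch_levels(nrpe))[2:5],
                  c("CAA", "CAG", "CAT", "CTC"))
})

test_that("expression simulation couples planted methylation to FPKM", {
  g <- fx_small_genome()
  design <- default_cohort_design()
  fpkm <- simulate_expression(g, design, seed = 31)
  expect_true(all(fpkm >= 0))
  expect_identical(colnames(fpkm), design$sample_id)

  ## escaped genes ~2-fold derepressed in the reprogrammed female sample
  er <- expression_ratio(fpkm, "iRPE1", "cRPE4",
                         set_a = g$xci_escaped,
                         set_b = setdiff(g$xci_subject, g$xci_escaped))
  expect_lt(abs(attr(er, "median_a") - 1), 0.25)
  expect_lt(abs(attr(er, "median_b")), 0.2)

  ## zero coupling -> expression independent of planted structure
  f0 <- simulate_expression(g, design,
                            coupling = list(promoter = 0, dmr = 0,
                                            escape_fold = 1),
                            seed = 31)
  er0 <- expression_ratio(f0, "iRPE1", "cRPE4",
                          set_a = g$xci_escaped,
                          set_b = setdiff(g$xci_subject, g$xci_escaped))
  expect_lt(abs(attr(er0, "median_a")), 0.25)

  ## planted inverse gene-body mCH coupling is recoverable: gene-body mCH in
  ## nRPE anticorrelates with expression
  nrpe <- simulate_methylome(g, cell_state_params("nRPE", genome = g), seed = 8)
  gb <- autosomal_only(standard_features(g)$genebodies, g$autosomes)
  mm <- feature_means(list(nRPE1 = nrpe), gb, context = "CH")
  rownames(mm$levels) <- S4Vectors::mcols(gb)$gene_id
  mc <- mch_expression_correlation(mm$levels, fpkm, samples = "nRPE1")
  expect_lt(mc$rho, -0.3)
})
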