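test_that("iDMR status bands classify levels and summarize fractions", {
  idmrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:50 * 1000, width = 100))
  S4Vectors::mcols(idmrs)$name <- paste0("iDMR_", 1:50)
  ## constructed levels: patient 1 with 6 hyper, patient 2 with 6 + 13 hyper
  lv1 <- rep(0.5, 50); lv1[1:6] <- 0.9
  lv2 <- rep(0.5, 50); lv2[1:19] <- 0.9
  lv <- cbind(iRPE1 = lv1, iRPE2 = lv2)
  st <- idmr_status(idmrs, levels = lv)
  expect_equal(st$status[1, "iRPE1"], "hyper")
  expect_equal(st$status[10, "iRPE1"], "intermediate")
  sm <- idmr_summary(st$status)
  expect_equal(sm$pct_hyper[sm$sample == "iRPE1"], 12)   # 6 of 50
  expect_equal(sm$pct_hyper[sm$sample == "iRPE2"], 38)   # 19 of 50
  expect_equal(sm$frac_hyper, c(6, 19) / 50)

  ## band edges: 0.5 intermediate, extremes, NA uncallable
  lv3 <- cbind(s = c(0.5, 0.76, 0.24, NA, 0.75, 0.25))
  st3 <- idmr_status(idmrs[1:6], levels = lv3)
  expect_equal(unname(st3$status[, 1]),
               c("intermediate", "hyper", "hypo", "uncallable",
                 "intermediate", "intermediate"))
})

test_that("planted hyper-iDMRs are recovered from the simulated cohort", {
  g <- fx_small_genome()
  coh <- fx_small_cohort()
  st <- idmr_status(g$idmrs, coh$samples)
  called1 <- rownames(st$status)[st$status[, "iRPE1"] == "hyper"]
  called2 <- rownames(st$status)[st$status[, "iRPE2"] == "hyper"]
  expect_setequal(called1, g$idmr_error_shared)
  expect_setequal(called2, union(g$idmr_error_shared, g$idmr_error_patient2))
  ## non-reprogrammed samples stay intermediate
  expect_true(all(st$status[, "nRPE1"] == "intermediate"))
})

test_that("XCI candidate thresholds are respected at the boundaries", {
  tss <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1:5 * 10000, width = 1001))
  S4Vectors::mcols(tss)$gene_id <- paste0("x", 1:5)
  ## craft site tables with exact per-region levels
  mk <- function(levels, depth = 50L) {
    rows <- lapply(seq_along(levels), function(i) {
      pos <- seq(GenomicRanges::start(tss)[i],
                 GenomicRanges::end(tss)[i], by = 100L)
      data.frame(chrom = "chrX", pos = pos, strand = "+", context = "CG",
                 meth = as.integer(round(levels[i] * depth)), total = depth)
    })
    do.call(rbind, rows)
  }
  fem <- list(f1 = mk(c(0.33, 0.33, 0.33, 0.46, 0.18)))
  mal <- list(m1 = mk(c(0.05, 0.12, 0.10, 0.05, 0.05)))
  cand <- xci_candidates(tss, fem, mal)
  expect_equal(cand$status,
               c("XCI-subject",  # male .05, female .33
                 "not-XCI",      # male .12 above the 10% cut
                 "XCI-subject",  # male exactly .10
                 "not-XCI",      # female .46 above the band
                 "not-XCI"))     # female .18 below the band
  expect_equal(attr(cand, "n_callable"), 5)

  ## monotone: tightening the female band never adds XCI-subject genes
  base_set <- cand$gene_id[cand$status == "XCI-subject"]
  for (band in list(c(0.22, 0.45), c(0.20, 0.40), c(0.25, 0.35))) {
    tighter <- xci_candidates(tss, fem, mal, female_range = band)
    expect_true(all(tighter$gene_id[tighter$status == "XCI-subject"] %in%
                      base_set))
  }
})

test_that("escape calls require hypomethylation in all reprogrammed samples", {
  cand <- data.frame(gene_id = c("x1", "x2", "x3"),
                     male_mean = 0.05, female_mean = 0.33,
                     status = "XCI-subject", stringsAsFactors = FALSE)
  rl <- rbind(x1 = c(0.03, 0.04, 0.02),
              x2 = c(0.03, 0.06, 0.02),
              x3 = c(0.05, 0.05, 0.05))
  colnames(rl) <- c("iPSC1", "iRPE1", "xRPE1")
  esc <- xci_escape(cand, rl)
  expect_equal(esc$escaped, c(TRUE, FALSE, TRUE))  # 0.06 breaks the all rule
  esc_any <- xci_escape(cand, rl, all_samples = FALSE)
  expect_true(all(esc_any$escaped))
  expect_error(xci_escape(cand[0, ], rl), "no XCI-subject")
})

test_that("worked fractions: 394/773 callable and 45/394 escaped", {
  ## constructed classifier inputs reproducing the printed counts
  n <- 773
  tss <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1:n * 2000, width = 1001))
  S4Vectors::mcols(tss)$gene_id <- paste0("x", 1:n)
  f_lv <- c(rep(0.33, 394), rep(0.05, 379))
  m_lv <- rep(0.05, n)
  cand <- data.frame(gene_id = paste0("x", 1:n), male_mean = m_lv,
                     female_mean = f_lv,
                     status = ifelse(f_lv > 0.2, "XCI-subject", "not-XCI"),
                     stringsAsFactors = FALSE)
  expect_equal(round(100 * sum(cand$status == "XCI-subject") / n), 51)
  rl <- matrix(rep(c(rep(0.02, 45), rep(0.33, 349)), 3), ncol = 3,
               dimnames = list(paste0("x", 1:394), c("iPSC1", "iRPE1", "xRPE1")))
  esc <- xci_escape(cand, rl)
  expect_equal(attr(esc, "n_escaped"), 45)
  expect_equal(round(100 * attr(esc, "fraction_escaped")), 11)
})

test_that("expression ratios follow the pseudocount formula", {
  fpkm <- matrix(c(1, 1, 1, 0), 2, 2,
                 dimnames = list(c("g1", "g2"), c("a", "b")))
  er <- expression_ratio(fpkm, "a", "b")
  expect_equal(er$log2_ratio[1], 0)                       # 1 vs 1
  expect_equal(er$log2_ratio[2], log2(1.01 / 0.01),
               tolerance = 1e-12)                         # ~6.658
  expect_error(expression_ratio(fpkm, "a", "b", pseudocount = 0))
})
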