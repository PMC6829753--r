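test_that("the caller detects a planted region with the right direction", {
  ## 30-CpG, ~1-kb-scale region with delta = 0.5, 2 vs 2 samples
  tg <- make_two_group(n_sites = 3000, n1 = 2, n2 = 2, base = 0.4,
                       regions = data.frame(start_idx = 1500, end_idx = 1529,
                                            delta = 0.5),
                       depth = 10, seed = 5)
  dmrs <- call_dmrs(tg$g1, tg$g2, min_cpg = 20)
  expect_gte(nrow(dmrs), 1)
  hit <- dmrs[dmrs$start < tg$pos[1529] & dmrs$end > tg$pos[1500], ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$direction, "hyper")
  expect_lt(abs(hit$diff - 0.5), 0.12)
  ## every emitted DMR satisfies all three filters
  expect_true(all(dmrs$n_cpg >= 20))
  expect_true(all(dmrs$q_value < 0.01))
  expect_true(all(abs(dmrs$diff) > 0.30))
  ## members are non-overlapping
  expect_true(GenomicRanges::isDisjoint(dmrs_to_granges(dmrs)))
})

test_that("a 15-CpG planted region is rejected by the CpG-count filter", {
  tg <- make_two_group(n_sites = 2000, n1 = 2, n2 = 2, base = 0.4,
                       regions = data.frame(start_idx = 1000, end_idx = 1014,
                                            delta = 0.5),
                       depth = 10, seed = 6)
  dmrs <- call_dmrs(tg$g1, tg$g2, min_cpg = 20)
  expect_false(any(dmrs$start < tg$pos[1014] & dmrs$end > tg$pos[1000]))
  ## the same region passes when the filter allows it
  dmrs2 <- call_dmrs(tg$g1, tg$g2, min_cpg = 10)
  expect_true(any(dmrs2$start < tg$pos[1014] & dmrs2$end > tg$pos[1000]))
})

test_that("identical groups yield no DMRs", {
  for (seed in 1:3) {
    tg <- make_two_group(n_sites = 4000, n1 = 2, n2 = 4, base = 0.7,
                         regions = NULL, depth = 10, seed = seed)
    dmrs <- call_dmrs(tg$g1, tg$g2)
    expect_equal(nrow(dmrs), 0, info = paste("seed", seed))
  }
})

test_that("sex chromosomes are excluded by default", {
  tg <- make_two_group(n_sites = 2000, n1 = 2, n2 = 2, base = 0.3,
                       regions = data.frame(start_idx = 900, end_idx = 940,
                                            delta = 0.5), seed = 7)
  gx <- lapply(tg$g1, function(d) { d$chrom <- "chrX"; d })
  g2x <- lapply(tg$g2, function(d) { d$chrom <- "chrX"; d })
  expect_equal(nrow(call_dmrs(gx, g2x)), 0)
  expect_gt(nrow(call_dmrs(gx, g2x, exclude_chroms = character(0))), 0)
})

test_that("k-means separates planted profile archetypes deterministically", {
  set.seed(1)
  prof <- rbind(
    matrix(rep(c(0.9, 0.9, 0.1), each = 30), 30) + rnorm(90, 0, 0.03),
    matrix(rep(c(0.1, 0.2, 0.9), each = 20), 20) + rnorm(60, 0, 0.03)
  )
  colnames(prof) <- c("ipsc", "irpe", "nrpe")
  km <- kmeans_dmrs(prof, k = 2, seed = 3)
  expect_equal(km$sizes, c(30L, 20L))
  expect_equal(length(unique(km$cluster[1:30])), 1)
  expect_equal(length(unique(km$cluster[31:50])), 1)
  ## numbering by descending iPSC-state level: cluster 1 is the high-iPSC one
  expect_equal(unique(km$cluster[1:30]), 1L)
  ## determinism
  km2 <- kmeans_dmrs(prof, k = 2, seed = 3)
  expect_identical(km$cluster, km2$cluster)
  ## k = 1: centroid is the grand mean
  km1 <- kmeans_dmrs(prof, k = 1)
  expect_equal(unname(km1$centers[1, ]), unname(colMeans(prof)),
               tolerance = 1e-9)
  ## missing values imputed by the state mean
  profNA <- prof; profNA[1, 2] <- NA
  expect_silent(kmeans_dmrs(profNA, k = 2, seed = 3))
})

test_that("origin classification follows the iPSC/ESC tracing rules", {
  sm <- data.frame(
    ipsc = c(0.8, 0.8, 0.1, 0.8, 0.8, NA),
    esc  = c(0.8, 0.8, 0.1, 0.1, 0.8, 0.5),
    irpe = c(0.8, 0.1, 0.1, 0.8, 0.1, 0.5),
    xrpe = c(0.2, 0.1, 0.1, 0.8, 0.1, 0.5),
    nrpe = c(0.1, 0.8, 0.45, 0.1, 0.45, 0.5)
  )
  dir <- c("hyper", "hypo", "hypo", "hyper", "hypo", "hyper")
  of <- classify_origin_fate(sm, dir)
  expect_equal(of$origin, c("demethylation-error", "maintenance-error",
                            "de-novo-error", "reprogramming-error",
                            "maintenance-error", "unclassified"))
  ## fate: row 1 moved to the nRPE level in xRPE -> resolved
  expect_equal(of$fate[1], "resolved-in-xRPE")
  expect_equal(of$fate[2], "persistent")
  expect_true(is.na(of$fate[6]))
  ## row order does not matter
  of_r <- classify_origin_fate(sm[5:1, ], dir[5:1])
  expect_equal(of_r$origin, rev(of$origin[1:5]))
})

test_that("proximal genes respect the 5-kb gap rule and union counting", {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(10000, 30000, 60000), c(12000, 32000, 62000)))
  S4Vectors::mcols(genes)$gene_id <- c("g1", "g2", "g3")
  dmrs <- data.frame(chrom = "chr1",
                     start = c(4000, 17001, 54998),
                     end = c(4999, 18000, 54999),
                     direction = c("hyper", "hyper", "hypo"))
  px <- proximal_genes(dmrs, genes, max_dist = 5000)
  ## DMR1 ends at 4999 (0-based) -> gap to gene at 10000 is 5000: proximal
  expect_true(any(px$dmr == 1 & px$gene_id == "g1"))
  ## DMR2 gap 5001 bp combinations: [17001,18000) to 30000 -> gap 11999: no
  expect_false(any(px$dmr == 2))
  ## boundary: gap exactly 5001 -> not proximal
  d2 <- data.frame(chrom = "chr1", start = 4000, end = 4999)
  expect_equal(nrow(proximal_genes(d2, genes, max_dist = 5000)), 1)
  d3 <- data.frame(chrom = "chr1", start = 3998, end = 4998)
  expect_equal(nrow(proximal_genes(d3, genes, max_dist = 5000)), 0)

  ## union counting de-duplicates genes hit by both directions
  s <- proximal_gene_summary(c("a", "b", "c"), c("c", "d"))
  expect_equal(s$n_union, 4)
  expect_equal(s$n_both, 1)
})

test_that("proximal genes equal a brute-force all-pairs distance scan", {
  for (seed in 1:4) {
    set.seed(seed)
    gs <- sort(sample(50000, 8))
    genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(gs, gs + 999))
    S4Vectors::mcols(genes)$gene_id <- paste0("g", 1:8)
    ds <- sort(sample(50000, 10))
    dmrs <- data.frame(chrom = "chr1", start = ds, end = ds + 499)
    px <- proximal_genes(dmrs, genes, max_dist = 3000)
    ## oracle: gap = max(0, start2 - end1 - 1) over both orders (1-based)
    found <- matrix(FALSE, 10, 8)
    for (i in 1:10) for (j in 1:8) {
      d_s <- ds[i] + 1; d_e <- ds[i] + 500
      g_s <- gs[j]; g_e <- gs[j] + 999
      gap <- if (d_e < g_s) g_s - d_e - 1 else if (g_e < d_s) d_s - g_e - 1 else 0
      found[i, j] <- gap <= 3000
    }
    got <- matrix(FALSE, 10, 8)
    if (nrow(px)) got[cbind(px$dmr, match(px$gene_id, paste0("g", 1:8)))] <- TRUE
    expect_identical(got, found, info = paste("seed", seed))
  }
})

test_that("CGI flank profiles and the PMD co-occurrence test behave", {
  ## single CGI: profile equals its own binned levels
  pos <- seq(100L, by = 50L, length.out = 400)
  prob <- ifelse(pos >= 5000 & pos <= 6000, 0.9, 0.1)
  st <- make_cg_table(pos, prob, depth = 30, seed = 9)
  cgi <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 6000))
  pf <- cgi_flank_profile(cgi, st, flank = 2000, flank_bins = 4, body_bins = 4)
  expect_equal(nrow(pf), 12)
  body <- pf$mean_level[pf$zone == "cgi"]
  flank <- pf$mean_level[pf$zone != "cgi"]
  expect_true(all(body > 0.8, na.rm = TRUE))
  expect_true(all(flank < 0.2, na.rm = TRUE))

  ## planted co-occurrence of CGI hypermethylation and flank PMDs
  set.seed(10)
  hyper <- c(rep(TRUE, 30), rep(FALSE, 170))
  flank_pmd <- ifelse(hyper, runif(200) < 0.8, runif(200) < 0.1)
  co <- cgi_pmd_cooccurrence(hyper, flank_pmd)
  expect_gt(co$odds_ratio, 1)
  expect_lt(co$p_value, 0.01)
  ## independence: odds ratio near 1, p not extreme
  co0 <- cgi_pmd_cooccurrence(runif(500) < 0.3, runif(500) < 0.3)
  expect_gt(co0$p_value, 0.001)
})
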