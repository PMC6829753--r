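test_that("change-point segmentation recovers planted piecewise-constant blocks", {
  ## 0.85 | 0.45 | 0.85, 500 sites per block
  pos <- seq(100L, by = 150L, length.out = 1500)
  prob <- rep(c(0.85, 0.45, 0.85), each = 500)
  st <- make_cg_table(pos, prob, depth = 10, seed = 42)
  dom <- segment_methylome(st)
  expect_equal(nrow(dom), 3)
  expect_equal(dom$n_cpg, c(500, 500, 500), tolerance = 5 / 500)  # +-5 sites
  expect_lt(abs(dom$mean_level[2] - 0.45), 0.03)
  expect_lt(abs(dom$mean_level[1] - 0.85), 0.03)

  ## domains tile the covered block without overlap
  expect_true(all(dom$start[-1] == dom$end[-nrow(dom)]))

  ## nCpG-weighted mean of domain levels equals the overall site mean
  m <- merge_symmetric_cpg(st)
  m <- m[m$total > 0, ]
  expect_equal(sum(dom$mean_level * dom$n_cpg) / sum(dom$n_cpg),
               mean(m$meth / m$total), tolerance = 1e-12)
})

test_that("constant methylomes give one domain; infinite penalty forces one", {
  pos <- seq(100L, by = 150L, length.out = 800)
  st <- make_cg_table(pos, rep(0.8, 800), seed = 3)
  expect_equal(nrow(segment_methylome(st)), 1)

  st2 <- make_cg_table(pos, rep(c(0.85, 0.45), each = 400), seed = 4)
  expect_equal(nrow(segment_methylome(st2, penalty = Inf)), 1)
  expect_gt(nrow(segment_methylome(st2)), 1)

  ## too few sites: chromosome skipped with a warning
  tiny <- make_cg_table(seq(100L, by = 150L, length.out = 10), rep(0.5, 10))
  expect_warning(out <- segment_methylome(tiny), "fewer than")
  expect_equal(nrow(out), 0)
})

test_that("PMD calling applies the strict >10 kb and <70% thresholds", {
  dom <- data.frame(
    chrom = "chr1",
    start = c(0, 20000, 40000, 100000),
    end = c(15000, 30000, 90000, 200000),
    n_cpg = 100L,
    mean_level = c(0.55, 0.50, 0.70, 0.75)
  )
  pmd <- call_pmds(dom)
  expect_equal(nrow(pmd), 1)
  expect_equal(pmd$start, 0)         # 15 kb at 55%: PMD
  ## 10,000 bp at 50%: not a PMD (strict >)
  ## 50 kb at exactly 70%: not a PMD (strict <)
  expect_false(any(pmd$start == 20000))
  expect_false(any(pmd$start == 40000))
  ## output is a subset of the input domains
  expect_true(all(pmd$start %in% dom$start))
})

test_that("MDL table maps domains to (log10 size, percent) points", {
  dom <- data.frame(chrom = "chr1", start = 0, end = 1e5,
                    n_cpg = 500L, mean_level = 0.5)
  p <- mdl_table(dom)
  expect_equal(p$log10_size, 5)
  expect_equal(p$level_pct, 50)
  expect_error(mdl_table(dom[0, ]), "empty")
})

test_that("base-wise Venn partition is exact and sums to the union", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))    # [0,100)
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))   # [50,150)
  v <- interval_overlap_mb(A = a, B = b)
  get <- function(s) v$mb[v$section == s] * 1e6
  expect_equal(get("A&B"), 50)
  expect_equal(get("A"), 50)
  expect_equal(get("B"), 50)
  expect_equal(sum(v$mb) * 1e6, 150)  # sums to union size

  ## identical sets: symmetric differences zero
  v2 <- interval_overlap_mb(A = a, B = a)
  expect_equal(v2$mb[v2$section == "A"], 0)
  expect_equal(v2$mb[v2$section == "B"], 0)
  expect_equal(v2$mb[v2$section == "A&B"] * 1e6, 100)
})

test_that("Venn partition equals the per-base brute-force oracle on random sets", {
  for (seed in 1:6) {
    set.seed(seed)
    mk <- function() {
      s <- sort(sample(900, 4))
      GenomicRanges::reduce(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(s, s + sample(5:60, 4, TRUE))))
    }
    sets <- list(A = mk(), B = mk(), C = mk())
    v <- interval_overlap_mb(sets)
    oracle <- oracle_venn(sets, genome_len = 1000L)
    for (r in seq_len(nrow(v))) {
      expected <- if (v$section[r] %in% names(oracle))
        oracle[[v$section[r]]] else 0L
      expect_equal(v$mb[r] * 1e6, as.numeric(expected),
                   info = paste("seed", seed, v$section[r]))
    }
  }
})

test_that("PMD lineage classification follows the origin rules", {
  gr <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  fib <- gr(c(1000, 5000), c(2999, 6999))
  ipsc <- gr(5000, 6999)
  pan_crpe <- gr(20000, 24999)
  irpe <- gr(c(1000, 5000, 10000, 20000), c(2999, 6999, 11999, 21999))
  cls <- classify_pmds(fib, ipsc, irpe, pan_crpe)
  df <- as.data.frame(cls$regions)
  lab_at <- function(s) df$class[df$start == s]
  expect_equal(lab_at(1000), "recurrent")   # in fib, not in iPSC
  expect_equal(lab_at(5000), "persistent")  # in fib and iPSC
  expect_equal(lab_at(10000), "specific")   # outside fib and pan-cRPE
  expect_equal(lab_at(20000), "other")      # outside fib but in pan-cRPE
  expect_equal(sum(cls$fractions), 1)
  ## base-wise fractions: 2000 bp each class, 8000 bp iRPE PMD total
  expect_equal(unname(cls$fractions["persistent"]), 0.25)
})

test_that("PMD-prone regions are the reduced union; Jaccard behaves", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 200))
  u <- pmd_prone_regions(list(a, b))
  expect_equal(sum(IRanges::width(u)), 200)
  expect_equal(interval_jaccard(a, a), 1)
  expect_equal(interval_jaccard(a, b), 50 / 200)
})
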