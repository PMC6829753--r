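## Shared fixtures (built once per test run) and independent brute-force
## oracles. The oracles deliberately avoid the package's own code paths.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

## small genome: 2 x 3 Mb autosomes + 2 Mb X, reduced gene/feature counts
small_genome_config <- function() {
  genome_config(
    autosome_lengths = c(chr1 = 3e6, chr2 = 3e6), x_length = 2e6,
    genes_per_mb = 40, n_x_genes = 120, n_xci_subject = 60,
    n_xci_escaped = 8, n_rpe_signature = 20,
    n_hyper_retained = 8, n_hyper_resolved = 6,
    n_hypo_maintenance = 6, n_hypo_denovo = 4,
    n_lads_per_autosome = 4, lad_width_range = c(2e5, 4e5)
  )
}

fx_small_genome <- function() {
  fx_get("small_genome", function() generate_genome(small_genome_config(), seed = 11))
}

fx_small_cohort <- function() {
  fx_get("small_cohort", function() {
    simulate_cohort(fx_small_genome(), seed = 11)
  })
}

## full study-scale genome and cohort (acceptance suite)
fx_full_genome <- function() {
  fx_get("full_genome", function() generate_genome(genome_config(), seed = 101))
}

fx_full_cohort <- function() {
  fx_get("full_cohort", function() simulate_cohort(fx_full_genome(), seed = 101))
}

## direct site-table builder: one chromosome, plus-and-minus strand CpGs at
## the given positions with planted per-site probabilities
make_cg_table <- function(pos, prob, depth = 10, chrom = "chr1", seed = 1) {
  set.seed(seed)
  n <- length(pos)
  tot_p <- rpois(n, depth); tot_m <- rpois(n, depth)
  dt <- data.frame(
    chrom = chrom,
    pos = c(pos, pos + 1L),
    strand = rep(c("+", "-"), each = n),
    context = "CG",
    meth = c(rbinom(n, tot_p, prob), rbinom(n, tot_m, prob)),
    total = c(tot_p, tot_m)
  )
  dt[order(dt$pos), ]
}

## two-group site tables with planted differential regions
## regions: data.frame(start_idx, end_idx, delta) on the shared position grid
make_two_group <- function(n_sites = 20000, n1 = 2, n2 = 4, base = 0.85,
                           regions = NULL, depth = 10, seed = 1,
                           spacing = 150) {
  pos <- seq(100L, by = spacing, length.out = n_sites)
  p2 <- rep(base, n_sites)
  p1 <- p2
  if (!is.null(regions)) {
    for (k in seq_len(nrow(regions))) {
      idx <- regions$start_idx[k]:regions$end_idx[k]
      p1[idx] <- p1[idx] + regions$delta[k]
    }
  }
  p1 <- pmin(pmax(p1, 0), 1)
  g1 <- lapply(seq_len(n1), function(i) {
    make_cg_table(pos, p1, depth = depth, seed = seed * 1000 + i)
  })
  g2 <- lapply(seq_len(n2), function(i) {
    make_cg_table(pos, p2, depth = depth, seed = seed * 2000 + i)
  })
  names(g1) <- paste0("a", seq_len(n1)); names(g2) <- paste0("b", seq_len(n2))
  list(g1 = g1, g2 = g2, pos = pos)
}

## ---- independent oracles ----

## per-base Venn partition by scanning an integer occupancy vector
oracle_venn <- function(sets, genome_len = 1000L) {
  occ <- matrix(FALSE, genome_len, length(sets))
  for (k in seq_along(sets)) {
    df <- as.data.frame(sets[[k]])
    for (r in seq_len(nrow(df))) occ[df$start[r]:df$end[r], k] <- TRUE
  }
  lab <- apply(occ, 1, function(z) paste(names(sets)[z], collapse = "&"))
  tab <- table(lab[lab != ""])
  as.list(tab)
}

## two-sided Fisher p by hypergeometric enumeration on a 2x2 table
## (a = both, b = A only, c = B only, d = neither)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # size of A
  n2 <- c + d         # complement of A
  k <- a + c          # size of B
  lo <- max(0L, k - n2); hi <- min(m, k)
  probs <- dhyper(lo:hi, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## unweighted mean of site levels per interval, by explicit scan
oracle_feature_means <- function(sites, intervals) {
  df <- as.data.frame(intervals)
  lev <- sites$meth / sites$total
  sapply(seq_len(nrow(df)), function(i) {
    sel <- sites$chrom == df$seqnames[i] & sites$pos >= df$start[i] &
      sites$pos <= df$end[i] & sites$total > 0
    if (!any(sel)) NA_real_ else mean(lev[sel])
  })
}
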