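## Synthetic genome scaffold: chromosome set, CpG/CH site universe and the
## annotation tracks (CGIs, LADs, gene models, imprinted DMRs) that every
## downstream analysis consumes, plus the planted "truth" used to grade
## recovery (reprogramming-error CGIs, differentially methylated regions with
## known etiology, XCI gene sets).

#' Configuration for the synthetic genome scaffold
#'
#' Defaults describe a desk-scale genome (three 10-Mb autosomes plus a 5-Mb X)
#' carrying the annotation universe the pipeline needs: CpG islands with
#' elevated CpG density, lamina-associated domains (LADs) covering roughly a
#' third of each autosome, gene models with a unique TSS each, a catalogue of
#' 50 imprinted DMRs, 773 X-linked genes of which 394 are subject to X
#' inactivation and 45 escape it in the reprogrammed lineage of the female
#' patient, and a planted set of iRPE-vs-nRPE differential regions with known
#' etiology.
#'
#' @param autosome_lengths named integer vector of autosome lengths (bp).
#' @param x_length length of the X chromosome (bp).
#' @param cpg_spacing mean background spacing between CpG sites (bp).
#' @param cgi_cpg_spacing mean CpG spacing inside CpG islands (bp); must be
#'   smaller than `cpg_spacing` so islands have elevated density.
#' @param ch_spacing mean spacing between simulated non-CpG cytosines (bp).
#' @param genes_per_mb autosomal gene density.
#' @param n_x_genes number of X-linked genes.
#' @param promoter_cgi_frac fraction of genes whose promoter carries a CGI.
#' @param intergenic_cgi_per_mb density of non-promoter CGIs.
#' @param n_lads_per_autosome,lad_width_range LAD count and width range (bp).
#' @param n_idmr number of imprinted DMRs (catalogue size; default 50).
#' @param idmr_width width of each iDMR (bp).
#' @param n_rpe_signature number of genes in the RPE signature set.
#' @param n_xci_subject,n_xci_escaped X-linked genes subject to XCI, and the
#'   subset escaping XCI in the reprogrammed female lineage.
#' @param n_cgi_error_core CGIs hypermethylated by reprogramming in both
#'   patients; `n_cgi_error_patient` more are errored per patient.
#' @param n_cgi_error_patient per-patient additional errored CGIs.
#' @param n_cgi_flank_error subset of core errored CGIs whose flanks lose
#'   methylation (PMD-like) in the reprogrammed lineage.
#' @param n_idmr_error_shared iDMRs hypermethylated in both patients'
#'   reprogrammed cells; `n_idmr_error_patient2` more in patient 2 only.
#' @param n_idmr_error_patient2 patient-2-specific hypermethylated iDMRs.
#' @param n_hyper_retained,n_hyper_resolved planted hyper-DMRs (iRPE > nRPE):
#'   CGI-bearing regions whose hypermethylation persists in xRPE, and
#'   CGI-depleted regions demethylated upon xenotransplantation.
#' @param n_hypo_maintenance,n_hypo_denovo planted hypo-DMRs attributed to
#'   maintenance-methylation and de novo-methylation errors respectively.
#' @param dmr_width width of planted differential regions (bp).
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(autosome_lengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                          x_length = 5e6,
                          cpg_spacing = 150,
                          cgi_cpg_spacing = 30,
                          ch_spacing = 120,
                          genes_per_mb = 40,
                          n_x_genes = 773,
                          promoter_cgi_frac = 0.6,
                          intergenic_cgi_per_mb = 3,
                          n_lads_per_autosome = 6,
                          lad_width_range = c(3e5, 8e5),
                          n_idmr = 50,
                          idmr_width = 1000,
                          n_rpe_signature = 60,
                          n_xci_subject = 394,
                          n_xci_escaped = 45,
                          n_cgi_error_core = 25,
                          n_cgi_error_patient = 15,
                          n_cgi_flank_error = 12,
                          n_idmr_error_shared = 6,
                          n_idmr_error_patient2 = 13,
                          n_hyper_retained = 30,
                          n_hyper_resolved = 20,
                          n_hypo_maintenance = 25,
                          n_hypo_denovo = 12,
                          dmr_width = 5000) {
  cfg <- as.list(environment())
  if (any(autosome_lengths < 1e6) || x_length < 1e6) {
    stop("chromosome lengths must be at least 1 Mb", call. = FALSE)
  }
  if (is.null(names(autosome_lengths)) || anyDuplicated(names(autosome_lengths))) {
    stop("autosome_lengths must have unique names", call. = FALSE)
  }
  if (cgi_cpg_spacing >= cpg_spacing) {
    stop("CGIs must have elevated CpG density (cgi_cpg_spacing < cpg_spacing)",
         call. = FALSE)
  }
  if (n_idmr < 1 || n_xci_escaped > n_xci_subject || n_xci_subject > n_x_genes) {
    stop("invalid gene-set sizes in genome configuration", call. = FALSE)
  }
  if (n_cgi_flank_error > n_cgi_error_core) {
    stop("flank-errored CGIs must be a subset of core errored CGIs", call. = FALSE)
  }
  class(cfg) <- "genome_config"
  cfg
}

## sample n disjoint intervals of the given widths on one chromosome,
## rejecting overlap with 'mask' (GRanges); deterministic under the caller's
## RNG state
.place_intervals <- function(chrom, chrom_len, widths, mask, margin = 2000,
                             max_tries = 5000) {
  ## plain-vector interval arithmetic: the S4 containers are built once at
  ## the end, not once per rejection-sampling try
  if (is(mask, "GRanges")) {
    mask <- mask[as.character(seqnames(mask)) == chrom]
    ms <- start(mask); me <- end(mask)
  } else {
    ms <- integer(0); me <- integer(0)
  }
  out_start <- integer(0)
  out_end <- integer(0)
  for (w in widths) {
    placed <- FALSE
    for (i in seq_len(max_tries)) {
      s <- floor(runif(1, margin, chrom_len - w - margin))
      e <- s + w
      if (!any(ms <= e & me >= s + 1)) {
        out_start <- c(out_start, as.integer(s))
        out_end <- c(out_end, as.integer(e))
        ms <- c(ms, as.integer(s + 1)); me <- c(me, as.integer(e))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place interval on ", chrom,
                      "; genome too crowded", call. = FALSE)
  }
  GRanges(chrom, IRanges(out_start + 1L, out_end))
}

## jittered-grid site positions over [1, len]
.grid_positions <- function(len, spacing) {
  n <- floor(len / spacing)
  base <- seq(from = spacing / 2, by = spacing, length.out = n)
  pos <- as.integer(round(base + runif(n, -spacing * 0.3, spacing * 0.3)))
  sort(unique(pos[pos >= 2 & pos <= len - 2]))
}

#' Generate a synthetic genome scaffold
#'
#' Builds chromosomes, the CpG/CH site universe and all annotation tracks,
#' together with the planted structure (errored CGIs and iDMRs, XCI gene
#' sets, differential regions with known etiology) that the cohort simulator
#' realizes per cell state. Deterministic for a fixed seed.
#'
#' @param config a [genome_config()] list.
#' @param seed integer seed.
#' @return A list of class `genome_spec`; see fields in the source. Key
#'   members: `chrom_lengths`, `autosomes`, `x_chrom`, `cpg` (per-chrom CpG
#'   positions, plus strand C), `ch` (per-chrom data.frame of non-CpG sites),
#'   `cgis`, `lads`, `genes`, `idmrs`, `dmr_truth` (all GRanges), and the
#'   planted gene/interval sets.
#' @export
generate_genome <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  set.seed(child_seed(seed, "genome"))
  x_chrom <- "chrX"
  chrom_lengths <- c(config$autosome_lengths, structure(config$x_length, names = x_chrom))
  autosomes <- names(config$autosome_lengths)
  chroms <- names(chrom_lengths)

  ## --- LADs (autosomes only) ---
  lads <- GRanges()
  for (ch in autosomes) {
    w <- round(runif(config$n_lads_per_autosome,
                     config$lad_width_range[1], config$lad_width_range[2]))
    lads <- suppressWarnings(
      c(lads, .place_intervals(ch, chrom_lengths[[ch]], w, GRanges(),
                               margin = 1e5)))
  }
  mcols(lads)$name <- paste0("LAD_", seq_along(lads))

  ## --- genes ---
  gene_rows <- list()
  gi <- 0L
  for (ch in chroms) {
    n_genes <- if (ch == x_chrom) config$n_x_genes
               else round(config$genes_per_mb * chrom_lengths[[ch]] / 1e6)
    ## TSSs on an even grid with jitter keeps genes roughly non-overlapping
    slot <- chrom_lengths[[ch]] / (n_genes + 1)
    tss <- round(seq(slot, by = slot, length.out = n_genes) +
                   runif(n_genes, -slot * 0.2, slot * 0.2))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    glen <- round(runif(n_genes, 2000, pmin(15000, slot * 0.8)))
    start <- ifelse(strand == "+", tss, tss - glen)
    end <- ifelse(strand == "+", tss + glen, tss)
    keep <- start > 2000 & end < chrom_lengths[[ch]] - 2000
    gene_rows[[ch]] <- data.frame(
      chrom = ch, start = start[keep], end = end[keep],
      strand = strand[keep], tss = tss[keep],
      gene_id = paste0("G_", ch, "_", seq_len(sum(keep)))
    )
  }
  gene_df <- do.call(rbind, gene_rows)
  genes <- GRanges(gene_df$chrom, IRanges(gene_df$start, gene_df$end),
                   strand = gene_df$strand)
  mcols(genes)$gene_id <- gene_df$gene_id
  mcols(genes)$tss <- as.integer(gene_df$tss)
  ## exons: 3 blocks per gene (BED12-style), ends always included
  w <- width(genes)
  bl_start <- as.integer(rbind(1L, round(w * 0.45), w - 99L))
  bl_end <- as.integer(rbind(pmax(100L, round(w * 0.1)),
                             pmin(w - 101L, round(w * 0.55)), w))
  blocks <- S4Vectors::splitAsList(IRanges(bl_start, bl_end),
                                   rep(seq_along(genes), each = 3L))
  names(blocks) <- NULL
  mcols(genes)$blocks <- blocks

  ## --- CGIs: at a fraction of promoters, plus intergenic ones ---
  n_prom_cgi <- round(config$promoter_cgi_frac * length(genes))
  prom_cgi_genes <- sort(sample(seq_along(genes), n_prom_cgi))
  tssv <- mcols(genes)$tss
  cgi_w <- round(runif(n_prom_cgi, 600, 1400))
  cgi_prom <- GRanges(seqnames(genes)[prom_cgi_genes],
                      IRanges(start = pmax(1, tssv[prom_cgi_genes] - cgi_w %/% 2),
                              width = cgi_w))
  mask <- c(granges(cgi_prom), granges(genes))
  cgi_inter <- GRanges()
  for (ch in autosomes) {
    n_int <- round(config$intergenic_cgi_per_mb * chrom_lengths[[ch]] / 1e6)
    w <- round(runif(n_int, 600, 1400))
    cgi_inter <- suppressWarnings(
      c(cgi_inter, .place_intervals(ch, chrom_lengths[[ch]], w,
                                    mask[seqnames(mask) == ch])))
  }
  cgis <- sort(suppressWarnings(c(granges(cgi_prom), granges(cgi_inter))),
               ignore.strand = TRUE)
  strand(cgis) <- "*"
  cgis <- cgis[!duplicated(cgis)]
  ## drop rare overlaps from jittered promoter islands
  cgis <- cgis[countOverlaps(cgis, cgis) == 1L]
  mcols(cgis)$name <- paste0("CGI_", seq_along(cgis))

  ## --- iDMRs: autosomal, disjoint from CGIs ---
  idmr_list <- GRanges()
  per_chrom <- table(sample(autosomes, config$n_idmr, replace = TRUE))
  for (ch in names(per_chrom)) {
    idmr_list <- suppressWarnings(
      c(idmr_list,
        .place_intervals(ch, chrom_lengths[[ch]],
                         rep(config$idmr_width, per_chrom[[ch]]),
                         suppressWarnings(c(granges(cgis), idmr_list)))))
  }
  idmrs <- sort(idmr_list)
  mcols(idmrs)$name <- paste0("iDMR_", seq_along(idmrs))

  ## --- planted differential regions (iRPE vs nRPE truth) ---
  ## state-level methylation archetypes; columns are cell states
  arche <- rbind(
    hyper_retained  = c(fib = .85, ipsc = .85, esc = .85, irpe = .85, xrpe = .85, crpe = .15, nrpe = .10),
    hyper_resolved  = c(fib = .85, ipsc = .85, esc = .85, irpe = .85, xrpe = .25, crpe = .15, nrpe = .10),
    hypo_maint      = c(fib = .85, ipsc = .85, esc = .85, irpe = .15, xrpe = .15, crpe = .50, nrpe = .85),
    hypo_denovo     = c(fib = .30, ipsc = .05, esc = .05, irpe = .05, xrpe = .05, crpe = .05, nrpe = .45)
  )
  spec_rows <- data.frame(
    type = rep(c("hyper", "hyper", "hypo", "hypo"),
               times = c(config$n_hyper_retained, config$n_hyper_resolved,
                         config$n_hypo_maintenance, config$n_hypo_denovo)),
    arche = rep(rownames(arche),
                times = c(config$n_hyper_retained, config$n_hyper_resolved,
                          config$n_hypo_maintenance, config$n_hypo_denovo)),
    origin = rep(c("demethylation-error", "demethylation-error",
                   "maintenance-error", "de-novo-error"),
                 times = c(config$n_hyper_retained, config$n_hyper_resolved,
                           config$n_hypo_maintenance, config$n_hypo_denovo)),
    fate = rep(c("persistent", "resolved-in-xRPE", "persistent", "persistent"),
               times = c(config$n_hyper_retained, config$n_hyper_resolved,
                         config$n_hypo_maintenance, config$n_hypo_denovo))
  )
  avoid <- c(granges(cgis), granges(idmrs),
             GRanges(seqnames(genes), IRanges(pmax(1L, mcols(genes)$tss - 2500L),
                                              mcols(genes)$tss + 2500L)))
  ## maintenance-error hypo-DMRs preferentially inside LADs; the rest outside.
  ## plain-vector placement (one GRanges built at the end)
  rpe_sig_pool <- which(as.character(seqnames(genes)) != x_chrom)
  rpe_signature <- sort(sample(rpe_sig_pool, config$n_rpe_signature))
  sig_genes <- genes[rpe_signature]
  n_res <- config$n_hyper_resolved
  avoid_ch <- as.character(seqnames(avoid))
  lad_ch <- as.character(seqnames(lads))
  occ <- lapply(stats::setNames(nm = autosomes), function(ch) {
    list(s = start(avoid)[avoid_ch == ch], e = end(avoid)[avoid_ch == ch])
  })
  occ_lad <- lapply(stats::setNames(nm = autosomes), function(ch) {
    list(s = c(occ[[ch]]$s, start(lads)[lad_ch == ch]),
         e = c(occ[[ch]]$e, end(lads)[lad_ch == ch]))
  })
  free_at <- function(o, s, e) !any(o$s <= e & o$e >= s)
  pick <- function(o, ch, lo, hi, w, tries = 5000) {
    for (t in seq_len(tries)) {
      s <- floor(runif(1, lo, hi - w))
      if (free_at(o, s, s + w - 1)) return(s)
    }
    stop("could not place differential region on ", ch, call. = FALSE)
  }
  dmr_chrom <- character(nrow(spec_rows))
  dmr_start <- integer(nrow(spec_rows))
  dw <- config$dmr_width
  for (i in seq_len(nrow(spec_rows))) {
    if (spec_rows$arche[i] == "hypo_maint") {
      li <- sample(length(lads), 1)
      ch <- lad_ch[li]
      s <- tryCatch(pick(occ[[ch]], ch, start(lads)[li], end(lads)[li], dw,
                         tries = 200),
                    error = function(e) pick(occ[[ch]], ch, 2000,
                                             chrom_lengths[[ch]] - 2000, dw))
    } else if (spec_rows$arche[i] == "hyper_resolved") {
      ## next to an RPE signature gene (within 2 kb) so that xeno-resolved
      ## hyper-DMRs are enriched near signature genes
      g <- sig_genes[((i - config$n_hyper_retained - 1L) %% length(sig_genes)) + 1L]
      ch <- as.character(seqnames(g))
      s <- end(g) + 1500L
      if (s + dw >= chrom_lengths[[ch]] ||
          !free_at(occ[[ch]], s, s + dw - 1)) {
        s <- pick(occ_lad[[ch]], ch, 2000, chrom_lengths[[ch]] - 2000, dw)
      }
    } else {
      ch <- sample(autosomes, 1)
      s <- pick(occ_lad[[ch]], ch, 2000, chrom_lengths[[ch]] - 2000, dw)
    }
    dmr_chrom[i] <- ch
    dmr_start[i] <- as.integer(s)
    occ[[ch]]$s <- c(occ[[ch]]$s, as.integer(s))
    occ[[ch]]$e <- c(occ[[ch]]$e, as.integer(s + dw - 1))
    occ_lad[[ch]]$s <- c(occ_lad[[ch]]$s, as.integer(s))
    occ_lad[[ch]]$e <- c(occ_lad[[ch]]$e, as.integer(s + dw - 1))
  }
  dmr_gr <- GRanges(dmr_chrom, IRanges(dmr_start, dmr_start + dw - 1L))
  mcols(dmr_gr)$id <- paste0("TDMR_", seq_along(dmr_gr))
  mcols(dmr_gr)$type <- spec_rows$type
  mcols(dmr_gr)$origin <- spec_rows$origin
  mcols(dmr_gr)$fate <- spec_rows$fate
  lv <- arche[spec_rows$arche, , drop = FALSE]
  for (st in colnames(arche)) mcols(dmr_gr)[[st]] <- unname(lv[, st])
  dmr_truth <- sort(dmr_gr)

  ## --- CpG site universe: background grid + dense grid inside CGIs ---
  cpg <- list()
  for (ch in chroms) {
    bg <- .grid_positions(chrom_lengths[[ch]], config$cpg_spacing)
    isl <- cgis[seqnames(cgis) == ch]
    extra <- integer(0)
    if (length(isl) > 0) {
      for (k in seq_along(isl)) {
        n_in <- floor(width(isl)[k] / config$cgi_cpg_spacing)
        p <- start(isl)[k] + sort(sample.int(width(isl)[k] - 2L, n_in))
        extra <- c(extra, p)
      }
    }
    cpg[[ch]] <- sort(unique(c(bg, as.integer(extra))))
  }

  ## --- CH site universe: jittered grid, random strand, CHN context ---
  ctx12 <- c("CAA", "CAC", "CAG", "CAT", "CCA", "CCC", "CCG", "CCT",
             "CTA", "CTC", "CTG", "CTT")
  ctx_w <- c(CAA = .12, CAC = .10, CAG = .14, CAT = .11, CCA = .08, CCC = .06,
             CCG = .03, CCT = .07, CTA = .07, CTC = .08, CTG = .08, CTT = .06)
  ch_sites <- list()
  for (chn in chroms) {
    p <- .grid_positions(chrom_lengths[[chn]], config$ch_spacing)
    p <- setdiff(p, cpg[[chn]])
    ch_sites[[chn]] <- data.frame(
      pos = p,
      strand = sample(c("+", "-"), length(p), replace = TRUE),
      context = sample(ctx12, length(p), replace = TRUE, prob = ctx_w[ctx12]),
      stringsAsFactors = FALSE
    )
  }

  ## --- error catalogues (reprogramming memory, lineage-specific) ---
  n_cgi <- length(cgis)
  err_pool <- sample(n_cgi)
  core <- sort(err_pool[seq_len(config$n_cgi_error_core)])
  p1x <- sort(err_pool[config$n_cgi_error_core + seq_len(config$n_cgi_error_patient)])
  p2x <- sort(err_pool[config$n_cgi_error_core + config$n_cgi_error_patient +
                         seq_len(config$n_cgi_error_patient)])
  flank_err <- sort(sample(core, config$n_cgi_flank_error))
  idmr_shared <- sort(sample(config$n_idmr, config$n_idmr_error_shared))
  idmr_p2 <- sort(sample(setdiff(seq_len(config$n_idmr), idmr_shared),
                         config$n_idmr_error_patient2))

  x_gene_idx <- which(as.character(seqnames(genes)) == x_chrom)
  xci_subject <- sort(sample(x_gene_idx, config$n_xci_subject))
  xci_escaped <- sort(sample(xci_subject, config$n_xci_escaped))

  ## per-state marker promoters (cell-identity genes): disjoint sets of
  ## autosomal genes without a promoter CGI, hypomethylated only in their
  ## state; these give each cell state a distinct promoter methylome
  states6 <- c("Fibro", "iPSC", "iRPE", "xRPE", "cRPE", "nRPE")
  marker_pool <- setdiff(setdiff(rpe_sig_pool, prom_cgi_genes), rpe_signature)
  marker_pool <- sample(marker_pool)
  n_mark <- 40L
  state_markers <- lapply(seq_along(states6), function(i) {
    mcols(genes)$gene_id[marker_pool[((i - 1L) * n_mark + 1L):(i * n_mark)]]
  })
  names(state_markers) <- states6

  ## per-gene baseline expression (log2 FPKM) for the expression simulator
  base_expr <- stats::setNames(rnorm(length(genes), mean = 3, sd = 1.5),
                               mcols(genes)$gene_id)

  genome <- list(
    chrom_lengths = chrom_lengths,
    autosomes = autosomes,
    x_chrom = x_chrom,
    cpg = cpg,
    ch = ch_sites,
    cgis = cgis,
    lads = lads,
    genes = genes,
    idmrs = idmrs,
    dmr_truth = dmr_truth,
    rpe_signature = mcols(genes)$gene_id[rpe_signature],
    xci_subject = mcols(genes)$gene_id[xci_subject],
    xci_escaped = mcols(genes)$gene_id[xci_escaped],
    cgi_error_core = mcols(cgis)$name[core],
    cgi_error_patient = list(patient1 = mcols(cgis)$name[p1x],
                             patient2 = mcols(cgis)$name[p2x]),
    cgi_flank_error = mcols(cgis)$name[flank_err],
    idmr_error_shared = mcols(idmrs)$name[idmr_shared],
    idmr_error_patient2 = mcols(idmrs)$name[idmr_p2],
    state_markers = state_markers,
    base_expr = base_expr,
    config = config,
    seed = as.integer(seed)
  )
  class(genome) <- "genome_spec"
  validate_genome(genome)
  genome
}

#' Validate a genome scaffold's invariants
#'
#' Checks interval bounds, elevated CGI CpG density, iDMR count/disjointness
#' and TSS uniqueness; called by [generate_genome()].
#' @param genome a `genome_spec`.
#' @return `genome`, invisibly; stops on violation.
#' @export
validate_genome <- function(genome) {
  cl <- genome$chrom_lengths
  for (track in list(genome$cgis, genome$lads, genome$genes, genome$idmrs)) {
    ch <- as.character(seqnames(track))
    if (any(start(track) < 1) || any(end(track) > cl[ch])) {
      stop("annotation interval outside chromosome bounds", call. = FALSE)
    }
  }
  if (anyDuplicated(mcols(genome$genes)$tss +
                    as.numeric(factor(as.character(seqnames(genome$genes)))) * 1e9)) {
    stop("gene TSSs are not unique", call. = FALSE)
  }
  ## CGI density vs background
  cpg_gr <- .cpg_granges(genome)
  in_cgi <- sum(countOverlaps(genome$cgis, cpg_gr))
  dens_cgi <- in_cgi / sum(width(genome$cgis))
  dens_bg <- (length(cpg_gr) - in_cgi) /
    (sum(as.numeric(cl)) - sum(width(genome$cgis)))
  if (dens_cgi <= dens_bg) stop("CGIs lack elevated CpG density", call. = FALSE)
  if (length(genome$idmrs) != genome$config$n_idmr ||
      !isDisjoint(genome$idmrs)) {
    stop("iDMR catalogue must contain exactly n_idmr disjoint intervals",
         call. = FALSE)
  }
  invisible(genome)
}

.cpg_granges <- function(genome) {
  GRanges(rep(names(genome$cpg), lengths(genome$cpg)),
          IRanges(unlist(genome$cpg, use.names = FALSE), width = 1L))
}

#' TSS-anchored regions for all genes
#' @param genome a `genome_spec`.
#' @param flank half-width in bp (default 500, i.e. TSS +/- 500 bp).
#' @return GRanges named by gene id.
#' @export
tss_regions <- function(genome, flank = 500) {
  g <- genome$genes
  gr <- GRanges(seqnames(g),
                IRanges(pmax(1L, mcols(g)$tss - as.integer(flank)),
                        mcols(g)$tss + as.integer(flank)))
  mcols(gr)$gene_id <- mcols(g)$gene_id
  gr
}

#' Write the genome annotation tracks to disk
#'
#' CGIs, LADs and iDMRs as BED; gene models as BED12 (blocks = exons);
#' chromosome sizes as a two-column TSV.
#' @param genome a `genome_spec`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_genome_annotations <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(cgi = file.path(dir, "cgi.bed"),
             lad = file.path(dir, "lad.bed"),
             idmr = file.path(dir, "idmr.bed"),
             genes = file.path(dir, "genes.bed"),
             sizes = file.path(dir, "chrom.sizes"))
  rtracklayer::export.bed(genome$cgis, files["cgi"])
  rtracklayer::export.bed(genome$lads, files["lad"])
  rtracklayer::export.bed(genome$idmrs, files["idmr"])
  g <- genome$genes
  mcols(g)$name <- mcols(g)$gene_id
  mcols(g)$gene_id <- NULL
  mcols(g)$tss <- NULL
  rtracklayer::export.bed(g, files["genes"])
  write.table(data.frame(names(genome$chrom_lengths),
                         as.integer(genome$chrom_lengths)),
              files["sizes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(files)
}
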