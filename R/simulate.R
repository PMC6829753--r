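## WGBS cohort simulator. Cell-state parameter sets realize the planted
## genome structure as per-site methylation probabilities; observed counts
## are binomial draws at Poisson depth through a bisulfite non-conversion
## error floor.

.CHN_CONTEXTS <- c("CAA", "CAC", "CAG", "CAT", "CCA", "CCC", "CCG", "CCT",
                   "CTA", "CTC", "CTG", "CTT")

.KNOWN_STATES <- c("Fibro", "iPSC", "iRPE", "xRPE", "cRPE", "nRPE", "ESC")

## dmr_truth / archetype column for each cell state
.state_column <- c(Fibro = "fib", iPSC = "ipsc", iRPE = "irpe", xRPE = "xrpe",
                   cRPE = "crpe", nRPE = "nrpe", ESC = "esc")

.default_mch_rates <- function(state) {
  r <- stats::setNames(rep(0.001, 12), .CHN_CONTEXTS)
  if (state %in% c("iPSC", "ESC")) {
    ## pluripotent cells: CHG-skewed, CAG hotspot
    r[] <- 0.006
    r[c("CAG", "CTG")] <- c(0.040, 0.014)
    r[c("CAC", "CAA", "CAT", "CTC")] <- c(0.020, 0.015, 0.015, 0.010)
  } else if (state == "nRPE") {
    ## native RPE: high neural-like mCH, CAC hotspot
    r[] <- 0.012
    r["CAC"] <- 0.150
    r[c("CAA", "CAG", "CAT", "CTC")] <- 0.050
    r[c("CTG", "CTA", "CTT")] <- c(0.020, 0.015, 0.015)
    r[c("CCA", "CCC", "CCG", "CCT")] <- c(0.012, 0.010, 0.008, 0.012)
  } else if (state == "xRPE") {
    r <- .default_mch_rates("nRPE") / 2
  } else if (state %in% c("iRPE", "cRPE")) {
    r[] <- 0.003
  }
  r
}

#' Parameter set describing one cell state's methylome
#'
#' Defaults encode the six contrasted cell states: fibroblasts with deep PMDs
#' over all LADs; iPSCs with (almost) no PMDs, CHG-skewed mCH, and the
#' lineage's reprogramming errors (hypermethylated CGIs and iDMRs, eroded
#' XCI in the female patient); iRPE/xRPE with shallow PMDs inheriting the
#' iPSC errors, xRPE regaining mCH; cRPE with shallow culture-induced PMDs
#' and no reprogramming errors; nRPE with no PMDs and high CAC-skewed mCH;
#' and an ESC state (error-free pluripotent reference).
#'
#' @param state one of `"Fibro"`, `"iPSC"`, `"iRPE"`, `"xRPE"`, `"cRPE"`,
#'   `"nRPE"`, `"ESC"`.
#' @param patient `"patient1"` (female) or `"patient2"` (male) for the
#'   reprogrammed lineages and fibroblasts; any label for donors.
#' @param sex `"F"` or `"M"`.
#' @param genome a `genome_spec`; supplies the lineage error catalogues.
#' @param baseline genome-wide background mCG level (fraction).
#' @param pmd_depth methylation depression inside affected LADs (fraction).
#' @param pmd_occupancy fraction of LADs affected by PMDs.
#' @param mch_rates named vector of per-context CHN methylation rates.
#' @param nonconversion bisulfite non-conversion rate (symmetric error floor).
#' @param depth mean per-site, per-strand read depth (Poisson).
#' @param pmd_lads optional explicit integer indices of affected LADs
#'   (defaults to a deterministic draw shared by a patient's iRPE and xRPE).
#' @return A list of class `cell_state_params`.
#' @export
cell_state_params <- function(state, patient = "patient1",
                              sex = c("F", "M"), genome = NULL,
                              baseline = 0.85,
                              pmd_depth = NULL, pmd_occupancy = NULL,
                              mch_rates = NULL,
                              nonconversion = 0.005, depth = 10,
                              pmd_lads = NULL) {
  if (!state %in% .KNOWN_STATES) {
    stop("unknown cell state: ", state, call. = FALSE)
  }
  sex <- match.arg(sex)
  defaults <- list(
    Fibro = c(depth = 0.35, occ = 1.00),
    iPSC  = c(depth = 0.25, occ = 0.08),
    ESC   = c(depth = 0.25, occ = 0.08),
    iRPE  = c(depth = 0.18, occ = 0.80),
    xRPE  = c(depth = 0.18, occ = 0.80),
    cRPE  = c(depth = 0.15, occ = 0.60),
    nRPE  = c(depth = 0.00, occ = 0.00)
  )[[state]]
  if (is.null(pmd_depth)) pmd_depth <- unname(defaults["depth"])
  if (is.null(pmd_occupancy)) pmd_occupancy <- unname(defaults["occ"])
  if (is.null(mch_rates)) mch_rates <- .default_mch_rates(state)
  stopifnot(all(mch_rates >= 0 & mch_rates <= 1),
            baseline >= 0, baseline <= 1,
            pmd_depth >= 0, pmd_occupancy >= 0, pmd_occupancy <= 1,
            nonconversion >= 0, nonconversion < 0.5, depth > 0)

  reprogrammed <- state %in% c("iPSC", "iRPE", "xRPE")
  cgi_errors <- character(0); flank_errors <- character(0)
  idmr_hyper <- character(0); xci_escaped <- character(0)
  if (!is.null(genome) && reprogrammed) {
    ## lineage memory: identical error sets across iPSC/iRPE/xRPE of a patient
    pat_key <- if (patient %in% names(genome$cgi_error_patient)) patient else NULL
    cgi_errors <- sort(unique(c(genome$cgi_error_core,
                                if (!is.null(pat_key)) genome$cgi_error_patient[[pat_key]])))
    flank_errors <- genome$cgi_flank_error
    idmr_hyper <- genome$idmr_error_shared
    if (identical(patient, "patient2")) {
      idmr_hyper <- sort(unique(c(idmr_hyper, genome$idmr_error_patient2)))
    }
    if (sex == "F") xci_escaped <- genome$xci_escaped
  }
  if (!is.null(genome) && !is.null(xci_escaped) && length(xci_escaped) &&
      !all(xci_escaped %in% genome$xci_subject)) {
    stop("eroded XCI set must be a subset of XCI-subject genes", call. = FALSE)
  }
  if (is.null(pmd_lads) && !is.null(genome)) {
    n_lad <- length(genome$lads)
    n_aff <- round(pmd_occupancy * n_lad)
    ## iRPE and xRPE of one patient share their PMD footprint (PMDs persist
    ## after xenotransplantation); other states draw their own
    key <- if (state %in% c("iRPE", "xRPE")) paste0("pmd-iRPE-", patient)
           else paste0("pmd-", state, "-", patient)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(child_seed(genome$seed, key))
    pmd_lads <- sort(sample(n_lad, n_aff))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(list(
    state = state, patient = patient, sex = sex,
    reprogrammed = reprogrammed,
    baseline = baseline, pmd_depth = pmd_depth,
    pmd_occupancy = pmd_occupancy, pmd_lads = pmd_lads,
    cgi_errors = cgi_errors, flank_errors = flank_errors,
    idmr_hyper = idmr_hyper, xci_escaped = xci_escaped,
    mch_rates = mch_rates, nonconversion = nonconversion,
    depth = depth
  ), class = "cell_state_params")
}

## which of `pos` fall inside any range of `gr` restricted to `chrom`
.pos_in <- function(pos, gr, chrom) {
  gr <- gr[as.character(seqnames(gr)) == chrom]
  if (length(gr) == 0L) return(logical(length(pos)))
  overlapsAny(IRanges(pos, width = 1L), ranges(gr))
}

#' True per-site methylation probabilities for a cell state
#'
#' The planted truth: returns, per chromosome, the CpG methylation
#' probability vector and the CH-site probability vector implied by a
#' `cell_state_params`, before sequencing noise and non-conversion are
#' applied. [simulate_methylome()] draws counts from exactly these values,
#' so they serve as the oracle for recovery tests.
#'
#' @param genome a `genome_spec`.
#' @param params a [cell_state_params()].
#' @return list with elements `cpg` (per-chrom numeric vectors parallel to
#'   `genome$cpg`) and `ch` (per-chrom vectors parallel to `genome$ch` rows).
#' @export
site_probabilities <- function(genome, params) {
  stopifnot(inherits(genome, "genome_spec"), inherits(params, "cell_state_params"))
  stcol <- .state_column[[params$state]]
  cgis <- genome$cgis
  err_cgis <- cgis[mcols(cgis)$name %in% params$cgi_errors]
  flank_cgis <- cgis[mcols(cgis)$name %in% params$flank_errors]
  flanks <- GRanges()
  if (params$reprogrammed && length(flank_cgis)) {
    flanks <- GenomicRanges::setdiff(
      resize(flank_cgis, width = width(flank_cgis) + 4e4, fix = "center"),
      granges(cgis), ignore.strand = TRUE)
  }
  idmrs <- genome$idmrs
  err_idmrs <- idmrs[mcols(idmrs)$name %in% params$idmr_hyper]
  pmd_regions <- if (length(params$pmd_lads)) genome$lads[params$pmd_lads] else GRanges()
  tssr <- tss_regions(genome, 500)
  x_tss <- tssr[as.character(seqnames(tssr)) == genome$x_chrom]
  subj_tss <- x_tss[mcols(x_tss)$gene_id %in% genome$xci_subject]
  esc_tss <- x_tss[mcols(x_tss)$gene_id %in% params$xci_escaped]
  nonsubj_tss <- x_tss[!mcols(x_tss)$gene_id %in% genome$xci_subject]
  markers <- genome$state_markers[[if (params$state == "ESC") "iPSC" else params$state]]
  marker_tss <- tssr[mcols(tssr)$gene_id %in% markers]
  prom <- promoters_from_genes(genome$genes, upstream = 2000)
  marker_prom <- prom[mcols(prom)$gene_id %in% markers]
  sig_prom <- prom[mcols(prom)$gene_id %in% genome$rpe_signature]
  sig_tss <- tssr[mcols(tssr)$gene_id %in% genome$rpe_signature]
  is_rpe <- params$state %in% c("iRPE", "xRPE", "cRPE", "nRPE")
  truth <- genome$dmr_truth

  cpg_p <- list()
  for (chrom in names(genome$cpg)) {
    pos <- genome$cpg[[chrom]]
    p <- rep(params$baseline, length(pos))
    if (length(pmd_regions)) {
      p[.pos_in(pos, pmd_regions, chrom)] <- params$baseline - params$pmd_depth
    }
    if (length(flanks)) p[.pos_in(pos, flanks, chrom)] <- params$baseline - 0.35
    p[.pos_in(pos, cgis, chrom)] <- 0.05
    ## cell-identity promoters: unmethylated in their own state only
    if (length(marker_prom)) {
      p[.pos_in(pos, marker_prom, chrom) | .pos_in(pos, marker_tss, chrom)] <- 0.05
    }
    if (is_rpe && length(sig_prom)) {
      p[.pos_in(pos, sig_prom, chrom) | .pos_in(pos, sig_tss, chrom)] <- 0.10
    }
    if (length(err_cgis)) p[.pos_in(pos, err_cgis, chrom)] <- 0.85
    p[.pos_in(pos, idmrs, chrom)] <- 0.50
    if (length(err_idmrs)) p[.pos_in(pos, err_idmrs, chrom)] <- 0.90
    ov <- findOverlaps(IRanges(pos, width = 1L),
                       ranges(truth[as.character(seqnames(truth)) == chrom]))
    if (length(ov)) {
      lev <- mcols(truth[as.character(seqnames(truth)) == chrom])[[stcol]]
      p[queryHits(ov)] <- lev[subjectHits(ov)]
    }
    if (chrom == genome$x_chrom) {
      ## X modeled as the aggregate of two alleles: XCI-subject promoters sit
      ## in the intermediate female band, escape erases it
      p[.pos_in(pos, nonsubj_tss, chrom)] <- 0.05
      p[.pos_in(pos, subj_tss, chrom)] <- if (params$sex == "F") 0.33 else 0.05
      if (params$sex == "F" && length(esc_tss)) {
        p[.pos_in(pos, esc_tss, chrom)] <- 0.02
      }
    }
    cpg_p[[chrom]] <- pmin(pmax(p, 0), 1)
  }

  ## CH sites: per-context rate, modulated within gene bodies by expression
  ## rank (inverse coupling, the planted mCH-expression anticorrelation)
  expr_rank <- rank(genome$base_expr) / (length(genome$base_expr) + 1)
  body_factor <- 1.6 - 1.2 * expr_rank  # high expression -> low mCH
  names(body_factor) <- names(genome$base_expr)
  ch_p <- list()
  for (chrom in names(genome$ch)) {
    sites <- genome$ch[[chrom]]
    p <- unname(params$mch_rates[sites$context])
    g <- genome$genes[as.character(seqnames(genome$genes)) == chrom]
    if (length(g)) {
      ov <- findOverlaps(IRanges(sites$pos, width = 1L), ranges(g),
                         select = "first")
      hit <- !is.na(ov)
      p[hit] <- p[hit] * body_factor[mcols(g)$gene_id[ov[hit]]]
    }
    ch_p[[chrom]] <- pmin(pmax(p, 0), 1)
  }
  list(cpg = cpg_p, ch = ch_p)
}

#' Simulate one WGBS methylome
#'
#' Draws a per-cytosine site table from the planted probabilities of
#' [site_probabilities()]: per-strand total counts are Poisson at the state's
#' mean depth, methylated counts are binomial with the true probability passed
#' through a symmetric bisulfite non-conversion floor
#' (`obs = p(1 - e) + (1 - p)e`). CpG sites are emitted on both strands
#' (the minus-strand C at pos + 1); CH sites are strand-specific and carry
#' their CHN trinucleotide context.
#'
#' @param genome a `genome_spec`.
#' @param params a [cell_state_params()].
#' @param seed integer seed.
#' @return A site table: data.frame with columns `chrom`, `pos` (1-based),
#'   `strand`, `context` (`"CG"` or a CHN trinucleotide), `meth`, `total`,
#'   sorted by (chrom, pos).
#' @export
simulate_methylome <- function(genome, params, seed = 1L) {
  set.seed(child_seed(seed, paste0("methylome-", params$state, "-", params$patient)))
  probs <- site_probabilities(genome, params)
  e <- params$nonconversion
  parts <- list()
  for (chrom in names(genome$cpg)) {
    pos <- genome$cpg[[chrom]]
    p_obs <- probs$cpg[[chrom]] * (1 - e) + (1 - probs$cpg[[chrom]]) * e
    n <- length(pos)
    tot_p <- rpois(n, params$depth)
    tot_m <- rpois(n, params$depth)
    parts[[paste0(chrom, "_cg")]] <- data.table::data.table(
      chrom = chrom,
      pos = c(pos, pos + 1L),
      strand = rep(c("+", "-"), each = n),
      context = "CG",
      meth = c(rbinom(n, tot_p, p_obs), rbinom(n, tot_m, p_obs)),
      total = c(tot_p, tot_m)
    )
    chs <- genome$ch[[chrom]]
    p_ch <- probs$ch[[chrom]] * (1 - e) + (1 - probs$ch[[chrom]]) * e
    tot <- rpois(nrow(chs), params$depth)
    parts[[paste0(chrom, "_ch")]] <- data.table::data.table(
      chrom = chrom, pos = chs$pos, strand = chs$strand,
      context = chs$context,
      meth = rbinom(nrow(chs), tot, p_ch), total = tot
    )
  }
  out <- data.table::rbindlist(parts)
  data.table::setkey(out, chrom, pos)
  out[]
}

#' The 16-sample cohort design
#'
#' Two patients (patient 1 female, patient 2 male) each contribute
#' fibroblasts, iPSCs, iRPE and xRPE; four cultured RPE batches and four
#' native RPE donors (two female, two male each) serve as controls.
#'
#' @return data.frame with columns `sample_id`, `state`, `patient`, `sex`,
#'   `environment` (`in-vitro`/`in-vivo`) and `reprogrammed`.
#' @export
default_cohort_design <- function() {
  data.frame(
    sample_id = c("Fibro1", "Fibro2", "iPSC1", "iPSC2", "iRPE1", "iRPE2",
                  "xRPE1", "xRPE2", paste0("cRPE", 1:4), paste0("nRPE", 1:4)),
    state = c("Fibro", "Fibro", "iPSC", "iPSC", "iRPE", "iRPE",
              "xRPE", "xRPE", rep("cRPE", 4), rep("nRPE", 4)),
    patient = c("patient1", "patient2", "patient1", "patient2", "patient1",
                "patient2", "patient1", "patient2",
                paste0("donorC", 1:4), paste0("donorN", 1:4)),
    sex = c("F", "M", "F", "M", "F", "M", "F", "M",
            "F", "F", "M", "M", "F", "F", "M", "M"),
    environment = c(rep("in-vitro", 6), "in-vivo", "in-vivo",
                    rep("in-vitro", 4), rep("in-vivo", 4)),
    reprogrammed = c(FALSE, FALSE, rep(TRUE, 6), rep(FALSE, 8)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a WGBS cohort
#'
#' One site table per design row. Reprogrammed samples of a patient share the
#' same planted CGI/iDMR/XCI errors (lineage memory); xRPE shares iRPE's
#' errors and PMD footprint but regains mCH and demethylates the planted
#' xeno-resolved DMR subset.
#'
#' @param genome a `genome_spec`.
#' @param design a design data.frame as from [default_cohort_design()];
#'   must name at least one sample and known states.
#' @param seed integer seed.
#' @return list with `samples` (named list of site tables), `manifest`
#'   (the design plus per-sample seeds) and `params` (named list of
#'   `cell_state_params`).
#' @export
simulate_cohort <- function(genome, design = default_cohort_design(), seed = 1L) {
  stopifnot(nrow(design) >= 1)
  req <- c("sample_id", "state", "patient", "sex")
  if (!all(req %in% names(design))) {
    stop("design must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(design$state), .KNOWN_STATES)
  if (length(bad)) stop("design references unknown states: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  samples <- list(); params <- list()
  for (i in seq_len(nrow(design))) {
    pr <- cell_state_params(design$state[i], patient = design$patient[i],
                            sex = design$sex[i], genome = genome)
    params[[design$sample_id[i]]] <- pr
    samples[[design$sample_id[i]]] <-
      simulate_methylome(genome, pr, seed = child_seed(seed, design$sample_id[i]))
  }
  manifest <- design
  manifest$seed <- vapply(design$sample_id,
                          function(s) child_seed(seed, s), numeric(1))
  list(samples = samples, manifest = manifest, params = params)
}

#' Simulate gene expression (FPKM) coupled to the planted methylome
#'
#' Genes whose promoter CGI carries a reprogramming hypermethylation error
#' are downregulated in the affected lineage; genes proximal to planted
#' hyper-DMRs are downregulated in samples where the region is methylated;
#' XCI-escaped genes are derepressed (default 2-fold) in reprogrammed female
#' samples.
#'
#' @param genome a `genome_spec`.
#' @param design cohort design (states/patients/sex per sample).
#' @param coupling list of effect sizes: `promoter` (log2 shift for errored
#'   promoter CGIs, default -2), `dmr` (log2 shift for hyper-DMR-proximal
#'   genes where the region is methylated, default -1.5), `escape_fold`
#'   (derepression of XCI-escaped genes, default 2).
#' @param noise_sd lognormal noise (log2 scale) on expression.
#' @param seed integer seed.
#' @return matrix of FPKM, genes x samples.
#' @export
simulate_expression <- function(genome, design = default_cohort_design(),
                                coupling = list(promoter = -2, dmr = -1.5,
                                                escape_fold = 2),
                                noise_sd = 0.15, seed = 1L) {
  set.seed(child_seed(seed, "expression"))
  gid <- names(genome$base_expr)
  prom <- promoters_from_genes(genome$genes, upstream = 2000)
  truth <- genome$dmr_truth
  hyper <- truth[mcols(truth)$type == "hyper"]
  near_hyper <- gid[overlapsAny(genome$genes, hyper + 5000, ignore.strand = TRUE)]
  mat <- matrix(NA_real_, nrow = length(gid), ncol = nrow(design),
                dimnames = list(gid, design$sample_id))
  for (i in seq_len(nrow(design))) {
    pr <- cell_state_params(design$state[i], patient = design$patient[i],
                            sex = design$sex[i], genome = genome)
    lfc <- stats::setNames(rep(0, length(gid)), gid)
    if (length(pr$cgi_errors) && !is.null(coupling$promoter) && coupling$promoter != 0) {
      err_cgis <- genome$cgis[mcols(genome$cgis)$name %in% pr$cgi_errors]
      hit <- mcols(prom)$gene_id[overlapsAny(prom, err_cgis, ignore.strand = TRUE)]
      lfc[hit] <- lfc[hit] + coupling$promoter
    }
    if (!is.null(coupling$dmr) && coupling$dmr != 0 && length(near_hyper)) {
      stcol <- .state_column[[design$state[i]]]
      meth_hyper <- hyper[mcols(hyper)[[stcol]] > 0.5]
      hit <- gid[overlapsAny(genome$genes, meth_hyper + 5000, ignore.strand = TRUE)]
      lfc[hit] <- lfc[hit] + coupling$dmr
    }
    if (length(pr$xci_escaped) && !is.null(coupling$escape_fold) &&
        coupling$escape_fold != 1 && coupling$escape_fold != 0) {
      lfc[pr$xci_escaped] <- lfc[pr$xci_escaped] + log2(coupling$escape_fold)
    }
    l2 <- genome$base_expr + lfc + rnorm(length(gid), 0, noise_sd)
    mat[, i] <- 2^l2
  }
  mat
}
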