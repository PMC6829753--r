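## Imprinted-DMR methylation status and X-chromosome inactivation calls.

#' Methylation status of imprinted DMRs per sample
#'
#' An iDMR is `intermediate` at levels within the imprint band (default
#' [0.25, 0.75], symmetric around the expected 50% of a parent-of-origin
#' mark), `hyper` above it, `hypo` below it, and `uncallable` without covered
#' CpGs.
#'
#' @param idmrs GRanges of the iDMR catalogue (mcol `name` used as row id).
#' @param site_list named list of site tables (one per sample), or a
#'   precomputed iDMR x sample level matrix via `levels =`.
#' @param levels optional precomputed level matrix (overrides `site_list`).
#' @param hypo_max,hyper_min band boundaries.
#' @param min_sites minimum covered CpGs per iDMR.
#' @return list: `status` (character matrix, iDMR x sample), `levels`
#'   (numeric matrix).
#' @export
idmr_status <- function(idmrs, site_list = NULL, levels = NULL,
                        hypo_max = 0.25, hyper_min = 0.75, min_sites = 1) {
  if (is.null(levels)) {
    fm <- feature_means(site_list, idmrs, min_sites = min_sites)
    levels <- fm$levels
  }
  rn <- if (!is.null(mcols(idmrs)$name)) mcols(idmrs)$name else
    paste0("iDMR_", seq_along(idmrs))
  rownames(levels) <- rn
  status <- ifelse(is.na(levels), "uncallable",
                   ifelse(levels > hyper_min, "hyper",
                          ifelse(levels < hypo_max, "hypo", "intermediate")))
  list(status = status, levels = levels)
}

#' Per-sample iDMR hypermethylation summary
#'
#' @param status character matrix from [idmr_status()].
#' @return data.frame per sample: counts per status, fraction hypermethylated
#'   (of the whole catalogue) and as percent.
#' @export
idmr_summary <- function(status) {
  n <- nrow(status)
  out <- lapply(colnames(status), function(s) {
    tab <- table(factor(status[, s],
                        levels = c("hyper", "intermediate", "hypo", "uncallable")))
    data.frame(sample = s, n_idmr = n,
               n_hyper = as.integer(tab["hyper"]),
               n_intermediate = as.integer(tab["intermediate"]),
               n_hypo = as.integer(tab["hypo"]),
               n_uncallable = as.integer(tab["uncallable"]),
               frac_hyper = as.integer(tab["hyper"]) / n,
               pct_hyper = 100 * as.integer(tab["hyper"]) / n)
  })
  do.call(rbind, out)
}

#' Identify genes subject to X-chromosome inactivation
#'
#' A callable X-linked gene is XCI-subject when its TSS-proximal region is
#' lowly methylated in male non-reprogrammed samples (group mean <=
#' `male_max`) and intermediately methylated in female non-reprogrammed
#' samples (group mean within `female_range`) — the aggregate signature of
#' one methylated inactive allele. Callability requires at least `min_sites`
#' covered CpGs in the region in every sample used.
#'
#' @param tss GRanges of TSS-proximal regions with mcol `gene_id`.
#' @param female_sites,male_sites named lists of site tables
#'   (non-reprogrammed samples; >= 1 each).
#' @param male_max male-level threshold (default 0.10).
#' @param female_range female-level band (default c(0.20, 0.45)).
#' @param min_sites coverage threshold per region per sample (default 5).
#' @return data.frame per gene: gene_id, male_mean, female_mean, status in
#'   {XCI-subject, not-XCI, uncallable}; attribute `fraction_subject` gives
#'   the XCI-subject fraction of callable genes.
#' @export
xci_candidates <- function(tss, female_sites, male_sites,
                           male_max = 0.10, female_range = c(0.20, 0.45),
                           min_sites = 5) {
  stopifnot(length(female_sites) >= 1, length(male_sites) >= 1)
  fm_f <- feature_means(female_sites, tss, min_sites = min_sites)
  fm_m <- feature_means(male_sites, tss, min_sites = min_sites)
  f_mean <- rowMeans(fm_f$levels)
  m_mean <- rowMeans(fm_m$levels)   # NA if missing in any sample
  callable <- !is.na(f_mean) & !is.na(m_mean)
  status <- rep("uncallable", length(tss))
  subject <- callable & m_mean <= male_max &
    f_mean >= female_range[1] & f_mean <= female_range[2]
  status[callable] <- ifelse(subject[callable], "XCI-subject", "not-XCI")
  out <- data.frame(gene_id = mcols(tss)$gene_id,
                    male_mean = unname(m_mean),
                    female_mean = unname(f_mean),
                    status = status, stringsAsFactors = FALSE)
  attr(out, "n_callable") <- sum(callable)
  attr(out, "fraction_subject") <- sum(subject) / sum(callable)
  out
}

#' Identify XCI-subject genes escaping inactivation after reprogramming
#'
#' An XCI-subject gene escapes when its TSS-region methylation is prominently
#' low (<= `max_level`) in every reprogrammed female sample of the lineage
#' (set `all_samples = FALSE` for an any-sample rule).
#'
#' @param candidates output of [xci_candidates()].
#' @param reprogrammed_levels matrix of TSS-region levels, genes x
#'   reprogrammed samples, rows named by gene id.
#' @param max_level hypomethylation threshold (default 0.05).
#' @param all_samples require the threshold in all samples (default TRUE).
#' @return data.frame of XCI-subject genes with per-gene escape call;
#'   attribute `fraction_escaped` is escaped / subject.
#' @export
xci_escape <- function(candidates, reprogrammed_levels, max_level = 0.05,
                       all_samples = TRUE) {
  subj <- candidates$gene_id[candidates$status == "XCI-subject"]
  if (length(subj) == 0L) stop("no XCI-subject candidates", call. = FALSE)
  rl <- reprogrammed_levels[match(subj, rownames(reprogrammed_levels)), ,
                            drop = FALSE]
  low <- rl <= max_level
  escaped <- if (all_samples) {
    apply(low, 1, function(z) all(!is.na(z)) && all(z))
  } else {
    apply(low, 1, function(z) any(z, na.rm = TRUE))
  }
  out <- data.frame(gene_id = subj, escaped = unname(escaped),
                    stringsAsFactors = FALSE)
  attr(out, "n_subject") <- length(subj)
  attr(out, "n_escaped") <- sum(escaped)
  attr(out, "fraction_escaped") <- mean(escaped)
  out
}

#' Per-gene log2 expression ratio between two samples
#'
#' `log2((FPKM_a + c) / (FPKM_b + c))` with pseudocount `c`; optionally a
#' two-sided Wilcoxon rank-sum test comparing the ratios of two gene sets
#' (e.g. XCI-escaped vs XCI-subject).
#'
#' @param fpkm matrix of FPKM, genes x samples.
#' @param sample_a,sample_b column names.
#' @param pseudocount added to both numerator and denominator (default 0.01).
#' @param set_a,set_b optional gene-id vectors to compare.
#' @return data.frame (gene_id, log2_ratio); when both sets are given, the
#'   attributes `p_value` (Wilcoxon) and `median_a`/`median_b` are attached.
#' @export
expression_ratio <- function(fpkm, sample_a, sample_b, pseudocount = 0.01,
                             set_a = NULL, set_b = NULL) {
  stopifnot(pseudocount > 0)
  r <- log2((fpkm[, sample_a] + pseudocount) / (fpkm[, sample_b] + pseudocount))
  out <- data.frame(gene_id = rownames(fpkm), log2_ratio = unname(r),
                    stringsAsFactors = FALSE)
  if (!is.null(set_a) && !is.null(set_b)) {
    ra <- r[rownames(fpkm) %in% set_a]
    rb <- r[rownames(fpkm) %in% set_b]
    wt <- stats::wilcox.test(ra, rb)
    attr(out, "p_value") <- wt$p.value
    attr(out, "median_a") <- stats::median(ra)
    attr(out, "median_b") <- stats::median(rb)
  }
  out
}
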