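## Feature definition (windows, promoters, gene bodies, CGIs, TSS regions)
## and feature x sample methylation matrices.

#' Promoter intervals from gene models
#'
#' Promoter = the 2-kb (by default) region immediately upstream of the TSS on
#' the coding strand: `[TSS - up, TSS)` for plus-strand genes, `(TSS, TSS + up]`
#' for minus-strand genes.
#'
#' @param genes GRanges with mcols `gene_id` and `tss` and a set strand.
#' @param upstream promoter length in bp.
#' @return GRanges named by gene id.
#' @export
promoters_from_genes <- function(genes, upstream = 2000) {
  str <- as.character(strand(genes))
  if (any(str == "*")) stop("gene without strand", call. = FALSE)
  tss <- mcols(genes)$tss
  start <- ifelse(str == "+", tss - upstream, tss + 1L)
  end <- ifelse(str == "+", tss - 1L, tss + upstream)
  gr <- GRanges(seqnames(genes), IRanges(pmax(1L, start), end), strand = str)
  mcols(gr)$gene_id <- mcols(genes)$gene_id
  gr
}

#' Tile chromosomes with fixed-size windows
#' @param chrom_lengths named vector of chromosome lengths.
#' @param width window width in bp (default 100 kb).
#' @param step step between window starts (default `width`: tiling).
#' @return GRanges covering each chromosome once per offset.
#' @export
genome_windows <- function(chrom_lengths, width = 1e5, step = width) {
  parts <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1, chrom_lengths[[ch]], by = step)
    ends <- pmin(starts + width - 1, chrom_lengths[[ch]])
    keep <- ends - starts + 1 >= width / 2
    data.frame(chrom = ch, start = starts[keep], end = ends[keep])
  })
  df <- do.call(rbind, parts)
  GRanges(df$chrom, IRanges(df$start, df$end))
}

#' The standard feature sets used for clustering
#'
#' 100-kb windows tiling the autosomes, promoters (2 kb upstream of the TSS),
#' gene bodies (TSS to transcript end), CGI-masked gene bodies, CGIs and
#' TSS-proximal regions (TSS +/- 500 bp). Sex chromosomes are excluded from
#' windows; other feature sets carry all chromosomes and can be subset with
#' [autosomal_only()].
#'
#' @param genome a `genome_spec`.
#' @param window_width,window_step window geometry in bp.
#' @param promoter_upstream promoter length in bp.
#' @param tss_flank TSS-region half-width in bp.
#' @return named list of GRanges: windows, promoters, genebodies,
#'   genebodies_nocgi, cgis, tss.
#' @export
standard_features <- function(genome, window_width = 1e5,
                              window_step = window_width,
                              promoter_upstream = 2000, tss_flank = 500) {
  auto_len <- genome$chrom_lengths[genome$autosomes]
  genebodies <- granges(genome$genes)
  mcols(genebodies)$gene_id <- mcols(genome$genes)$gene_id
  nocgi <- GenomicRanges::setdiff(genebodies, granges(genome$cgis),
                                  ignore.strand = TRUE)
  ov <- findOverlaps(nocgi, genebodies, ignore.strand = TRUE, select = "first")
  mcols(nocgi)$gene_id <- mcols(genebodies)$gene_id[ov]
  list(
    windows = genome_windows(auto_len, window_width, window_step),
    promoters = promoters_from_genes(genome$genes, promoter_upstream),
    genebodies = genebodies,
    genebodies_nocgi = nocgi,
    cgis = granges(genome$cgis),
    tss = tss_regions(genome, tss_flank)
  )
}

#' Restrict a feature set to autosomes
#' @param gr GRanges.
#' @param autosomes character vector of autosome names.
#' @return the subset of `gr` on autosomes.
#' @export
autosomal_only <- function(gr, autosomes) {
  gr[as.character(seqnames(gr)) %in% autosomes]
}

#' Feature x sample matrix of mean methylation levels
#'
#' The methylation level of a feature is the unweighted mean of the levels of
#' its covered sites (not the pooled-count ratio). A feature is missing (NA)
#' for a sample when it contains fewer than `min_sites` covered sites.
#'
#' @param site_list named list of site tables (one per sample).
#' @param intervals GRanges of features.
#' @param min_sites minimum covered sites per feature (default 1).
#' @param context `"CG"` (symmetric CpGs merged first) or `"CH"`.
#' @param merge_strands merge symmetric CpGs before averaging (CG only).
#' @return A list of class `feature_matrix`: `levels` (features x samples),
#'   `n_sites` (covered-site counts), `intervals` (the GRanges).
#' @export
feature_means <- function(site_list, intervals, min_sites = 1,
                          context = c("CG", "CH"), merge_strands = TRUE) {
  context <- match.arg(context)
  if (length(intervals) == 0L) stop("empty interval set", call. = FALSE)
  if (is.data.frame(site_list)) site_list <- list(sample = site_list)
  if (is.null(names(site_list))) {
    names(site_list) <- paste0("sample", seq_along(site_list))
  }
  nfeat <- length(intervals)
  lv <- matrix(NA_real_, nfeat, length(site_list),
               dimnames = list(NULL, names(site_list)))
  ns <- matrix(0L, nfeat, length(site_list),
               dimnames = list(NULL, names(site_list)))
  for (s in names(site_list)) {
    sites <- site_list[[s]]
    if (context == "CG") {
      sites <- sites[sites$context == "CG", ]
      if (merge_strands) sites <- merge_symmetric_cpg(sites)
      sites <- filter_by_coverage(sites, min_cg = 1)
    } else {
      sites <- sites[sites$context != "CG", ]
      sites <- filter_by_coverage(sites, min_ch = 10)
    }
    gr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
    lev <- sites$meth / sites$total
    ov <- findOverlaps(intervals, gr, ignore.strand = TRUE)
    if (length(ov)) {
      sums <- tapply(lev[subjectHits(ov)], queryHits(ov), sum)
      cnts <- tapply(lev[subjectHits(ov)], queryHits(ov), length)
      idx <- as.integer(names(sums))
      lv[idx, s] <- sums / cnts
      ns[idx, s] <- as.integer(cnts)
    }
    lv[ns[, s] < min_sites, s] <- NA_real_
  }
  fid <- if (!is.null(mcols(intervals)$gene_id)) mcols(intervals)$gene_id
         else if (!is.null(mcols(intervals)$name)) mcols(intervals)$name
         else paste0("feat_", seq_len(nfeat))
  rownames(lv) <- fid; rownames(ns) <- fid
  structure(list(levels = lv, n_sites = ns, intervals = intervals),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features x %d samples (%.1f%% missing)\n",
              nrow(x$levels), ncol(x$levels),
              100 * mean(is.na(x$levels))))
  invisible(x)
}

#' Drop features missing in any sample (listwise deletion)
#' @param fm a `feature_matrix`.
#' @return the complete-feature subset.
#' @export
complete_features <- function(fm) {
  keep <- stats::complete.cases(fm$levels)
  structure(list(levels = fm$levels[keep, , drop = FALSE],
                 n_sites = fm$n_sites[keep, , drop = FALSE],
                 intervals = fm$intervals[keep]),
            class = "feature_matrix")
}

#' Write a feature matrix as TSV (interval columns + one column per sample)
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(feature = rownames(fm$levels),
                   chrom = as.character(seqnames(fm$intervals)),
                   start = start(fm$intervals) - 1L,
                   end = end(fm$intervals),
                   fm$levels, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
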