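## Site-table i/o and site-level utilities. The on-disk dialect is the
## Bismark-style cytosine report: chrom, pos (1-based), strand, methylated
## count, unmethylated count, context class (CG/CHG/CHH), trinucleotide.

.context_class <- function(context) {
  ifelse(context == "CG", "CG",
         ifelse(substr(context, 3, 3) == "G" & substr(context, 2, 2) != "G",
                "CHG", "CHH"))
}

.check_site_table <- function(sites) {
  req <- c("chrom", "pos", "strand", "context", "meth", "total")
  if (!all(req %in% names(sites))) {
    stop("site table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  invisible(sites)
}

#' Write a site table as a Bismark-style cytosine report
#'
#' Tab-separated, no header: chrom, pos (1-based), strand, methylated count,
#' unmethylated count, context class (CG/CHG/CHH), trinucleotide context.
#'
#' @param sites a site table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sites, path) {
  .check_site_table(sites)
  out <- data.frame(sites$chrom, sites$pos, sites$strand, sites$meth,
                    sites$total - sites$meth,
                    .context_class(sites$context), sites$context)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Bismark-style cytosine report
#'
#' Malformed lines (negative counts, methylated > total, unknown context)
#' are reported with their line numbers. Input unsorted by (chrom, pos) is
#' sorted on load with a warning.
#'
#' @param path input file (dialect of [write_cytosine_report()]).
#' @return A site table (data.frame: chrom, pos, strand, context, meth, total).
#' @export
read_cytosine_report <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "pos", "strand", "meth",
                                         "unmeth", "class", "context"),
                           colClasses = c("character", "integer", "character",
                                         "integer", "integer", "character",
                                         "character"))
  valid_ctx <- c("CG", .CHN_CONTEXTS)
  bad <- which(raw$meth < 0 | raw$unmeth < 0 |
               !raw$strand %in% c("+", "-") |
               !raw$context %in% valid_ctx)
  if (length(bad)) {
    stop("malformed cytosine report lines: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  sites <- data.table::data.table(
    chrom = raw$chrom, pos = raw$pos, strand = raw$strand,
    context = raw$context, meth = raw$meth, total = raw$meth + raw$unmeth
  )
  srt <- order(sites$chrom, sites$pos)
  if (!identical(srt, seq_len(nrow(sites)))) {
    warning("cytosine report was not sorted by (chrom, pos); sorting")
    sites <- sites[srt, ]
  }
  data.table::setkey(sites, chrom, pos)
  sites[]
}

#' Apply the coverage filter
#'
#' CG sites are retained when covered at least `min_cg` times (default once);
#' CH sites when covered at least `min_ch` times (default 10).
#'
#' @param sites a site table.
#' @param min_cg,min_ch minimum total counts for CG and CH sites.
#' @return The filtered site table.
#' @export
filter_by_coverage <- function(sites, min_cg = 1, min_ch = 10) {
  .check_site_table(sites)
  is_cg <- sites$context == "CG"
  sites[(is_cg & sites$total >= min_cg) | (!is_cg & sites$total >= min_ch), ]
}

#' Merge symmetric CpG counts onto the plus-strand coordinate
#'
#' Counts of a minus-strand CpG cytosine at position p are added to the
#' plus-strand record at p - 1; an unpaired minus-strand record is re-anchored
#' to its plus-strand coordinate. CH records pass through untouched. Total
#' methylated and total read counts are conserved.
#'
#' @param sites a site table.
#' @return A site table with one `+`-strand record per CpG.
#' @export
merge_symmetric_cpg <- function(sites) {
  .check_site_table(sites)
  dt <- data.table::as.data.table(sites)
  cg <- dt[context == "CG"]
  chh <- dt[context != "CG"]
  if (nrow(cg) == 0L) return(sites)
  cg[, pos := ifelse(strand == "-", pos - 1L, pos)]
  merged <- cg[, list(strand = "+", context = "CG",
                      meth = sum(meth), total = sum(total)),
               by = list(chrom, pos)]
  out <- data.table::rbindlist(list(
    merged[, list(chrom, pos, strand, context, meth, total)], chh),
    use.names = TRUE)
  data.table::setkey(out, chrom, pos)
  out[]
}

#' Per-site methylation levels
#' @param sites a site table.
#' @return numeric vector meth/total (NA where total is 0).
#' @export
site_levels <- function(sites) {
  ifelse(sites$total > 0, sites$meth / sites$total, NA_real_)
}

#' Convert a site table to GRanges with a `level` column
#' @param sites a site table.
#' @param chrom_lengths optional named chromosome lengths.
#' @return GRanges (width-1 ranges) with mcols level, meth, total, context.
#' @export
sites_to_granges <- function(sites, chrom_lengths = NULL) {
  .check_site_table(sites)
  gr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L),
                strand = sites$strand)
  mcols(gr)$level <- site_levels(sites)
  mcols(gr)$meth <- sites$meth
  mcols(gr)$total <- sites$total
  mcols(gr)$context <- sites$context
  if (!is.null(chrom_lengths)) {
    seqlevels(gr) <- names(chrom_lengths)
    seqlengths(gr) <- chrom_lengths
  }
  gr
}

#' Export site methylation levels as bedGraph
#'
#' One 0-based half-open record per covered site with the methylation level
#' in percent.
#' @param sites a site table.
#' @param path output file.
#' @param context_filter optional context class (e.g. "CG") to restrict to.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(sites, path, context_filter = NULL) {
  .check_site_table(sites)
  if (!is.null(context_filter)) {
    sites <- sites[.context_class(sites$context) == context_filter, ]
  }
  sites <- sites[sites$total > 0, ]
  out <- data.frame(sites$chrom, sites$pos - 1L, sites$pos,
                    round(100 * sites$meth / sites$total, 2))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as GRanges
#' @param path BED file (0-based half-open on disk).
#' @return GRanges (1-based in memory).
#' @export
read_bed <- function(path) rtracklayer::import.bed(path)

#' Write GRanges as BED
#' @param gr GRanges; an mcol `score` lands in the BED score column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export.bed(gr, path)
  invisible(path)
}
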