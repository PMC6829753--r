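#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle
#' @importFrom GenomeInfoDb seqlevels seqlengths seqnames seqlevels<- seqlengths<-
#' @importFrom data.table data.table setDT setkey as.data.table := .N .SD
#' @importFrom stats rbinom rpois rnorm runif dist hclust cutree
#'   prcomp wilcox.test fisher.test p.adjust kmeans cor.test setNames
#'   dhyper complete.cases
#' @importFrom utils read.table write.table head tail
#' @importFrom methods is
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "chrom", "pos", "strand", "context", "meth", "total", "level",
  "site_id", "feature", "sample_id", "J"
))

## Coordinate conventions (centralized, see spec of the two dialects used):
##  - site positions are 1-based (cytosine report convention)
##  - annotation intervals are BED 0-based half-open on disk, GRanges
##    (1-based closed) in memory; rtracklayer performs the shift on i/o.

#' Convert a 0-based half-open interval table to GRanges
#'
#' @param df data.frame with columns chrom, start (0-based), end (exclusive)
#'   and optionally name, strand.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A [GenomicRanges::GRanges] object (1-based closed).
#' @keywords internal
bed_to_granges <- function(df, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  if ("name" %in% names(df)) mcols(gr)$name <- df$name
  if (!is.null(seqlengths)) {
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- seqlengths
  }
  gr
}

#' Total width of a set of (possibly overlapping) intervals, in bp
#' @param gr GRanges
#' @return integer number of distinct bases covered
#' @keywords internal
covered_bp <- function(gr) {
  sum(as.numeric(width(GenomicRanges::reduce(gr, ignore.strand = TRUE))))
}

#' Derive a child seed from a master seed and a label
#'
#' Deterministic, label-specific streams keep sub-simulations independent of
#' call order. Kept below 2^31 - 1.
#' @keywords internal
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1009L + (h %% 99991L)) %% 2147483587L
}

#' Mean that returns NA (not NaN) on empty input
#' @keywords internal
mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  invisible(x)
}
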