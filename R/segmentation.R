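## Methylome segmentation by least-squares binary segmentation on per-site
## mCG levels, PMD calling by the classical size/level thresholds, the
## Methylated Domain Landscape (MDL) table, base-wise interval set algebra
## and lineage classification of PMDs.

## Least-squares binary segmentation. x: numeric signal. A split is accepted
## when it reduces the within-segment sum of squares by more than `penalty`.
## Returns sorted last-indices of segments (excluding n implicit).
.binseg <- function(x, penalty, min_len) {
  n <- length(x)
  breaks <- integer(0)
  if (n < 2 * min_len) return(breaks)
  best_split <- function(i, j) {
    ## candidate split after k, k in [i+min_len-1, j-min_len]
    seg <- x[i:j]
    m <- length(seg)
    if (m < 2L * min_len) return(NULL)
    cs <- cumsum(seg)
    cs2 <- cumsum(seg^2)
    tot_sse <- cs2[m] - cs[m]^2 / m
    ks <- seq.int(min_len, m - min_len)
    left_sse <- cs2[ks] - cs[ks]^2 / ks
    nr <- m - ks
    right_sse <- (cs2[m] - cs2[ks]) - (cs[m] - cs[ks])^2 / nr
    gain <- tot_sse - left_sse - right_sse
    kbest <- which.max(gain)
    list(gain = gain[kbest], at = i + ks[kbest] - 1L)
  }
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    sp <- best_split(seg[1], seg[2])
    if (!is.null(sp) && sp$gain > penalty) {
      breaks <- c(breaks, sp$at)
      stack <- c(stack, list(c(seg[1], sp$at)), list(c(sp$at + 1L, seg[2])))
    }
  }
  sort(breaks)
}

#' Segment a methylome into methylation domains
#'
#' Change-point detection on per-CpG methylation levels: breakpoints are
#' placed where they reduce the within-segment sum of squared deviations by
#' more than `penalty`, recursively (binary segmentation), with at least
#' `min_sites` CpGs per segment. CpG strands are merged and the coverage
#' filter applied first. Runs of uncovered sequence longer than `max_gap`
#' split the signal into independent blocks so assembly gaps are not bridged.
#' Deterministic; chromosomes are processed independently.
#'
#' @param sites a site table (CG sites are used).
#' @param penalty sum-of-squares reduction (in squared level fractions)
#'   required to accept a change-point.
#' @param min_sites minimum CpGs per segment.
#' @param max_gap maximum site-to-site gap (bp) bridged within a block.
#' @param merge_strands merge symmetric CpGs before segmentation.
#' @return A domain set: data.frame with chrom, start (0-based), end, n_cpg,
#'   mean_level; domains tile each covered block without overlap.
#' @export
segment_methylome <- function(sites, penalty = 1.0, min_sites = 20,
                              max_gap = 1e5, merge_strands = TRUE) {
  .check_site_table(sites)
  cg <- sites[sites$context == "CG", ]
  if (merge_strands) cg <- merge_symmetric_cpg(cg)
  cg <- filter_by_coverage(cg, min_cg = 1)
  out <- list()
  for (ch in unique(cg$chrom)) {
    d <- as.data.frame(cg)[cg$chrom == ch, ]
    if (nrow(d) < min_sites) {
      warning("chromosome ", ch, " has fewer than ", min_sites,
              " covered CpGs; skipped")
      next
    }
    pos <- d$pos
    lev <- d$meth / d$total
    block <- cumsum(c(1L, diff(pos) > max_gap))
    for (b in unique(block)) {
      sel <- block == b
      p <- pos[sel]; x <- lev[sel]
      if (length(x) < min_sites) next
      br <- .binseg(x, penalty, min_sites)
      last <- c(br, length(x))
      first <- c(1L, utils::head(last, -1) + 1L)
      ## domain bounds: block edges at terminal sites, interior boundaries at
      ## the midpoint between flanking sites, so domains tile the block
      bounds <- c(p[1] - 1L,
                  if (length(br)) floor((p[br] + p[br + 1L]) / 2) else integer(0),
                  p[length(p)])
      out[[paste(ch, b)]] <- data.frame(
        chrom = ch,
        start = bounds[-length(bounds)],
        end = bounds[-1],
        n_cpg = last - first + 1L,
        mean_level = vapply(seq_along(first),
                            function(i) mean(x[first[i]:last[i]]), numeric(1))
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_cpg = integer(0),
                      mean_level = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), ]
}

#' Call partially methylated domains
#'
#' The classical definition: segments strictly larger than `min_size` bp and
#' with mean mCG level strictly below `max_level`.
#'
#' @param domains a domain set from [segment_methylome()].
#' @param min_size size threshold in bp (default 10,000, strict >).
#' @param max_level level threshold as a fraction (default 0.70, strict <).
#' @return The PMD subset of `domains`.
#' @export
call_pmds <- function(domains, min_size = 10000, max_level = 0.70) {
  size <- domains$end - domains$start
  domains[size > min_size & domains$mean_level < max_level, , drop = FALSE]
}

#' Methylated Domain Landscape table
#'
#' One point per domain: log10 of its size in bp against its mean methylation
#' level in percent. The classical PMD region of the plot is
#' `{x > log10(10^4), y < 70}`.
#'
#' @param domains a non-empty domain set.
#' @return data.frame with log10_size, level_pct, n_cpg, chrom, start, end.
#' @export
mdl_table <- function(domains) {
  if (nrow(domains) == 0L) stop("empty domain set", call. = FALSE)
  data.frame(
    log10_size = log10(domains$end - domains$start),
    level_pct = 100 * domains$mean_level,
    n_cpg = domains$n_cpg,
    chrom = domains$chrom, start = domains$start, end = domains$end
  )
}

#' Convert a domain set to GRanges
#' @param domains a domain set (0-based start, exclusive end).
#' @return GRanges with mcols n_cpg, mean_level.
#' @export
domains_to_granges <- function(domains) {
  gr <- GRanges(domains$chrom, IRanges(domains$start + 1, domains$end))
  mcols(gr)$n_cpg <- domains$n_cpg
  mcols(gr)$mean_level <- domains$mean_level
  gr
}

#' Base-wise Venn partition of two or three interval sets
#'
#' Sizes (in Mb) of every occupancy class of the Venn diagram, computed on
#' distinct covered bases (not interval counts). The partition sums to the
#' size of the union.
#'
#' @param ... two or three named GRanges (or a single named list).
#' @return data.frame with one row per non-empty Venn section: `section`
#'   (e.g. `"A&B"`), per-set membership flags, and `mb`.
#' @export
interval_overlap_mb <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "GRanges")) {
    sets <- sets[[1]]
  }
  if (length(sets) < 2L || length(sets) > 3L) {
    stop("interval_overlap_mb takes 2 or 3 interval sets", call. = FALSE)
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_along(sets)]
  }
  sets <- lapply(sets, function(g) GenomicRanges::reduce(granges(g), ignore.strand = TRUE))
  n <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    memb <- unlist(combos[i, ])
    gr <- sets[[which(memb)[1]]]
    for (j in which(memb)[-1]) {
      gr <- GenomicRanges::intersect(gr, sets[[j]], ignore.strand = TRUE)
    }
    for (j in which(!memb)) {
      gr <- GenomicRanges::setdiff(gr, sets[[j]], ignore.strand = TRUE)
    }
    cbind(data.frame(section = paste(names(sets)[memb], collapse = "&")),
          as.data.frame(t(memb)),
          data.frame(mb = covered_bp(gr) / 1e6))
  })
  do.call(rbind, rows)
}

#' Classify PMDs of an iPSC-derived sample by lineage history
#'
#' Base-wise partition of an iRPE-like PMD set against fibroblast, iPSC and
#' pan-cRPE PMDs: bases also PMD in fibroblasts are `persistent` when PMD in
#' iPSC too (inherited through reprogramming), else `recurrent` (re-emerged
#' during differentiation); bases in neither fibroblast nor pan-cRPE PMDs are
#' `specific`; the remainder is `other`.
#'
#' @param fib,ipsc,irpe,pan_crpe PMD interval sets (GRanges or domain-set
#'   data.frames) from the same genome.
#' @return list with `regions` (GRanges labelled by class) and `fractions`
#'   (named numeric, base-wise fractions of the iRPE PMD bases).
#' @export
classify_pmds <- function(fib, ipsc, irpe, pan_crpe) {
  as_gr <- function(x) {
    if (is.data.frame(x)) x <- domains_to_granges(x)
    GenomicRanges::reduce(granges(x), ignore.strand = TRUE)
  }
  fib <- as_gr(fib); ipsc <- as_gr(ipsc)
  irpe <- as_gr(irpe); pan_crpe <- as_gr(pan_crpe)
  isect <- function(a, b) GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  sdiff <- function(a, b) GenomicRanges::setdiff(a, b, ignore.strand = TRUE)
  shared_fib <- isect(irpe, fib)
  persistent <- isect(shared_fib, ipsc)
  recurrent <- sdiff(shared_fib, ipsc)
  specific <- sdiff(sdiff(irpe, fib), pan_crpe)
  other <- sdiff(sdiff(irpe, shared_fib), specific)
  lab <- function(gr, l) { if (length(gr)) mcols(gr)$class <- l; gr }
  regions <- suppressWarnings(
    c(lab(persistent, "persistent"), lab(recurrent, "recurrent"),
      lab(specific, "specific"), lab(other, "other")))
  tot <- covered_bp(irpe)
  fractions <- c(
    persistent = covered_bp(persistent) / tot,
    recurrent = covered_bp(recurrent) / tot,
    specific = covered_bp(specific) / tot,
    other = covered_bp(other) / tot
  )
  list(regions = sort(regions), fractions = fractions)
}

#' PMD-prone regions
#'
#' The union of fibroblast PMDs across patients, used to mask (or select)
#' PMD-prone sequence in clustering.
#' @param pmd_sets list of PMD sets (GRanges or domain-set data.frames).
#' @return reduced GRanges.
#' @export
pmd_prone_regions <- function(pmd_sets) {
  grs <- lapply(pmd_sets, function(x) {
    if (is.data.frame(x)) x <- domains_to_granges(x)
    granges(x)
  })
  GenomicRanges::reduce(suppressWarnings(do.call(c, unname(grs))),
                        ignore.strand = TRUE)
}

#' Base-wise Jaccard index of two interval sets
#' @param a,b GRanges.
#' @return numeric in [0, 1].
#' @export
interval_jaccard <- function(a, b) {
  a <- GenomicRanges::reduce(granges(a), ignore.strand = TRUE)
  b <- GenomicRanges::reduce(granges(b), ignore.strand = TRUE)
  inter <- covered_bp(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
  uni <- covered_bp(GenomicRanges::union(a, b, ignore.strand = TRUE))
  if (uni == 0) return(NA_real_)
  inter / uni
}
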