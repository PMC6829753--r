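## DMR calling between two sample groups and the downstream classification
## logic: k-means profile clusters, origin/fate tracing across cell states,
## proximal-gene mapping and CGI flank profiling.

## per-CpG mean level across a group's samples (strand-merged, coverage
## filtered); returns data.table(chrom, pos, level, n_samples)
.group_cpg_levels <- function(site_list) {
  per <- lapply(names(site_list), function(s) {
    x <- site_list[[s]]
    x <- x[x$context == "CG", ]
    x <- merge_symmetric_cpg(x)
    x <- filter_by_coverage(x, min_cg = 1)
    data.table::data.table(chrom = x$chrom, pos = x$pos,
                           level = x$meth / x$total, sample = s)
  })
  dt <- data.table::rbindlist(per)
  dt[, list(level = mean(level), n_samples = .N), by = list(chrom, pos)]
}

## best contiguous subsegment of x (centered on `mu`) by summed deviation:
## returns c(i, j, score) with score = |sum(x[i:j] - mu)|, or NULL
.max_subsegment <- function(x, mu) {
  n <- length(x)
  cs <- cumsum(x - mu)
  s0 <- c(0, cs)
  ## positive: max over j of cs[j] - min over i <= j of s0[i]
  cmin <- cummin(s0[-(n + 1)])
  gain_pos <- cs - cmin
  jp <- which.max(gain_pos)
  ip <- which.min(s0[seq_len(jp)])      # i - 1 index into s0
  cmax <- cummax(s0[-(n + 1)])
  gain_neg <- cmax - cs
  jn <- which.max(gain_neg)
  in_ <- which.max(s0[seq_len(jn)])
  if (gain_pos[jp] >= gain_neg[jn]) c(ip, jp, gain_pos[jp])
  else c(in_, jn, gain_neg[jn])
}

## recursive maximum-subsegment candidate search on a difference signal:
## within each segment, find the contiguous run deviating most from the
## segment mean (so runs are found on any regional background); record it as
## a candidate when it is long enough and its absolute mean difference
## reaches seed_diff (zero difference is the natural reference), then
## recurse into the run and its flanks
.diff_candidates <- function(d, min_seg, seed_diff) {
  out <- vector("list", 256L); n_out <- 0L
  put <- function(i, j) {
    if (j - i + 1L >= min_seg && abs(mean(d[i:j])) >= seed_diff) {
      n_out <<- n_out + 1L
      out[[n_out]] <<- c(i, j)
    }
  }
  stack <- list(c(1L, length(d)))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1]; hi <- seg[2]
    n <- hi - lo + 1L
    if (n < min_seg) next
    ## every visited segment is itself a candidate: a segment whose span is
    ## exactly a differential region would otherwise only contribute its
    ## interior noise runs
    put(lo, hi)
    x <- d[lo:hi]
    ms <- .max_subsegment(x, mean(x))
    i <- lo + ms[1] - 1L; j <- lo + ms[2] - 1L
    if (i == lo && j == hi) {
      ## the extreme run is the whole segment: halve to reach any interior
      ## structure
      if (n >= 2L * min_seg) {
        mid <- lo + n %/% 2L
        stack <- c(stack, list(c(lo, mid - 1L)), list(c(mid, hi)))
      }
      next
    }
    put(i, j)
    stack <- c(stack, list(c(lo, i - 1L)), list(c(j + 1L, hi)))
    if (j - i + 1L < n) stack <- c(stack, list(c(i, j)))
  }
  unique(out[seq_len(n_out)])
}

#' Call differentially methylated regions between two sample groups
#'
#' Candidate segments are found by recursive segmentation of the per-CpG
#' difference between group mean levels (CpGs covered in every sample of
#' both groups): within each segment the contiguous subsegment deviating
#' most from the segment mean (maximum summed deviation) is extracted and
#' the search recurses into it and its flanks, so small isolated regions are
#' found regardless of chromosome length. Each candidate is tested with a
#' two-sided Wilcoxon signed-rank test on the per-CpG group differences,
#' q-values are Benjamini-Hochberg across all candidates, and the emitted
#' set is filtered to segments with at least `min_cpg` CpGs, `q < max_q` and
#' an absolute group-mean difference above `min_diff`; overlapping survivors
#' are resolved in favor of the larger |difference|. Direction is `hyper`
#' when group 1 exceeds group 2. Sex chromosomes are excluded by default.
#'
#' @param group1,group2 named lists of site tables (>= 1 sample each).
#' @param min_cpg minimum CpGs per DMR (default 20).
#' @param max_q q-value threshold (default 0.01).
#' @param min_diff minimum |group-mean difference| as a fraction (default 0.30).
#' @param seed_diff minimum mean shift (vs the enclosing segment) for a
#'   candidate; keep below `min_diff`.
#' @param min_seg minimum CpGs per candidate segment.
#' @param exclude_chroms chromosomes dropped before calling (default X/Y).
#' @return A DMR set: data.frame with chrom, start (0-based), end, n_cpg,
#'   mean_g1, mean_g2, diff, direction, p_value, q_value. Members are
#'   non-overlapping and all satisfy the three filters.
#' @export
call_dmrs <- function(group1, group2, min_cpg = 20, max_q = 0.01,
                      min_diff = 0.30, seed_diff = 0.15, min_seg = 10,
                      exclude_chroms = c("chrX", "chrY", "X", "Y")) {
  g1 <- .group_cpg_levels(group1)
  g2 <- .group_cpg_levels(group2)
  n1 <- length(group1); n2 <- length(group2)
  ## CpGs covered in all samples of both groups
  g1 <- g1[g1$n_samples == n1]
  g2 <- g2[g2$n_samples == n2]
  dt <- merge(g1[, list(chrom, pos, l1 = level)],
              g2[, list(chrom, pos, l2 = level)], by = c("chrom", "pos"))
  dt <- dt[!chrom %in% exclude_chroms]
  data.table::setkey(dt, chrom, pos)
  cand <- list()
  for (ch in unique(dt$chrom)) {
    d <- as.data.frame(dt)[dt$chrom == ch, ]
    if (nrow(d) < 2 * min_seg) next
    diff_sig <- d$l1 - d$l2
    cands <- .diff_candidates(diff_sig, min_seg, seed_diff)
    ## recursion boundaries can bisect a region; add merged spans of nearby
    ## same-sign candidates so fragmented regions are testable whole
    if (length(cands) > 1) {
      cm <- do.call(rbind, cands)
      cm <- cm[order(cm[, 1], cm[, 2]), , drop = FALSE]
      sgn <- sign(vapply(seq_len(nrow(cm)),
                         function(k) mean(diff_sig[cm[k, 1]:cm[k, 2]]),
                         numeric(1)))
      merged <- list()
      cur <- cm[1, ]; cur_s <- sgn[1]; grew <- FALSE
      for (k in seq_len(nrow(cm))[-1]) {
        if (sgn[k] == cur_s && cm[k, 1] - cur[2] <= 5L) {
          cur[2] <- max(cur[2], cm[k, 2]); grew <- TRUE
        } else {
          if (grew) merged[[length(merged) + 1L]] <- cur
          cur <- cm[k, ]; cur_s <- sgn[k]; grew <- FALSE
        }
      }
      if (grew) merged[[length(merged) + 1L]] <- cur
      cands <- unique(c(cands, merged))
    }
    for (cc in cands) {
      idx <- cc[1]:cc[2]
      m1 <- mean(d$l1[idx]); m2 <- mean(d$l2[idx])
      pv <- suppressWarnings(
        stats::wilcox.test(d$l1[idx], d$l2[idx], paired = TRUE,
                           exact = FALSE)$p.value)
      if (is.na(pv)) next
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = ch, start = d$pos[cc[1]] - 1L, end = d$pos[cc[2]],
        n_cpg = length(idx), mean_g1 = m1, mean_g2 = m2,
        diff = m1 - m2, p_value = pv
      )
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      n_cpg = integer(0), mean_g1 = numeric(0),
                      mean_g2 = numeric(0), diff = numeric(0),
                      direction = character(0), p_value = numeric(0),
                      q_value = numeric(0)))
  }
  res <- do.call(rbind, cand)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[res$n_cpg >= min_cpg & res$q_value < max_q &
               abs(res$diff) > min_diff, , drop = FALSE]
  ## nested/overlapping survivors: keep the best-supported segment
  ## (smallest q, then most CpGs, then largest |difference|)
  if (nrow(res) > 1) {
    res <- res[order(res$q_value, -res$n_cpg, -abs(res$diff)), ]
    gr <- GRanges(res$chrom, IRanges(res$start + 1, res$end))
    keep <- rep(TRUE, nrow(res))
    for (i in seq_len(nrow(res))[-1]) {
      prev <- which(keep[seq_len(i - 1)])
      if (any(overlapsAny(gr[i], gr[prev]))) keep[i] <- FALSE
    }
    res <- res[keep, , drop = FALSE]
  }
  res$direction <- ifelse(res$diff > 0, "hyper", "hypo")
  res <- res[order(res$chrom, res$start),
             c("chrom", "start", "end", "n_cpg", "mean_g1", "mean_g2",
               "diff", "direction", "p_value", "q_value")]
  rownames(res) <- NULL
  res
}

#' Convert a DMR set to GRanges
#' @param dmrs a DMR set data.frame.
#' @return GRanges with the statistics as mcols.
#' @export
dmrs_to_granges <- function(dmrs) {
  gr <- GRanges(dmrs$chrom, IRanges(dmrs$start + 1, dmrs$end))
  for (cc in setdiff(names(dmrs), c("chrom", "start", "end"))) {
    mcols(gr)[[cc]] <- dmrs[[cc]]
  }
  gr
}

#' k-means clustering of DMR methylation profiles
#'
#' Fixed-seed k-means (k-means++-like via multiple deterministic restarts)
#' over DMR x state mean-methylation profiles; missing values are imputed by
#' the state (column) mean. Cluster numbers are relabelled by descending mean
#' iPSC-state level (or by the first column when no `ipsc` column exists) so
#' numbering is reproducible.
#'
#' @param profiles numeric matrix, DMRs x states.
#' @param k number of clusters (>= 1; the conventional defaults are 5 for
#'   hyper-DMRs and 2 for hypo-DMRs).
#' @param seed integer seed.
#' @param order_by column name used to order cluster labels.
#' @return list: `cluster` (integer labels), `centers`, `sizes`.
#' @export
kmeans_dmrs <- function(profiles, k, seed = 1L, order_by = "ipsc") {
  stopifnot(k >= 1, nrow(profiles) >= k)
  m <- as.matrix(profiles)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- mean(m[, j], na.rm = TRUE)
  }
  set.seed(child_seed(seed, "kmeans-dmr"))
  km <- stats::kmeans(m, centers = k, nstart = 25, iter.max = 100)
  ord_col <- if (order_by %in% colnames(m)) order_by else colnames(m)[1]
  relabel <- order(-km$centers[, ord_col])
  new_lab <- match(km$cluster, relabel)
  centers <- km$centers[relabel, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(cluster = new_lab, centers = centers,
       sizes = as.integer(table(factor(new_lab, levels = seq_len(k)))))
}

#' Trace the origin and fate of DMRs across cell states
#'
#' Origin: when the region is similarly methylated in iPSC and ESC
#' (|difference| <= `similar_tol`), the error arose during differentiation —
#' a hyper-DMR with the region methylated in iPSC is a demethylation error
#' (failure to demethylate on the way to RPE), a hypo-DMR with iPSC
#' methylated is a maintenance-methylation error, and a hypo-DMR with iPSC
#' unmethylated is a de novo-methylation error. When iPSC and ESC disagree
#' and the iPSC state was transmitted to iRPE (same side of 0.5), the DMR is
#' a reprogramming error. Anything else is unclassified. Fate: a DMR is
#' resolved-in-xRPE when xenotransplantation moved it closer to the nRPE
#' level by more than `fate_margin`.
#'
#' @param state_means data.frame or matrix with one row per DMR and columns
#'   `ipsc`, `esc`, `irpe`, `xrpe`, `nrpe` (fractions).
#' @param direction character vector, `"hyper"`/`"hypo"` per DMR.
#' @param similar_tol threshold for "similarly methylated" (default 0.15).
#' @param fate_margin margin for fate calls (default 0.10).
#' @return data.frame with columns `origin` and `fate`; rows with any missing
#'   state mean are `unclassified`/`NA`.
#' @export
classify_origin_fate <- function(state_means, direction,
                                 similar_tol = 0.15, fate_margin = 0.10) {
  sm <- as.data.frame(state_means)
  need <- c("ipsc", "esc", "irpe", "xrpe", "nrpe")
  if (!all(need %in% names(sm))) {
    stop("state_means needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(sm)
  stopifnot(length(direction) == n)
  origin <- rep("unclassified", n)
  fate <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- sm[i, need]
    if (anyNA(v)) next
    reprogram_ok <- abs(v$ipsc - v$esc) <= similar_tol
    if (reprogram_ok) {
      if (direction[i] == "hyper" && v$ipsc > 0.5) {
        origin[i] <- "demethylation-error"
      } else if (direction[i] == "hypo" && v$ipsc > 0.5) {
        origin[i] <- "maintenance-error"
      } else if (direction[i] == "hypo" && v$ipsc <= 0.5) {
        origin[i] <- "de-novo-error"
      }
    } else if ((v$ipsc > 0.5) == (v$irpe > 0.5)) {
      origin[i] <- "reprogramming-error"
    }
    fate[i] <- if (abs(v$xrpe - v$nrpe) < abs(v$irpe - v$nrpe) - fate_margin) {
      "resolved-in-xRPE"
    } else "persistent"
  }
  data.frame(origin = origin, fate = fate, stringsAsFactors = FALSE)
}

#' Map DMRs to proximal genes
#'
#' A gene is proximal to a DMR when the gap between the DMR interval and the
#' gene span is at most `max_dist` bp (0 when they overlap).
#'
#' @param dmrs a DMR set (data.frame or GRanges).
#' @param genes GRanges with mcol `gene_id`.
#' @param max_dist maximum gap in bp (default 5,000).
#' @return data.frame with one row per (DMR, gene) pair: dmr index, gene_id,
#'   distance.
#' @export
proximal_genes <- function(dmrs, genes, max_dist = 5000) {
  stopifnot(max_dist >= 0)
  gr <- if (is.data.frame(dmrs)) dmrs_to_granges(dmrs) else granges(dmrs)
  hits <- findOverlaps(gr, genes, maxgap = max_dist, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(data.frame(dmr = integer(0), gene_id = character(0),
                      distance = integer(0)))
  }
  d <- GenomicRanges::distance(gr[queryHits(hits)], genes[subjectHits(hits)],
                               ignore.strand = TRUE)
  keep <- !is.na(d) & d <= max_dist
  data.frame(dmr = queryHits(hits)[keep],
             gene_id = mcols(genes)$gene_id[subjectHits(hits)][keep],
             distance = d[keep], stringsAsFactors = FALSE)
}

#' Union counts of DMR-proximal genes by direction
#'
#' De-duplicates genes proximal to both hyper- and hypo-DMRs:
#' `union = hyper + hypo - both`.
#'
#' @param hyper_genes,hypo_genes character vectors of gene ids proximal to
#'   hyper- and hypo-DMRs.
#' @return named list: n_hyper, n_hypo, n_both, n_union.
#' @export
proximal_gene_summary <- function(hyper_genes, hypo_genes) {
  hyper_genes <- unique(hyper_genes); hypo_genes <- unique(hypo_genes)
  both <- intersect(hyper_genes, hypo_genes)
  list(n_hyper = length(hyper_genes), n_hypo = length(hypo_genes),
       n_both = length(both),
       n_union = length(union(hyper_genes, hypo_genes)))
}

#' Average methylation profile across CGIs and their flanks
#'
#' Bins each CGI body into `body_bins` relative bins and each flank into
#' `flank_bins` fixed-width bins, averages site levels per bin within each
#' CGI, then across CGIs (missing bins ignored).
#'
#' @param cgis GRanges of CGIs.
#' @param sites a site table (CG sites used, strands merged).
#' @param flank flank width in bp (default 20,000).
#' @param flank_bins,body_bins bin counts.
#' @return data.frame: bin index, zone (`upstream`/`cgi`/`downstream`),
#'   relative position, mean level.
#' @export
cgi_flank_profile <- function(cgis, sites, flank = 2e4, flank_bins = 20,
                              body_bins = 10) {
  stopifnot(flank > 0)
  cg <- sites[sites$context == "CG", ]
  cg <- merge_symmetric_cpg(cg)
  cg <- filter_by_coverage(cg, min_cg = 1)
  lev <- cg$meth / cg$total
  pos_gr <- GRanges(cg$chrom, IRanges(cg$pos, width = 1L))
  n_bins <- 2L * flank_bins + body_bins
  acc <- matrix(NA_real_, length(cgis), n_bins)
  for (i in seq_along(cgis)) {
    ch <- as.character(seqnames(cgis))[i]
    s <- start(cgis)[i]; e <- end(cgis)[i]
    sel <- which(cg$chrom == ch & cg$pos >= s - flank & cg$pos <= e + flank)
    if (length(sel) == 0L) next
    p <- cg$pos[sel]; l <- lev[sel]
    bin <- integer(length(p))
    up <- p < s
    dn <- p > e
    body <- !up & !dn
    bin[up] <- pmin(flank_bins, 1L + floor((p[up] - (s - flank)) / (flank / flank_bins)))
    bin[body] <- flank_bins +
      pmin(body_bins, 1L + floor((p[body] - s) / ((e - s + 1) / body_bins)))
    bin[dn] <- flank_bins + body_bins +
      pmin(flank_bins, 1L + floor((p[dn] - e - 1) / (flank / flank_bins)))
    mt <- tapply(l, bin, mean)
    acc[i, as.integer(names(mt))] <- mt
  }
  zone <- rep(c("upstream", "cgi", "downstream"),
              c(flank_bins, body_bins, flank_bins))
  data.frame(
    bin = seq_len(n_bins), zone = zone,
    rel_pos = c(seq(-flank, -flank / flank_bins, length.out = flank_bins),
                seq(0, 1, length.out = body_bins),
                seq(flank / flank_bins, flank, length.out = flank_bins)),
    mean_level = colMeans(acc, na.rm = TRUE)
  )
}

#' Co-occurrence of CGI hypermethylation and flank hypomethylation
#'
#' Fisher's exact test on the 2x2 table {CGI hypermethylated?} x {flanks
#' inside a PMD?} over a CGI universe.
#'
#' @param cgi_hyper logical vector: CGI hypermethylated.
#' @param flank_pmd logical vector: CGI flanks fall in a PMD.
#' @return the [fisher_overlap()]-style result list.
#' @export
cgi_pmd_cooccurrence <- function(cgi_hyper, flank_pmd) {
  stopifnot(length(cgi_hyper) == length(flank_pmd))
  universe <- seq_along(cgi_hyper)
  fisher_overlap(universe[cgi_hyper], universe[flank_pmd], universe)
}

#' Write a DMR set as BED (level difference in the score) and a stats TSV
#' @param dmrs a DMR set.
#' @param bed_path,tsv_path output files (either may be NULL).
#' @return invisibly, the paths written.
#' @export
write_dmrs <- function(dmrs, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    gr <- dmrs_to_granges(dmrs)
    mcols(gr) <- NULL
    mcols(gr)$name <- paste0(dmrs$direction, "_", seq_len(nrow(dmrs)))
    mcols(gr)$score <- round(100 * dmrs$diff, 1)
    rtracklayer::export.bed(gr, bed_path)
  }
  if (!is.null(tsv_path)) {
    write.table(dmrs, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed_path, tsv_path))
}
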