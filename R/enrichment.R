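## Exact-test utilities: Fisher overlap of two sets within a universe and
## classic Fisher gene-set enrichment with term-size and reporting filters.

#' Fisher's exact test for the overlap of two sets
#'
#' Two-sided Fisher's exact test on the 2x2 membership table of `a` and `b`
#' within `universe`. Reports both the conditional-MLE odds ratio (from
#' [stats::fisher.test()]) and the sample odds ratio.
#'
#' @param a,b vectors (subsets of `universe`).
#' @param universe the background set.
#' @return list: table (2x2), p_value, odds_ratio (conditional MLE),
#'   sample_odds_ratio, n_overlap.
#' @export
fisher_overlap <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    stop("both sets must be subsets of the universe", call. = FALSE)
  }
  in_a <- universe %in% a
  in_b <- universe %in% b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)), 2, 2,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
  ft <- stats::fisher.test(tab)
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate),
       sample_odds_ratio = or_sample,
       n_overlap = tab[1, 1])
}

#' Classic Fisher gene-set enrichment
#'
#' Per-term Fisher's exact test of a query gene set against an annotation
#' mapping. Terms annotating fewer than `min_term` or more than `max_term`
#' genes (within the universe) are removed before testing; a term is
#' reported when `p < max_p` and at least `min_overlap` query genes carry
#' the annotation. BH-adjusted p-values are exported alongside, but the
#' reporting gate is the raw-p rule.
#'
#' @param genes query gene set.
#' @param annotation named list: term -> character vector of genes.
#' @param universe background gene set (non-empty).
#' @param min_term,max_term term-size filter (defaults 10 and 500).
#' @param max_p significance level on the raw p (default 0.01).
#' @param min_overlap minimum annotated query genes (default 3).
#' @param report_all return all tested terms instead of significant only.
#' @return data.frame per term: term, n_term, n_overlap, odds_ratio, p_value,
#'   p_adjust, significant — sorted by p.
#' @export
geneset_enrichment <- function(genes, annotation, universe,
                               min_term = 10, max_term = 500,
                               max_p = 0.01, min_overlap = 3,
                               report_all = FALSE) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (length(annotation) == 0L) stop("empty annotation", call. = FALSE)
  universe <- unique(universe)
  genes <- unique(intersect(genes, universe))
  ann <- lapply(annotation, function(g) unique(intersect(g, universe)))
  sizes <- lengths(ann)
  ann <- ann[sizes >= min_term & sizes <= max_term]
  if (length(ann) == 0L) {
    return(data.frame(term = character(0), n_term = integer(0),
                      n_overlap = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), p_adjust = numeric(0),
                      significant = logical(0)))
  }
  rows <- lapply(names(ann), function(tm) {
    fo <- fisher_overlap(genes, ann[[tm]], universe)
    data.frame(term = tm, n_term = length(ann[[tm]]),
               n_overlap = fo$n_overlap, odds_ratio = fo$odds_ratio,
               p_value = fo$p_value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value < max_p & res$n_overlap >= min_overlap
  res <- res[order(res$p_value), ]
  rownames(res) <- NULL
  if (report_all) res else res[res$significant, , drop = FALSE]
}

#' Read a GMT or two-column TSV annotation file
#' @param path GMT (term, description, genes...) or two-column (term, gene)
#'   TSV.
#' @return named list term -> genes.
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1)
  nfields <- length(strsplit(first, "\t")[[1]])
  if (nfields > 2) {
    lines <- strsplit(readLines(path), "\t")
    stats::setNames(lapply(lines, function(x) unique(x[-(1:2)])),
                    vapply(lines, `[[`, character(1), 1))
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("term", "gene"),
                            colClasses = "character")
    split(df$gene, df$term)
  }
}
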