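## Non-CpG (CH) methylation: class levels, the 12 CHN trinucleotide context
## profile and mCH-expression correlation.

## CHG/CHH class membership of the 12 CHN contexts. CCG (a CG-adjacent
## trinucleotide) is kept as its own displayed axis and excluded from both
## class means by default; set include_ccg_in_chg = TRUE for the dialect
## that counts it as CHG.
.chg_contexts <- function(include_ccg_in_chg = FALSE) {
  c("CAG", "CTG", if (include_ccg_in_chg) "CCG")
}
.chh_contexts <- function() {
  c("CAA", "CAC", "CAT", "CCA", "CCC", "CCT", "CTA", "CTC", "CTT")
}

#' Non-CpG methylation context profile
#'
#' Mean methylation per CHN trinucleotide context (unweighted mean of site
#' levels over CH sites covered at least `min_cov` times; CH sites are
#' strand-specific and never merged), plus the CHG and CHH class means.
#'
#' @param sites a site table.
#' @param min_cov CH coverage threshold (default 10).
#' @param include_ccg_in_chg count CCG in the CHG class (default FALSE; CCG
#'   stays a separate axis).
#' @return list of class `context_profile`: `contexts` (named 12-vector of
#'   levels), `n_sites` (sites per context), `chg`, `chh` (class means,
#'   site-weighted over their member contexts).
#' @export
mch_levels <- function(sites, min_cov = 10, include_ccg_in_chg = FALSE) {
  .check_site_table(sites)
  ch <- sites[sites$context != "CG", ]
  ch <- ch[ch$total >= min_cov, ]
  lev <- ch$meth / ch$total
  means <- tapply(lev, factor(ch$context, levels = .CHN_CONTEXTS), mean)
  ns <- tapply(lev, factor(ch$context, levels = .CHN_CONTEXTS), length)
  ns[is.na(ns)] <- 0L
  chg_ctx <- .chg_contexts(include_ccg_in_chg)
  chh_ctx <- setdiff(.chh_contexts(), chg_ctx)
  wmean <- function(ctxs) {
    w <- ns[ctxs]; v <- means[ctxs]
    ok <- !is.na(v) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  structure(list(contexts = means, n_sites = as.integer(ns),
                 chg = wmean(chg_ctx), chh = wmean(chh_ctx),
                 chg_contexts = chg_ctx, chh_contexts = chh_ctx),
            class = "context_profile")
}

#' @export
print.context_profile <- function(x, ...) {
  cat(sprintf("mCH profile: CHG %.3f, CHH %.3f\n", x$chg, x$chh))
  print(round(x$contexts, 4))
  invisible(x)
}

#' Rank CHN contexts by methylation level
#'
#' Descending by level; exact ties broken lexicographically.
#' @param profile a `context_profile` (or named numeric vector).
#' @return character vector of context names, highest first.
#' @export
context_ranking <- function(profile) {
  v <- if (inherits(profile, "context_profile")) profile$contexts else profile
  v <- v[!is.na(v)]
  names(v)[order(-v, names(v))]
}

#' Context-profile table on the radar chart's log2 axis
#' @param profiles named list of `context_profile`s (one per sample).
#' @return data.frame: sample, context, level, log2_pct
#'   (log2 of the level in percent; the radar axis).
#' @export
mch_radar_table <- function(profiles) {
  rows <- lapply(names(profiles), function(s) {
    v <- profiles[[s]]$contexts
    data.frame(sample = s, context = names(v), level = unname(v),
               log2_pct = log2(pmax(unname(v), 1e-6) * 100))
  })
  do.call(rbind, rows)
}

#' Correlation between feature mCH levels and gene expression
#'
#' Spearman correlation of per-gene mCH level against expression, per sample.
#' Genes present in both inputs are used; degenerate inputs (constant
#' expression or mCH) yield NA.
#'
#' @param mch_matrix matrix of feature mCH levels, genes x samples (rows
#'   named by gene id).
#' @param expression matrix of FPKM, genes x samples.
#' @param samples samples to evaluate (default: columns shared by both).
#' @return data.frame per sample: rho, p_value, n_genes.
#' @export
mch_expression_correlation <- function(mch_matrix, expression,
                                       samples = NULL) {
  if (is.null(samples)) {
    samples <- intersect(colnames(mch_matrix), colnames(expression))
  }
  genes <- intersect(rownames(mch_matrix), rownames(expression))
  if (length(genes) < 10) stop("need >= 10 shared genes", call. = FALSE)
  rows <- lapply(samples, function(s) {
    x <- mch_matrix[genes, s]; y <- expression[genes, s]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 10 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(data.frame(sample = s, rho = NA_real_, p_value = NA_real_,
                        n_genes = sum(ok)))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
    data.frame(sample = s, rho = unname(ct$estimate),
               p_value = ct$p.value, n_genes = sum(ok))
  })
  do.call(rbind, rows)
}
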