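## The three sample-clustering workflows over a feature matrix: raw
## methylation levels, PCA and ICA, plus component interpretation
## (common-component removal, contributor extraction, group discrimination).

#' Hierarchical clustering on raw methylation levels
#'
#' Ward clustering (on squared Euclidean distances, `ward.D2`) of samples
#' using the complete features (listwise deletion of features missing in any
#' sample).
#'
#' @param fm a `feature_matrix` (or plain features x samples matrix).
#' @return an [stats::hclust] tree over samples.
#' @export
cluster_raw <- function(fm) {
  m <- if (inherits(fm, "feature_matrix")) complete_features(fm)$levels else {
    fm[stats::complete.cases(fm), , drop = FALSE]
  }
  if (nrow(m) < 2) stop("need at least two complete features", call. = FALSE)
  stats::hclust(stats::dist(t(m)), method = "ward.D2")
}

#' ICA of a feature matrix
#'
#' Runs [fastica_decompose()] on the complete features of `fm`.
#' @param fm a `feature_matrix` or matrix.
#' @param n_components number of components (default samples - 1).
#' @param seed integer seed.
#' @param ... passed to [fastica_decompose()].
#' @return an `ica_decomposition`.
#' @export
run_ica <- function(fm, n_components = NULL, seed = 1L, ...) {
  m <- if (inherits(fm, "feature_matrix")) complete_features(fm)$levels else {
    fm[stats::complete.cases(fm), , drop = FALSE]
  }
  if (is.null(n_components)) n_components <- ncol(m) - 1L
  fastica_decompose(m, n_components = n_components, seed = seed, ...)
}

#' PCA of a feature matrix, in the same S/A layout as ICA
#'
#' Principal components of the sample-centered matrix; `S` holds the
#' per-feature scores scaled to unit variance (loadings in SD units) and `A`
#' the corresponding sample weights, so `S %*% A` reconstructs the centered
#' data. Components are variance-sorted and orthogonal.
#'
#' @param fm a `feature_matrix` or matrix.
#' @param n_components number of components (default samples - 1).
#' @return list of class `ica_decomposition` with `method = "pca"`.
#' @export
run_pca <- function(fm, n_components = NULL) {
  m <- if (inherits(fm, "feature_matrix")) complete_features(fm)$levels else {
    fm[stats::complete.cases(fm), , drop = FALSE]
  }
  if (is.null(n_components)) n_components <- ncol(m) - 1L
  center <- colMeans(m)
  Xc <- sweep(m, 2, center)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  S <- sv$u[, seq_len(n_components), drop = FALSE]
  A <- diag(sv$d[seq_len(n_components)], n_components) %*%
    t(sv$v[, seq_len(n_components), drop = FALSE])
  sds <- apply(S, 2, sd); sds[sds == 0] <- 1
  S <- sweep(S, 2, sds, `/`)
  A <- sweep(A, 1, sds, `*`)
  sgn <- vapply(seq_len(ncol(S)), function(j) {
    v <- S[which.max(abs(S[, j])), j]; if (v < 0) -1 else 1
  }, numeric(1))
  S <- sweep(S, 2, sgn, `*`)
  A <- sweep(A, 1, sgn, `*`)
  rownames(A) <- colnames(S) <- paste0("PC", seq_len(n_components))
  colnames(A) <- colnames(m)
  rownames(S) <- rownames(m)
  structure(list(S = S, A = A, center = center, converged = TRUE,
                 iterations = 0L, seed = NA_integer_, method = "pca",
                 var_explained = sv$d[seq_len(n_components)]^2 / sum(sv$d^2)),
            class = "ica_decomposition")
}

#' Identify the common component of a decomposition
#'
#' The component whose mixing-weight vector is closest to constant across
#' samples (lowest coefficient of variation): a shared baseline carried by
#' all samples, removed before component-based clustering.
#'
#' @param dec an `ica_decomposition`.
#' @return the component name.
#' @export
common_component <- function(dec) {
  cv <- apply(dec$A, 1, function(w) {
    m <- mean(w)
    if (abs(m) < 1e-12) Inf else sd(w) / abs(m)
  })
  names(which.min(cv))
}

#' Hierarchical clustering of samples on component weights
#'
#' Ward clustering of samples on the Euclidean distances between their
#' mixing-weight vectors (columns of A), after removal of the common
#' component. Weights are used as-is: with unit-variance sources, the mixing
#' rows carry each component's share of the signal, so strong components
#' dominate the distances just as they do in the raw-level workflow.
#'
#' @param dec an `ica_decomposition` (ICA or PCA).
#' @param drop_common remove the [common_component()] first (default TRUE).
#' @return an [stats::hclust] tree over samples.
#' @export
cluster_components <- function(dec, drop_common = TRUE) {
  A <- dec$A
  if (drop_common && nrow(A) > 1L) {
    A <- A[setdiff(rownames(A), common_component(dec)), , drop = FALSE]
  }
  stats::hclust(stats::dist(t(A)), method = "ward.D2")
}

#' Features contributing most to a component
#'
#' Either all features whose |loading| meets `threshold` (loadings are in SD
#' units, default 5), or the `top_n` features ranked by loading in the chosen
#' direction.
#'
#' @param dec an `ica_decomposition`.
#' @param component component name or index.
#' @param threshold absolute-loading cutoff (ignored when `top_n` is given).
#' @param top_n select the top n features by loading instead.
#' @param direction for `top_n`: `"positive"`, `"negative"` or `"absolute"`.
#' @return data.frame of feature, loading — ordered by |loading| (threshold
#'   mode) or by the ranking criterion (top-n mode).
#' @export
top_contributors <- function(dec, component, threshold = 5, top_n = NULL,
                             direction = c("absolute", "positive", "negative")) {
  direction <- match.arg(direction)
  ld <- dec$S[, component]
  if (is.null(top_n)) {
    sel <- which(abs(ld) >= threshold)
    sel <- sel[order(-abs(ld[sel]))]
  } else {
    ord <- switch(direction,
                  positive = order(-ld),
                  negative = order(ld),
                  absolute = order(-abs(ld)))
    sel <- utils::head(ord, top_n)
  }
  data.frame(feature = rownames(dec$S)[sel], loading = unname(ld[sel]),
             stringsAsFactors = FALSE)
}

#' Which component discriminates two sample groups?
#'
#' Exact two-sided Wilcoxon rank-sum p-values comparing each component's
#' mixing weights between two groups of samples, ranked by p.
#'
#' @param dec an `ica_decomposition`.
#' @param group_a,group_b character vectors of sample names (non-empty,
#'   disjoint).
#' @return data.frame (component, p_value) sorted ascending by p.
#' @export
discriminating_component <- function(dec, group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  missing <- setdiff(c(group_a, group_b), colnames(dec$A))
  if (length(missing)) stop("unknown samples: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  p <- apply(dec$A, 1, function(w) {
    ## ties (possible with degenerate weights) fall back to the normal
    ## approximation silently
    suppressWarnings(
      stats::wilcox.test(w[group_a], w[group_b], exact = TRUE)$p.value)
  })
  out <- data.frame(component = names(p), p_value = unname(p),
                    stringsAsFactors = FALSE)
  out[order(out$p_value), ]
}

#' Do samples of each group form exclusive clades?
#'
#' Cuts the tree into `length(unique(labels))` clusters and checks that the
#' clusters coincide with the labels.
#'
#' @param hc an hclust tree whose leaf names appear in `names(labels)`.
#' @param labels named character vector sample -> group.
#' @return TRUE when every cluster is exactly one label group.
#' @export
clades_recovered <- function(hc, labels) {
  k <- length(unique(labels))
  ct <- stats::cutree(hc, k = k)
  ct <- ct[names(labels)]
  tab <- table(ct, labels[names(ct)])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

#' Export a dendrogram in Newick format
#' @param hc an hclust tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  node_txt <- function(i) {
    ## negative entries in merge are leaves
    m <- hc$merge
    build <- function(row) {
      kids <- vapply(m[row, ], function(x) {
        if (x < 0) hc$labels[-x] else build(x)
      }, character(1))
      sprintf("(%s,%s)", kids[1], kids[2])
    }
    build(i)
  }
  writeLines(paste0(node_txt(nrow(hc$merge)), ";"), path)
  invisible(path)
}
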