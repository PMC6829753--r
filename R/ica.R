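## FastICA: the fixed-point algorithm with the logcosh contrast and
## symmetric decorrelation, operating on a features x samples matrix
## decomposed as X ~ S %*% A (S: per-feature source values, "loadings";
## A: mixing matrix, components x samples).

#' Independent component analysis of a data matrix
#'
#' Fixed-point ICA (logcosh nonlinearity, symmetric decorrelation) on a
#' features x samples matrix. Columns (samples) are mean-centered; the data
#' are whitened by PCA; an orthogonal rotation is estimated iteratively from
#' a seeded random start. The decomposition is normalized so that source
#' columns (loadings) have unit variance — loadings are in SD units — and is
#' sign-fixed so each source's largest-magnitude loading is positive.
#'
#' @param X numeric matrix, features x samples (no missing values).
#' @param n_components number of components (must not exceed `ncol(X)`).
#' @param seed integer seed for the random start.
#' @param max_iter,tol iteration cap and convergence tolerance.
#' @return list of class `ica_decomposition`: `S` (features x components,
#'   unit-variance columns), `A` (components x samples), `center` (per-sample
#'   means), `converged`, `iterations`, `seed`.
#' @export
fastica_decompose <- function(X, n_components = ncol(X) - 1L, seed = 1L,
                              max_iter = 500L, tol = 1e-6) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n_components > p) {
    stop("n_components must not exceed the number of samples", call. = FALSE)
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  ## PCA whitening: Z = Xc %*% K with cov(Z) = I (feature-wise covariance of
  ## samples); K is p x c
  cv <- crossprod(Xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_components)
  dpos <- pmax(eg$values[keep], 1e-12)
  K <- eg$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(dpos), n_components)
  Z <- Xc %*% K
  ## symmetric FastICA iteration
  set.seed(child_seed(seed, "fastica"))
  W <- matrix(rnorm(n_components^2), n_components)
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  converged <- FALSE
  it <- 0L
  alpha <- 1
  for (it in seq_len(max_iter)) {
    WX <- Z %*% W                      # n x c source estimates
    G <- tanh(alpha * WX)
    Gp <- alpha * (1 - G^2)
    W_new <- crossprod(Z, G) / n - sweep(W, 2, colMeans(Gp), `*`)
    W_new <- sym_orth(W_new)
    delta <- max(abs(abs(colSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("fastICA did not converge in %d iterations (seed %d)",
                    max_iter, seed))
  }
  S <- Z %*% W                          # n x c, ~unit variance by whitening
  ## A solves Xc ~ S A in least squares; with c = rank this is exact
  A <- t(W) %*% t(K %*% solve(crossprod(K)))  # c x p, inverse of whitening
  ## normalize: unit-variance loadings, scale absorbed into A; fix signs
  sds <- apply(S, 2, sd)
  sds[sds == 0] <- 1
  S <- sweep(S, 2, sds, `/`)
  A <- sweep(A, 1, sds, `*`)
  sgn <- vapply(seq_len(ncol(S)), function(j) {
    v <- S[which.max(abs(S[, j])), j]
    if (v < 0) -1 else 1
  }, numeric(1))
  S <- sweep(S, 2, sgn, `*`)
  A <- sweep(A, 1, sgn, `*`)
  rownames(A) <- colnames(S) <- paste0("IC", seq_len(n_components))
  colnames(A) <- colnames(X)
  rownames(S) <- rownames(X)
  structure(list(S = S, A = A, center = center, converged = converged,
                 iterations = it, seed = seed, method = "ica"),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("%s decomposition: %d features, %d components, %d samples%s\n",
              toupper(x$method), nrow(x$S), ncol(x$S), ncol(x$A),
              if (isTRUE(x$converged) || is.null(x$converged)) ""
              else " (NOT converged)"))
  invisible(x)
}
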