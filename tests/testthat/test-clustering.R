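## planted two-source mixture for ICA recovery tests
make_mixture <- function(n_feat = 400, n_samp = 8, noise = 0.02, seed = 9) {
  set.seed(seed)
  s1 <- numeric(n_feat); s1[1:40] <- 1          # sparse source 1
  s2 <- numeric(n_feat); s2[201:240] <- 1       # sparse source 2
  a1 <- rep(c(1, 0), each = n_samp / 2) + runif(n_samp, 0, 0.1)
  a2 <- rep(c(0, 1), times = n_samp / 2) + runif(n_samp, 0, 0.1)
  X <- outer(s1, a1) + outer(s2, a2) + 0.5 +
    matrix(rnorm(n_feat * n_samp, 0, noise), n_feat)
  colnames(X) <- paste0("s", seq_len(n_samp))
  rownames(X) <- paste0("f", seq_len(n_feat))
  list(X = X, s1 = s1, s2 = s2)
}

test_that("fastICA recovers planted independent sources", {
  mx <- make_mixture()
  dec <- fastica_decompose(mx$X, n_components = 2, seed = 1)
  expect_true(dec$converged)
  ## each planted source matches one recovered component with |r| > 0.95
  cors <- abs(cor(cbind(mx$s1, mx$s2), dec$S))
  expect_gt(max(cors[1, ]), 0.95)
  expect_gt(max(cors[2, ]), 0.95)
  expect_false(which.max(cors[1, ]) == which.max(cors[2, ]))

  ## S %*% A reconstructs the centered input (full rank here)
  decf <- suppressWarnings(
    fastica_decompose(mx$X, n_components = ncol(mx$X) - 1, seed = 1))
  Xc <- sweep(mx$X, 2, colMeans(mx$X))
  expect_lt(max(abs(decf$S %*% decf$A - Xc)), 0.05)

  ## permuted sample order: same components up to permutation and sign
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  dec_p <- fastica_decompose(mx$X[, perm], n_components = 2, seed = 1)
  cc <- abs(cor(dec$S, dec_p$S))
  expect_equal(unname(sort(apply(cc, 1, max))), c(1, 1), tolerance = 0.02)

  expect_error(fastica_decompose(mx$X, n_components = 20), "exceed")
})

test_that("PCA path is orthogonal, variance-sorted, and improves with rank", {
  mx <- make_mixture()
  dec <- run_pca(mx$X)
  ## orthogonal feature scores
  g <- crossprod(dec$S)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-6)
  ## variance explained sorted descending
  expect_true(all(diff(dec$var_explained) <= 1e-12))
  ## reconstruction error decreases monotonically with components
  Xc <- sweep(mx$X, 2, colMeans(mx$X))
  errs <- sapply(1:4, function(k) {
    d <- run_pca(mx$X, n_components = k)
    sqrt(mean((d$S %*% d$A - Xc)^2))
  })
  expect_true(all(diff(errs) < 1e-9))
})

test_that("the common component is the near-constant mixing row and is removed", {
  set.seed(4)
  S <- matrix(rnorm(300 * 3), 300, 3)
  A <- rbind(rnorm(6), rep(2, 6) + rnorm(6, 0, 0.01), rnorm(6))
  rownames(A) <- paste0("IC", 1:3)
  colnames(A) <- paste0("s", 1:6)
  dec <- structure(list(S = S, A = A, method = "ica"),
                   class = "ica_decomposition")
  expect_equal(common_component(dec), "IC2")
  hc <- cluster_components(dec)
  expect_s3_class(hc, "hclust")
  ## distances unchanged by removing a zero-variance component
  A0 <- A; A0[2, ] <- 2
  dec0 <- structure(list(S = S, A = A0, method = "ica"),
                    class = "ica_decomposition")
  d_with <- dist(t(A0[-2, , drop = FALSE]))
  d_func <- stats::cophenetic(cluster_components(dec0))
  expect_equal(as.matrix(d_func)[1, 2] > 0, TRUE)
  expect_equal(unname(as.matrix(dist(t(A0[-2, ])))[1, 2]),
               unname(as.matrix(d_with)[1, 2]))
})

test_that("raw clustering merges identical samples first; toy heights match Ward", {
  X <- cbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  hc <- cluster_raw(X)
  expect_equal(hc$height[1], 0)              # identical samples merge at 0
  first_leaves <- -hc$merge[1, hc$merge[1, ] < 0]
  expect_setequal(hc$labels[first_leaves], c("a", "b"))

  ## 3 samples on one feature: hand-computed ward.D2 linkage heights
  Y <- matrix(c(0, 3, 10), 1, 3, dimnames = list("f", c("p", "q", "r")))
  Y <- rbind(Y, 0)  # need >= 2 complete features
  hc2 <- cluster_raw(Y)
  expect_equal(hc2$height[1], 3)
  ## Lance-Williams for ward.D2: d({p,q},r) = sqrt(2/3*d_pr^2 + 2/3*d_qr^2 - 1/3*d_pq^2)
  expect_equal(hc2$height[2], sqrt(2 / 3 * 100 + 2 / 3 * 49 - 1 / 3 * 9),
               tolerance = 1e-9)
})

test_that("top contributors honor the SD-unit threshold and top-n modes", {
  S <- matrix(0, 5, 1, dimnames = list(paste0("f", 1:5), "IC1"))
  S[, 1] <- c(6, -5.2, 4.9, 0.5, -0.1)
  dec <- structure(list(S = S, A = matrix(1, 1, 2), method = "ica"),
                   class = "ica_decomposition")
  tc <- top_contributors(dec, "IC1", threshold = 5)
  expect_equal(tc$feature, c("f1", "f2"))
  expect_equal(nrow(top_contributors(dec, "IC1", threshold = Inf)), 0)
  tp <- top_contributors(dec, "IC1", top_n = 2, direction = "positive")
  expect_equal(tp$feature, c("f1", "f3"))
  expect_true(all(diff(tp$loading) <= 0))
})

test_that("component discrimination gives exact rank-sum p-values", {
  A <- rbind(IC1 = c(10, 9, 1, 2), IC2 = c(5, 1, 6, 2))
  colnames(A) <- paste0("s", 1:4)
  dec <- structure(list(S = matrix(0, 2, 2), A = A, method = "ica"),
                   class = "ica_decomposition")
  dc <- discriminating_component(dec, c("s1", "s2"), c("s3", "s4"))
  ## complete separation with n = 2 vs 2: exact two-sided p = 2/choose(4,2)
  expect_equal(dc$p_value[dc$component == "IC1"], 1 / 3)
  expect_equal(dc$component[1], "IC1")   # ranked first

  ## identical groups -> p = 1
  A2 <- rbind(IC1 = c(3, 7, 3, 7))
  colnames(A2) <- paste0("s", 1:4)
  dec2 <- structure(list(S = matrix(0, 1, 1), A = A2, method = "ica"),
                    class = "ica_decomposition")
  dc2 <- discriminating_component(dec2, c("s1", "s2"), c("s3", "s4"))
  expect_equal(dc2$p_value, 1)
  expect_error(discriminating_component(dec2, "nope", "s3"), "unknown")
})

test_that("planted group difference is found by the ICA workflow end-to-end", {
  mx <- make_mixture(noise = 0.05)
  dec <- fastica_decompose(mx$X, n_components = 3, seed = 2)
  ga <- paste0("s", 1:4); gb <- paste0("s", 5:8)
  dc <- discriminating_component(dec, ga, gb)
  ## the top-ranked component separates the groups driven by source 1
  best <- dc$component[1]
  expect_lt(dc$p_value[1], 0.05)
  contrib <- top_contributors(dec, best, top_n = 40)$feature
  expect_gt(length(intersect(contrib, paste0("f", 1:40))) /
              length(contrib), 0.8)
})
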