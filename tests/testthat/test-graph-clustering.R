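two_cliques <- function(m = 5) {
  A <- matrix(0, 2 * m, 2 * m)
  A[1:m, 1:m] <- 1
  A[(m + 1):(2 * m), (m + 1):(2 * m)] <- 1
  diag(A) <- 0
  A
}

test_that("preprocessing standardizes columns and unit-normalizes rows", {
  set.seed(1)
  X <- matrix(stats::rnorm(60), 10, 6)
  P <- preprocess_features(X)
  expect_equal(unname(rowSums(P^2)), rep(1, 10), tolerance = 1e-12)
  # identical rows map to identical unit vectors
  X2 <- rbind(X[1, ], X[1, ], X[2:10, ])
  P2 <- suppressWarnings(preprocess_features(X2))
  expect_equal(P2[1, ], P2[2, ])
  # constant column dropped with a warning
  X3 <- cbind(X, 5)
  expect_warning(P3 <- preprocess_features(X3), "zero-variance")
  expect_equal(ncol(P3), 6L)
  expect_error(preprocess_features(matrix(NA_real_, 3, 2)), "missing")
})

test_that("kNN graph is symmetric, hollow, and deterministic", {
  set.seed(2)
  X <- preprocess_features(matrix(stats::rnorm(200), 40, 5))
  g1 <- build_knn_graph(X, n_neighbors = 10)
  g2 <- build_knn_graph(X, n_neighbors = 10)
  A <- g1$adjacency
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_true(all(A >= 0 & A <= 1 + 1e-12))
  expect_identical(A, g2$adjacency)
  expect_error(build_knn_graph(X[1:10, ], n_neighbors = 20), "n_neighbors")
})

test_that("modularity matches the brute-force double sum to 1e-12", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    A <- matrix(stats::runif(n * n), n, n) * (matrix(stats::runif(n * n),
                                                     n, n) < 0.2)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    for (g in c(0, 0.7, 1, 2.5)) {
      labels <- sample(1:4, n, replace = TRUE)
      expect_equal(modularity_score(A, labels, gamma = g),
                   modularity_bruteforce(A, labels, gamma = g),
                   tolerance = 1e-12)
    }
  }
  # the all-in-one partition at gamma = 1 has Q = sum(A^2 terms) ...
  A <- two_cliques()
  expect_equal(modularity_score(A, rep(1, 10), gamma = 1),
               modularity_bruteforce(A, rep(1, 10), gamma = 1),
               tolerance = 1e-12)
})

test_that("Louvain separates disconnected cliques and reports own-Q", {
  A <- two_cliques()
  cl <- louvain_cluster(A, resolution = 1, seed = 4)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(length(unique(cl$labels[1:5])), 1L)
  expect_equal(length(unique(cl$labels[6:10])), 1L)
  expect_false(cl$labels[1] == cl$labels[6])
  expect_equal(cl$modularity,
               modularity_bruteforce(A, cl$labels, gamma = 1),
               tolerance = 1e-12)
  # resolution 0: the null term vanishes, so the single community scores
  # at least as high as any split the optimizer returns
  cl0 <- louvain_cluster(A, resolution = 0, seed = 4)
  expect_gte(modularity_score(A, rep(1, 10), gamma = 0),
             cl0$modularity - 1e-12)
})

test_that("resolution scan recovers planted clusters with zero count SD", {
  mix <- gaussian_mixture(20, centers = 5 * diag(4), sd = 1, seed = 5)
  X <- preprocess_features(mix$X)
  g <- build_knn_graph(X, n_neighbors = 10)
  sel <- select_resolution(g, resolutions = c(0, 0.5, 1), n_repeats = 10,
                           subsample_frac = 0.9, seed = 6)
  expect_gt(sel$gamma_star, 0)
  row <- sel$stability[sel$stability$resolution == sel$gamma_star, ]
  expect_equal(row$k_sd, 0)
  expect_equal(row$k_mean, 4)
  expect_equal(sel$result$n_clusters, 4L)
  expect_gt(adjusted_rand_index(sel$result$labels, mix$labels), 0.99)
  # a single-value grid returns that value
  sel1 <- select_resolution(g, resolutions = 1, n_repeats = 3, seed = 7)
  expect_equal(sel1$gamma_star, 1)
})

test_that("ECG consensus agrees with Louvain on clean structure", {
  A <- two_cliques(8)
  e <- ecg_cluster(A, k = 8, w_star = 0.05, seed = 8)
  cl <- louvain_cluster(A, seed = 8)
  expect_equal(adjusted_rand_index(e$labels, cl$labels), 1)
  # ensemble weights stay within [w*, 1] on the 2-core
  expect_true(all(e$ensemble_weights >= 0.05 - 1e-12 &
                    e$ensemble_weights <= 1 + 1e-12))
  expect_error(ecg_cluster(A, w_star = 1.2), "w_star")
})

test_that("cluster likelihood is the row-normalized contingency", {
  P <- cluster_likelihood(c(1, 1, 2, 2), c(1, 2, 1, 1))
  expect_equal(unclass(P), matrix(c(0.5, 1, 0.5, 0), 2, 2),
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(P)), c(1, 1))
  # identical labelings give the identity pattern
  P2 <- cluster_likelihood(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(unclass(P2), diag(3), ignore_attr = TRUE)
  set.seed(9)
  a <- sample(1:4, 60, replace = TRUE); b <- sample(1:3, 60, replace = TRUE)
  expect_equal(unname(rowSums(cluster_likelihood(a, b))), rep(1, 4))
})

test_that("ARI and AMI behave as chance-adjusted agreement indices", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_mutual_information(a, a), 1)
  # invariance under label permutation
  b <- c(3, 3, 1, 1, 2, 2)
  expect_equal(adjusted_rand_index(a, b), 1)
  expect_equal(adjusted_mutual_information(a, b), 1)
  # independent labelings score near zero
  set.seed(10)
  x <- sample(1:5, 1000, replace = TRUE)
  y <- sample(1:5, 1000, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(x, y)), 0.05)
  expect_lt(abs(adjusted_mutual_information(x, y)), 0.05)
  # symmetry
  cmp1 <- compare_labelings(x, y); cmp2 <- compare_labelings(y, x)
  expect_equal(cmp1$ari, cmp2$ari)
  expect_equal(cmp1$ami, cmp2$ami, tolerance = 1e-12)
})

test_that("ARI matches the independent mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (i in 1:10) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("cosine summaries match the brute-force block averages", {
  # hand-computed 4-vector case
  X <- rbind(c(1, 0), c(0, 1), c(1, 1) / sqrt(2), c(-1, 0))
  la <- c(1, 1, 2, 2)
  lb <- c(1, 2, 1, 2)
  expect_equal(cosine_summary(X, la, lb),
               cosine_summary_bruteforce(X, la, lb, same = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
  # same-labeling diagonal blocks use the strict upper triangle
  expect_equal(cosine_summary(X, la),
               cosine_summary_bruteforce(X, la),
               ignore_attr = TRUE, tolerance = 1e-12)
  # identical vectors -> all entries 1; orthogonal groups -> 0 off-diagonal
  Xi <- matrix(rep(c(0.6, 0.8), each = 6), 6, 2)
  expect_true(all(abs(cosine_summary(Xi, rep(1:2, 3)) - 1) < 1e-12))
  Xo <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(cosine_summary(Xo, c(1, 1, 2, 2))[1, 2], 0)
  set.seed(12)
  Xr <- preprocess_features(matrix(stats::rnorm(80), 16, 5))
  lr <- sample(1:3, 16, replace = TRUE)
  expect_equal(cosine_summary(Xr, lr),
               cosine_summary_bruteforce(Xr, lr),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("similarity groups enumerate within/across pairs", {
  set.seed(13)
  X <- preprocess_features(matrix(stats::rnorm(25), 5, 5))
  cls <- c("E", "E", "E", "I", "I")
  g <- similarity_groups(X, cls)
  expect_equal(lengths(g), c("E-E" = 3L, "I-I" = 1L, "E-I" = 6L))
  # brute-force cross-check of every value
  S <- X %*% t(X)
  expect_equal(sort(g[["E-E"]]), sort(c(S[1, 2], S[1, 3], S[2, 3])))
  expect_equal(g[["I-I"]], S[4, 5])
  expect_equal(sort(g[["E-I"]]), sort(as.numeric(S[1:3, 4:5])))
  Xi <- matrix(rep(c(1, 0), each = 4), 4, 2)
  gi <- similarity_groups(Xi, c("E", "E", "I", "I"))
  expect_true(all(abs(unlist(gi) - 1) < 1e-12))
})
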