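#' Standardize columns and L2-normalize rows of a feature matrix
#'
#' Columns are z-scored with the population standard deviation, then each
#' row (one neuron's feature vector) is scaled to unit L2 norm — the
#' preprocessing applied to every attribute set before graph construction.
#' Zero-variance columns carry no information and would produce NaNs under
#' z-scoring; they are dropped with a warning.
#'
#' @param X numeric matrix, one row per neuron.
#' @return matrix with unit-norm rows; attribute `dropped` lists removed
#'   column indices.
#' @export
preprocess_features <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  if (anyNA(X)) stop("missing values must be imputed or dropped by the caller")
  n <- nrow(X)
  mu <- colMeans(X)
  sdp <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  drop <- which(sdp == 0)
  if (length(drop)) {
    warning(length(drop), " zero-variance column(s) dropped")
    X <- X[, -drop, drop = FALSE]
    mu <- mu[-drop]; sdp <- sdp[-drop]
  }
  Z <- sweep(sweep(X, 2L, mu), 2L, sdp, "/")
  nrm <- sqrt(rowSums(Z^2))
  nrm[nrm == 0] <- 1
  out <- Z / nrm
  attr(out, "dropped") <- drop
  out
}

# smooth-kNN membership strengths (the fuzzy simplicial set construction):
# rho_i is the distance to the nearest neighbour, sigma_i solves
# sum_j exp(-(d_ij - rho_i)_+ / sigma_i) = log2(k) by bisection
smooth_knn <- function(d, k) {
  rho <- d[1L]
  target <- log2(k)
  f <- function(sig) sum(exp(-pmax(d - rho, 0) / sig)) - target
  lo <- 1e-6; hi <- max(d) + 1
  if (f(hi) < 0) return(list(rho = rho, sigma = hi))
  for (it in 1:64) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  list(rho = rho, sigma = (lo + hi) / 2)
}

#' Build the fuzzy k-nearest-neighbour graph
#'
#' The high-dimensional graph substrate used for clustering: exact
#' k-nearest neighbours under Euclidean distance, per-point membership
#' strengths `exp(-(d - rho_i)/sigma_i)` with the smooth-kNN calibration
#' (`sum = log2(k)`), symmetrized by the probabilistic t-conorm
#' `a + a' - a a'`. The 2-D layout step is deliberately not part of the
#' clustering path (it is plot-only in this pipeline), so the construction
#' is deterministic; `min_dist` and `seed` are recorded as build parameters.
#'
#' @param X preprocessed feature matrix (rows = neurons).
#' @param n_neighbors neighbourhood size; default 20.
#' @param min_dist embedding parameter, recorded only; default 0.1.
#' @param seed recorded build seed.
#' @return object of class `neighbor_graph`: `adjacency` (dense symmetric
#'   matrix, zero diagonal), `graph` (igraph, weighted), `params`.
#' @export
build_knn_graph <- function(X, n_neighbors = 20L, min_dist = 0.1,
                            seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_neighbors + 1L)
    stop("need at least n_neighbors + 1 rows (", n_neighbors + 1L, ")")
  D <- as.matrix(stats::dist(X))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d_all <- D[i, -i]
    ord <- order(d_all)[seq_len(n_neighbors)]
    nb <- which(seq_len(n) != i)[ord]
    d <- D[i, nb]
    sk <- smooth_knn(d, n_neighbors)
    A[i, nb] <- exp(-pmax(d - sk$rho, 0) / sk$sigma)
  }
  S <- A + t(A) - A * t(A)
  diag(S) <- 0
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE)
  out <- list(adjacency = S, graph = g,
              params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                            seed = seed))
  class(out) <- "neighbor_graph"
  out
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d nodes, %d edges (k = %d)\n",
              nrow(x$adjacency), igraph::ecount(x$graph),
              x$params$n_neighbors))
  invisible(x)
}

as_adjacency <- function(graph) {
  if (inherits(graph, "neighbor_graph")) return(graph$adjacency)
  if (inherits(graph, "igraph"))
    return(as.matrix(igraph::as_adjacency_matrix(graph, attr =
      if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL)))
  as.matrix(graph)
}

as_igraph <- function(graph) {
  if (inherits(graph, "neighbor_graph")) return(graph$graph)
  if (inherits(graph, "igraph")) return(graph)
  igraph::graph_from_adjacency_matrix(as.matrix(graph), mode = "undirected",
                                      weighted = TRUE)
}

#' Modularity of a partition at resolution gamma
#'
#' Direct evaluation of
#' `Q = (1/w) sum_ij [A_ij - gamma d_i d_j / w] delta(c_i, c_j)` on the
#' symmetric weighted adjacency (`d_i` the weighted degree, `w` the total
#' weight including both edge orientations), independent of any community
#' detector's internal value. Computed by community aggregation, which is
#' algebraically identical to the double sum.
#'
#' @param graph a `neighbor_graph`, igraph, or adjacency matrix.
#' @param labels community id per node.
#' @param gamma resolution parameter.
#' @return modularity Q.
#' @export
modularity_score <- function(graph, labels, gamma = 1) {
  A <- as_adjacency(graph)
  stopifnot(nrow(A) == length(labels))
  w <- sum(A)
  if (w == 0) return(0)
  d <- rowSums(A)
  labs <- unique(labels)
  q <- 0
  for (cl in labs) {
    m <- labels == cl
    q <- q + sum(A[m, m]) / w - gamma * (sum(d[m]) / w)^2
  }
  q
}

#' Louvain community detection at a fixed resolution
#'
#' Runs Louvain modularity optimization on the weighted graph. The
#' modularity reported for the returned labels is recomputed with
#' [modularity_score()], not taken from the optimizer. Node-order
#' tie-breaking is controlled by the seed; with `n_restarts > 1` the run
#' with the highest recomputed Q is returned.
#'
#' @param graph a `neighbor_graph`, igraph or adjacency matrix.
#' @param resolution resolution parameter gamma.
#' @param seed integer seed.
#' @param n_restarts number of restarts; the max-Q run is kept.
#' @return object of class `cluster_result`: `labels`, `resolution`,
#'   `modularity`, `n_clusters`, `method`.
#' @export
louvain_cluster <- function(graph, resolution = 1, seed = NULL,
                            n_restarts = 1L) {
  g <- as_igraph(graph)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    labels <- as.integer(igraph::membership(cl))
    q <- modularity_score(graph, labels, gamma = resolution)
    if (is.null(best) || q > best$modularity)
      best <- list(labels = labels, modularity = q)
  }
  out <- list(labels = best$labels, resolution = resolution,
              modularity = best$modularity,
              n_clusters = length(unique(best$labels)), method = "louvain")
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s: %d clusters at gamma = %g, Q = %.4f\n",
              x$method, x$n_clusters, x$resolution, x$modularity))
  invisible(x)
}

#' Resolution scan with subsample stability
#'
#' For each resolution in the grid, clusters `n_repeats` random node
#' subsamples (induced subgraphs of fraction `subsample_frac`) and records
#' the mean and SD of the recomputed modularity and of the cluster count.
#' The selected resolution maximizes the mean modularity over the strictly
#' positive grid values (gamma = 0 has a degenerate single-community
#' optimum and is recorded but excluded from the argmax).
#'
#' @param graph a `neighbor_graph` or igraph.
#' @param resolutions resolution grid; default `seq(0, 5, 0.5)`.
#' @param n_repeats subsample repeats per resolution; default 25.
#' @param subsample_frac node fraction per repeat; default 0.9.
#' @param restarts Louvain restarts per subsample run (max-Q kept), so the
#'   stability statistics reflect the data, not optimizer tie-breaking.
#' @param seed integer seed.
#' @return list with `gamma_star`, `stability` (data.frame: resolution,
#'   q_mean, q_sd, k_mean, k_sd), and `result` (a `cluster_result` on the
#'   full graph at `gamma_star`, best of `n_repeats` restarts).
#' @export
select_resolution <- function(graph, resolutions = seq(0, 5, by = 0.5),
                              n_repeats = 25L, subsample_frac = 0.9,
                              restarts = 3L, seed = NULL) {
  stopifnot(length(resolutions) >= 1L)
  A <- as_adjacency(graph)
  n <- nrow(A)
  if (!is.null(seed)) set.seed(seed)
  m <- max(2L, round(subsample_frac * n))
  rows <- lapply(resolutions, function(res) {
    qs <- ks <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      keep <- sort(sample.int(n, m))
      As <- A[keep, keep]
      gs <- igraph::graph_from_adjacency_matrix(As, mode = "undirected",
                                                weighted = TRUE)
      q_best <- -Inf; k_best <- NA_integer_
      for (j in seq_len(restarts)) {
        lab <- as.integer(igraph::membership(
          igraph::cluster_louvain(gs, resolution = res)))
        q <- modularity_score(As, lab, gamma = res)
        if (q > q_best) { q_best <- q; k_best <- length(unique(lab)) }
      }
      qs[r] <- q_best
      ks[r] <- k_best
    }
    c(resolution = res, q_mean = mean(qs), q_sd = stats::sd(qs),
      k_mean = mean(ks), k_sd = stats::sd(ks))
  })
  stab <- as.data.frame(do.call(rbind, rows))
  pos <- stab$resolution > 0
  if (!any(pos)) stop("resolution grid must contain a positive value")
  gamma_star <- stab$resolution[pos][which.max(stab$q_mean[pos])]
  res_full <- louvain_cluster(graph, resolution = gamma_star,
                              n_restarts = n_repeats)
  list(gamma_star = gamma_star, stability = stab, result = res_full)
}

#' Ensemble clustering for graphs (consensus Louvain)
#'
#' Generation step: `k` level-1 (first-pass) Louvain partitions with
#' randomized vertex order. Integration step: each edge is reweighted to
#' `w* + (1 - w*) * (co-clustering frequency)` if it lies in the 2-core of
#' the graph and to the floor `w*` otherwise, and a final Louvain pass runs
#' on the reweighted graph.
#'
#' @param graph a `neighbor_graph` or igraph.
#' @param k number of level-1 partitions; default 16.
#' @param w_star minimum ensemble weight, in (0, 1); default 0.05.
#' @param resolution resolution for the final pass.
#' @param seed integer seed.
#' @return a `cluster_result` (method "ecg") with the consensus labels;
#'   `modularity` is evaluated on the original graph at the given
#'   resolution. The reweighted adjacency is attached as `ensemble_weights`.
#' @export
ecg_cluster <- function(graph, k = 16L, w_star = 0.05, resolution = 1,
                        seed = NULL) {
  if (w_star <= 0 || w_star >= 1) stop("`w_star` must be in (0, 1)")
  g <- as_igraph(graph)
  A <- as_adjacency(graph)
  n <- igraph::vcount(g)
  if (!is.null(seed)) set.seed(seed)
  edges <- igraph::as_edgelist(g, names = FALSE)
  co <- numeric(nrow(edges))
  for (i in seq_len(k)) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp, resolution = resolution)
    memb_all <- cl$memberships
    lev1 <- if (!is.null(memb_all) && nrow(memb_all) >= 1L)
      memb_all[1L, ] else as.integer(igraph::membership(cl))
    lab <- integer(n)
    lab[perm] <- lev1          # map back to original vertex ids
    co <- co + (lab[edges[, 1L]] == lab[edges[, 2L]])
  }
  core <- igraph::coreness(g)
  in2core <- core[edges[, 1L]] >= 2 & core[edges[, 2L]] >= 2
  wts <- ifelse(in2core, w_star + (1 - w_star) * co / k, w_star)
  g2 <- g
  igraph::E(g2)$weight <- wts
  cl <- igraph::cluster_louvain(g2, resolution = resolution)
  labels <- as.integer(igraph::membership(cl))
  out <- list(labels = labels, resolution = resolution,
              modularity = modularity_score(A, labels, gamma = resolution),
              n_clusters = length(unique(labels)), method = "ecg",
              ensemble_weights = wts, k = k, w_star = w_star)
  class(out) <- "cluster_result"
  out
}

#' Cluster-membership likelihood matrix
#'
#' Row-normalized contingency matrix: entry (i, j) is the probability that
#' a neuron in cluster i of the first labeling falls in cluster j of the
#' second.
#'
#' @param labels_a,labels_b labelings of the same neurons.
#' @return matrix with rows summing to 1 (rows of empty clusters are NaN
#'   and flagged via the `empty_rows` attribute).
#' @export
cluster_likelihood <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  C <- table(labels_a, labels_b)
  P <- sweep(unclass(C), 1L, rowSums(C), "/")
  attr(P, "empty_rows") <- rownames(C)[rowSums(C) == 0]
  P
}

#' Adjusted Rand index
#'
#' Chance-corrected pairwise agreement between two labelings.
#'
#' @param labels_a,labels_b labelings of the same items.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  C <- unclass(table(labels_a, labels_b))
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(C))
  sum_a <- sum(ch2(rowSums(C)))
  sum_b <- sum(ch2(colSums(C)))
  exp_idx <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)   # both partitions trivial
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Adjusted mutual information
#'
#' Mutual information corrected for chance under the permutation
#' (hypergeometric) model, normalized by the arithmetic mean of the two
#' entropies.
#'
#' @param labels_a,labels_b labelings of the same items.
#' @return AMI (1 for identical partitions, ~0 for independent ones).
#' @export
adjusted_mutual_information <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  C <- unclass(table(labels_a, labels_b))
  a <- rowSums(C); b <- colSums(C)
  N <- sum(C)
  ent <- function(x) {
    p <- x[x > 0] / N
    -sum(p * log(p))
  }
  h_a <- ent(a); h_b <- ent(b)
  p <- C / N
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (C[i, j] > 0)
      mi <- mi + p[i, j] * log(p[i, j] / (a[i] * b[j] / N^2))
  }
  # expected MI under random permutations (hypergeometric model)
  emi <- 0
  lfac <- lgamma(seq_len(N + 1))  # lfac[x+1] = log(x!)
  lf <- function(x) lfac[x + 1]
  for (i in seq_along(a)) for (j in seq_along(b)) {
    ai <- a[i]; bj <- b[j]
    lo <- max(1, ai + bj - N); hi <- min(ai, bj)
    if (hi < lo) next
    for (nij in lo:hi) {
      term1 <- nij / N * log(N * nij / (ai * bj))
      term2 <- exp(lf(ai) + lf(bj) + lf(N - ai) + lf(N - bj) - lf(N) -
                     lf(nij) - lf(ai - nij) - lf(bj - nij) -
                     lf(N - ai - bj + nij))
      emi <- emi + term1 * term2
    }
  }
  denom <- (h_a + h_b) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(1)
  unname((mi - emi) / denom)
}

#' ARI and AMI between two labelings
#'
#' @param labels_a,labels_b labelings of the same items.
#' @return list with `ari` and `ami`.
#' @export
compare_labelings <- function(labels_a, labels_b) {
  list(ari = adjusted_rand_index(labels_a, labels_b),
       ami = adjusted_mutual_information(labels_a, labels_b))
}

#' Per-cluster-pair mean cosine similarity
#'
#' Averages the pairwise cosine-similarity matrix over the block of each
#' (cluster_a, cluster_b) pair. When both labelings are the same partition
#' of the same matrix, the diagonal blocks (within-cluster comparisons)
#' average only the strict upper triangle, so self-similarities do not
#' inflate the within-cluster mean.
#'
#' @param X feature matrix with unit-normalized rows (labels_a blocks).
#' @param labels_a cluster labels for the rows of `X`.
#' @param labels_b second labeling; either of the same rows (default
#'   `labels_a`) or of the rows of `X_b`.
#' @param X_b optional second matrix (e.g. the other protocol's features);
#'   default `X`.
#' @return matrix of block means (clusters_a x clusters_b); singleton
#'   within-cluster blocks are NaN.
#' @export
cosine_summary <- function(X, labels_a, labels_b = labels_a, X_b = X) {
  X <- as.matrix(X); X_b <- as.matrix(X_b)
  stopifnot(nrow(X) == length(labels_a), nrow(X_b) == length(labels_b))
  S <- X %*% t(X_b)
  ua <- sort(unique(labels_a)); ub <- sort(unique(labels_b))
  same <- identical(dim(X), dim(X_b)) && all(X == X_b) &&
    length(labels_a) == length(labels_b) && all(labels_a == labels_b)
  out <- matrix(NA_real_, length(ua), length(ub),
                dimnames = list(ua, ub))
  for (i in seq_along(ua)) for (j in seq_along(ub)) {
    ra <- which(labels_a == ua[i]); rb <- which(labels_b == ub[j])
    blk <- S[ra, rb, drop = FALSE]
    if (same && ua[i] == ub[j]) {
      if (length(ra) < 2L) { out[i, j] <- NaN; next }
      out[i, j] <- mean(blk[upper.tri(blk)])
    } else {
      out[i, j] <- mean(blk)
    }
  }
  out
}

#' Within- and across-class cosine-similarity value sets
#'
#' Builds the three groups compared by the downstream omnibus test: the
#' strict upper-triangular within-class cosines for each of the two classes
#' and all cross-class cosines. The test itself (e.g. `oneway.test`, i.e.
#' Welch's ANOVA) is left to standard routines.
#'
#' @param X feature matrix with unit-normalized rows.
#' @param class_labels two-level labeling (e.g. "E"/"I") of the rows.
#' @return named list of three numeric vectors: within first class, within
#'   second class, across; empty within-sets (class size < 2) are flagged
#'   with a warning.
#' @export
similarity_groups <- function(X, class_labels) {
  X <- as.matrix(X)
  lv <- sort(unique(class_labels))
  if (length(lv) != 2L) stop("`class_labels` must have exactly two levels")
  i1 <- which(class_labels == lv[1L]); i2 <- which(class_labels == lv[2L])
  S <- X %*% t(X)
  w1 <- S[i1, i1, drop = FALSE][upper.tri(matrix(0, length(i1), length(i1)))]
  w2 <- S[i2, i2, drop = FALSE][upper.tri(matrix(0, length(i2), length(i2)))]
  if (!length(w1) || !length(w2))
    warning("a class has fewer than 2 members; its within-set is empty")
  out <- list(w1, w2, as.numeric(S[i1, i2]))
  names(out) <- c(paste0(lv[1L], "-", lv[1L]), paste0(lv[2L], "-", lv[2L]),
                  paste0(lv[1L], "-", lv[2L]))
  out
}
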