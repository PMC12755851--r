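#' Attribute set container
#'
#' One of the multi-modal feature families (action-potential attributes,
#' passive biophysics, adaptation current, spike-triggered average) as a
#' neurons x features matrix sharing a common neuron roster.
#'
#' @param Y numeric matrix, neurons in rows.
#' @param name set name.
#' @return object of class `attribute_set` (a matrix with a `name`
#'   attribute).
#' @export
attribute_set <- function(Y, name) {
  Y <- as.matrix(Y)
  attr(Y, "name") <- name
  class(Y) <- c("attribute_set", class(Y))
  Y
}

set_name <- function(Y, default = "set") attr(Y, "name") %||% default

#' Shared-dimension selection by eigenvalue thresholding
#'
#' Counts the correlation-matrix eigenvalues above a noise threshold for
#' each standardized attribute set (and for the pooled matrix when a list
#' is given). Two threshold rules are available: `one_plus_ratio` uses
#' `1 + p/N` (a conservative heuristic, the default); `mp_edge` uses the
#' Marchenko-Pastur bulk edge `(1 + sqrt(p/N))^2`, the standard
#' random-matrix choice. The shared
#' dimension `d` passed to [fit_mcfa()] is a user decision informed by
#' these counts.
#'
#' @param Y a matrix (neurons x features) or list of such matrices.
#' @param rule `"one_plus_ratio"` or `"mp_edge"`.
#' @return for a single matrix, the count (integer with attribute
#'   `threshold`); for a list, a list with per-set counts and the pooled
#'   count.
#' @export
select_shared_dim <- function(Y, rule = c("one_plus_ratio", "mp_edge")) {
  rule <- match.arg(rule)
  count_one <- function(M) {
    M <- as.matrix(M)
    N <- nrow(M); p <- ncol(M)
    if (N < 2L) stop("need at least 2 samples")
    Z <- scale(M) * sqrt(N / (N - 1))       # population-SD standardization
    Z[is.na(Z)] <- 0
    ev <- svd(Z / sqrt(N), nu = 0, nv = 0)$d^2
    thr <- if (rule == "one_plus_ratio") 1 + p / N else (1 + sqrt(p / N))^2
    structure(sum(ev > thr), threshold = thr)
  }
  if (is.matrix(Y) || is.data.frame(Y)) return(count_one(Y))
  per_set <- lapply(Y, count_one)
  names(per_set) <- vapply(seq_along(Y), function(i)
    set_name(Y[[i]], paste0("set", i)), character(1))
  pooled <- count_one(do.call(cbind, lapply(Y, as.matrix)))
  list(per_set = vapply(per_set, as.integer, 1L),
       pooled = as.integer(pooled), rule = rule)
}

# z-score columns (sample SD); constant columns centred only
standardize_cols <- function(M) {
  M <- as.matrix(M)
  s <- apply(M, 2L, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  sweep(sweep(M, 2L, colMeans(M)), 2L, s, "/")
}

#' Fit the multi-set shared/private factor model by EM
#'
#' Gaussian latent model in which every attribute set `Y_m` loads on a
#' common shared factor `z` (dimension `d`) through `W_m` and on its own
#' private factor `x_m` (dimension `k_m`) through `L_m`, plus diagonal
#' residual noise `Psi_m`:
#' `y_m = W_m z + L_m x_m + eps_m`, `z ~ N(0, I_d)`, `x_m ~ N(0, I_km)`.
#' Jointly this is a factor model with block-structured loadings; the EM
#' iterations compute exact posterior moments of `(z, x_1, ..., x_M)` and
#' maximize the expected complete-data likelihood per set, preserving the
#' block-zero pattern. Features are z-scored before fitting. Initialization
#' is from the top-`d` principal components of the concatenated
#' standardized data (shared) and per-set residual principal components
#' (private). The marginal log-likelihood is checked to be non-decreasing
#' at every iteration.
#'
#' @param Y list of matrices (neurons x features) over a common roster.
#' @param d shared dimension (>= 1).
#' @param k private dimensions; a single value or one per set. Default 2,
#'   with 1 for any set of 8 or fewer features (the convention used for the
#'   low-dimensional passive set).
#' @param tol stop when the log-likelihood gain falls below `tol`.
#' @param max_iter iteration cap.
#' @param seed integer seed (initialization is deterministic; the seed
#'   covers any residual tie-breaking).
#' @return object of class `mcfa_model`: `W` (shared loadings per set),
#'   `L` (private loadings), `psi` (residual variance vectors), `z_hat`
#'   (posterior shared scores, N x d), `x_hat` (private scores per set),
#'   `d`, `k`, `loglik` (trace), `converged`, `var_total` (per-set total
#'   feature variance of the standardized data), `names`.
#' @export
fit_mcfa <- function(Y, d, k = NULL, tol = 1e-6, max_iter = 500L,
                     seed = NULL) {
  stopifnot(is.list(Y), length(Y) >= 2L, d >= 1L)
  M <- length(Y)
  Ys <- lapply(Y, standardize_cols)
  N <- nrow(Ys[[1L]])
  if (!all(vapply(Ys, nrow, 1L) == N))
    stop("all attribute sets must share the same neuron roster")
  p <- vapply(Ys, ncol, 1L)
  if (is.null(k)) k <- ifelse(p <= 8L, 1L, 2L)
  if (length(k) == 1L) k <- rep(k, M)
  stopifnot(length(k) == M, all(k >= 0L))
  nms <- vapply(seq_len(M), function(i) set_name(Y[[i]], paste0("set", i)),
                character(1))
  if (!is.null(seed)) set.seed(seed)

  Ycat <- do.call(cbind, Ys)
  P <- ncol(Ycat)
  off <- c(0L, cumsum(p))         # feature offsets
  qoff <- c(0L, cumsum(k))        # private-latent offsets
  q <- d + sum(k)

  # ---- initialization: shared from pooled PCs, private from residual PCs
  sv <- svd(Ycat / sqrt(N), nu = min(d, N), nv = d)
  W0 <- sv$v %*% diag(sv$d[seq_len(d)], d)       # PCA loadings
  # unit-variance pooled scores so that Z0 W0' reproduces the PC projection
  Z0 <- Ycat %*% sv$v %*% diag(1 / sv$d[seq_len(d)], d)
  W <- lapply(seq_len(M), function(m)
    W0[(off[m] + 1L):off[m + 1L], , drop = FALSE])
  L <- vector("list", M); psi <- vector("list", M)
  for (m in seq_len(M)) {
    R <- Ys[[m]] - Z0 %*% t(W[[m]])
    if (k[m] > 0L) {
      svr <- svd(R / sqrt(N), nu = 0, nv = k[m])
      L[[m]] <- svr$v %*% diag(svr$d[seq_len(k[m])], k[m])
    } else L[[m]] <- matrix(0, p[m], 0L)
    res_var <- pmax(colMeans(R^2) - rowSums(L[[m]]^2), 1e-3)
    psi[[m]] <- res_var
  }

  build_lambda <- function() {
    Lam <- matrix(0, P, q)
    for (m in seq_len(M)) {
      rows <- (off[m] + 1L):off[m + 1L]
      Lam[rows, seq_len(d)] <- W[[m]]
      if (k[m] > 0L)
        Lam[rows, d + (qoff[m] + 1L):qoff[m + 1L]] <- L[[m]]
    }
    Lam
  }

  loglik_trace <- numeric(0)
  converged <- FALSE
  EU <- NULL; Minv <- NULL
  for (it in seq_len(max_iter)) {
    Lam <- build_lambda()
    psiv <- unlist(psi)
    Lp <- Lam / psiv                   # Psi^-1 Lambda
    Mq <- diag(q) + crossprod(Lam, Lp) # I + Lam' Psi^-1 Lam
    Mq <- (Mq + t(Mq)) / 2
    Minv <- solve(Mq)
    # marginal log-likelihood via Woodbury / determinant lemma
    T1 <- Ycat %*% Lp                  # N x q
    quad <- rowSums(sweep(Ycat, 2L, sqrt(psiv), "/")^2) -
      rowSums((T1 %*% Minv) * T1)
    logdet <- sum(log(psiv)) + determinant(Mq, logarithm = TRUE)$modulus[1L]
    ll <- -0.5 * (N * P * log(2 * pi) + N * logdet + sum(quad))
    if (length(loglik_trace) &&
        ll < loglik_trace[length(loglik_trace)] - 1e-5 * (abs(ll) + 1))
      stop("EM monotonicity violated; log-likelihood decreased")
    gain <- if (length(loglik_trace))
      ll - loglik_trace[length(loglik_trace)] else Inf
    loglik_trace <- c(loglik_trace, ll)
    if (gain < tol) { converged <- TRUE; break }

    # E-step: posterior moments of u = (z, x_1..x_M)
    EU <- T1 %*% Minv                  # N x q
    # M-step per set (block structure preserved)
    for (m in seq_len(M)) {
      cols <- c(seq_len(d),
                if (k[m] > 0L) d + (qoff[m] + 1L):qoff[m + 1L])
      Um <- EU[, cols, drop = FALSE]
      G <- N * Minv[cols, cols, drop = FALSE] + crossprod(Um)
      A <- crossprod(Ys[[m]], Um)      # p_m x q_m
      Lm_new <- A %*% solve(G)
      psi_new <- pmax(colMeans(Ys[[m]]^2) - rowSums(Lm_new * A) / N, 1e-4)
      W[[m]] <- Lm_new[, seq_len(d), drop = FALSE]
      L[[m]] <- if (k[m] > 0L)
        Lm_new[, d + seq_len(k[m]), drop = FALSE] else matrix(0, p[m], 0L)
      psi[[m]] <- psi_new
    }
  }
  Lam <- build_lambda()
  psiv <- unlist(psi)
  Lp <- Lam / psiv
  Mq <- diag(q) + crossprod(Lam, Lp)
  Minv <- solve((Mq + t(Mq)) / 2)
  EU <- (Ycat %*% Lp) %*% Minv
  x_hat <- lapply(seq_len(M), function(m)
    if (k[m] > 0L) EU[, d + (qoff[m] + 1L):qoff[m + 1L], drop = FALSE]
    else matrix(0, N, 0L))
  var_total <- vapply(Ys, function(y)
    sum(apply(y, 2L, stats::var)), numeric(1))
  out <- list(W = W, L = L, psi = psi, z_hat = EU[, seq_len(d), drop = FALSE],
              x_hat = x_hat, d = d, k = k, loglik = loglik_trace,
              converged = converged, var_total = var_total,
              names = nms, Y_std = Ys)
  class(out) <- "mcfa_model"
  out
}

#' @export
print.mcfa_model <- function(x, ...) {
  cat(sprintf("<mcfa_model> %d sets, d = %d shared, k = (%s) private; %sconverged after %d EM iterations\n",
              length(x$W), x$d, paste(x$k, collapse = ", "),
              if (x$converged) "" else "NOT ", length(x$loglik)))
  invisible(x)
}

#' Shared / private / residual variance decomposition
#'
#' Per attribute set, the percentage of total feature variance explained by
#' all shared factors (`sum_jd W_m(j,d)^2`), by all private factors
#' (`sum_jk L_m(j,k)^2`), and left as residual (`sum_j psi_mj`), plus a
#' per-shared-dimension contribution matrix.
#'
#' @param model a fitted `mcfa_model`.
#' @return object of class `mcfa_variance`: data.frame `summary` (set,
#'   shared_pct, private_pct, residual_pct) and matrix `per_dimension`
#'   (sets x shared dimensions, percent of set variance).
#' @export
variance_report <- function(model) {
  stopifnot(inherits(model, "mcfa_model"))
  M <- length(model$W)
  shared <- vapply(model$W, function(w) sum(w^2), numeric(1))
  private <- vapply(model$L, function(l) sum(l^2), numeric(1))
  resid <- vapply(model$psi, sum, numeric(1))
  tot <- model$var_total
  per_dim <- do.call(rbind, lapply(model$W, function(w) colSums(w^2)))
  per_dim <- sweep(per_dim, 1L, tot, "/") * 100
  dimnames(per_dim) <- list(model$names, paste0("dim", seq_len(model$d)))
  out <- list(summary = data.frame(set = model$names,
                                   shared_pct = 100 * shared / tot,
                                   private_pct = 100 * private / tot,
                                   residual_pct = 100 * resid / tot),
              per_dimension = per_dim)
  class(out) <- "mcfa_variance"
  out
}

#' @export
print.mcfa_variance <- function(x, ...) {
  cat("<mcfa_variance> percent of total variance per set:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Shared-factor feature importance across modes
#'
#' For each attribute set the posterior mean of the shared factor given
#' that set alone, `Zhat_m = E[z | y_m]` (standard Gaussian conditional
#' mean under the single-mode marginal model
#' `y_m ~ N(0, W_m W_m' + L_m L_m' + Psi_m)`), and for each shared
#' dimension the cross-correlation of the single-mode posteriors: the mean
#' pairwise Pearson correlation of column `d` across modes. A dimension
#' supported by every set scores near 1; one driven by a single set scores
#' near 0.
#'
#' @param model a fitted `mcfa_model`.
#' @return list with `S` (importance per shared dimension) and `z_single`
#'   (the per-mode posterior means).
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "mcfa_model"))
  M <- length(model$W)
  zs <- vector("list", M)
  for (m in seq_len(M)) {
    Lam <- cbind(model$W[[m]], model$L[[m]])
    psiv <- model$psi[[m]]
    Lp <- Lam / psiv
    Minv <- solve(diag(ncol(Lam)) + crossprod(Lam, Lp))
    B <- Lp %*% Minv                  # p_m x q_m
    # E[z|y_m] = y Sigma^-1 W = y (Psi^-1 W - Psi^-1 Lam Minv Lam' Psi^-1 W)
    SW <- model$W[[m]] / psiv - B %*% (crossprod(Lam, model$W[[m]] / psiv))
    zs[[m]] <- model$Y_std[[m]] %*% SW
  }
  S <- vapply(seq_len(model$d), function(dd) {
    cols <- vapply(zs, function(z) z[, dd], numeric(nrow(zs[[1L]])))
    sds <- apply(cols, 2L, stats::sd)
    if (any(sds == 0)) return(NA_real_)
    cm <- stats::cor(cols)
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  list(S = S, z_single = zs)
}
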