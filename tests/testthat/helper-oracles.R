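# Independent brute-force oracles used across tests. These deliberately use
# naive double loops so they share no code with the implementation.

# modularity by the literal double sum over ordered node pairs
modularity_bruteforce <- function(A, labels, gamma = 1) {
  n <- nrow(A)
  w <- sum(A)
  d <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] == labels[j])
      q <- q + A[i, j] - gamma * d[i] * d[j] / w
  }
  q / w
}

# block means of pairwise cosine similarities by explicit enumeration
cosine_summary_bruteforce <- function(X, labels_a, labels_b = labels_a,
                                      X_b = X, same = missing(X_b) &&
                                        missing(labels_b)) {
  ua <- sort(unique(labels_a)); ub <- sort(unique(labels_b))
  out <- matrix(NA_real_, length(ua), length(ub))
  cosv <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  for (a in seq_along(ua)) for (b in seq_along(ub)) {
    ia <- which(labels_a == ua[a]); ib <- which(labels_b == ub[b])
    vals <- c()
    for (i in ia) for (j in ib) {
      if (same && ua[a] == ub[b] && j <= i) next
      vals <- c(vals, cosv(X[i, ], X_b[j, ]))
    }
    out[a, b] <- if (length(vals)) mean(vals) else NaN
  }
  out
}

# small standard GLIF parameter set used by several tests
test_glif_params <- function(eta_amp = 60, eta_tau = 120, gamma_amp = 4,
                             gamma_tau = 40, template = TRUE, ...) {
  kb <- kernel_basis()
  mids <- (kb$edges[-1] + kb$edges[-length(kb$edges)]) / 2
  defaults <- list(C = 200, g_L = 10, E_L = -70, V_reset = -60,
                   VT_star = -45, delta_V = 2,
                   eta_basis = kb, eta_coef = eta_amp * exp(-mids / eta_tau),
                   gamma_basis = kb,
                   gamma_coef = gamma_amp * exp(-mids / gamma_tau),
                   template = if (template) spike_template(35, 0.5, 0.9))
  args <- utils::modifyList(defaults, list(...))
  do.call(glif_params, args)
}

# frozen-noise drive of a given duration for simulation tests
test_fn_current <- function(duration = 30000, dt = 0.05, baseline = 200,
                            tau = 250, seed = 11) {
  pop <- presynaptic_population(200, seed = seed)
  hid <- generate_hidden_state(tau, duration, dt, seed = seed + 1L)
  generate_fn_current(pop, hid, baseline = baseline, target_sd = 50,
                      seed = seed + 2L)
}

# well-separated Gaussian mixture in the plane-like feature space
gaussian_mixture <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers); p <- ncol(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(stats::rnorm(n_per * p, sd = sd), n_per, p) +
      matrix(centers[j, ], n_per, p, byrow = TRUE)
  }))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}
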