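test_that("reset voltage is the averaged potential at peak + t_ref", {
  # constructed trace: V equals -55 exactly 4 ms after each listed peak
  dt <- 0.05
  V <- rep(-70, 10000)
  peaks <- c(100, 200, 300)
  for (tp in peaks) V[round((tp + 4) / dt) + 1L] <- -55
  rec <- recording(V, current_trace(numeric(10000), dt), spike_times = peaks)
  expect_equal(extract_reset_voltage(rec, t_ref = 4), -55)

  rec2 <- recording(V, current_trace(numeric(10000), dt),
                    spike_times = c(100, 103))
  expect_error(extract_reset_voltage(rec2, t_ref = 4), "inter-spike")
  rec3 <- recording(V, current_trace(numeric(10000), dt))
  expect_error(extract_reset_voltage(rec3, t_ref = 4), "no spikes")
})

test_that("noiseless spike-free subthreshold fit recovers C, g_L, E_L
           almost exactly", {
  p <- test_glif_params(VT_star = 1e6, eta_amp = 0, gamma_amp = 0,
                        template = FALSE)
  cur <- test_fn_current(20000, baseline = 50)
  rec <- simulate_glif(p, cur, seed = 2)
  expect_length(rec$spike_times, 0L)
  sub <- fit_subthreshold(rec, train_window = 20000)
  expect_lt(abs(sub$C - p$C) / p$C, 1e-6)
  expect_lt(abs(sub$g_L - p$g_L) / p$g_L, 1e-6)
  expect_lt(abs(sub$E_L - p$E_L) / abs(p$E_L), 1e-6)
  expect_gt(sub$r2, 0.999999)
})

test_that("with zero adaptation the fitted eta coefficients are negligible", {
  p <- test_glif_params(eta_amp = 0, gamma_amp = 0)
  cur <- test_fn_current(60000, baseline = 200)
  rec <- simulate_glif(p, cur, seed = 3)
  expect_gt(length(rec$spike_times), 20)
  sub <- fit_subthreshold(rec, train_window = 60000)
  expect_lt(max(abs(sub$eta_coef)), 0.01 * stats::sd(cur$values))
})

test_that("spike exclusion removes (t - 5 ms, t + t_ref) from the design", {
  dt <- 0.05
  n <- round(200 / dt)
  set.seed(4)
  V <- -70 + stats::rnorm(n, sd = 0.5)
  rec <- recording(V, current_trace(stats::rnorm(n, 100, 20), dt),
                   spike_times = 50)
  sub <- fit_subthreshold(rec, train_window = 200)
  n_excl_samples <- sum(ephysclust:::spike_exclusion_mask(50, n, dt, 5, 4))
  expect_equal(n_excl_samples, length(seq(45 + dt, 54 - dt, by = dt)))
  # rows need both i and i+1 clean, so one extra row drops at the window edge
  expect_equal(sub$n_obs, (n - 1L) - (n_excl_samples + 1L))
})

test_that("threshold MLE recovers VT* and delta_V from simulated spikes", {
  p <- test_glif_params(gamma_amp = 0, eta_amp = 30, template = FALSE)
  cur <- test_fn_current(100000, baseline = 200)
  rec <- simulate_glif(p, cur, seed = 5)
  expect_gt(length(rec$spike_times), 100)
  sub <- fit_subthreshold(rec)
  thr <- fit_threshold(rec, sub, V_reset = p$V_reset)
  expect_true(thr$converged)
  expect_lt(abs(thr$VT_star - p$VT_star), 1)
  expect_lt(abs(thr$delta_V - p$delta_V) / p$delta_V, 0.2)
})

test_that("the threshold objective is maximal at the fitted optimum", {
  p <- test_glif_params(gamma_amp = 2, template = FALSE)
  cur <- test_fn_current(30000, baseline = 220)
  rec <- simulate_glif(p, cur, seed = 6)
  sub <- fit_subthreshold(rec, train_window = 30000)
  thr <- fit_threshold(rec, sub, V_reset = p$V_reset, train_window = 30000,
                       keep_objective = TRUE)
  obj <- thr$objective
  ll_hat <- obj(thr$theta)
  set.seed(7)
  for (i in 1:100)
    expect_gte(ll_hat + 1e-9, obj(thr$theta + stats::rnorm(length(thr$theta),
                                                           sd = 0.02)))
})

test_that("reparametrized threshold objective is concave (Hessian NSD)", {
  set.seed(8)
  Z <- cbind(stats::rnorm(500), 1, stats::rpois(500, 0.2))
  for (i in 1:5) {
    th <- stats::rnorm(3, sd = 0.5)
    H <- -ephysclust:::poisson_glm_stats_cpp(Z, th, TRUE)$hess
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(ev), 1e-8)
  }
})

test_that("subthreshold r2 has its documented fixed points and invariance", {
  p <- test_glif_params(VT_star = 1e6, eta_amp = 0, gamma_amp = 0,
                        template = FALSE)
  cur <- test_fn_current(5000, baseline = 50)
  rec <- simulate_glif(p, cur, seed = 9)
  # model identical to data
  expect_equal(subthreshold_r2(rec, p), 1, tolerance = 1e-9)
  # shifting both data and model by a constant leaves r2 unchanged
  rec_shift <- rec
  rec_shift$V <- rec$V + 7
  p_shift <- p; p_shift$E_L <- p$E_L + 7
  expect_equal(subthreshold_r2(rec_shift, p_shift),
               subthreshold_r2(rec, p), tolerance = 1e-9)
  # a wrong model explaining nothing beyond the mean scores ~ 0
  p_flat <- test_glif_params(C = 1e9, g_L = 1e9, E_L = mean(rec$V),
                             VT_star = 1e6, eta_amp = 0, gamma_amp = 0,
                             template = FALSE)
  expect_lt(abs(subthreshold_r2(rec, p_flat)), 0.05)
  # zero-variance data is signalled
  rec_const <- recording(rep(-70, 1000), current_trace(numeric(1000), 0.05))
  expect_error(subthreshold_r2(rec_const, p), "zero-variance")
})

test_that("full GLIF fit round-trips a simulated neuron and flags bad fits", {
  p <- test_glif_params()
  cur <- test_fn_current(60000, baseline = 200)
  rec <- simulate_glif(p, cur, seed = 10)
  f <- fit_glif(rec, train_window = 60000)
  expect_length(f$passive, 6L)
  expect_false(f$excluded)
  truth <- clustering_params(p)
  expect_lt(max(abs(f$passive[c("C", "g_L")] - truth[c("C", "g_L")]) /
                  truth[c("C", "g_L")]), 0.05)
  expect_lt(abs(f$passive[["E_L"]] - truth[["E_L"]]) / abs(truth[["E_L"]]),
            0.05)
  expect_lt(abs(f$passive[["V_reset"]] - truth[["V_reset"]]), 0.5)
  # eta kernel recovery: cosine similarity on the sampled grid
  eta_true <- eval_kernel(p$eta_basis, p$eta_coef, rec$dt)
  cs <- sum(eta_true * f$eta) / sqrt(sum(eta_true^2) * sum(f$eta^2))
  expect_gt(cs, 0.9)

  # a recording the subthreshold model cannot explain is excluded but
  # still returned
  set.seed(11)
  rec_bad <- rec
  rec_bad$V <- rec$V + stats::rnorm(length(rec$V), sd = 10)
  rec_bad$spike_times <- rec$spike_times
  f_bad <- fit_glif(rec_bad, train_window = 20000)
  expect_true(f_bad$excluded)
  expect_lte(f_bad$r2, 0.7)
})
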