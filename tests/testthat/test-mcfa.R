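# principal angles (degrees) between column spans
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

test_that("eigenvalue thresholding finds no signal in pure noise and
           detects a planted component", {
  hits <- 0L
  for (i in 1:100) {
    set.seed(i)
    X <- matrix(stats::rnorm(300 * 20), 300, 20)
    if (select_shared_dim(X, rule = "mp_edge") == 0L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)

  # rank-1 signal with SD 5 is always detected, under both rules
  for (i in 1:20) {
    set.seed(1000 + i)
    u <- stats::rnorm(300); v <- stats::rnorm(20)
    X <- matrix(stats::rnorm(300 * 20), 300, 20) + 5 * u %*% t(v / sqrt(20))
    expect_gte(select_shared_dim(X, rule = "mp_edge"), 1L)
    expect_gte(select_shared_dim(X, rule = "one_plus_ratio"), 1L)
  }
  # both thresholds exceed 1, and the MP edge is the larger of the two
  expect_lt(attr(select_shared_dim(matrix(rnorm(100 * 10), 100, 10),
                                   "one_plus_ratio"), "threshold"),
            attr(select_shared_dim(matrix(rnorm(100 * 10), 100, 10),
                                   "mp_edge"), "threshold"))
  expect_error(select_shared_dim(matrix(1, 1, 3)), "2 samples")
})

test_that("EM recovers generative loading subspaces and variance split", {
  gen <- generate_mcfa_testdata(N = 500, p_list = c(20, 25), d = 2,
                                k_list = 2, split = c(0.6, 0.3, 0.1),
                                seed = 21)
  m <- fit_mcfa(gen$Y, d = 2, k = 2, seed = 22)
  expect_true(all(diff(m$loglik) > -1e-6))         # monotone non-decreasing
  expect_true(m$converged)
  for (mm in 1:2) {
    ang <- principal_angles(m$W[[mm]], gen$truth$W[[mm]])
    expect_lt(max(ang), 10)
  }
  vr <- variance_report(m)
  expect_true(all(abs(vr$summary$shared_pct - 60) < 5))
  expect_true(all(abs(vr$summary$private_pct - 30) < 5))
  expect_true(all(abs(vr$summary$residual_pct - 10) < 5))
  tot <- with(vr$summary, shared_pct + private_pct + residual_pct)
  expect_true(all(abs(tot - 100) < 1))
  expect_true(all(m$psi[[1]] >= 0))
})

test_that("a pure-shared model attributes ~all variance to shared factors", {
  gen <- generate_mcfa_testdata(N = 400, p_list = c(15, 15), d = 2,
                                k_list = 0, split = c(0.98, 0, 0.02),
                                seed = 23)
  m <- fit_mcfa(gen$Y, d = 2, k = 0, seed = 24)
  vr <- variance_report(m)
  expect_true(all(vr$summary$shared_pct > 90))
  expect_true(all(vr$summary$private_pct == 0))
})

test_that("per-set shared variance is invariant to shared-space rotation", {
  gen <- generate_mcfa_testdata(N = 200, p_list = c(10, 12), d = 3,
                                k_list = 1, seed = 25)
  m <- fit_mcfa(gen$Y, d = 3, k = 1, seed = 26)
  vr <- variance_report(m)
  set.seed(27)
  for (i in 1:5) {
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    m_rot <- m
    m_rot$W <- lapply(m$W, function(w) w %*% R)
    vr_rot <- variance_report(m_rot)
    expect_equal(vr_rot$summary$shared_pct, vr$summary$shared_pct,
                 tolerance = 1e-9)
  }
})

test_that("private dimension defaults follow the low-dimension convention", {
  gen <- generate_mcfa_testdata(N = 100, p_list = c(22, 6), d = 1,
                                k_list = 1, seed = 28)
  m <- fit_mcfa(gen$Y, d = 1, tol = 1e-3, max_iter = 50)
  expect_equal(m$k, c(2L, 1L))                     # 6 features -> k = 1
})

test_that("feature importance is 1 for duplicated sets and small for
           independent noise", {
  set.seed(29)
  Y1 <- matrix(stats::rnorm(1000 * 10), 1000, 10)
  m_dup <- fit_mcfa(list(Y1, Y1), d = 1, k = 0, seed = 30)
  fi <- feature_importance(m_dup)
  expect_equal(unname(fi$S), rep(1, m_dup$d), tolerance = 1e-6)

  Y2 <- matrix(stats::rnorm(1000 * 10), 1000, 10)
  m_ind <- fit_mcfa(list(Y1, Y2), d = 1, k = 1, seed = 31, max_iter = 200)
  fi2 <- feature_importance(m_ind)
  expect_true(all(abs(fi2$S) <= 1))
  # a cross-set shared factor fitted to independent noise can only pick up
  # the spurious top canonical correlation, ~sqrt(p/N) here
  expect_lt(abs(fi2$S[1]), 0.25)
})

test_that("generated test data reproduces its specified variance split", {
  gen <- generate_mcfa_testdata(N = 1000, p_list = c(30, 30), d = 2,
                                k_list = 2, split = c(0.6, 0.3, 0.1),
                                seed = 32)
  for (mset in 1:2) {
    Wm <- gen$truth$W[[mset]]; Lm <- gen$truth$L[[mset]]
    zc <- gen$truth$z %*% t(Wm)
    xc <- gen$truth$x[[mset]] %*% t(Lm)
    v_sh <- mean(apply(zc, 2, stats::var))
    v_pr <- mean(apply(xc, 2, stats::var))
    v_tot <- mean(apply(gen$Y[[mset]], 2, stats::var))
    expect_lt(abs(100 * v_sh / v_tot - 60), 2)
    expect_lt(abs(100 * v_pr / v_tot - 30), 2)
  }
  gen2 <- generate_mcfa_testdata(N = 1000, p_list = c(30, 30), d = 2,
                                 k_list = 2, split = c(0.6, 0.3, 0.1),
                                 seed = 32)
  expect_identical(gen$Y, gen2$Y)
})
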