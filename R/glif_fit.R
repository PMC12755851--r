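#' Extract the reset voltage from a recording
#'
#' Averages all spike waveforms aligned on the peak and returns the averaged
#' membrane potential at `peak + t_ref`. The refractory period must be
#' shorter than the minimum inter-spike interval.
#'
#' @param rec a `recording` with at least one spike.
#' @param t_ref refractory period (ms); default 4.
#' @return reset voltage (mV).
#' @export
extract_reset_voltage <- function(rec, t_ref = 4) {
  stopifnot(inherits(rec, "recording"))
  if (length(rec$spike_times) < 1L)
    stop("reset voltage is not applicable: recording has no spikes")
  if (length(rec$spike_times) > 1L && t_ref >= min(diff(rec$spike_times)))
    stop("`t_ref` must be lower than the minimum inter-spike interval")
  off <- round(t_ref / rec$dt)
  idx <- round(rec$spike_times / rec$dt) + 1L + off
  idx <- idx[idx <= length(rec$V)]
  if (!length(idx)) stop("no spike has a full refractory window in the trace")
  mean(rec$V[idx])
}

# Spike-history regressors: column k counts spikes whose elapsed time falls
# in basis bin k, i.e. sample lags m with mb[k] < m <= mb[k+1] (identical
# binning to eval_kernel()). spike_idx is 1-based sample indices.
spike_history_columns <- function(spike_idx, n, dt, basis) {
  mb <- basis_sample_breaks(basis, dt)
  K <- basis$K
  out <- matrix(0, n, K)
  if (!length(spike_idx)) return(out)
  # sparse accumulation: each spike raises column k by 1 over the index
  # range (s + mb[k], s + mb[k+1]]; realized by a difference vector + cumsum
  for (k in seq_len(K)) {
    d <- numeric(n + 1L)
    lo <- spike_idx + mb[k] + 1L
    hi <- pmin(spike_idx + mb[k + 1L], n)
    ok <- lo <= hi
    if (!any(ok)) next
    lo <- lo[ok]; hi <- hi[ok]
    for (j in seq_along(lo)) {
      d[lo[j]] <- d[lo[j]] + 1
      d[hi[j] + 1L] <- d[hi[j] + 1L] - 1
    }
    out[, k] <- cumsum(d[-(n + 1L)])
  }
  out
}

# logical mask of samples excluded around spikes: time in (ts - pre, ts + t_ref)
spike_exclusion_mask <- function(spike_times, n, dt, pre, t_ref) {
  excl <- logical(n)
  if (!length(spike_times)) return(excl)
  lo <- pmax(1L, floor((spike_times - pre) / dt + 1e-9) + 2L)  # (i-1)dt > ts-pre
  hi <- pmin(n, ceiling((spike_times + t_ref) / dt - 1e-9))    # (i-1)dt < ts+t_ref
  for (j in seq_along(lo)) if (lo[j] <= hi[j]) excl[lo[j]:hi[j]] <- TRUE
  excl
}

#' Fit the subthreshold GLIF dynamics by multilinear regression
#'
#' Regresses the forward-difference voltage derivative on
#' `[V, 1, I, f(1), ..., f(K)]` by ordinary least squares, where the `f(k)`
#' are spike-history counts in the rectangular adaptation basis. Samples
#' within `(t_spike - exclude_pre, t_spike + t_ref)` of any spike are
#' excluded, so only subthreshold data enter the fit. The injected current
#' is included as a regressor (coefficient `1/C`); without it the
#' capacitance is not identifiable. Coefficients map to the membrane
#' parameters as `C = 1/b_I`, `g_L = -b_V * C`, `E_L = -b_1 / b_V`,
#' `a_k = -b_k * C`.
#'
#' @param rec a `recording`.
#' @param eta_basis adaptation-current `kernel_basis`.
#' @param t_ref refractory period (ms).
#' @param train_window training window from the start of the trial (ms);
#'   default 100000 (100 s).
#' @param exclude_pre exclusion window before each spike (ms); default 5.
#' @return object of class `subthreshold_fit`: list with `C`, `g_L`, `E_L`,
#'   `eta_coef`, `eta_basis`, `r2` (variance explained of the reconstructed
#'   subthreshold voltage), `coefficients`, `design_columns`, `n_obs`.
#' @export
fit_subthreshold <- function(rec, eta_basis = kernel_basis(), t_ref = 4,
                             train_window = 1e5, exclude_pre = 5) {
  stopifnot(inherits(rec, "recording"))
  dt <- rec$dt
  n <- min(length(rec$V), round(train_window / dt))
  if (n < 10L) stop("training window too short")
  V <- rec$V[seq_len(n)]; I <- rec$I$values[seq_len(n)]
  st <- rec$spike_times[rec$spike_times < (n - 1L) * dt]
  spike_idx <- round(st / dt) + 1L
  excl <- spike_exclusion_mask(st, n, dt, exclude_pre, t_ref)

  H <- spike_history_columns(spike_idx, n, dt, eta_basis)
  rows <- which(!excl[-n] & !excl[-1L])          # need samples i and i+1 clean
  if (length(rows) < 10L) stop("too few subthreshold samples after exclusion")
  vdot <- (V[rows + 1L] - V[rows]) / dt
  Hr <- H[rows, , drop = FALSE]
  keep_k <- colSums(Hr != 0) > 0                 # bins never visited carry a_k = 0
  X <- cbind(V = V[rows], intercept = 1, I = I[rows],
             Hr[, keep_k, drop = FALSE])
  cn <- c("V", "intercept", "I",
          if (any(keep_k)) paste0("eta", which(keep_k)))
  colnames(X) <- cn
  # ordinary least squares by normal equations (the design is long and thin)
  XtX <- crossprod(X)
  qr_x <- qr(XtX)
  if (qr_x$rank < ncol(X)) {
    bad <- cn[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(X))]]
    stop("singular subthreshold design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  b <- drop(solve(qr_x, crossprod(X, vdot)))
  names(b) <- cn
  C <- 1 / b[["I"]]
  g_L <- -b[["V"]] * C
  E_L <- -b[["intercept"]] / b[["V"]]
  eta_coef <- numeric(eta_basis$K)
  eta_coef[keep_k] <- -b[cn[-(1:3)]] * C

  out <- list(C = C, g_L = g_L, E_L = E_L, eta_coef = eta_coef,
              eta_basis = eta_basis, t_ref = t_ref,
              exclude_pre = exclude_pre, train_window = train_window,
              coefficients = b, design_columns = cn, n_obs = length(rows))
  class(out) <- "subthreshold_fit"
  out$r2 <- tryCatch(
    subthreshold_r2_fit(rec, out), error = function(e) NA_real_)
  out
}

#' @export
print.subthreshold_fit <- function(x, ...) {
  cat(sprintf("<subthreshold_fit> C = %.1f pF, g_L = %.2f nS, E_L = %.1f mV, R2 = %.3f (%d samples)\n",
              x$C, x$g_L, x$E_L, x$r2, x$n_obs))
  invisible(x)
}

# r2 of the reconstructed subthreshold voltage for a subthreshold_fit
subthreshold_r2_fit <- function(rec, sub, V_reset = NULL) {
  if (is.null(V_reset))
    V_reset <- tryCatch(extract_reset_voltage(rec, sub$t_ref),
                        error = function(e) sub$E_L)
  p <- glif_params(C = sub$C, g_L = sub$g_L, E_L = sub$E_L,
                   V_reset = V_reset, VT_star = 0, delta_V = 1,
                   t_ref = sub$t_ref, eta_basis = sub$eta_basis,
                   eta_coef = sub$eta_coef)
  subthreshold_r2(rec, p, t_ref = sub$t_ref, exclude_pre = sub$exclude_pre,
                  train_window = sub$train_window)
}

#' Variance explained of the subthreshold membrane potential
#'
#' `1 - SSE/SST` between data and model voltage on the spike-exclusion
#' filtered samples (the same exclusion windows as [fit_subthreshold()]).
#' Invariant to adding a constant to both traces. Fits retained for
#' clustering require a value above 0.7.
#'
#' @param rec a `recording`.
#' @param params a `glif_params` (threshold fields are not used).
#' @param t_ref,exclude_pre exclusion window around spikes (ms).
#' @param train_window window from trial start (ms); `NULL` for the full trace.
#' @return variance explained (dimensionless, `<= 1`).
#' @export
subthreshold_r2 <- function(rec, params, t_ref = 4, exclude_pre = 5,
                            train_window = NULL) {
  stopifnot(inherits(rec, "recording"), inherits(params, "glif_params"))
  dt <- rec$dt
  n <- if (is.null(train_window)) length(rec$V) else
    min(length(rec$V), round(train_window / dt))
  eta_kern <- eval_kernel(params$eta_basis, params$eta_coef, dt)
  Vm <- subthreshold_voltage(rec, params$C, params$g_L, params$E_L,
                             params$V_reset, eta_kern, t_ref = t_ref,
                             V0 = rec$V[1L])[seq_len(n)]
  st <- rec$spike_times[rec$spike_times < n * dt]
  excl <- spike_exclusion_mask(st, n, dt, exclude_pre, t_ref)
  vd <- rec$V[seq_len(n)][!excl]; vm <- Vm[!excl]
  sst <- sum((vd - mean(vd))^2)
  if (sst == 0) stop("zero-variance subthreshold data; R2 undefined")
  1 - sum((vd - vm)^2) / sst
}

#' Fit the spike-threshold parameters by maximum likelihood
#'
#' Maximizes the point-process likelihood of the observed spike train given
#' the model subthreshold voltage, in the log-linear reparametrization
#' `log lambda = log lambda0 + b_V V + b_0 + sum_p b_p f(p)` with
#' `b_V = 1/delta_V`, `b_0 = -VT*/delta_V`, `b_p = -gamma_p/delta_V`
#' (a concave Poisson-GLM objective, solved by Newton iterations with step
#' halving). Time bins within `(t_spike, t_spike + t_ref]` are excluded
#' from the integral term.
#'
#' @param rec a `recording` with at least `min_spikes` spikes.
#' @param sub a `subthreshold_fit`.
#' @param gamma_basis threshold-movement `kernel_basis`.
#' @param lambda0 base intensity (Hz); the fitting convention fixes 1.
#' @param t_ref refractory period (ms).
#' @param V_reset reset voltage; default extracted from the recording.
#' @param train_window window from trial start (ms).
#' @param min_spikes minimum spike count (default 10; below this the MLE is
#'   ill-conditioned).
#' @param tol convergence tolerance on the gradient norm.
#' @param max_iter Newton iteration cap.
#' @param keep_objective if `TRUE`, attach the penalized objective as a
#'   function of `theta` (element `objective`; used by diagnostics).
#' @param ridge small L2 penalty on the threshold-kernel coefficients.
#'   Basis bins in which no spike is ever observed have a likelihood
#'   maximized only at infinite coefficient; the penalty keeps those
#'   directions bounded and the Newton system strongly concave while
#'   biasing well-identified bins negligibly.
#' @return object of class `threshold_fit`: `delta_V`, `VT_star`,
#'   `gamma_coef`, `gamma_basis`, `loglik`, `converged`, `n_iter`,
#'   `grad_norm`.
#' @export
fit_threshold <- function(rec, sub, gamma_basis = kernel_basis(),
                          lambda0 = 1, t_ref = 4, V_reset = NULL,
                          train_window = 1e5, min_spikes = 10L,
                          tol = 1e-8, max_iter = 200L, ridge = 1e-2,
                          keep_objective = FALSE) {
  stopifnot(inherits(rec, "recording"), inherits(sub, "subthreshold_fit"))
  if (length(rec$spike_times) < min_spikes)
    stop("threshold fit requires at least ", min_spikes, " spikes")
  dt <- rec$dt; dt_s <- dt / 1000
  n <- min(length(rec$V), round(train_window / dt))
  if (is.null(V_reset)) V_reset <- extract_reset_voltage(rec, t_ref)
  eta_kern <- eval_kernel(sub$eta_basis, sub$eta_coef, dt)
  Vm <- subthreshold_voltage(rec, sub$C, sub$g_L, sub$E_L, V_reset,
                             eta_kern, t_ref = t_ref, V0 = rec$V[1L])[seq_len(n)]
  st <- rec$spike_times[rec$spike_times < (n - 1L) * dt]
  spike_idx <- round(st / dt) + 1L
  # Omega excludes (t_spike, t_spike + t_ref]; the spike bin itself stays
  n_ref <- ceiling(t_ref / dt)
  excl <- logical(n)
  for (s in spike_idx) {
    hi <- min(n, s + n_ref)
    if (s + 1L <= hi) excl[(s + 1L):hi] <- TRUE
  }
  H <- spike_history_columns(spike_idx, n, dt, gamma_basis)
  keep_p <- colSums(H != 0) > 0
  # center the voltage column for a well-conditioned Newton system; the
  # intercept is mapped back afterwards
  vbar <- mean(Vm)
  Z <- cbind(Vm - vbar, 1, H[, keep_p, drop = FALSE])
  omega <- which(!excl)
  Zo <- Z[omega, , drop = FALSE]
  Zs <- Z[spike_idx, , drop = FALSE]
  q <- ncol(Z)
  gsum <- colSums(Zs)

  # initialization: delta_V = 4 mV, VT* near the top of the voltage range,
  # intercept adjusted so the expected count matches the observed count
  theta <- numeric(q)
  theta[1L] <- 1 / 4
  theta[2L] <- -(stats::quantile(Vm, 0.999, names = FALSE) - vbar) / 4
  eta_lin <- Zo %*% theta
  theta[2L] <- theta[2L] +
    log(length(spike_idx) / (dt_s * lambda0 * sum(exp(eta_lin))))

  pen <- c(0, 0, rep(ridge, q - 2L))          # penalize kernel coefficients only
  ll_from <- function(th, sum_exp)
    sum(Zs %*% th) - dt_s * lambda0 * sum_exp - 0.5 * sum(pen * th^2)
  st <- poisson_glm_stats_cpp(Zo, theta, TRUE)
  ll <- ll_from(theta, st$sum_exp)
  converged <- FALSE; it <- 0L; gnorm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    grad <- gsum - dt_s * lambda0 * st$zte - pen * theta
    gnorm <- sqrt(sum(grad^2))
    if (gnorm < tol) { converged <- TRUE; break }
    Hm <- dt_s * lambda0 * st$hess + diag(pen, q)
    step <- tryCatch(solve(Hm, grad), error = function(err) grad / max(diag(Hm)))
    # full Newton step, halved only if the concave objective ever decreases
    alpha <- 1
    repeat {
      th_new <- theta + alpha * step
      st_new <- poisson_glm_stats_cpp(Zo, th_new, TRUE)
      ll_new <- ll_from(th_new, st_new$sum_exp)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    if (alpha < 1e-12) break
    stalled <- abs(ll_new - ll) < 1e-12 * (abs(ll) + 1)
    theta <- th_new; ll <- ll_new; st <- st_new
    if (stalled) {
      grad <- gsum - dt_s * lambda0 * st$zte - pen * theta
      gnorm <- sqrt(sum(grad^2))
      converged <- gnorm < 1e-4 * (1 + abs(ll))
      break
    }
  }
  if (!converged && gnorm > 1e-3 * (1 + abs(ll)))
    warning(sprintf("threshold fit did not converge (grad norm %.3g after %d iterations)",
                    gnorm, it))
  if (theta[1L] <= 0)
    stop("threshold fit degenerate: estimated 1/delta_V is non-positive")
  theta <- unname(theta)
  theta[2L] <- theta[2L] - theta[1L] * vbar   # undo the voltage centering
  delta_V <- 1 / theta[1L]
  VT_star <- -theta[2L] * delta_V
  gamma_coef <- numeric(gamma_basis$K)
  if (q > 2L) gamma_coef[keep_p] <- -theta[-(1:2)] * delta_V

  out <- list(delta_V = delta_V, VT_star = VT_star, gamma_coef = gamma_coef,
              gamma_basis = gamma_basis, lambda0 = lambda0,
              loglik = ll + length(spike_idx) * log(lambda0 * dt_s),
              converged = converged, n_iter = it, grad_norm = gnorm,
              theta = theta, V_reset = V_reset)
  if (keep_objective)
    out$objective <- function(th) {
      th <- th + c(0, th[1L] * vbar, numeric(q - 2L))  # re-center voltage
      ll_from(th, poisson_glm_stats_cpp(Zo, th, FALSE)$sum_exp)
    }
  class(out) <- "threshold_fit"
  out
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> VT* = %.2f mV, delta_V = %.2f mV, %sconverged (%d iter)\n",
              x$VT_star, x$delta_V, if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Full three-step GLIF fit
#'
#' Chains reset-voltage extraction, subthreshold multilinear regression and
#' threshold maximum likelihood, and assembles the fitted parameter set.
#' Fits with subthreshold variance explained at or below `r2_threshold`
#' (protocol value 0.7) are flagged `excluded = TRUE` but still returned.
#'
#' @param rec a `recording`.
#' @param eta_basis,gamma_basis kernel bases for the adaptation current and
#'   threshold movement.
#' @param t_ref refractory period (ms).
#' @param train_window training window (ms); applied to both the
#'   subthreshold and threshold stages.
#' @param lambda0 base intensity (Hz).
#' @param r2_threshold exclusion threshold on subthreshold variance explained.
#' @param min_spikes floor for the threshold stage.
#' @return object of class `glif_fit`: `params` (a `glif_params`),
#'   `passive` (the six-parameter clustering vector), `r2`, `excluded`,
#'   `eta` (adaptation kernel sampled at the recording resolution),
#'   `sub`, `thr` (stage objects).
#' @export
fit_glif <- function(rec, eta_basis = kernel_basis(),
                     gamma_basis = kernel_basis(), t_ref = 4,
                     train_window = 1e5, lambda0 = 1, r2_threshold = 0.7,
                     min_spikes = 10L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  V_reset <- stage("reset", extract_reset_voltage(rec, t_ref))
  sub <- stage("subthreshold",
               fit_subthreshold(rec, eta_basis, t_ref, train_window))
  thr <- stage("threshold",
               fit_threshold(rec, sub, gamma_basis, lambda0, t_ref,
                             V_reset = V_reset, train_window = train_window,
                             min_spikes = min_spikes))
  params <- glif_params(C = sub$C, g_L = sub$g_L, E_L = sub$E_L,
                        V_reset = V_reset, VT_star = thr$VT_star,
                        delta_V = thr$delta_V, lambda0 = lambda0,
                        t_ref = t_ref, eta_basis = eta_basis,
                        eta_coef = sub$eta_coef, gamma_basis = gamma_basis,
                        gamma_coef = thr$gamma_coef)
  out <- list(params = params, passive = clustering_params(params),
              r2 = sub$r2, excluded = !is.na(sub$r2) && sub$r2 <= r2_threshold,
              eta = eval_kernel(eta_basis, sub$eta_coef, rec$dt),
              sub = sub, thr = thr)
  if (is.na(sub$r2)) out$excluded <- TRUE
  class(out) <- "glif_fit"
  out
}

#' @export
print.glif_fit <- function(x, ...) {
  cat("<glif_fit>", if (x$excluded) "(excluded)" else "", "\n")
  print(x$params)
  cat(sprintf("  subthreshold R2 = %.3f\n", x$r2))
  invisible(x)
}
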