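#' Rectangular kernel basis
#'
#' Non-overlapping rectangular basis functions partitioning `[0, support)`,
#' used to expand the spike-triggered adaptation current `eta(t)` and the
#' threshold movement `gamma(t)` as linear sums. The default edges are
#' log-spaced so the basis is fine near the spike, where the kernels vary
#' fastest.
#'
#' @param edges strictly increasing breakpoints (ms) starting at 0; `K + 1`
#'   values define `K` bins. If `NULL`, `K` log-spaced bins over
#'   `[0, support)` are built with first interior edge `first_edge`.
#' @param K number of bins when `edges` is `NULL`.
#' @param support total extent (ms); default 500 (10000 samples at 20 kHz).
#' @param first_edge first interior breakpoint (ms) for the log spacing.
#' @return object of class `kernel_basis`: list with `edges`, `K`, `support`.
#' @export
kernel_basis <- function(edges = NULL, K = 10L, support = 500,
                         first_edge = 5) {
  if (is.null(edges)) {
    stopifnot(K >= 1L, support > first_edge, first_edge > 0)
    edges <- if (K == 1L) c(0, support) else
      c(0, exp(seq(log(first_edge), log(support), length.out = K)))
  }
  if (edges[1L] != 0) stop("basis edges must start at 0")
  if (any(diff(edges) <= 0)) stop("basis edges must be strictly increasing")
  out <- list(edges = edges, K = length(edges) - 1L,
              support = edges[length(edges)])
  class(out) <- "kernel_basis"
  out
}

#' Evaluate a basis expansion on a regular time grid
#'
#' Samples `sum_k coef[k] f_k(t)` at elapsed times `m * dt`, `m = 1..L`
#' where `L = round(support/dt)`; this is the sampling convention used by
#' both the simulator (kernel deposited from the sample after a spike) and
#' the fitter (regressor counts spikes whose elapsed time falls in a bin),
#' so simulation and fitting are exactly consistent.
#'
#' @param basis a `kernel_basis`.
#' @param coef coefficients, length `basis$K`.
#' @param dt sampling interval (ms).
#' @return numeric vector of kernel samples at `dt, 2 dt, ..., support`.
#' @export
eval_kernel <- function(basis, coef, dt) {
  stopifnot(inherits(basis, "kernel_basis"), length(coef) == basis$K)
  mb <- basis_sample_breaks(basis, dt)
  L <- mb[length(mb)]
  if (L == 0L) return(numeric(0))
  # bin k covers samples m with mb[k] < m <= mb[k+1]
  bin <- findInterval(seq_len(L), mb, left.open = TRUE)
  out <- numeric(L)
  ok <- bin >= 1L & bin <= basis$K
  out[ok] <- coef[bin[ok]]
  out
}

# integer sample-index breakpoints of the basis edges at resolution dt;
# shared by eval_kernel() and the spike-history regressors so that the
# simulator and the fitter use bit-identical binning
basis_sample_breaks <- function(basis, dt) {
  as.integer(floor(basis$edges / dt + 1e-9))
}

#' Stereotyped action-potential template
#'
#' The forward GLIF model is a point process and does not generate the spike
#' waveform itself; a parameterized template is pasted over the reset window
#' at each spike so that downstream peak detection and waveform features see
#' a suprathreshold action potential. The template rises linearly to the
#' peak (placed at the spike sample) and falls linearly back to the reset
#' voltage; narrow- and broad-spiking classes are produced by the rise/fall
#' times.
#'
#' @param peak peak voltage (mV), well above the 20 mV detection height.
#' @param rise_ms,fall_ms rise/fall durations (ms).
#' @return object of class `spike_template`.
#' @export
spike_template <- function(peak = 35, rise_ms = 0.5, fall_ms = 0.9) {
  stopifnot(peak > 20, rise_ms > 0, fall_ms > 0)
  out <- list(peak = peak, rise_ms = rise_ms, fall_ms = fall_ms)
  class(out) <- "spike_template"
  out
}

#' GLIF model parameter set
#'
#' Full generative parameter set for one neuron: passive membrane, reset,
#' stochastic threshold, and the spike-triggered adaptation-current and
#' threshold-movement kernels. Also both the simulator input and the
#' fitter output.
#'
#' @param C membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param E_L resting potential (mV).
#' @param V_reset post-spike reset potential (mV).
#' @param VT_star threshold baseline (mV).
#' @param delta_V threshold sharpness (mV).
#' @param lambda0 base firing intensity (Hz); the fitting convention fixes 1.
#' @param t_ref absolute refractory period (ms); default 4.
#' @param eta_basis,eta_coef adaptation-current kernel basis and
#'   coefficients (pA).
#' @param gamma_basis,gamma_coef threshold-movement kernel basis and
#'   coefficients (mV).
#' @param template optional `spike_template` pasted at spike times.
#' @return object of class `glif_params`.
#' @export
glif_params <- function(C, g_L, E_L, V_reset, VT_star, delta_V,
                        lambda0 = 1, t_ref = 4,
                        eta_basis = kernel_basis(),
                        eta_coef = numeric(eta_basis$K),
                        gamma_basis = kernel_basis(),
                        gamma_coef = numeric(gamma_basis$K),
                        template = NULL) {
  stopifnot(C > 0, g_L > 0, delta_V > 0, t_ref > 0, lambda0 >= 0,
            length(eta_coef) == eta_basis$K,
            length(gamma_coef) == gamma_basis$K)
  out <- list(C = C, g_L = g_L, E_L = E_L, V_reset = V_reset,
              VT_star = VT_star, delta_V = delta_V, lambda0 = lambda0,
              t_ref = t_ref, eta_basis = eta_basis, eta_coef = eta_coef,
              gamma_basis = gamma_basis, gamma_coef = gamma_coef,
              template = template)
  class(out) <- "glif_params"
  out
}

#' @export
print.glif_params <- function(x, ...) {
  cat(sprintf(
    "<glif_params> C = %.1f pF, g_L = %.2f nS (tau_m %.1f ms), E_L = %.1f mV\n",
    x$C, x$g_L, x$C / x$g_L, x$E_L))
  cat(sprintf("  V_reset = %.1f mV, VT* = %.1f mV, delta_V = %.2f mV, t_ref = %g ms\n",
              x$V_reset, x$VT_star, x$delta_V, x$t_ref))
  cat(sprintf("  eta: %d bins over %g ms; gamma: %d bins over %g ms\n",
              x$eta_basis$K, x$eta_basis$support,
              x$gamma_basis$K, x$gamma_basis$support))
  invisible(x)
}

#' The six-parameter vector used for passive-biophysical clustering
#'
#' @param params a `glif_params`.
#' @return named numeric vector `(g_L, delta_V, C, VT_star, E_L, V_reset)`.
#' @export
clustering_params <- function(params) {
  stopifnot(inherits(params, "glif_params"))
  c(g_L = params$g_L, delta_V = params$delta_V, C = params$C,
    VT_star = params$VT_star, E_L = params$E_L, V_reset = params$V_reset)
}

#' Recording container
#'
#' @param V membrane potential samples (mV).
#' @param I a `current_trace` of equal length.
#' @param spike_times spike peak times (ms), strictly increasing.
#' @param meta list of metadata (cell id, protocol, class label, ...).
#' @return object of class `recording` with fields `V`, `I`, `dt`,
#'   `spike_times`, `meta`.
#' @export
recording <- function(V, I, spike_times = numeric(0), meta = list()) {
  stopifnot(inherits(I, "current_trace"), length(V) == length(I$values))
  if (length(spike_times) > 1L && any(diff(spike_times) <= 0))
    stop("`spike_times` must be strictly increasing")
  out <- list(V = as.numeric(V), I = I, dt = I$dt,
              spike_times = as.numeric(spike_times), meta = meta)
  class(out) <- "recording"
  out
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s, %.1f s @ %g kHz, %d spikes (%.2f Hz)\n",
              x$I$protocol, length(x$V) * x$dt / 1000, 1 / x$dt / 1000 * 1000,
              length(x$spike_times),
              length(x$spike_times) / (length(x$V) * x$dt / 1000)))
  invisible(x)
}

#' Simulate a GLIF neuron
#'
#' Forward-Euler integration of the GLIF membrane equation with stochastic
#' (exponential-hazard) spiking, spike-triggered adaptation current, moving
#' threshold, and post-spike clamping to `V_reset` for `t_ref`. When the
#' parameter set carries a `spike_template`, the template is pasted over the
#' reset window at each spike (peak at the spike sample) without altering
#' the recorded spike times.
#'
#' @param params a `glif_params`.
#' @param current a `current_trace` (pA).
#' @param seed integer seed; reproducible under a fixed seed.
#' @param V0 initial voltage (mV); default `E_L`.
#' @param return_threshold if `TRUE`, attach the effective threshold trace
#'   as `meta$VT` (used by diagnostics).
#' @param meta extra metadata stored on the recording.
#' @return a `recording`; a warning is issued if the per-step hazard
#'   `lambda * dt` exceeded 0.2 anywhere (dt too coarse).
#' @export
simulate_glif <- function(params, current, seed = NULL, V0 = NULL,
                          return_threshold = FALSE, meta = list()) {
  stopifnot(inherits(params, "glif_params"), inherits(current, "current_trace"))
  if (any(!is.finite(current$values))) stop("NaN/Inf in input current")
  if (!is.null(seed)) set.seed(seed)
  dt <- current$dt
  eta_kern <- eval_kernel(params$eta_basis, params$eta_coef, dt)
  gamma_kern <- eval_kernel(params$gamma_basis, params$gamma_coef, dt)
  if (is.null(V0)) V0 <- params$E_L
  res <- glif_forward_cpp(current$values, dt, params$C, params$g_L,
                          params$E_L, params$V_reset, params$VT_star,
                          params$delta_V, params$lambda0, params$t_ref,
                          eta_kern, gamma_kern, V0, return_threshold)
  if (res$rate_warning)
    warning("per-step spike hazard exceeded 0.2; dt may be too coarse")
  V <- res$V
  spikes <- res$spike_idx
  if (!is.null(params$template) && length(spikes))
    V <- paste_templates(V, spikes, dt, params$template, params$V_reset,
                         params$t_ref)
  if (return_threshold) meta$VT <- res$VT
  meta$params <- params
  recording(V, current, spike_times = spikes * dt, meta = meta)
}

# Overwrite the reset window around each spike with the AP template:
# linear rise ending at the spike sample, linear fall to V_reset, then
# V_reset until integration resumed.
paste_templates <- function(V, spike_idx, dt, template, V_reset, t_ref) {
  n <- length(V)
  n_rise <- max(1L, round(template$rise_ms / dt))
  n_fall <- max(1L, round(template$fall_ms / dt))
  for (s in spike_idx) {
    s1 <- s + 1L  # R indexing
    v0 <- V[s1]   # voltage at spike onset (pre-reset value)
    i_r <- max(1L, s1 - n_rise):s1
    V[i_r] <- seq(v0, template$peak, length.out = length(i_r))
    i_f <- s1:min(n, s1 + n_fall)
    V[i_f] <- seq(template$peak, V_reset, length.out = length(i_f))
  }
  V
}

#' Deterministic subthreshold GLIF voltage given observed spikes
#'
#' Integrates the membrane equation with the supplied passive parameters and
#' adaptation kernel while forcing the observed spike times: at each spike
#' the voltage is clamped to `V_reset` for `t_ref` and integration resumes.
#' This is the model trace used by the threshold-likelihood fit and the
#' subthreshold variance-explained diagnostic.
#'
#' @param rec a `recording` (supplies the current and spike times).
#' @param C,g_L,E_L,V_reset passive/reset parameters.
#' @param eta_kern adaptation kernel sampled at `rec$dt` (see
#'   [eval_kernel()]), or `NULL` for none.
#' @param t_ref refractory period (ms).
#' @param V0 initial voltage; default first sample of the data.
#' @return numeric vector of model voltage, same length as `rec$V`.
#' @export
subthreshold_voltage <- function(rec, C, g_L, E_L, V_reset,
                                 eta_kern = NULL, t_ref = 4, V0 = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(eta_kern)) eta_kern <- numeric(0)
  if (is.null(V0)) V0 <- rec$V[1L]
  spike_idx <- as.integer(round(rec$spike_times / rec$dt))
  glif_subthreshold_cpp(rec$I$values, rec$dt, C, g_L, E_L, V_reset, t_ref,
                        spike_idx, eta_kern, V0)
}
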