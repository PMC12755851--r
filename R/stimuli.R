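#' Two-state Markov hidden state trace
#'
#' Generates the binary hidden state that modulates the frozen-noise (FN)
#' presynaptic population. The state is a symmetric two-state Markov chain
#' sampled on the stimulus grid: in either state the per-sample switching
#' probability is `dt / tau`, giving exponentially distributed dwell times
#' with mean `tau` in both states.
#'
#' @param tau switching time constant (ms); mean dwell time in each state.
#'   The experimental protocol uses 250 ms for slow-responding (putatively
#'   excitatory) neurons and 50 ms otherwise.
#' @param duration total duration (ms).
#' @param dt sampling interval (ms); default 0.05 (20 kHz).
#' @param seed integer seed; the trace is bit-reproducible under a fixed seed.
#' @return object of class `hidden_state`: list with `states` (integer 0/1
#'   vector of length `round(duration/dt)`), `dt`, `tau`.
#' @export
generate_hidden_state <- function(tau, duration, dt = 0.05, seed = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single positive number")
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive")
  if (duration < 0) stop("`duration` must be non-negative")
  n <- round(duration / dt)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) {
    out <- list(states = integer(0), dt = dt, tau = tau)
    class(out) <- "hidden_state"
    return(out)
  }
  p_switch <- min(dt / tau, 1)
  s0 <- sample(0:1, 1L)
  # state flips whenever a switch event occurs; parity of cumulative switches
  flips <- stats::runif(n - 1L) < p_switch
  states <- as.integer((s0 + c(0L, cumsum(flips))) %% 2L)
  out <- list(states = states, dt = dt, tau = tau)
  class(out) <- "hidden_state"
  out
}

#' @export
print.hidden_state <- function(x, ...) {
  cat(sprintf("<hidden_state> %d samples, dt = %g ms, tau = %g ms, on-fraction %.3f\n",
              length(x$states), x$dt, x$tau,
              if (length(x$states)) mean(x$states) else NA_real_))
  invisible(x)
}

#' Dwell times of a hidden state trace
#'
#' Durations (ms) of the maximal constant-state runs, excluding the censored
#' first and last runs. Used to check the dwell distribution against the
#' exponential with mean `tau`.
#'
#' @param hidden a `hidden_state` object.
#' @return numeric vector of complete dwell durations in ms.
#' @export
dwell_times <- function(hidden) {
  stopifnot(inherits(hidden, "hidden_state"))
  r <- rle(hidden$states)
  if (length(r$lengths) <= 2L) return(numeric(0))
  r$lengths[-c(1L, length(r$lengths))] * hidden$dt
}

#' Simulated presynaptic Poisson population
#'
#' Defines the population of Poisson units whose state-modulated activity is
#' summed into the FN current. Each unit i fires at `q_on[i]` Hz while the
#' hidden state is on and `q_off[i]` Hz while off, and contributes with
#' weight `w[i] = log(q_on[i] / q_off[i])` (so units with equal rates carry
#' zero weight, and off-preferring units carry negative weight).
#'
#' Per-unit rates are drawn as `q_off ~ U(q_off_range)` and
#' `q_on = q_off * g` with gain `g ~ U(gain_range)`; the defaults produce a
#' mixture of on- and off-preferring units.
#'
#' @param n_units number of presynaptic units (protocol value 1000).
#' @param kernel_tau exponential synaptic kernel decay (ms); protocol value 5.
#' @param q_off_range,gain_range uniform draw ranges for the off-state rate
#'   (Hz) and the on/off gain.
#' @param seed integer seed for the rate draws.
#' @return object of class `presynaptic_population` with fields `n_units`,
#'   `q_on`, `q_off`, `weights`, `kernel_tau`.
#' @export
presynaptic_population <- function(n_units = 1000L, kernel_tau = 5,
                                   q_off_range = c(1, 10),
                                   gain_range = c(0.5, 2),
                                   seed = NULL) {
  stopifnot(n_units >= 1L, kernel_tau > 0,
            all(q_off_range > 0), all(gain_range > 0))
  if (!is.null(seed)) set.seed(seed)
  q_off <- stats::runif(n_units, q_off_range[1L], q_off_range[2L])
  g <- stats::runif(n_units, gain_range[1L], gain_range[2L])
  q_on <- q_off * g
  out <- list(n_units = as.integer(n_units), q_on = q_on, q_off = q_off,
              weights = log(q_on / q_off), kernel_tau = kernel_tau)
  class(out) <- "presynaptic_population"
  out
}

#' @export
print.presynaptic_population <- function(x, ...) {
  cat(sprintf("<presynaptic_population> %d units, kernel tau %g ms, mean |w| = %.3f\n",
              x$n_units, x$kernel_tau, mean(abs(x$weights))))
  invisible(x)
}

#' Current trace container
#'
#' @param values current samples (pA).
#' @param dt sampling interval (ms).
#' @param baseline additive offset (pA) already applied to `values`.
#' @param scale multiplicative factor already applied to `values`.
#' @param protocol one of "FN", "SH".
#' @param meta optional list of extra metadata.
#' @return object of class `current_trace`.
#' @export
current_trace <- function(values, dt, baseline = 0, scale = 1,
                          protocol = c("FN", "SH"), meta = list()) {
  protocol <- match.arg(protocol)
  if (dt <= 0) stop("`dt` must be positive")
  if (any(!is.finite(values))) stop("current values must be finite")
  out <- list(values = as.numeric(values), dt = dt, baseline = baseline,
              scale = scale, protocol = protocol, meta = meta)
  class(out) <- "current_trace"
  out
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %s, %d samples @ dt = %g ms, sd = %.2f pA, baseline = %g pA\n",
              x$protocol, length(x$values), x$dt,
              stats::sd(x$values), x$baseline))
  invisible(x)
}

#' Frozen-noise current from a hidden-state-modulated Poisson population
#'
#' Every unit emits Poisson spikes at its state-dependent rate; the pooled
#' spike train (weighted by `w_i = log(q_on_i/q_off_i)`) is convolved with a
#' causal exponential kernel `exp(-t/kernel_tau)` (unit amplitude at the
#' spike sample), scaled, and offset by `baseline`.
#'
#' Sampling is exact: the pooled per-sample spike count is Poisson with the
#' summed state rate, and each spike is attributed to a unit with probability
#' proportional to that unit's state rate, which is equivalent to
#' independent per-unit Poisson trains.
#'
#' If `scale` is `NULL` it is chosen so that the standard deviation of the
#' output equals `target_sd` (the protocol scales the dimensionless summed
#' input before injection; the scaling factor is stored in the result).
#'
#' @param pop a `presynaptic_population`.
#' @param hidden a `hidden_state` on the desired grid.
#' @param baseline additive offset (pA).
#' @param scale multiplicative factor, or `NULL` to target `target_sd`.
#' @param target_sd desired output SD (pA) when `scale` is `NULL`.
#' @param seed integer seed.
#' @param keep_unit_counts if `TRUE`, attach per-unit spike counts in on/off
#'   states (for statistical checks) as `meta$unit_counts`.
#' @return a `current_trace` (protocol "FN") the same length as `hidden`.
#' @export
generate_fn_current <- function(pop, hidden, baseline = 0, scale = NULL,
                                target_sd = 50, seed = NULL,
                                keep_unit_counts = FALSE) {
  stopifnot(inherits(pop, "presynaptic_population"),
            inherits(hidden, "hidden_state"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(hidden$states)
  dt <- hidden$dt
  dt_s <- dt / 1000  # rates are in Hz
  on <- hidden$states == 1L

  drive <- numeric(n)
  unit_counts <- NULL
  if (any(pop$weights != 0) || keep_unit_counts) {
    q_tot <- c(sum(pop$q_off), sum(pop$q_on))
    counts <- stats::rpois(n, q_tot[hidden$states + 1L] * dt_s)
    total <- sum(counts)
    if (total > 0) {
      samp_idx <- rep.int(seq_len(n), counts)
      spike_on <- on[samp_idx]
      units <- integer(total)
      n_on <- sum(spike_on)
      if (n_on > 0)
        units[spike_on] <- sample.int(pop$n_units, n_on, replace = TRUE,
                                      prob = pop$q_on)
      if (total - n_on > 0)
        units[!spike_on] <- sample.int(pop$n_units, total - n_on,
                                       replace = TRUE, prob = pop$q_off)
      w_spk <- pop$weights[units]
      inc <- numeric(n)
      agg <- rowsum(w_spk, samp_idx)
      inc[as.integer(rownames(agg))] <- agg[, 1L]
      drive <- inc
      if (keep_unit_counts) {
        unit_counts <- list(
          on  = tabulate(units[spike_on], nbins = pop$n_units),
          off = tabulate(units[!spike_on], nbins = pop$n_units),
          t_on = sum(on) * dt_s, t_off = sum(!on) * dt_s)
      }
    } else if (keep_unit_counts) {
      unit_counts <- list(on = integer(pop$n_units), off = integer(pop$n_units),
                          t_on = sum(on) * dt_s, t_off = sum(!on) * dt_s)
    }
  }

  # causal exponential kernel == first-order recursive filter
  raw <- as.numeric(stats::filter(drive, exp(-dt / pop$kernel_tau),
                                  method = "recursive"))
  if (is.null(scale)) {
    s <- stats::sd(raw)
    scale <- if (is.na(s) || s == 0) 1 else target_sd / s
  }
  current_trace(raw * scale + baseline, dt = dt, baseline = baseline,
                scale = scale, protocol = "FN",
                meta = list(tau = hidden$tau, kernel_tau = pop$kernel_tau,
                            unit_counts = unit_counts))
}

#' Step-and-hold current protocol
#'
#' A family of rectangular depolarizing current pulses of equal duration and
#' linearly spaced amplitude, the conventional characterization protocol
#' (10 steps of 500 ms from 40 pA to 400 pA, holding at -70 mV).
#'
#' @param step_min,step_max lowest/highest step amplitude (pA).
#' @param n_steps number of steps (amplitudes equally spaced inclusive).
#' @param step_duration pulse duration (ms).
#' @param holding_potential recorded as metadata (mV).
#' @param dt sampling interval (ms).
#' @param pad_pre,pad_post zero-current padding around the pulse (ms).
#' @return list of `current_trace` objects (protocol "SH"), each with
#'   `meta$step_amplitude`, `meta$step_onset`, `meta$step_duration`,
#'   `meta$holding_potential`.
#' @export
generate_sh_protocol <- function(step_min = 40, step_max = 400, n_steps = 10L,
                                 step_duration = 500, holding_potential = -70,
                                 dt = 0.05, pad_pre = 100, pad_post = 100) {
  if (n_steps < 1L) stop("`n_steps` must be >= 1")
  if (step_max < step_min) stop("`step_max` must be >= `step_min`")
  amps <- if (n_steps == 1L) step_max else
    seq(step_min, step_max, length.out = n_steps)
  n_pre <- round(pad_pre / dt); n_on <- round(step_duration / dt)
  n_post <- round(pad_post / dt)
  lapply(amps, function(a) {
    vals <- c(numeric(n_pre), rep(a, n_on), numeric(n_post))
    current_trace(vals, dt = dt, baseline = 0, scale = 1, protocol = "SH",
                  meta = list(step_amplitude = a, step_onset = pad_pre,
                              step_duration = step_duration,
                              holding_potential = holding_potential))
  })
}
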