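#' Detect spikes as suprathreshold voltage peaks
#'
#' Local maxima of the membrane potential with height at least `height` and
#' pairwise separation at least `min_distance`. When two candidate peaks are
#' closer than `min_distance`, the larger is kept (ties to the earlier one);
#' on a plateau the first sample is taken.
#'
#' @param V membrane potential (mV).
#' @param dt sampling interval (ms).
#' @param height minimum peak height (mV); default 20.
#' @param min_distance minimum peak separation (ms); default 4 (80 samples
#'   at 20 kHz).
#' @return object of class `spike_train`: list with `times` (ms, peak
#'   sample times on the 0-based grid), `dt`, `n`.
#' @export
detect_spikes <- function(V, dt, height = 20, min_distance = 4) {
  stopifnot(dt > 0)
  n <- length(V)
  out <- list(times = numeric(0), dt = dt, n = 0L)
  class(out) <- "spike_train"
  if (n < 3L) return(out)
  # local maximum: strictly above the previous differing value and not
  # below the next one; plateaus resolve to their first sample
  dv <- diff(V)
  rise <- c(FALSE, dv > 0)
  fall_next <- c(dv < 0, FALSE)
  flat_next <- c(dv == 0, TRUE)
  cand <- which(rise & (fall_next | flat_next) & V >= height)
  # drop plateau continuations (previous sample equal and also candidate)
  if (length(cand) > 1L) {
    keep <- c(TRUE, !(diff(cand) == 1L & V[cand[-length(cand)]] == V[cand[-1L]]))
    cand <- cand[keep]
  }
  if (!length(cand)) return(out)
  min_gap <- round(min_distance / dt)
  ord <- cand[order(-V[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  out$times <- (kept - 1L) * dt
  out$n <- length(kept)
  out
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes\n", x$n)); invisible(x)
}

#' Extract aligned spike waveforms
#'
#' Cuts a window of `window_pre` ms before and `window_post` ms after each
#' spike peak. Spikes adjacent to an inter-spike interval below `isi_min`
#' are discarded (non-bursting shapes only), as are spikes whose window does
#' not fit in the trace.
#'
#' @param V membrane potential (mV).
#' @param dt sampling interval (ms).
#' @param spikes a `spike_train` (or numeric spike times in ms).
#' @param window_pre,window_post cut window (ms); protocol values 2 and 3
#'   for the 5-ms waveform, 5 and 5 for the 10-ms waveform.
#' @param isi_min minimum flanking ISI (ms); default 3.
#' @return object of class `waveform_set`: `waveforms` (retained spikes x
#'   samples matrix), `mean_waveform`, `times` (retained spike times),
#'   `dt`, `window_pre`, `window_post`, `n_discarded`.
#' @export
extract_waveforms <- function(V, dt, spikes, window_pre = 2, window_post = 3,
                              isi_min = 3) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else
    as.numeric(spikes)
  n <- length(V)
  keep <- rep(TRUE, length(times))
  if (length(times) > 1L) {
    isi <- diff(times)
    short <- isi < isi_min
    keep[c(short, FALSE)] <- FALSE
    keep[c(FALSE, short)] <- FALSE
  }
  n_pre <- round(window_pre / dt); n_post <- round(window_post / dt)
  len <- n_pre + n_post
  idx <- round(times / dt) + 1L
  keep <- keep & (idx - n_pre >= 1L) & (idx + n_post - 1L <= n)
  kept_idx <- idx[keep]
  W <- if (length(kept_idx))
    t(vapply(kept_idx, function(i) V[(i - n_pre):(i + n_post - 1L)],
             numeric(len))) else matrix(numeric(0), 0L, len)
  out <- list(waveforms = W,
              mean_waveform = if (nrow(W)) colMeans(W) else rep(NA_real_, len),
              times = times[keep], dt = dt,
              window_pre = window_pre, window_post = window_post,
              n_discarded = sum(!keep))
  class(out) <- "waveform_set"
  out
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("<waveform_set> %d waveforms of %d samples (%d discarded)\n",
              nrow(x$waveforms), ncol(x$waveforms), x$n_discarded))
  invisible(x)
}

#' Spike threshold by the dV/dt criterion
#'
#' Voltage at the earliest sample in a search window before the spike peak
#' where the forward-difference derivative first reaches
#' `slope_criterion` (default 25 mV/ms).
#'
#' @param V membrane potential (mV).
#' @param dt sampling interval (ms).
#' @param spike_time peak time (ms).
#' @param slope_criterion derivative criterion (mV/ms).
#' @param search_window how far back from the peak to search (ms).
#' @return list with `threshold` (mV, `NA` if the criterion is never met),
#'   `time` (ms of the crossing sample) and `reason` (`"ok"` or
#'   `"no_crossing"`).
#' @export
spike_threshold <- function(V, dt, spike_time, slope_criterion = 25,
                            search_window = 5) {
  peak <- round(spike_time / dt) + 1L
  lo <- max(1L, peak - round(search_window / dt))
  if (peak - lo < 1L)
    return(list(threshold = NA_real_, time = NA_real_, reason = "no_window"))
  seg <- V[lo:peak]
  dv <- diff(seg) / dt
  hit <- which(dv >= slope_criterion)
  if (!length(hit))
    return(list(threshold = NA_real_, time = NA_real_, reason = "no_crossing"))
  i <- hit[1L]
  list(threshold = seg[i], time = (lo + i - 2L) * dt, reason = "ok")
}

#' Action-potential width and amplitude
#'
#' Width is the time from the last upward threshold crossing before the
#' peak to the first downward crossing after it; amplitude is
#' `V(peak) - threshold`.
#'
#' @param V membrane potential (mV).
#' @param dt sampling interval (ms).
#' @param spike_time peak time (ms).
#' @param threshold AP threshold (mV) for this spike.
#' @param search_window how far around the peak to search for the
#'   crossings (ms).
#' @return list with `width` (ms, `NA` if no downward crossing) and
#'   `amplitude` (mV). Crossing times are linearly interpolated between
#'   samples.
#' @export
ap_width_amplitude <- function(V, dt, spike_time, threshold,
                               search_window = 10) {
  peak <- round(spike_time / dt) + 1L
  n <- length(V)
  amplitude <- V[peak] - threshold
  lo <- max(1L, peak - round(search_window / dt))
  hi <- min(n, peak + round(search_window / dt))
  pre <- V[lo:peak]
  up <- which(pre[-length(pre)] <= threshold & pre[-1L] > threshold)
  post <- V[peak:hi]
  down <- which(post[-length(post)] > threshold & post[-1L] <= threshold)
  if (!length(up) || !length(down))
    return(list(width = NA_real_, amplitude = amplitude))
  iu <- up[length(up)]
  frac_u <- (threshold - pre[iu]) / (pre[iu + 1L] - pre[iu])
  t_up <- (lo + iu - 2L + frac_u) * dt
  id <- down[1L]
  frac_d <- (post[id] - threshold) / (post[id] - post[id + 1L])
  t_down <- (peak + id - 2L + frac_d) * dt
  list(width = t_down - t_up, amplitude = amplitude)
}

ap_feature_names <- c(
  "current_at_first_spike", "ap_count", "time_to_first_spike", "firing_rate",
  "isi_mean", "isi_median", "isi_min", "isi_max", "instantaneous_rate",
  "threshold_first", "threshold_mean", "threshold_median", "threshold_max",
  "threshold_min", "width_mean", "width_median", "width_max", "width_min",
  "amplitude_mean", "amplitude_median", "amplitude_max", "amplitude_min")

# per-spike threshold / width / amplitude stats pooled over a set of traces;
# traces is a list of list(V, dt, times)
per_spike_stats <- function(traces, slope_criterion = 25) {
  thr <- wid <- amp <- numeric(0)
  for (tr in traces) {
    for (ts in tr$times) {
      th <- spike_threshold(tr$V, tr$dt, ts, slope_criterion)
      if (is.na(th$threshold)) next
      wa <- ap_width_amplitude(tr$V, tr$dt, ts, th$threshold)
      thr <- c(thr, th$threshold)
      wid <- c(wid, wa$width)
      amp <- c(amp, wa$amplitude)
    }
  }
  list(threshold = thr, width = wid[!is.na(wid)], amplitude = amp)
}

stat4 <- function(x) {
  if (!length(x)) return(rep(NA_real_, 4L))
  c(mean(x), stats::median(x), max(x), min(x))
}

#' The 22 action-potential attributes of a trial
#'
#' Computes the fixed, documented 22-attribute vector (spiking dynamics,
#' spike threshold, AP height and width with mean/median/max/min
#' statistics; see `ap_feature_names`). For the FN protocol the windows
#' span the full trial. For the SH protocol, `rec` is the list of step
#' sweeps: AP count and firing rate are taken over the step window of the
#' highest-amplitude sweep, time to first spike from the lowest step that
#' produced a spike, current at first spike is that step's amplitude, and
#' the per-spike statistics pool spikes from all sweeps.
#'
#' @param rec a `recording` (FN) or a list of `recording` sweeps with
#'   `meta$step_amplitude`, `meta$step_onset`, `meta$step_duration` (SH).
#' @param protocol `"FN"` or `"SH"`.
#' @param height,min_distance spike-detection parameters.
#' @param slope_criterion threshold dV/dt criterion (mV/ms).
#' @return named numeric vector of length 22 with attribute
#'   `incomplete` (`TRUE` if fewer than 2 spikes made the ISI statistics
#'   undefined).
#' @export
ap_feature_vector <- function(rec, protocol = c("FN", "SH"), height = 20,
                              min_distance = 4, slope_criterion = 25) {
  protocol <- match.arg(protocol)
  f <- stats::setNames(rep(NA_real_, 22L), ap_feature_names)

  if (protocol == "FN") {
    stopifnot(inherits(rec, "recording"))
    spk <- detect_spikes(rec$V, rec$dt, height, min_distance)
    T_s <- length(rec$V) * rec$dt / 1000
    f["ap_count"] <- spk$n
    f["firing_rate"] <- spk$n / T_s
    all_isi <- if (spk$n >= 2L) diff(spk$times) else numeric(0)
    if (spk$n >= 1L) {
      f["time_to_first_spike"] <- spk$times[1L]
      th1 <- spike_threshold(rec$V, rec$dt, spk$times[1L], slope_criterion)
      t_cross <- if (!is.na(th1$time)) th1$time else spk$times[1L]
      f["current_at_first_spike"] <-
        rec$I$values[round(t_cross / rec$dt) + 1L]
      f["threshold_first"] <- th1$threshold
    }
    traces <- list(list(V = rec$V, dt = rec$dt, times = spk$times))
  } else {
    stopifnot(is.list(rec), length(rec) >= 1L,
              all(vapply(rec, inherits, TRUE, "recording")))
    amps <- vapply(rec, function(r) r$meta$step_amplitude %||%
                     r$I$meta$step_amplitude, numeric(1))
    ord <- order(amps)
    det <- lapply(rec, function(r) detect_spikes(r$V, r$dt, height,
                                                 min_distance))
    step_spikes <- function(i) {
      r <- rec[[i]]
      on <- r$meta$step_onset %||% r$I$meta$step_onset
      dur <- r$meta$step_duration %||% r$I$meta$step_duration
      ts <- det[[i]]$times
      ts[ts >= on & ts < on + dur]
    }
    in_step <- lapply(seq_along(rec), step_spikes)
    i_top <- ord[length(ord)]
    dur_top <- rec[[i_top]]$meta$step_duration %||%
      rec[[i_top]]$I$meta$step_duration
    f["ap_count"] <- length(in_step[[i_top]])
    f["firing_rate"] <- length(in_step[[i_top]]) / (dur_top / 1000)
    first_i <- ord[which(vapply(in_step[ord], length, 1L) > 0)[1L]]
    if (!is.na(first_i)) {
      on <- rec[[first_i]]$meta$step_onset %||%
        rec[[first_i]]$I$meta$step_onset
      f["current_at_first_spike"] <- amps[first_i]
      f["time_to_first_spike"] <- in_step[[first_i]][1L] - on
      th1 <- spike_threshold(rec[[first_i]]$V, rec[[first_i]]$dt,
                             in_step[[first_i]][1L], slope_criterion)
      f["threshold_first"] <- th1$threshold
    }
    all_isi <- unlist(lapply(seq_along(rec), function(i)
      if (length(in_step[[i]]) >= 2L) diff(in_step[[i]]) else numeric(0)))
    traces <- lapply(seq_along(rec), function(i)
      list(V = rec[[i]]$V, dt = rec[[i]]$dt, times = in_step[[i]]))
  }

  incomplete <- length(all_isi) < 1L
  if (!incomplete) {
    f[c("isi_mean", "isi_median", "isi_max", "isi_min")] <- stat4(all_isi)
    f["instantaneous_rate"] <- 1000 / mean(all_isi)
  }
  ps <- per_spike_stats(traces, slope_criterion)
  f[c("threshold_mean", "threshold_median", "threshold_max",
      "threshold_min")] <- stat4(ps$threshold)
  f[c("width_mean", "width_median", "width_max", "width_min")] <-
    stat4(ps$width)
  f[c("amplitude_mean", "amplitude_median", "amplitude_max",
      "amplitude_min")] <- stat4(ps$amplitude)
  attr(f, "incomplete") <- incomplete || anyNA(f)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spike-triggered average of the stimulus
#'
#' Mean of the stimulus segments in a fixed window preceding each spike
#' (`STA = (1/N) sum_n s(t_n)`; the window ends at the sample before the
#' spike peak; spikes without a full preceding window are dropped). The
#' vector is then standardized (its own mean and SD) and scaled to unit L2
#' norm. No whitening or regularization is applied.
#'
#' @param current a `current_trace`.
#' @param spikes a `spike_train` or numeric spike times (ms).
#' @param window window length (ms); default 100 (2000 samples at 20 kHz).
#' @return object of class `sta_vector`: `values` (normalized, unit L2
#'   norm), `raw` (the plain average), `window`, `dt`, `n_spikes`.
#' @export
compute_sta <- function(current, spikes, window = 100) {
  stopifnot(inherits(current, "current_trace"))
  times <- if (inherits(spikes, "spike_train")) spikes$times else
    as.numeric(spikes)
  dt <- current$dt
  L <- round(window / dt)
  idx <- round(times / dt) + 1L
  idx <- idx[idx - L >= 1L & idx <= length(current$values)]
  if (!length(idx)) stop("no spike has a full stimulus window before it")
  acc <- numeric(L)
  for (i in idx) acc <- acc + current$values[(i - L):(i - 1L)]
  raw <- acc / length(idx)
  s <- stats::sd(raw)
  if (s == 0) stop("STA undefined: zero variance before normalization")
  z <- (raw - mean(raw)) / s
  out <- list(values = z / sqrt(sum(z^2)), raw = raw, window = window,
              dt = dt, n_spikes = length(idx))
  class(out) <- "sta_vector"
  out
}

#' @export
print.sta_vector <- function(x, ...) {
  cat(sprintf("<sta_vector> %d samples (%g ms) from %d spikes\n",
              length(x$values), x$window, x$n_spikes))
  invisible(x)
}
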