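make_triangle_trace <- function(peak_times, dt = 0.05, dur = NULL,
                                base = -70, peak = 30, rise = 0.5,
                                fall = 0.5) {
  if (is.null(dur)) dur <- max(peak_times) + 20
  n <- round(dur / dt)
  V <- rep(base, n)
  nr <- round(rise / dt); nf <- round(fall / dt)
  for (tp in peak_times) {
    i <- round(tp / dt) + 1L
    V[(i - nr):i] <- seq(base, peak, length.out = nr + 1L)
    V[i:(i + nf)] <- seq(peak, base, length.out = nf + 1L)
  }
  V
}

test_that("spike detection finds suprathreshold peaks with separation", {
  V <- make_triangle_trace(c(50, 100), dt = 0.05)
  spk <- detect_spikes(V, 0.05, height = 20)
  expect_equal(spk$times, c(50, 100))

  expect_equal(detect_spikes(rep(-70, 1000), 0.05)$n, 0L)
  expect_equal(detect_spikes(make_triangle_trace(60, peak = 15), 0.05)$n, 0L)

  # two peaks 2 ms apart with min_distance 4 ms: the larger one wins
  V2 <- make_triangle_trace(c(50, 52), dt = 0.05, peak = 30)
  i2 <- round(52 / 0.05) + 1L
  V2[i2] <- 35
  expect_equal(detect_spikes(V2, 0.05, min_distance = 4)$times, 52)

  # plateau resolves to its first sample
  V3 <- rep(-70, 2000)
  V3[800:810] <- 30
  expect_equal(detect_spikes(V3, 0.05)$times, (800 - 1) * 0.05)
})

test_that("waveform extraction windows, ISI exclusion and averaging", {
  dt <- 0.05
  V <- make_triangle_trace(c(50, 100, 150), dt = dt)
  spk <- detect_spikes(V, dt)
  ws <- extract_waveforms(V, dt, spk, window_pre = 2, window_post = 3)
  expect_equal(ncol(ws$waveforms), 100L)            # 5 ms at 20 kHz
  expect_equal(nrow(ws$waveforms), 3L)
  # identical spikes -> mean equals any member
  expect_equal(ws$mean_waveform, ws$waveforms[1, ])

  # a pair with ISI 2 ms < 3 ms: both excluded
  V2 <- make_triangle_trace(c(50, 52, 120), dt = dt, rise = 0.4, fall = 0.4)
  spk2 <- detect_spikes(V2, dt, min_distance = 1)
  expect_equal(spk2$n, 3L)
  ws2 <- extract_waveforms(V2, dt, spk2, isi_min = 3)
  expect_equal(ws2$times, 120)
  expect_equal(ws2$n_discarded, 2L)
})

test_that("spike threshold is V at the first dV/dt crossing", {
  # piecewise-linear rise: 10 mV/ms from -50 until -40, then 50 mV/ms to
  # +30; the 25 mV/ms criterion is first met exactly at -40 mV
  dt <- 0.05
  seg1 <- seq(-50, -40, by = 10 * dt)
  seg2 <- seq(-40, 30, by = 50 * dt)[-1]
  V <- c(rep(-50, 100), seg1, seg2, seq(30, -60, by = -50 * dt)[-1])
  pk <- which.max(V)
  th <- spike_threshold(V, dt, (pk - 1) * dt)
  expect_equal(th$threshold, -40)
  expect_equal(th$reason, "ok")

  # slope never reaches the criterion
  Vs <- seq(-70, 30, by = 10 * dt)
  th2 <- spike_threshold(Vs, dt, (length(Vs) - 1) * dt)
  expect_true(is.na(th2$threshold))
  expect_equal(th2$reason, "no_crossing")
})

test_that("AP width and amplitude from constructed geometry", {
  # triangular spike rising from -40 to +30 in 0.5 ms and falling back in
  # 0.5 ms: width at a -40 threshold is 1.0 ms, amplitude 70 mV
  dt <- 0.05
  V <- make_triangle_trace(50, dt = dt, base = -40, peak = 30,
                           rise = 0.5, fall = 0.5)
  wa <- ap_width_amplitude(V, dt, 50, threshold = -40)
  expect_equal(wa$amplitude, 70)
  expect_equal(wa$width, 1.0, tolerance = 0.01)
  # symmetric spike: crossings equidistant from the peak
  wa2 <- ap_width_amplitude(V, dt, 50, threshold = -10)
  expect_equal(wa2$width / 2,
               0.5 * (30 - (-10)) / (30 - (-40)), tolerance = 0.01)
  # monotone rise with no fall: width missing
  Vr <- seq(-70, 30, length.out = 2000)
  wa3 <- ap_width_amplitude(Vr, dt, (2000 - 1) * dt, threshold = -40)
  expect_true(is.na(wa3$width))
})

test_that("the 22-attribute vector matches hand-computed values on a
           uniform train", {
  dt <- 0.05
  peaks <- seq(500, 3500, by = 100)                 # 100 ms ISIs
  V <- make_triangle_trace(peaks, dt = dt, dur = 10000)
  rec <- recording(V, current_trace(rep(50, round(10000 / dt)), dt))
  f <- ap_feature_vector(rec, protocol = "FN")
  expect_length(f, 22L)
  expect_identical(names(f), ephysclust:::ap_feature_names)
  expect_equal(f[["ap_count"]], length(peaks))
  expect_equal(f[["firing_rate"]], length(peaks) / 10)
  expect_equal(unname(f[c("isi_mean", "isi_median", "isi_min", "isi_max")]),
               rep(100, 4))
  expect_equal(f[["instantaneous_rate"]], 10)
  expect_equal(f[["time_to_first_spike"]], 500)
  expect_true(f[["isi_min"]] <= f[["isi_median"]] &&
                f[["isi_median"]] <= f[["isi_max"]])

  # appending spike-free padding changes the rate only through T
  V_pad <- c(V, rep(-70, round(10000 / dt)))
  rec_pad <- recording(V_pad, current_trace(rep(50, length(V_pad)), dt))
  f_pad <- ap_feature_vector(rec_pad, protocol = "FN")
  expect_equal(f_pad[["firing_rate"]], f[["firing_rate"]] / 2)
  expect_equal(f_pad[["isi_mean"]], f[["isi_mean"]])
  expect_equal(f_pad[["width_mean"]], f[["width_mean"]])
})

test_that("SH attributes use the correct steps", {
  dt <- 0.05
  sh <- generate_sh_protocol(dt = dt)
  # neuron spiking only from the 120-pA step (step 3) upward; top step
  # carries 5 spikes in the 500-ms window
  recs <- lapply(seq_along(sh), function(i) {
    n <- length(sh[[i]]$values)
    if (i < 3) V <- rep(-70, n)
    else {
      k <- if (i == 10) 5 else 2
      V <- make_triangle_trace(100 + 30 * (1:k), dt = dt,
                               dur = n * dt)
    }
    recording(V, sh[[i]], meta = sh[[i]]$meta)
  })
  f <- ap_feature_vector(recs, protocol = "SH")
  expect_equal(f[["current_at_first_spike"]], 120)
  expect_equal(f[["ap_count"]], 5)
  expect_equal(f[["firing_rate"]], 10)              # 5 spikes / 0.5 s
  expect_equal(f[["time_to_first_spike"]], 30)      # 130 ms - 100 ms onset
})

test_that("STA averages the pre-spike stimulus and normalizes to unit L2", {
  dt <- 0.05
  set.seed(12)
  n <- 40000
  cur <- current_trace(stats::rnorm(n, 0, 30), dt)
  # single spike: raw STA equals the 100-ms segment before the peak
  st <- compute_sta(cur, 1500, window = 100)
  L <- round(100 / dt)
  i <- round(1500 / dt) + 1L
  expect_equal(st$raw, cur$values[(i - L):(i - 1L)])
  expect_equal(length(st$values), 2000L)
  expect_equal(sum(st$values^2), 1, tolerance = 1e-12)

  # spikes independent of a white stimulus: raw STA RMS shrinks as 1/sqrt(N)
  long <- current_trace(stats::rnorm(4e6, 0, 30), dt)
  t_all <- sort(sample(seq(3000, 4e6 - 1), 10000)) * dt
  rms <- function(x) sqrt(mean(x^2))
  r_small <- rms(compute_sta(long, t_all[1:100], window = 100)$raw)
  r_big <- rms(compute_sta(long, t_all, window = 100)$raw)
  expect_gt(r_small / r_big, 5)
  expect_lt(r_small / r_big, 20)

  expect_error(compute_sta(cur, 1, window = 100), "window")
  cz <- current_trace(rep(5, 10000), dt)
  expect_error(compute_sta(cz, 400, window = 100), "zero variance")
})
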