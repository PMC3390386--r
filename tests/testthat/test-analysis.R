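test_that("peak detection recovers sinusoid maxima and rejects flats", {
  x <- sine_trace(8, duration_s = 5)
  pk <- detect_peaks(x)
  expect_true(abs(length(pk) - 40) <= 1)
  # analytic maxima at t = (k + 1/4)/8 s; detected within one sample
  analytic <- (seq_along(pk) - 1 + 0.25) / 8 * 1000
  expect_lt(max(abs(pk - analytic[seq_along(pk)])), 1.01)
  expect_length(detect_peaks(rep(-60, 1000)), 0)
  expect_length(detect_peaks(sine_trace(8, amplitude = 0.05)), 0)
})

test_that("peak amplitudes of a damped oscillation decrease", {
  t <- seq(0, 5, by = 1e-3)
  x <- -60 + 5 * exp(-t / 1.4) * sin(2 * pi * 6 * t)
  pk <- detect_peaks(x)
  amps <- x[round(pk) + 1]
  expect_true(all(diff(amps) < 0))
})

test_that("stability rule separates sustained from damped oscillations", {
  expect_true(is_stable(sine_trace(8, duration_s = 4))$stable)
  t <- seq(0, 4, by = 1e-3)
  damped <- -60 + 5 * 2^(-t / 1) * sin(2 * pi * 8 * t)   # half-life 1 s
  expect_false(is_stable(damped)$stable)
  flat <- rep(-60, 4000) + 0.1 * sin(2 * pi * 8 * seq_len(4000) / 1000)
  expect_false(is_stable(flat)$stable)    # below the 0.5 mV floor
  expect_error(is_stable(sine_trace(8, duration_s = 1)), "shorter")
})

test_that("frequency estimation is sharp on known signals", {
  fe <- estimate_frequency(sine_trace(9.2, duration_s = 4))
  expect_true(fe$oscillatory)
  expect_lt(abs(fe$frequency - 9.2), 0.05)
  expect_equal(fe$resolution, 1000 / 4001, tolerance = 1e-6)
  set.seed(42)
  noise <- estimate_frequency(rnorm(4000))
  expect_false(noise$oscillatory)
  expect_true(is.na(noise$frequency))
})

test_that("spectral and peak-train rate estimators agree", {
  r <- ref_result()
  keep <- r$time >= 1000
  v <- r$V[1, keep]
  fe <- estimate_frequency(v)
  pk <- detect_peaks(v)
  rate <- (length(pk) - 1) / diff(range(pk)) * 1000
  expect_lt(abs(fe$frequency - rate), fe$resolution)
})

test_that("the spectrogram tracks a mid-trace frequency step", {
  x <- c(sine_trace(6.3, duration_s = 5), sine_trace(10.9, duration_s = 5))
  sg <- stft_spectrogram(x, window = 1000, hop = 250)
  early <- sg$dominant[sg$time < 4000]
  late <- sg$dominant[sg$time > 6500]
  expect_true(all(abs(early - 6.3) < 0.5))
  expect_true(all(abs(late - 10.9) < 0.5))
  # stationary input: constant dominant row, consistent with the full FFT
  sgc <- stft_spectrogram(sine_trace(8, duration_s = 5))
  expect_lt(diff(range(sgc$dominant)), 1e-9)
  fe <- estimate_frequency(sine_trace(8, duration_s = 5))
  expect_lt(abs(sgc$dominant[1] - fe$frequency), 0.5)
})

test_that("phase maps encode fractional peak-time offsets in degrees", {
  base <- seq(100, 4900, by = 125)           # 8 Hz train
  trains <- list(base, base + 31.25, base - 31.25, base)
  pm <- phase_map(trains, reference = 1)
  expect_equal(pm$phase_deg[1], 0)
  expect_equal(pm$phase_deg[2], 90, tolerance = 1e-6)
  expect_equal(pm$phase_deg[3], -90, tolerance = 1e-6)
  expect_equal(pm$phase_deg[4], 0, tolerance = 1e-6)
})

test_that("changing the reference shifts all phases by one constant", {
  base <- seq(100, 4900, by = 125)
  trains <- list(base, base + 20, base + 45, base - 10)
  p1 <- phase_map(trains, reference = 1)
  p2 <- phase_map(trains, reference = 3)
  d <- (p1$phase_deg - p2$phase_deg) %% 360
  expect_lt(diff(range(d)), 1e-6)
})

test_that("phase maps refuse non-synchronized input", {
  fast <- seq(100, 4900, by = 100)
  slow <- seq(100, 4900, by = 170)
  expect_error(phase_map(list(fast, slow)), "not synchronized")
})

test_that("cross-correlograms localize train offsets", {
  base <- seq(100, 4900, by = 125)
  auto <- peak_crosscorrelogram(base, base)
  expect_equal(auto$peak_lag, 0)
  off <- peak_crosscorrelogram(base, base + 40, bin = 5)
  expect_equal(off$peak_lag, 40)
  expect_error(peak_crosscorrelogram(numeric(0), base))
})

test_that("phase relations are stable across halves of a network run", {
  r <- ref_result()
  keep1 <- r$time >= 1000 & r$time < 3000
  keep2 <- r$time >= 3000
  tr <- function(i, keep) detect_peaks(r$V[i, keep], time = r$time[keep])
  a1 <- peak_crosscorrelogram(tr(1, keep1), tr(13, keep1), bin = 10)
  a2 <- peak_crosscorrelogram(tr(1, keep2), tr(13, keep2), bin = 10)
  expect_lt(abs(a1$peak_lag - a2$peak_lag), 11)
})

test_that("wave order scores constructed activation sequences", {
  kin <- test_kin()
  net <- ref_net()
  ord <- order(tapply(net$neurons$g_Ca, net$neurons$cluster, mean),
               decreasing = TRUE)
  # build synthetic traces: each cluster peaks later down the g_Ca order
  t <- seq(0, 5000)
  V <- matrix(0, nrow(net$neurons), length(t))
  for (k in seq_along(ord)) {
    lagms <- (k - 1) * 12
    rows <- which(net$neurons$cluster == ord[k])
    V[rows, ] <- rep(-60 + 5 * sin(2 * pi * 8 * (t - lagms) / 1000),
                     each = length(rows))
  }
  res <- structure(list(time = t, V = V, h = V * 0, events = list(),
                        meta = list()), class = "sim_result")
  wv <- wave_order(res, net)
  expect_equal(wv$concordance, 1)
  # reversing the order flips the sign
  res_rev <- res
  res_rev$V <- V[rev(seq_len(nrow(V))), ]
  net_rev <- net
  net_rev$neurons$cluster <- rev(net$neurons$cluster)
  wv_rev <- wave_order(res_rev, net)
  expect_lt(wv_rev$concordance, 0)
})

test_that("wave order is invariant to the cycle-anchoring neuron", {
  r <- ref_result()
  net <- ref_net()
  w1 <- wave_order(r, net, reference = 1)
  w2 <- wave_order(r, net, reference = 25)
  expect_equal(w1$concordance, w2$concordance, tolerance = 0.15)
})

test_that("frequency and phase estimators hit known two-oscillator truths", {
  set.seed(99)
  for (i in 1:20) {
    f <- runif(1, 4, 12)
    dphi <- runif(1, -150, 150)
    lag_s <- dphi / 360 / f
    a <- sine_trace(f, duration_s = 5)
    b <- sine_trace(f, duration_s = 5, phase = -2 * pi * f * lag_s)
    fe <- estimate_frequency(a)
    expect_lt(abs(fe$frequency - f), 0.1)
    pm <- phase_map(list(detect_peaks(a), detect_peaks(b)))
    expect_lt(abs(pm$phase_deg[2] - dphi), 5)
  }
})

test_that("network synchrony requires one shared dominant frequency", {
  r <- ref_result()
  nf <- network_frequency(r)
  expect_true(nf$synchronized)
  expect_true(all(nf$per_neuron$in_band))
  expect_lt(diff(range(nf$per_neuron$frequency)), 2 * nf$resolution)
  # splicing in an alien trace breaks synchrony
  r2 <- r
  r2$V[4, ] <- sine_trace(15, duration_s = 5)[seq_len(ncol(r2$V))]
  nf2 <- network_frequency(r2)
  expect_false(nf2$synchronized)
  expect_false(nf2$per_neuron$in_band[4])
})
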