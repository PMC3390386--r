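#' Detect subthreshold oscillation peaks
#'
#' Local-maximum detection with a prominence criterion and a minimum peak
#' separation. Prominence of a candidate maximum is its height above the
#' higher of the two valley minima separating it from the nearest larger
#' samples on either side. When two candidates fall within
#' `min_separation`, the larger one wins. Deterministic; an empty train is
#' a valid result.
#'
#' @param x Numeric voltage trace, mV, sampled uniformly.
#' @param time Optional sample times, ms; defaults to `0, 1/fs, ...`.
#' @param fs Sampling rate, Hz.
#' @param prominence Minimum prominence, mV. The default is half the 0.5 mV
#'   oscillation amplitude floor, tying detection to the stability rule.
#' @param min_separation Minimum separation between retained peaks, ms.
#' @return Sorted numeric vector of peak times (ms) with attribute
#'   `settings`; class `peak_train`.
#' @export
detect_peaks <- function(x, time = NULL, fs = 1000, prominence = 0.25,
                         min_separation = 20) {
  stopifnot(is.numeric(x), length(x) >= 3)
  if (is.null(time)) time <- (seq_along(x) - 1) * 1000 / fs
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand)) {
    prom <- vapply(cand, function(i) {
      pk <- x[i]
      lmin <- pk; j <- i
      while (j > 1 && x[j] <= pk) { j <- j - 1; lmin <- min(lmin, x[j]) }
      if (j == 1 && x[1] <= pk) lmin <- min(x[1:i])
      rmin <- pk; j <- i
      while (j < n && x[j] <= pk) { j <- j + 1; rmin <- min(rmin, x[j]) }
      if (j == n && x[n] <= pk) rmin <- min(x[i:n])
      pk - max(lmin, rmin)
    }, numeric(1))
    cand <- cand[prom >= prominence]
  }
  # enforce minimum separation, largest peaks first
  if (length(cand) > 1) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord)
      if (!length(kept) || all(abs(time[i] - time[kept]) >= min_separation))
        kept <- c(kept, i)
    cand <- sort(kept)
  }
  structure(time[cand], class = "peak_train",
            settings = list(prominence = prominence,
                            min_separation = min_separation, fs = fs))
}

#' Test a trace for stable (non-damping) oscillation
#'
#' A trace counts as a stable oscillation when its peak-to-peak amplitude in
#' the final comparison window is at least `ratio` of the amplitude in the
#' first comparison window *and* exceeds the oscillation amplitude floor.
#' The trace passed in should already have its initial transient discarded;
#' the early window then probes post-transient amplitude and the final
#' window probes persistence.
#'
#' @param x Numeric voltage trace, mV, transient already discarded.
#' @param fs Sampling rate, Hz.
#' @param window Comparison window length, ms.
#' @param ratio Minimum final/early amplitude ratio for stability.
#' @param amplitude_floor Minimum final peak-to-peak amplitude, mV.
#' @return List with `stable` (logical), `amplitude_early`,
#'   `amplitude_final` (mV) and `ratio_observed`.
#' @export
is_stable <- function(x, fs = 1000, window = 1000, ratio = 0.9,
                      amplitude_floor = 0.5) {
  nwin <- round(window * fs / 1000)
  if (length(x) < 2 * nwin)
    stop("trace shorter than two comparison windows (",
         2 * window, " ms required)")
  early <- x[seq_len(nwin)]
  final <- x[(length(x) - nwin + 1):length(x)]
  a_e <- diff(range(early)); a_f <- diff(range(final))
  list(stable = a_f >= amplitude_floor && a_f >= ratio * a_e,
       amplitude_early = a_e, amplitude_final = a_f,
       ratio_observed = if (a_e > 0) a_f / a_e else Inf)
}

# Hann-tapered, zero-padded magnitude spectrum; shared by the frequency
# estimator and the spectrogram.
taper_spectrum <- function(x, fs, zero_pad = 4) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xp <- c(x * w, rep(0, (zero_pad - 1) * n))
  m <- Mod(stats::fft(xp))[seq_len(floor(length(xp) / 2))]
  list(frequency = (seq_along(m) - 1) * fs / length(xp), magnitude = m)
}

#' Estimate the dominant oscillation frequency
#'
#' Argmax of the Hann-tapered, zero-padded magnitude spectrum over the
#' search band, refined by parabolic interpolation of the log-magnitude
#' around the peak bin. A trace whose spectral peak does not stand out
#' above the in-band noise floor (median magnitude) is flagged
#' non-oscillatory. The native resolution (1/window length) is reported so
#' downstream synchrony checks can compare estimates at one-bin precision.
#'
#' @param x Numeric voltage trace, mV, transient already discarded.
#' @param fs Sampling rate, Hz.
#' @param band Search band, Hz.
#' @param zero_pad Zero-padding factor for the FFT.
#' @param floor_ratio Minimum peak/median magnitude ratio to accept a peak.
#' @return List of class `frequency_estimate`: `frequency` (Hz; `NA` when
#'   non-oscillatory), `resolution` (Hz), `oscillatory` (logical),
#'   `peak_ratio`.
#' @export
estimate_frequency <- function(x, fs = 1000, band = c(1, 20), zero_pad = 4,
                               floor_ratio = 10) {
  stopifnot(length(x) >= fs)  # at least 1 s
  sp <- taper_spectrum(x, fs, zero_pad)
  inb <- sp$frequency >= band[1] & sp$frequency <= band[2]
  mag <- sp$magnitude[inb]; fr <- sp$frequency[inb]
  i <- which.max(mag)
  ratio <- mag[i] / stats::median(mag)
  res <- fs / length(x)
  if (!is.finite(ratio) || ratio < floor_ratio)
    return(structure(list(frequency = NA_real_, resolution = res,
                          oscillatory = FALSE, peak_ratio = ratio),
                     class = "frequency_estimate"))
  f <- fr[i]
  if (i > 1 && i < length(mag)) {
    la <- log(mag[i - 1]); lb <- log(mag[i]); lc <- log(mag[i + 1])
    d <- 0.5 * (la - lc) / (la - 2 * lb + lc)
    if (is.finite(d) && abs(d) <= 1) f <- f + d * (fr[2] - fr[1])
  }
  structure(list(frequency = f, resolution = res, oscillatory = TRUE,
                 peak_ratio = ratio),
            class = "frequency_estimate")
}

#' Short-time Fourier spectrogram
#'
#' Sliding-window magnitude spectrogram (Hann taper, mean removal and
#' zero-padding per column). A frequency-shift event in the trace appears
#' as a step in the per-column argmax track.
#'
#' @inheritParams estimate_frequency
#' @param window Window length, ms.
#' @param hop Hop between successive windows, ms.
#' @return List of class `stft`: `time` (window centers, ms), `frequency`
#'   (Hz), `magnitude` (frequency x time), `dominant` (argmax track, Hz).
#' @export
stft_spectrogram <- function(x, fs = 1000, window = 1000, hop = 250,
                             band = c(1, 20), zero_pad = 4) {
  nwin <- round(window * fs / 1000); nhop <- round(hop * fs / 1000)
  stopifnot(window >= 1000, length(x) >= nwin)
  starts <- seq(1, length(x) - nwin + 1, by = nhop)
  cols <- lapply(starts, function(s) taper_spectrum(x[s:(s + nwin - 1)], fs,
                                                    zero_pad))
  fr <- cols[[1]]$frequency
  inb <- fr >= band[1] & fr <= band[2]
  mag <- vapply(cols, function(cc) cc$magnitude[inb],
                numeric(sum(inb)))
  dom <- fr[inb][apply(mag, 2, which.max)]
  structure(list(time = (starts - 1 + nwin / 2) * 1000 / fs,
                 frequency = fr[inb], magnitude = mag, dominant = dom),
            class = "stft")
}

# Wrap angles in degrees to (-180, 180].
wrap_angle <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

circular_mean_deg <- function(a) {
  r <- a * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Per-neuron phase map relative to a reference neuron
#'
#' For each neuron, each of its oscillation peaks is matched to the nearest
#' reference peak; the time difference, expressed in degrees of the
#' reference inter-peak interval, is averaged circularly over all cycles in
#' the window. The reference neuron has phase 0 by construction and all
#' phases are reported in (-180, 180]. Positive phase = peaking after the
#' reference (phase lag); negative = phase lead.
#'
#' Requires a synchronized input: when `x` is a simulation result, all
#' per-neuron dominant frequencies must agree within one spectral
#' resolution bin, otherwise an error names the offending neurons.
#'
#' @param x A `sim_result` or a list of `peak_train`/numeric peak-time
#'   vectors (ms).
#' @param reference Index of the reference neuron.
#' @param transient Transient discard for `sim_result` input, ms.
#' @param ... Passed to [detect_peaks()] for `sim_result` input.
#' @return A data.frame of class `phase_map` with columns `neuron`,
#'   `phase_deg`; attributes `reference` and `period` (ms).
#' @export
phase_map <- function(x, reference = 1, transient = 1000, ...) {
  if (inherits(x, "sim_result")) {
    nf <- network_frequency(x, transient = transient)
    if (!nf$synchronized) {
      bad <- which(!nf$per_neuron$in_band)
      stop("input not synchronized; offending neurons: ",
           paste(bad, collapse = ", "))
    }
    keep <- x$time >= (x$time[1] + transient)
    trains <- lapply(seq_len(nrow(x$V)), function(i)
      detect_peaks(x$V[i, keep], time = x$time[keep], ...))
  } else {
    trains <- x
    rate <- vapply(trains, function(tt) (length(tt) - 1) / diff(range(tt)),
                   numeric(1))
    if (diff(range(rate)) > 0.15 * stats::median(rate))
      stop("input not synchronized; offending neurons: ",
           paste(which(abs(rate - stats::median(rate)) >
                         0.075 * stats::median(rate)), collapse = ", "))
  }
  ref <- trains[[reference]]
  if (length(ref) < 2) stop("reference train too short for a phase map")
  period <- stats::median(diff(ref))
  ph <- vapply(trains, function(tt) {
    if (!length(tt)) return(NA_real_)
    d <- vapply(tt, function(p) p - ref[which.min(abs(ref - p))], numeric(1))
    circular_mean_deg(d / period * 360)
  }, numeric(1))
  ph[reference] <- 0
  structure(data.frame(neuron = seq_along(trains), phase_deg = ph),
            class = c("phase_map", "data.frame"),
            reference = reference, period = period)
}

#' Cross-correlogram of two peak trains
#'
#' Histogram of all pairwise peak-time differences `b - a` within the lag
#' range, computed from peak times in the manner usual for spike trains.
#' For two synchronized oscillators the correlogram peaks at the phase
#' offset plus integer multiples of the common period.
#'
#' @param a,b Peak-time vectors, ms.
#' @param lag_max Maximum |lag|, ms.
#' @param bin Bin width, ms.
#' @return List of class `correlogram`: `lag` (bin centers, ms), `count`,
#'   and `peak_lag` (center of the most populated bin).
#' @export
peak_crosscorrelogram <- function(a, b, lag_max = 250, bin = 5) {
  stopifnot(length(a) > 0, length(b) > 0)
  d <- as.vector(outer(b, a, "-"))
  d <- d[abs(d) <= lag_max]
  breaks <- seq(-lag_max - bin / 2, lag_max + bin / 2, by = bin)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(lag = h$mids, count = h$counts,
                 peak_lag = h$mids[which.max(h$counts)]),
            class = "correlogram")
}

#' Per-neuron conductance / amplitude / phase relation table
#'
#' Collates, for every neuron of a synchronized simulation, its T-type
#' conductance density, mean oscillation peak voltage, and phase relative
#' to the reference neuron. Downstream tests correlate phase lead and peak
#' amplitude with g_Ca.
#'
#' @param network An `io_network`.
#' @param result A `sim_result` from that network.
#' @param reference Reference neuron index for the phase map.
#' @param transient Transient discard, ms.
#' @return A data.frame with columns `neuron`, `cluster`, `g_Ca`,
#'   `peak_v` (mV), `phase_deg`.
#' @export
phase_amplitude_relation <- function(network, result, reference = 1,
                                     transient = 1000) {
  pm <- phase_map(result, reference = reference, transient = transient)
  keep <- result$time >= (result$time[1] + transient)
  pv <- vapply(seq_len(nrow(result$V)), function(i) {
    tr <- detect_peaks(result$V[i, keep], time = result$time[keep])
    idx <- match(tr, result$time[keep])
    mean(result$V[i, keep][idx])
  }, numeric(1))
  data.frame(neuron = network$neurons$id, cluster = network$neurons$cluster,
             g_Ca = network$neurons$g_Ca, peak_v = pv,
             phase_deg = pm$phase_deg)
}

#' Wave-order concordance of cluster activation
#'
#' Within each oscillation cycle (anchored on the reference neuron's
#' peaks), ranks clusters by their mean peak time and measures Kendall
#' concordance with the descending order of cluster mean g_Ca. +1 means
#' clusters activate strictly in descending g_Ca order (a perfect
#' propagating wave); 0 is chance order.
#'
#' @param result A synchronized `sim_result`.
#' @param network The `io_network` that produced it.
#' @param reference Reference neuron for cycle anchoring.
#' @param transient Transient discard, ms.
#' @return List: `concordance` (mean Kendall tau over cycles), `per_cycle`.
#' @export
wave_order <- function(result, network, reference = 1, transient = 1000) {
  keep <- result$time >= (result$time[1] + transient)
  trains <- lapply(seq_len(nrow(result$V)), function(i)
    detect_peaks(result$V[i, keep], time = result$time[keep]))
  ref <- trains[[reference]]
  if (length(ref) < 3) stop("too few reference cycles for wave ordering")
  period <- stats::median(diff(ref))
  cl <- network$neurons$cluster
  gca_cl <- tapply(network$neurons$g_Ca, cl, mean)
  taus <- vapply(seq_along(ref), function(k) {
    # cluster mean peak time within half a period of this reference peak
    mt <- vapply(names(gca_cl), function(cc) {
      pts <- unlist(lapply(trains[cl == cc], function(tt)
        tt[abs(tt - ref[k]) <= period / 2]))
      if (length(pts)) mean(pts) else NA_real_
    }, numeric(1))
    if (any(is.na(mt)) || length(unique(mt)) < 2) return(NA_real_)
    -stats::cor(mt, as.vector(gca_cl), method = "kendall")
  }, numeric(1))
  taus <- taus[!is.na(taus)]
  list(concordance = mean(taus), per_cycle = taus)
}

#' Network-level frequency and synchrony
#'
#' Estimates each neuron's dominant frequency after transient discard and
#' applies the synchrony definition: the network is synchronized when every
#' neuron oscillates and all dominant frequencies fall within one spectral
#' resolution bin of their shared value (same frequency, not necessarily
#' same phase).
#'
#' @param result A `sim_result`.
#' @param transient Transient discard, ms.
#' @param band Search band, Hz.
#' @return List: `frequency` (median over neurons, Hz), `synchronized`
#'   (logical), `resolution` (Hz), `per_neuron` (data.frame with
#'   `frequency`, `oscillating`, `in_band`).
#' @export
network_frequency <- function(result, transient = 1000, band = c(1, 20)) {
  keep <- result$time >= (result$time[1] + transient)
  fs <- 1000 / stats::median(diff(result$time))
  est <- lapply(seq_len(nrow(result$V)), function(i)
    estimate_frequency(result$V[i, keep], fs = fs, band = band))
  f <- vapply(est, `[[`, numeric(1), "frequency")
  osc <- vapply(est, `[[`, logical(1), "oscillatory")
  res <- est[[1]]$resolution
  med <- stats::median(f[osc])
  in_band <- osc & !is.na(f) & abs(f - med) <= res
  list(frequency = med, synchronized = all(in_band), resolution = res,
       per_neuron = data.frame(frequency = f, oscillating = osc,
                               in_band = in_band))
}

#' Which neurons of a simulation oscillate stably?
#'
#' Applies the per-trace stability rule to every neuron after transient
#' discard.
#'
#' @inheritParams network_frequency
#' @return Logical vector, one element per neuron.
#' @export
oscillating_neurons <- function(result, transient = 1000) {
  keep <- result$time >= (result$time[1] + transient)
  fs <- 1000 / stats::median(diff(result$time))
  vapply(seq_len(nrow(result$V)), function(i)
    is_stable(result$V[i, keep], fs = fs)$stable, logical(1))
}
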