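#' Staged-coupling experiment
#'
#' Runs the three-stage protocol (uncoupled, intra-cluster only, fully
#' coupled) on a network and reports, for each stage, how many neurons
#' oscillate stably, the within-cluster synchrony, and — for the full
#' stage — the network frequency, synchrony and stability.
#'
#' @param network An `io_network`.
#' @param duration Per-stage simulated time, ms.
#' @param seed Initial-condition jitter seed.
#' @param transient Transient discard for all measurements, ms.
#' @return A list of class `io_report` with per-stage summaries; every
#'   number is recomputable from the stored inputs and seeds.
#' @export
run_staged_protocol <- function(network, duration = 5000, seed = 1,
                                transient = 1000) {
  stages <- staged_coupling_run(network, duration = duration, seed = seed)
  cl <- network$neurons$cluster
  stage_summary <- lapply(stages, function(s) {
    osc <- oscillating_neurons(s, transient = transient)
    keep <- s$time >= transient
    fs <- 1000 / stats::median(diff(s$time))
    freqs <- vapply(seq_len(nrow(s$V)), function(i) {
      fe <- estimate_frequency(s$V[i, keep], fs = fs)
      fe$frequency %||% NA_real_
    }, numeric(1))
    per_cluster <- lapply(split(seq_len(nrow(s$V)), cl), function(ix) {
      f <- freqs[ix]
      list(n_oscillating = sum(osc[ix]),
           freq_spread = if (sum(!is.na(f)) > 1) diff(range(f, na.rm = TRUE))
                         else NA_real_,
           frequency = stats::median(f, na.rm = TRUE))
    })
    list(n_oscillating = sum(osc), oscillating = osc, frequency = freqs,
         per_cluster = per_cluster)
  })
  nf <- network_frequency(stages$full, transient = transient)
  stable <- all(oscillating_neurons(stages$full, transient = transient))
  structure(list(protocol = "staged_coupling",
                 inputs = list(seed = seed, duration = duration,
                               transient = transient,
                               network_meta = network$meta),
                 stages = stage_summary,
                 full_network = list(frequency = nf$frequency,
                                     synchronized = nf$synchronized,
                                     stable = stable),
                 results = stages),
            class = "io_report")
}

#' Coupling-modulation experiment
#'
#' Simulates a network with a mid-run modulation of the inter-cluster
#' coupling strengths and reports the synchronized frequency before and
#' after the event, the shift, and the short-time Fourier track of one
#' neuron across the event.
#'
#' @param network An `io_network`.
#' @param schedule A [modulation_schedule()] (a single timed event).
#' @param duration Total simulated time, ms.
#' @param seed Initial-condition jitter seed.
#' @param transient Transient discarded after the start and after the
#'   event, ms.
#' @param stft_neuron Neuron (row index) for the spectrogram.
#' @return A list of class `io_report`.
#' @export
run_modulation_protocol <- function(network, schedule, duration = 10000,
                                    seed = 1, transient = 1000,
                                    stft_neuron = 1) {
  res <- run_with_modulation(network, schedule, duration = duration,
                             seed = seed)
  t_ev <- if (length(schedule)) schedule[[1]]$time else duration
  fs <- 1000 / stats::median(diff(res$time))
  pre_w <- res$time >= transient & res$time < t_ev
  post_w <- res$time >= t_ev + transient
  freq_in <- function(w) {
    f <- vapply(seq_len(nrow(res$V)), function(i) {
      fe <- estimate_frequency(res$V[i, w], fs = fs)
      fe$frequency
    }, numeric(1))
    list(frequency = stats::median(f, na.rm = TRUE),
         synchronized = all(!is.na(f)) &&
           diff(range(f)) <= fs / sum(w))
  }
  pre <- freq_in(pre_w)
  post <- if (any(post_w)) freq_in(post_w) else list(frequency = NA,
                                                     synchronized = NA)
  sg <- stft_spectrogram(res$V[stft_neuron, ], fs = fs, window = 1000,
                         hop = 250)
  structure(list(protocol = "modulation",
                 inputs = list(seed = seed, duration = duration,
                               schedule = schedule,
                               network_meta = network$meta),
                 pre = pre, post = post,
                 shift = post$frequency - pre$frequency,
                 stft = sg, result = res),
            class = "io_report")
}

#' Ensemble of synchronized network frequencies
#'
#' Two ensemble designs: `mode = "specs"` generates `n` fresh networks
#' from a spec family (one child seed each) and records each network's
#' synchronized frequency; `mode = "resample_coupling"` keeps one
#' network's topology and conductances but redraws all inter-cluster
#' coupling-coefficient targets `n` times, recalibrates, and records the
#' frequency each variant settles to — the same topology can oscillate in
#' synchrony at many frequencies.
#'
#' @param x A [generator_spec()] (specs mode; its seed seeds the ensemble)
#'   or an `io_network` (resample mode).
#' @param n Number of networks / resamples.
#' @param seed Ensemble seed (required for resample mode).
#' @param mode Ensemble design, see above.
#' @param duration Per-network simulated time, ms.
#' @param transient Transient discard, ms.
#' @param cc_range CC target range for resampled inter-cluster junctions.
#' @param kin Kinetics for specs mode.
#' @return A list of class `io_report` with `table` (data.frame: network,
#'   frequency, synchronized) and `summary` (median and quartiles of the
#'   synchronized frequencies).
#' @export
run_frequency_ensemble <- function(x, n = 30, seed = NULL,
                                   mode = c("specs", "resample_coupling"),
                                   duration = 5000, transient = 1000,
                                   cc_range = c(0.02, 0.20),
                                   kin = gating_kinetics()) {
  mode <- match.arg(mode)
  rows <- vector("list", n)
  if (mode == "specs") {
    stopifnot(inherits(x, "generator_spec"))
    seeds <- child_seeds(seed %||% x$seed, n)
    for (i in seq_len(n)) {
      sp <- x; sp$seed <- seeds[i]
      net <- generate_network(sp, kin)
      r <- simulate_network(net, duration, seed = seeds[i])
      nf <- network_frequency(r, transient = transient)
      rows[[i]] <- data.frame(network = i, seed = seeds[i],
                              frequency = nf$frequency,
                              synchronized = nf$synchronized)
    }
  } else {
    stopifnot(inherits(x, "io_network"), !is.null(seed))
    inter <- which(x$junctions$kind == "inter")
    if (!length(inter)) stop("network has no inter-cluster junctions")
    seeds <- child_seeds(seed, n)
    for (i in seq_len(n)) {
      net <- x
      net$junctions$cc_target[inter] <-
        with_seed(seeds[i], stats::runif(length(inter), cc_range[1],
                                         cc_range[2]))
      net <- calibrate_network(net, subset = inter)
      r <- simulate_network(net, duration, seed = seeds[i])
      nf <- network_frequency(r, transient = transient)
      rows[[i]] <- data.frame(network = i, seed = seeds[i],
                              frequency = nf$frequency,
                              synchronized = nf$synchronized)
    }
  }
  tab <- do.call(rbind, rows)
  fs <- tab$frequency[tab$synchronized]
  structure(list(protocol = paste0("ensemble_", mode),
                 inputs = list(n = n, seed = seed, duration = duration,
                               cc_range = cc_range),
                 table = tab,
                 summary = list(n_synchronized = sum(tab$synchronized),
                                median = stats::median(fs),
                                quartiles = stats::quantile(fs,
                                  c(0.25, 0.75), names = FALSE))),
            class = "io_report")
}

#' Phase-structure experiment
#'
#' On a synchronized simulation, computes the per-neuron phase map, the
#' maximum pairwise phase difference, peak-time cross-correlograms between
#' one representative neuron per cluster, the per-neuron
#' conductance/amplitude/phase relation, and the wave-order concordance of
#' cluster activation with descending g_Ca.
#'
#' @param network An `io_network`.
#' @param result An existing `sim_result`; if `NULL`, one is simulated.
#' @param duration,seed Used when simulating.
#' @param reference Reference neuron index for phases.
#' @param transient Transient discard, ms.
#' @return A list of class `io_report`.
#' @export
run_phase_protocol <- function(network, result = NULL, duration = 5000,
                               seed = 1, reference = 1, transient = 1000) {
  if (is.null(result))
    result <- simulate_network(network, duration, seed = seed)
  pm <- phase_map(result, reference = reference, transient = transient)
  dphi <- abs(wrap_angle(outer(pm$phase_deg, pm$phase_deg, "-")))
  rel <- phase_amplitude_relation(network, result, reference = reference,
                                  transient = transient)
  wv <- wave_order(result, network, reference = reference,
                   transient = transient)
  keep <- result$time >= transient
  cl <- network$neurons$cluster
  rep_neuron <- vapply(split(seq_len(nrow(result$V)), cl), `[[`, integer(1), 1)
  trains <- lapply(rep_neuron, function(i)
    detect_peaks(result$V[i, keep], time = result$time[keep]))
  xc <- list()
  for (i in seq_along(trains)[-1])
    xc[[paste0(names(trains)[1], "-", names(trains)[i])]] <-
      peak_crosscorrelogram(trains[[1]], trains[[i]])
  structure(list(protocol = "phase_structure",
                 inputs = list(seed = seed, duration = duration,
                               reference = reference,
                               network_meta = network$meta),
                 phase_map = pm,
                 max_phase_difference = max(dphi),
                 relation = rel, wave_order = wv,
                 crosscorrelograms = xc, result = result),
            class = "io_report")
}

#' @export
print.io_report <- function(x, ...) {
  cat("io_report:", x$protocol, "\n")
  if (!is.null(x$full_network))
    cat(sprintf("  full network: %.2f Hz, synchronized: %s, stable: %s\n",
                x$full_network$frequency, x$full_network$synchronized,
                x$full_network$stable))
  if (!is.null(x$shift))
    cat(sprintf("  frequency shift: %.2f -> %.2f Hz (%+.2f)\n",
                x$pre$frequency, x$post$frequency, x$shift))
  if (!is.null(x$max_phase_difference))
    cat(sprintf("  max pairwise phase difference: %.1f deg\n",
                x$max_phase_difference))
  if (!is.null(x$summary) && !is.null(x$summary$median))
    cat(sprintf("  synchronized: %d/%d, median %.2f Hz [%.2f, %.2f]\n",
                x$summary$n_synchronized, nrow(x$table), x$summary$median,
                x$summary$quartiles[1], x$summary$quartiles[2]))
  invisible(x)
}
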