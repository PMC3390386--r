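#' Parameters of a single model neuron
#'
#' A single-compartment conductance-based cell with two currents: a passive
#' leak and a low-threshold (T-type) Ca2+ current. Conductances are surface
#' densities (mS/cm^2); `area` converts them to absolute conductances where
#' junctional coupling requires them.
#'
#' @param g_l Leak conductance density, mS/cm^2.
#' @param g_Ca Maximal T-type Ca2+ conductance density, mS/cm^2.
#' @param E_l Leak reversal potential, mV.
#' @param E_Ca Ca2+ reversal potential, mV.
#' @param Cm Specific membrane capacitance, uF/cm^2.
#' @param area Membrane area, cm^2. One default for all cells; coupling
#'   coefficients are calibrated in absolute units so network results are
#'   invariant to this choice once CCs are fixed.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(g_l, g_Ca, E_l = -63, E_Ca = 120, Cm = 1,
                          area = 1e-4) {
  stopifnot(g_l >= 0, g_Ca >= 0, Cm > 0, area > 0,
            is.finite(E_l), is.finite(E_Ca))
  structure(list(g_l = g_l, g_Ca = g_Ca, E_l = E_l, E_Ca = E_Ca,
                 Cm = Cm, area = area),
            class = "neuron_params")
}

#' Time derivatives of the membrane equation
#'
#' Pure function computing the right-hand side of the two-state membrane
#' model: `Cm dV/dt = -g_l (V - E_l) - g_Ca m_inf(V)^p h (V - E_Ca) + i_ext`
#' and `dh/dt = (h_inf(V) - h)/tau_h(V)`. Activation is instantaneous
#' (`m = m_inf(V)`); inactivation `h` is the single slow state.
#'
#' @param state Numeric vector `c(V, h)`: membrane potential (mV) and
#'   inactivation gate (dimensionless).
#' @param params A [neuron_params()] object.
#' @param kin A [gating_kinetics()] object.
#' @param i_ext External current density, uA/cm^2.
#' @return Numeric vector `c(dV, dh)` in mV/ms and 1/ms.
#' @export
cell_derivatives <- function(state, params, kin, i_ext = 0) {
  if (any(!is.finite(state)))
    stop("non-finite state: numerical blow-up")
  v <- state[[1]]; h <- state[[2]]
  i_ca <- params$g_Ca * m_inf(kin, v)^kin$m_exponent * h * (v - params$E_Ca)
  dv <- (-params$g_l * (v - params$E_l) - i_ca + i_ext) / params$Cm
  dh <- (h_inf(kin, v) - h) / tau_h(kin, v)
  c(dv, dh)
}

# Integrate a batch of mutually uncoupled cells (vectorized RHS). Used by
# the single-cell harness, the frequency map and the boundary search.
# i_ext may be a scalar, a per-cell vector, or NULL. g_load adds a linear
# shunt of g_load nS (per cell) toward e_load, mimicking a junctional load.
integrate_cells <- function(g_l, g_Ca, kin, E_l = -63, E_Ca = kin$E_Ca,
                            Cm = 1, area = 1e-4, duration = 4000,
                            dt_out = 1, v0 = E_l, h0 = NULL, i_ext = 0,
                            g_load = 0, e_load = E_l,
                            method = "lsoda", rtol = 1e-8, atol = 1e-8,
                            t0 = 0) {
  n <- length(g_l)
  stopifnot(length(g_Ca) == n, duration > 0)
  v0 <- rep_len(v0, n)
  if (is.null(h0)) h0 <- h_inf(kin, v0) else h0 <- rep_len(h0, n)
  i_ext <- rep_len(i_ext, n)
  g_load_den <- rep_len(g_load, n) / (area * 1e6)  # nS -> mS/cm^2
  p <- kin$m_exponent
  rhs <- function(t, y, parms) {
    v <- y[seq_len(n)]; h <- y[n + seq_len(n)]
    i_ca <- g_Ca * m_inf(kin, v)^p * h * (v - E_Ca)
    dv <- (-g_l * (v - E_l) - i_ca - g_load_den * (v - e_load) + i_ext) / Cm
    dh <- (h_inf(kin, v) - h) / tau_h(kin, v)
    list(c(dv, dh))
  }
  times <- seq(t0, t0 + duration, by = dt_out)
  out <- deSolve::ode(c(v0, h0), times, rhs, NULL, method = method,
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out)))
    stop("solver failure while integrating cell batch")
  list(time = out[, 1],
       V = out[, 1 + seq_len(n), drop = FALSE],
       h = out[, 1 + n + seq_len(n), drop = FALSE])
}

#' Simulate a single model neuron
#'
#' Integrates one cell on a uniform output grid with the package's default
#' adaptive solver. The stimulus may be a constant current density or a
#' rectangular step described by `list(amplitude, onset, duration)`
#' (uA/cm^2, ms); step edges are handled by integration restarts, never by
#' smoothing through the discontinuity.
#'
#' @inheritParams cell_derivatives
#' @param duration Total simulated time, ms.
#' @param dt_out Output sampling interval, ms.
#' @param i_ext Constant current density (uA/cm^2) or a step descriptor.
#' @param v0,h0 Initial conditions; default `V(0) = E_l`, `h(0) = h_inf(V0)`.
#' @param g_load Optional junctional load, absolute nS, shunting toward `E_l`.
#' @param method,rtol,atol Solver settings passed to [deSolve::ode()].
#' @return A list of class `cell_trace` with elements `time`, `V`, `h`.
#' @export
simulate_cell <- function(params, kin = gating_kinetics(), duration = 5000,
                          dt_out = 1, i_ext = 0, v0 = params$E_l, h0 = NULL,
                          g_load = 0, method = "lsoda",
                          rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "neuron_params"), duration > 0)
  seg <- function(dur, i, v0, h0, t0)
    integrate_cells(params$g_l, params$g_Ca, kin, E_l = params$E_l,
                    E_Ca = params$E_Ca, Cm = params$Cm, area = params$area,
                    duration = dur, dt_out = dt_out, v0 = v0, h0 = h0,
                    i_ext = i, g_load = g_load, method = method,
                    rtol = rtol, atol = atol, t0 = t0)
  if (is.list(i_ext)) {
    on <- i_ext$onset; off <- i_ext$onset + i_ext$duration
    stopifnot(on >= 0, off <= duration)
    pieces <- list()
    state <- c(v0, if (is.null(h0)) h_inf(kin, v0) else h0)
    bounds <- unique(c(0, on, off, duration))
    for (k in seq_len(length(bounds) - 1)) {
      amp <- if (bounds[k] >= on && bounds[k] < off) i_ext$amplitude else 0
      s <- seg(bounds[k + 1] - bounds[k], amp, state[1], state[2], bounds[k])
      state <- c(s$V[nrow(s$V), 1], s$h[nrow(s$h), 1])
      keep <- if (k == 1) seq_along(s$time) else -1L  # drop duplicated knot
      pieces[[k]] <- list(time = s$time[keep], V = s$V[keep, 1], h = s$h[keep, 1])
    }
    res <- list(time = unlist(lapply(pieces, `[[`, "time")),
                V = unlist(lapply(pieces, `[[`, "V")),
                h = unlist(lapply(pieces, `[[`, "h")))
  } else {
    s <- seg(duration, i_ext, v0, if (is.null(h0)) h_inf(kin, v0) else h0, 0)
    res <- list(time = s$time, V = s$V[, 1], h = s$h[, 1])
  }
  res$params <- params
  res$solver <- list(method = method, rtol = rtol, atol = atol, dt_out = dt_out)
  class(res) <- "cell_trace"
  res
}

# Classify a batch of cells by simulation; returns a data.frame with one row
# per cell. Oscillation = non-damped periodicity after transient discard,
# using the same stability rule as the network analysis.
classify_cells <- function(g_l, g_Ca, kin, duration = 4000, transient = 1000,
                           dt_out = 1, amplitude_floor = 0.5, ...) {
  sim <- integrate_cells(g_l, g_Ca, kin, duration = duration,
                         dt_out = dt_out, ...)
  keep <- sim$time >= transient
  t_win <- sim$time[keep]
  out <- lapply(seq_along(g_l), function(i) {
    v <- sim$V[keep, i]
    st <- is_stable(v, fs = 1000 / dt_out, amplitude_floor = amplitude_floor)
    if (st$stable) {
      fe <- estimate_frequency(v, fs = 1000 / dt_out)
      data.frame(oscillating = TRUE, frequency = fe$frequency,
                 amplitude = st$amplitude_final)
    } else {
      data.frame(oscillating = FALSE, frequency = NA_real_,
                 amplitude = st$amplitude_final)
    }
  })
  cbind(data.frame(g_l = g_l, g_Ca = g_Ca), do.call(rbind, out))
}

#' Classify the dynamical regime of a single cell
#'
#' Simulates the cell from rest, discards a transient window and tests
#' whether the trace shows non-damped periodic activity above the
#' oscillation amplitude floor (0.5 mV, the lower edge of the experimentally
#' reported amplitude range). Classification is binary: a cell is either a
#' spontaneous oscillator or stable. Conditional-oscillator and bistable
#' behaviour are not distinguished.
#'
#' @inheritParams simulate_cell
#' @param transient Initial window discarded before analysis, ms.
#' @param amplitude_floor Minimum peak-to-peak amplitude (mV) to count as
#'   oscillating.
#' @return A list of class `regime_label` with elements `regime`
#'   (`"spontaneous_oscillator"` or `"stable"`), `frequency` (Hz, `NA` when
#'   stable) and `amplitude` (peak-to-peak mV in the final window).
#' @export
classify_regime <- function(params, kin = gating_kinetics(), duration = 4000,
                            transient = 1000, amplitude_floor = 0.5, ...) {
  stopifnot(inherits(params, "neuron_params"))
  df <- classify_cells(params$g_l, params$g_Ca, kin, duration = duration,
                       transient = transient,
                       amplitude_floor = amplitude_floor,
                       E_l = params$E_l, E_Ca = params$E_Ca, Cm = params$Cm,
                       area = params$area, ...)
  structure(list(
    regime = if (df$oscillating) "spontaneous_oscillator" else "stable",
    frequency = df$frequency, amplitude = df$amplitude),
    class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  if (x$regime == "spontaneous_oscillator")
    cat(sprintf("spontaneous oscillator: %.2f Hz, %.2f mV peak-to-peak\n",
                x$frequency, x$amplitude))
  else
    cat(sprintf("stable (final amplitude %.3f mV)\n", x$amplitude))
  invisible(x)
}

#' Map oscillation frequency over the conductance plane
#'
#' Simulates a dense grid of uncoupled cells across the (g_l, g_Ca) plane
#' and records, for each grid point, whether the cell oscillates
#' spontaneously and at what frequency. The map is deterministic (no
#' randomness in the pipeline) and carries its resolution and solver
#' settings as metadata.
#'
#' @param g_l,g_Ca Numeric vectors of grid values, mS/cm^2.
#' @param kin A [gating_kinetics()] object.
#' @param duration,transient Simulation and discard windows, ms.
#' @param chunk Maximum number of cells integrated per solver call.
#' @return A list of class `frequency_map` with matrices `frequency`,
#'   `amplitude`, `oscillating` (rows: `g_l`, columns: `g_Ca`).
#' @export
frequency_map <- function(g_l = seq(0.15, 0.40, by = 0.01),
                          g_Ca = seq(0.2, 1.4, by = 0.05),
                          kin = gating_kinetics(), duration = 4000,
                          transient = 1000, chunk = 200) {
  grid <- expand.grid(g_l = g_l, g_Ca = g_Ca)
  idx <- split(seq_len(nrow(grid)), ceiling(seq_len(nrow(grid)) / chunk))
  res <- do.call(rbind, lapply(idx, function(i)
    classify_cells(grid$g_l[i], grid$g_Ca[i], kin, duration = duration,
                   transient = transient)))
  shape <- function(col) matrix(res[[col]], nrow = length(g_l),
                                dimnames = list(format(g_l), format(g_Ca)))
  structure(list(g_l = g_l, g_Ca = g_Ca,
                 frequency = shape("frequency"),
                 amplitude = shape("amplitude"),
                 oscillating = shape("oscillating"),
                 meta = list(duration = duration, transient = transient,
                             kinetics = unclass(kin))),
            class = "frequency_map")
}

#' Locate the spontaneous-oscillation onset boundary
#'
#' For each requested leak density, bisects on g_Ca for the onset of
#' spontaneous oscillation (the interface between the quiescent and
#' oscillatory regions of the conductance plane). Results are cached per
#' kinetics/settings combination within the session, since the search is
#' deterministic.
#'
#' @param kin A [gating_kinetics()] object.
#' @param g_l Leak densities at which to locate the boundary, mS/cm^2.
#' @param g_Ca_range Search interval for g_Ca, mS/cm^2.
#' @param tol Bisection tolerance on g_Ca, mS/cm^2.
#' @param duration Per-probe simulation length, ms.
#' @return A data.frame with columns `g_l` and `g_Ca` (the onset boundary;
#'   `NA` where no oscillation occurs anywhere in the search interval).
#' @export
oscillation_boundary <- function(kin = gating_kinetics(),
                                 g_l = seq(0.15, 0.40, by = 0.01),
                                 g_Ca_range = c(0.2, 1.4), tol = 0.005,
                                 duration = 3000) {
  key <- paste(format(c(unlist(kin[1:10]), g_l, g_Ca_range, tol, duration),
                      digits = 12), collapse = "|")
  cache <- package_env$boundary_cache %||% list()
  if (!is.null(cache[[key]])) return(cache[[key]])
  osc <- function(gca) classify_cells(g_l, gca, kin,
                                      duration = duration)$oscillating
  # The oscillatory region can be a band in g_Ca (re-stabilization at high
  # g_Ca), so first bracket the onset with a coarse ladder, then bisect.
  ladder <- seq(g_Ca_range[1], g_Ca_range[2], length.out = 13)
  osc_at <- vapply(ladder, function(gc) osc(rep(gc, length(g_l))),
                   logical(length(g_l)))
  if (length(g_l) == 1) osc_at <- matrix(osc_at, nrow = 1)
  first_osc <- apply(osc_at, 1, function(r)
    if (any(r)) which(r)[1] else NA_integer_)
  lo <- hi <- rep(NA_real_, length(g_l))
  hi[!is.na(first_osc)] <- ladder[first_osc[!is.na(first_osc)]]
  lo[!is.na(first_osc)] <- ifelse(first_osc[!is.na(first_osc)] == 1,
                                  g_Ca_range[1],
                                  ladder[first_osc[!is.na(first_osc)] - 1])
  act <- which(!is.na(first_osc) & first_osc > 1)
  while (length(act) && max(hi[act] - lo[act]) > tol) {
    mid <- (lo + hi) / 2
    m_osc <- rep(FALSE, length(g_l))
    m_osc[act] <- classify_cells(g_l[act], mid[act], kin,
                                 duration = duration)$oscillating
    hi[act] <- ifelse(m_osc[act], mid[act], hi[act])
    lo[act] <- ifelse(m_osc[act], lo[act], mid[act])
  }
  b <- (lo + hi) / 2
  b[!is.na(first_osc) & first_osc == 1] <- g_Ca_range[1]
  out <- data.frame(g_l = g_l, g_Ca = b)
  cache[[key]] <- out
  package_env$boundary_cache <- cache
  out
}

#' Input resistance of a model cell
#'
#' Measures input resistance with a small hyperpolarizing current step:
#' the cell settles, a step of `step` uA/cm^2 is applied for `step_dur` ms,
#' and R = dV_ss/dI from the difference of the mean potential over the last
#' 100 ms of the step and the 100 ms preceding it. An optional junctional
#' load (absolute nS) is included in parallel. If the cell oscillates above
#' the amplitude floor during the baseline, the measurement averages over
#' the cycle and the result is flagged with attribute `oscillating = TRUE`.
#'
#' @inheritParams simulate_cell
#' @param g_load Junctional load, absolute nS.
#' @param step Step current density, uA/cm^2 (negative = hyperpolarizing).
#' @param settle Settling time before the step, ms.
#' @param step_dur Step duration, ms.
#' @param block_ca If `TRUE`, the T-type conductance is set to zero during
#'   the measurement (oscillation-suppressing condition used for coupling
#'   calibration).
#' @return Input resistance in MOhm, with attribute `oscillating`.
#' @export
input_resistance <- function(params, kin = gating_kinetics(), g_load = 0,
                             step = -0.5, settle = 1000, step_dur = 500,
                             block_ca = FALSE, ...) {
  stopifnot(inherits(params, "neuron_params"), step != 0)
  p <- params
  if (block_ca) p <- neuron_params(p$g_l, 0, p$E_l, p$E_Ca, p$Cm, p$area)
  tr <- simulate_cell(p, kin, duration = settle + step_dur,
                      i_ext = list(amplitude = step, onset = settle,
                                   duration = step_dur),
                      g_load = g_load, ...)
  pre <- tr$V[tr$time >= settle - 100 & tr$time < settle]
  post <- tr$V[tr$time >= settle + step_dur - 100]
  oscillating <- diff(range(pre)) > 0.5
  dv <- mean(post) - mean(pre)     # mV
  di <- step * p$area              # uA/cm^2 * cm^2 = absolute uA
  structure(dv / di / 1000,        # mV/uA = kOhm -> MOhm
            oscillating = oscillating)
}
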