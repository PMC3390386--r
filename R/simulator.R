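# Assemble the coupled ODE right-hand side for a network. States are
# c(V_1..V_N, h_1..h_N). Gap currents enter through the sparse junction
# Laplacian: for neuron i, sum_j g_ij (V_j - V_i) = -(L V)_i in nS*mV.
build_network_rhs <- function(network, block_ca = FALSE, i_ext = NULL) {
  nn <- network$neurons
  n <- nrow(nn)
  kin <- network$kinetics
  g_l <- nn$g_l
  g_ca <- if (block_ca) rep(0, n) else nn$g_Ca
  e_l <- nn$E_l; e_ca <- nn$E_Ca; cm <- nn$Cm; area <- nn$area
  p <- kin$m_exponent
  i_ext <- if (is.null(i_ext)) numeric(n) else rep_len(i_ext, n)
  j <- network$junctions
  if (nrow(j)) {
    idx <- stats::setNames(seq_len(n), nn$id)
    a <- idx[as.character(j$a)]; b <- idx[as.character(j$b)]
    L <- Matrix::sparseMatrix(i = c(a, b, a, b), j = c(a, b, b, a),
                              x = c(j$g_gap, j$g_gap, -j$g_gap, -j$g_gap),
                              dims = c(n, n))
    gap <- function(v) -as.vector(L %*% v) / area * NS_MV_TO_UA_PER_CM2
  } else {
    gap <- function(v) 0
  }
  function(t, y, parms) {
    v <- y[seq_len(n)]; h <- y[n + seq_len(n)]
    i_ca <- g_ca * m_inf(kin, v)^p * h * (v - e_ca)
    dv <- (-g_l * (v - e_l) - i_ca + gap(v) + i_ext) / cm
    dh <- (h_inf(kin, v) - h) / tau_h(kin, v)
    list(c(dv, dh))
  }
}

# Default initial conditions: V = E_l plus optional seeded uniform jitter
# (symmetry breaking), h at steady state.
initial_state <- function(network, jitter = 1, seed = NULL) {
  n <- nrow(network$neurons)
  dj <- if (!is.null(seed) && jitter > 0)
    with_seed(seed, stats::runif(n, -jitter, jitter)) else numeric(n)
  v0 <- network$neurons$E_l + dj
  c(v0, h_inf(network$kinetics, v0))
}

#' Integrate a network of coupled model neurons
#'
#' Solves the coupled membrane system (two states per neuron) with the
#' package's default adaptive solver on a uniform output grid. Initial
#' conditions default to `V(0) = E_l` with optional seeded uniform jitter
#' of +/-`jitter` mV (to break symmetry in homogeneous networks) and
#' `h(0) = h_inf(V(0))`. Deterministic for fixed seed and solver settings.
#'
#' @param network An `io_network`.
#' @param duration Simulated time, ms.
#' @param dt_out Output sampling interval, ms.
#' @param seed Seed for the initial-condition jitter; `NULL` disables
#'   jitter.
#' @param jitter Jitter half-range, mV.
#' @param v0,h0 Explicit initial conditions (override the jitter rule).
#' @param i_ext Per-neuron constant external current density, uA/cm^2.
#' @param block_ca Simulate the passive skeleton (T-type conductance
#'   blocked); used by measurement protocols.
#' @param method,rtol,atol Solver settings ([deSolve::ode()]).
#' @param v_bounds Sanity window for voltages, mV; traces leaving it abort
#'   the run.
#' @return Object of class `sim_result`: `time` (ms), `V` and `h`
#'   (neuron x time matrices), `events` (modulation log, possibly empty),
#'   `meta` (solver settings, seed).
#' @export
simulate_network <- function(network, duration, dt_out = 1, seed = NULL,
                             jitter = 1, v0 = NULL, h0 = NULL, i_ext = NULL,
                             block_ca = FALSE, method = "lsoda",
                             rtol = 1e-8, atol = 1e-8,
                             v_bounds = c(-120, 60)) {
  stopifnot(inherits(network, "io_network"), duration > 0)
  n <- nrow(network$neurons)
  y0 <- if (!is.null(v0)) {
    c(rep_len(v0, n),
      if (is.null(h0)) h_inf(network$kinetics, rep_len(v0, n))
      else rep_len(h0, n))
  } else initial_state(network, jitter = jitter, seed = seed)
  rhs <- build_network_rhs(network, block_ca = block_ca, i_ext = i_ext)
  times <- seq(0, duration, by = dt_out)
  out <- deSolve::ode(y0, times, rhs, NULL, method = method,
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out)))
    stop("solver failure at t = ", max(out[is.finite(out[, 2]), 1]), " ms")
  V <- t(out[, 1 + seq_len(n), drop = FALSE])
  h <- t(out[, 1 + n + seq_len(n), drop = FALSE])
  if (min(V) < v_bounds[1] || max(V) > v_bounds[2])
    stop("voltage left the sanity window [", v_bounds[1], ", ",
         v_bounds[2], "] mV")
  structure(list(time = out[, 1], V = V, h = h, events = list(),
                 meta = list(solver = list(method = method, rtol = rtol,
                                           atol = atol, dt_out = dt_out),
                             seed = seed, jitter = jitter)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d neurons, %.0f ms (dt %.3g ms), %d event(s)\n",
              nrow(x$V), max(x$time) - min(x$time),
              x$meta$solver$dt_out %||% diff(x$time[1:2]), length(x$events)))
  invisible(x)
}

#' Run a network with mid-simulation coupling modulation
#'
#' Integrates the network piecewise, rescaling the listed junction
#' conductances exactly at each event time (stop-and-restart; no smoothing
#' through the discontinuity). The event log records the old and new
#' conductance of every affected junction.
#'
#' @param network An `io_network`.
#' @param schedule List of modulation events as produced by
#'   [modulation_schedule()]: each a list with `time` (ms), `junction`
#'   (row indices into the junction table) and `factors` (multiplicative).
#' @param duration Total simulated time, ms.
#' @param ... Passed to [simulate_network()].
#' @return A `sim_result` spanning the full duration, with `events` filled.
#' @export
run_with_modulation <- function(network, schedule, duration = 10000, ...) {
  if (!length(schedule))
    return(simulate_network(network, duration, ...))
  tms <- vapply(schedule, `[[`, numeric(1), "time")
  stopifnot(all(tms > 0), all(tms < duration), !is.unsorted(tms))
  bounds <- c(0, tms, duration)
  net <- network
  pieces <- list(); events <- list()
  state_v <- NULL; state_h <- NULL
  args <- list(...)
  for (k in seq_len(length(bounds) - 1)) {
    seg_args <- c(list(network = net, duration = bounds[k + 1] - bounds[k]),
                  args)
    if (k > 1) {
      seg_args$v0 <- state_v; seg_args$h0 <- state_h
      seg_args$seed <- NULL
    }
    s <- do.call(simulate_network, seg_args)
    state_v <- s$V[, ncol(s$V)]; state_h <- s$h[, ncol(s$h)]
    keep <- if (k == 1) seq_along(s$time) else -1L
    pieces[[k]] <- list(time = s$time[keep] + bounds[k],
                        V = s$V[, keep, drop = FALSE],
                        h = s$h[, keep, drop = FALSE])
    if (k <= length(schedule)) {
      ev <- schedule[[k]]
      old <- net$junctions$g_gap[ev$junction]
      net$junctions$g_gap[ev$junction] <- old * ev$factors
      events[[k]] <- list(time = ev$time, junction = ev$junction,
                          factors = ev$factors, g_old = old,
                          g_new = old * ev$factors,
                          note = ev$note %||% NULL)
    }
  }
  structure(list(time = do.call(c, lapply(pieces, `[[`, "time")),
                 V = do.call(cbind, lapply(pieces, `[[`, "V")),
                 h = do.call(cbind, lapply(pieces, `[[`, "h")),
                 events = events,
                 meta = c(list(schedule = schedule), args)),
            class = "sim_result")
}

#' Staged coupling protocol: uncoupled, intra-only, fully coupled
#'
#' Simulates the same network three times with junction subsets none /
#' intra-cluster only / all, keeping neuron parameters and initial
#' conditions identical across stages, so that the effect of each coupling
#' tier can be compared directly.
#'
#' @param network An `io_network`.
#' @param duration Per-stage simulated time, ms.
#' @param seed Initial-condition jitter seed shared by all stages.
#' @param ... Passed to [simulate_network()].
#' @return Named list of `sim_result`s: `uncoupled`, `intra`, `full`.
#' @export
staged_coupling_run <- function(network, duration = 5000, seed = NULL, ...) {
  y0 <- initial_state(network, seed = seed)
  n <- nrow(network$neurons)
  sub <- function(kinds) {
    net <- network
    net$junctions <- network$junctions[network$junctions$kind %in% kinds, ,
                                       drop = FALSE]
    net
  }
  run <- function(net) simulate_network(net, duration,
                                        v0 = y0[seq_len(n)],
                                        h0 = y0[n + seq_len(n)], ...)
  list(uncoupled = run(sub(character(0))),
       intra = run(sub("intra")),
       full = run(sub(c("intra", "inter"))))
}

#' Fixed-step fourth-order reference integrator
#'
#' Classical RK4 with a constant step, independent of the adaptive default
#' solver's machinery; used to verify solver accuracy. Slow by design.
#'
#' @param network An `io_network`.
#' @param duration Simulated time, ms.
#' @param dt Fixed step, ms.
#' @param dt_out Output sampling interval, ms (multiple of `dt`).
#' @param seed,jitter,v0,h0,i_ext,block_ca As in [simulate_network()].
#' @return A `sim_result`.
#' @export
integrate_rk4 <- function(network, duration, dt = 0.001, dt_out = 1,
                          seed = NULL, jitter = 1, v0 = NULL, h0 = NULL,
                          i_ext = NULL, block_ca = FALSE) {
  n <- nrow(network$neurons)
  y <- if (!is.null(v0)) {
    c(rep_len(v0, n),
      if (is.null(h0)) h_inf(network$kinetics, rep_len(v0, n))
      else rep_len(h0, n))
  } else initial_state(network, jitter = jitter, seed = seed)
  rhs <- build_network_rhs(network, block_ca = block_ca, i_ext = i_ext)
  f <- function(y) rhs(0, y, NULL)[[1]]
  stride <- round(dt_out / dt)
  stopifnot(abs(stride * dt - dt_out) < 1e-9)
  nsteps <- round(duration / dt)
  nout <- floor(nsteps / stride)
  V <- matrix(NA_real_, n, nout + 1)
  H <- matrix(NA_real_, n, nout + 1)
  V[, 1] <- y[seq_len(n)]; H[, 1] <- y[n + seq_len(n)]
  col <- 1L
  h2 <- dt / 2
  for (s in seq_len(nsteps)) {
    k1 <- f(y)
    k2 <- f(y + h2 * k1)
    k3 <- f(y + h2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (s %% stride == 0) {
      col <- col + 1L
      V[, col] <- y[seq_len(n)]; H[, col] <- y[n + seq_len(n)]
    }
  }
  if (any(!is.finite(V))) stop("non-finite state in RK4 integration")
  structure(list(time = seq(0, by = dt_out, length.out = nout + 1),
                 V = V, h = H, events = list(),
                 meta = list(solver = list(method = "rk4", dt = dt,
                                           dt_out = dt_out), seed = seed)),
            class = "sim_result")
}

# Wrap a single cell as a one-neuron network (shared plumbing for tests
# and the average-neuron predictor).
as_network <- function(params, kin = gating_kinetics()) {
  io_network(data.frame(id = 1L, cluster = 1L, g_l = params$g_l,
                        g_Ca = params$g_Ca, E_l = params$E_l,
                        E_Ca = params$E_Ca, Cm = params$Cm,
                        area = params$area),
             NULL, kinetics = kin)
}
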