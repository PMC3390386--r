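#' Construct a clustered gap-junction network
#'
#' The network container holds per-neuron conductance parameters, cluster
#' membership, and the gap-junction list with absolute junctional
#' conductances. Structural invariants (no self-junctions, at most one
#' junction per pair, positive conductances) are enforced at construction;
#' the physiological constraints (degree limits, coupling-coefficient
#' bounds) are checked by [validate_network()].
#'
#' @param neurons data.frame with columns `id`, `cluster`, `g_l`, `g_Ca`
#'   (mS/cm^2), `E_l`, `E_Ca` (mV), `Cm` (uF/cm^2), `area` (cm^2).
#' @param junctions data.frame with columns `a`, `b` (neuron ids), `g_gap`
#'   (absolute nS), `kind` (`"intra"` or `"inter"`); optional `cc_target`.
#' @param clusters data.frame with columns `id`, `center_g_l`,
#'   `center_g_Ca`, `size`; may be `NULL` for ad-hoc networks.
#' @param kinetics A [gating_kinetics()] object shared by all neurons.
#' @param meta Named list of provenance (seed, generator settings, ...).
#' @return An object of class `io_network`.
#' @export
io_network <- function(neurons, junctions, clusters = NULL,
                       kinetics = gating_kinetics(), meta = list()) {
  need <- c("id", "cluster", "g_l", "g_Ca", "E_l", "E_Ca", "Cm", "area")
  stopifnot(all(need %in% names(neurons)))
  if (is.null(junctions) || !nrow(junctions))
    junctions <- data.frame(a = integer(), b = integer(),
                            g_gap = numeric(), kind = character())
  stopifnot(all(c("a", "b", "g_gap", "kind") %in% names(junctions)))
  stopifnot(all(neurons$g_l >= 0), all(neurons$g_Ca >= 0),
            all(neurons$Cm > 0), all(neurons$area > 0),
            !anyDuplicated(neurons$id))
  if (nrow(junctions)) {
    stopifnot(all(junctions$g_gap > 0),
              all(junctions$a %in% neurons$id),
              all(junctions$b %in% neurons$id))
    if (any(junctions$a == junctions$b))
      stop("self-junctions are not allowed")
    key <- paste(pmin(junctions$a, junctions$b),
                 pmax(junctions$a, junctions$b))
    if (anyDuplicated(key))
      stop("duplicate junctions: ", paste(key[duplicated(key)], collapse = "; "))
  }
  structure(list(neurons = neurons, junctions = junctions,
                 clusters = clusters, kinetics = kinetics, meta = meta),
            class = "io_network")
}

#' @export
print.io_network <- function(x, ...) {
  cat(sprintf("io_network: %d neurons, %d clusters, %d junctions (%d intra, %d inter)\n",
              nrow(x$neurons),
              length(unique(x$neurons$cluster)),
              nrow(x$junctions),
              sum(x$junctions$kind == "intra"),
              sum(x$junctions$kind == "inter")))
  invisible(x)
}

#' Number of junctions attached to each neuron
#' @param network An `io_network`.
#' @return Named integer vector over neuron ids.
#' @export
neuron_degrees <- function(network) {
  ids <- network$neurons$id
  tab <- table(factor(c(network$junctions$a, network$junctions$b),
                      levels = ids))
  stats::setNames(as.integer(tab), ids)
}

#' Gap-junction current density
#'
#' Ohmic junctional current received by a cell from one peer, expressed as
#' a current density over the cell's membrane area:
#' `i = g_gap (V_peer - V_self) / area`, converted from nS*mV to uA/cm^2.
#' Antisymmetric under endpoint swap, so a junction's two contributions sum
#' to zero in absolute current at every instant.
#'
#' @param v_self,v_peer Membrane potentials, mV.
#' @param g_gap Junctional conductance, nS.
#' @param area Membrane area of the receiving cell, cm^2.
#' @return Current density, uA/cm^2.
#' @export
gap_current <- function(v_self, v_peer, g_gap, area = 1e-4) {
  stopifnot(all(g_gap > 0))
  g_gap * (v_peer - v_self) / area * NS_MV_TO_UA_PER_CM2
}

#' Steady-state coupling coefficient from resistances
#'
#' The voltage divider of paired recordings: with current injected in the
#' first neuron, the coupling coefficient seen at the second is
#' `CC = R_2 / (R_2 + R_c)`, where `R_2` is the second neuron's input
#' resistance and `R_c` the junctional resistance.
#'
#' @param r_peer Input resistance of the non-injected neuron, MOhm.
#' @param r_c Junctional (coupling) resistance, MOhm.
#' @return Dimensionless fraction in (0, 1).
#' @export
coupling_coefficient <- function(r_peer, r_c) {
  stopifnot(all(r_peer > 0), all(r_c > 0))
  r_peer / (r_peer + r_c)
}

# Dense conductance matrix (nS) of the passive skeleton: leak to ground on
# the diagonal plus the gap-junction Laplacian. Junctional coupling
# coefficients are defined on this skeleton (T-type conductance blocked).
passive_conductance_matrix <- function(network, g_gap = NULL) {
  nn <- network$neurons
  n <- nrow(nn)
  idx <- stats::setNames(seq_len(n), nn$id)
  L <- diag(density_to_ns(nn$g_l, nn$area), n)
  j <- network$junctions
  g <- g_gap %||% j$g_gap
  for (k in seq_len(nrow(j))) {
    a <- idx[[as.character(j$a[k])]]; b <- idx[[as.character(j$b[k])]]
    L[a, a] <- L[a, a] + g[k]; L[b, b] <- L[b, b] + g[k]
    L[a, b] <- L[a, b] - g[k]; L[b, a] <- L[b, a] - g[k]
  }
  L
}

#' Coupling coefficients of all junctions (resistor-network solution)
#'
#' Solves the passive resistor network (leak conductances to ground plus
#' gap-junction Laplacian) for the steady-state voltage ratios of every
#' junction in both directions. This is the steady state the step protocol
#' of [measure_cc()] converges to under T-type blockade, computed exactly;
#' the generator's calibration loop runs on it.
#'
#' @param network An `io_network`.
#' @return data.frame with one row per junction: `a`, `b`, `cc_ab`
#'   (injection in `a`, seen at `b`), `cc_ba`, `cc_max`.
#' @export
cc_linear <- function(network) {
  j <- network$junctions
  if (!nrow(j))
    return(data.frame(a = integer(), b = integer(), cc_ab = numeric(),
                      cc_ba = numeric(), cc_max = numeric()))
  M <- solve(passive_conductance_matrix(network))
  idx <- stats::setNames(seq_len(nrow(network$neurons)), network$neurons$id)
  a <- idx[as.character(j$a)]; b <- idx[as.character(j$b)]
  cc_ab <- M[cbind(b, a)] / M[cbind(a, a)]
  cc_ba <- M[cbind(a, b)] / M[cbind(b, b)]
  data.frame(a = j$a, b = j$b, cc_ab = cc_ab, cc_ba = cc_ba,
             cc_max = pmax(cc_ab, cc_ba))
}

#' Measure a junction's coupling coefficients by paired step experiments
#'
#' Runs the simulated analogue of a paired recording in the full network
#' context: two independent experiments, one injecting a small
#' hyperpolarizing step into each endpoint, with the steady-state voltage
#' deflection ratio giving the directional coupling coefficient. By default
#' the T-type conductance is blocked during the measurement
#' (oscillation-suppressing condition), which makes the steady state the
#' passive resistor-network solution of [cc_linear()].
#'
#' @param network An `io_network`.
#' @param pair Length-2 vector of neuron ids forming a junction.
#' @param step Step current density, uA/cm^2.
#' @param settle Pre-step settling time, ms.
#' @param step_dur Step duration, ms.
#' @param block_ca Block the T-type conductance during measurement.
#' @return List of class `cc_pair`: `cc_ab`, `cc_ba` (fractions), and
#'   `meta` (protocol settings).
#' @export
measure_cc <- function(network, pair, step = -0.5, settle = 300,
                       step_dur = 500, block_ca = TRUE) {
  j <- network$junctions
  hit <- (j$a == pair[1] & j$b == pair[2]) | (j$a == pair[2] & j$b == pair[1])
  if (!any(hit)) stop("pair is not junction-connected in this network")
  idx <- stats::setNames(seq_len(nrow(network$neurons)), network$neurons$id)
  one <- function(inj, peer) {
    i_inj <- idx[[as.character(inj)]]; i_peer <- idx[[as.character(peer)]]
    base <- simulate_network(network, duration = settle, dt_out = 1,
                             block_ca = block_ca, jitter = 0)
    iv <- numeric(nrow(network$neurons)); iv[i_inj] <- step
    st <- simulate_network(network, duration = step_dur, dt_out = 1,
                           block_ca = block_ca, jitter = 0, i_ext = iv,
                           v0 = base$V[, ncol(base$V)],
                           h0 = base$h[, ncol(base$h)])
    if (any(!is.finite(st$V)))
      stop("network unstable under CC measurement step")
    pre_w <- base$time >= settle - 100
    post_w <- st$time >= step_dur - 100
    dv_inj <- mean(st$V[i_inj, post_w]) - mean(base$V[i_inj, pre_w])
    dv_peer <- mean(st$V[i_peer, post_w]) - mean(base$V[i_peer, pre_w])
    dv_peer / dv_inj
  }
  structure(list(cc_ab = one(pair[1], pair[2]),
                 cc_ba = one(pair[2], pair[1]),
                 meta = list(step = step, settle = settle,
                             step_dur = step_dur, block_ca = block_ca)),
            class = "cc_pair")
}

# Sherman-Morrison update of M = L^-1 when one junction's conductance
# changes by delta along u = e_a - e_b.
sm_update <- function(M, a, b, delta) {
  m <- M[, a] - M[, b]
  q <- m[a] - m[b]
  M - (delta / (1 + delta * q)) * tcrossprod(m)
}

# Directional CCs of junction (a, b) as a function of replacing its
# conductance g0 by g, given M = inverse conductance matrix at g0.
cc_of_updated <- function(M, a, b, g0, g) {
  delta <- g - g0
  m <- M[, a] - M[, b]
  q <- m[a] - m[b]
  cfac <- delta / (1 + delta * q)
  vaa <- M[a, a] - cfac * m[a]^2
  vba <- M[b, a] - cfac * m[b] * m[a]
  vbb <- M[b, b] - cfac * m[b]^2
  vab <- M[a, b] - cfac * m[a] * m[b]
  c(ab = vba / vaa, ba = vab / vbb)
}

#' Calibrate one junction's conductance to a target coupling coefficient
#'
#' Root-finds the junctional conductance at which the larger of the two
#' directional coupling coefficients (measured in the full network context,
#' all other junctions fixed) equals the target. The larger direction is
#' used so the 20% physiological cap can never be exceeded by the hidden
#' direction of an asymmetric junction.
#'
#' @param network An `io_network`.
#' @param junction Row index into `network$junctions`.
#' @param target_cc Target coupling coefficient, a fraction in (0, 0.2].
#' @param tol Absolute tolerance on the achieved CC.
#' @param g_range Admissible conductance range, nS.
#' @return The calibrated conductance, nS.
#' @export
calibrate_gap_conductance <- function(network, junction, target_cc,
                                      tol = 1e-5, g_range = c(1e-4, 500)) {
  if (target_cc <= 0 || target_cc > 0.2)
    stop("target_cc must lie in (0, 0.2]")
  j <- network$junctions
  idx <- stats::setNames(seq_len(nrow(network$neurons)), network$neurons$id)
  a <- idx[[as.character(j$a[junction])]]
  b <- idx[[as.character(j$b[junction])]]
  M <- solve(passive_conductance_matrix(network))
  g0 <- j$g_gap[junction]
  f <- function(g) max(cc_of_updated(M, a, b, g0, g)) - target_cc
  if (f(g_range[1]) > 0 || f(g_range[2]) < 0)
    stop(sprintf("junction %d-%d: target CC %.3f unreachable within g_gap bounds",
                 j$a[junction], j$b[junction], target_cc))
  stats::uniroot(f, g_range, tol = tol * 1e-2)$root
}

# Jointly calibrate junction conductances to their cc_target values by
# Gauss-Seidel sweeps with Sherman-Morrison updates. Deterministic. With
# `subset`, only those junction rows are recalibrated (the others keep
# their conductances and are excluded from the convergence check).
#
# A junction whose endpoints are already coupled above its target through
# parallel paths cannot be made weak enough; it is clamped to the minimum
# conductance and its recorded target replaced by the achieved coupling
# (which by construction still respects the 20% cap), provided the
# parallel-path coupling itself is admissible.
calibrate_network <- function(network, tol = 1e-4, max_sweeps = 12,
                              g_range = c(1e-4, 500), subset = NULL) {
  j <- network$junctions
  stopifnot(!is.null(j$cc_target))
  rows <- subset %||% seq_len(nrow(j))
  idx <- stats::setNames(seq_len(nrow(network$neurons)), network$neurons$id)
  a <- idx[as.character(j$a)]; b <- idx[as.character(j$b)]
  g <- j$g_gap
  clamped <- integer(0)
  for (sweep in seq_len(max_sweeps)) {
    M <- solve(passive_conductance_matrix(network, g_gap = g))
    for (k in rows) {
      f <- function(gk) max(cc_of_updated(M, a[k], b[k], g[k], gk)) -
        network$junctions$cc_target[k]
      if (f(g_range[1]) > 0) {
        floor_cc <- max(cc_of_updated(M, a[k], b[k], g[k], g_range[1]))
        if (floor_cc > 0.20 + tol)
          stop(sprintf("junction %d-%d: parallel-path coupling %.3f exceeds the CC cap",
                       j$a[k], j$b[k], floor_cc))
        gk <- g_range[1]
        network$junctions$cc_target[k] <- floor_cc
        clamped <- union(clamped, k)
      } else if (f(g_range[2]) < 0) {
        stop(sprintf("junction %d-%d: target CC %.3f unreachable within g_gap bounds",
                     j$a[k], j$b[k], network$junctions$cc_target[k]))
      } else {
        gk <- stats::uniroot(f, g_range, tol = 1e-8)$root
      }
      M <- sm_update(M, a[k], b[k], gk - g[k])
      g[k] <- gk
    }
    network$junctions$g_gap <- g
    cc <- cc_linear(network)
    network$junctions$cc_target[clamped] <- cc$cc_max[clamped]
    if (max(abs(cc$cc_max[rows] - network$junctions$cc_target[rows])) <= tol)
      break
  }
  cc <- cc_linear(network)
  if (max(abs(cc$cc_max[rows] - network$junctions$cc_target[rows])) > tol)
    stop("coupling-coefficient calibration did not converge")
  network$junctions$cc_ab <- cc$cc_ab
  network$junctions$cc_ba <- cc$cc_ba
  if (length(clamped))
    network$meta$clamped_junctions <-
      union(network$meta$clamped_junctions, clamped)
  network
}

#' Conductance-weighted "average neuron"
#'
#' Collapses a set of electrically coupled neurons into the single
#' hypothetical cell carrying their weighted mean conductance densities.
#' Averaging is defined only when the cells share reversal potentials,
#' capacitance and area.
#'
#' @param neurons data.frame of neuron rows (as in `io_network$neurons`).
#' @param weights Nonnegative per-neuron weights; default equal.
#' @return A [neuron_params()] object.
#' @export
average_neuron <- function(neurons, weights = NULL) {
  w <- weights %||% rep(1, nrow(neurons))
  stopifnot(length(w) == nrow(neurons), all(w >= 0), sum(w) > 0)
  same <- function(col) length(unique(neurons[[col]])) == 1
  if (!all(vapply(c("E_l", "E_Ca", "Cm", "area"), same, logical(1))))
    stop("averaging undefined: heterogeneous E_l/E_Ca/Cm/area across neurons")
  neuron_params(g_l = sum(w * neurons$g_l) / sum(w),
                g_Ca = sum(w * neurons$g_Ca) / sum(w),
                E_l = neurons$E_l[1], E_Ca = neurons$E_Ca[1],
                Cm = neurons$Cm[1], area = neurons$area[1])
}

# Per-neuron coupling weights: 1 + (total attached junctional conductance,
# normalized by the network mean). Reduces to equal weights for homogeneous
# coupling; strengthening a cluster's afferents pulls the average toward it.
coupling_weights <- function(network) {
  ids <- network$neurons$id
  tot <- stats::setNames(numeric(length(ids)), ids)
  j <- network$junctions
  for (k in seq_len(nrow(j))) {
    tot[as.character(j$a[k])] <- tot[as.character(j$a[k])] + j$g_gap[k]
    tot[as.character(j$b[k])] <- tot[as.character(j$b[k])] + j$g_gap[k]
  }
  if (mean(tot) == 0) return(rep(1, length(ids)))
  1 + tot / mean(tot)
}

#' Predict the synchronized network frequency from the average neuron
#'
#' The rule of thumb for electrically coupled ensembles: the network
#' oscillates like the single hypothetical neuron carrying the (coupling-
#' weighted) average conductance densities of its members, and fails to
#' oscillate when that average falls in the quiescent region of the
#' conductance plane.
#'
#' @param network An `io_network`.
#' @param weighting `"coupling"` (default: weights grow with a neuron's
#'   total junctional conductance) or `"uniform"`.
#' @return List: `frequency` (Hz, `NA` when non-oscillatory), `regime`,
#'   `params` (the average [neuron_params()]).
#' @export
predict_average_neuron_frequency <- function(network,
                                             weighting = c("coupling",
                                                           "uniform")) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "coupling") coupling_weights(network)
       else rep(1, nrow(network$neurons))
  avg <- average_neuron(network$neurons, w)
  lab <- classify_regime(avg, network$kinetics)
  list(frequency = lab$frequency, regime = lab$regime, params = avg)
}

#' Validate the physiological constraints of a network
#'
#' Checks the architectural constraints: every neuron connected with
#' between 1 and 38 junctions, every measured coupling coefficient within
#' the 2-20% experimental bounds (with numerical slack), and, for
#' generator-produced networks, the exact intra-cluster degree. All
#' violations are collected and reported together.
#'
#' @param network An `io_network`.
#' @param cc_bounds Admissible coupling-coefficient range.
#' @param slack Numerical slack on the CC bounds.
#' @return Invisibly `TRUE`; stops with the list of violations otherwise.
#' @export
validate_network <- function(network, cc_bounds = c(0.02, 0.20),
                             slack = 1e-3) {
  bad <- character(0)
  deg <- neuron_degrees(network)
  if (any(deg < 1))
    bad <- c(bad, paste("unconnected neurons:",
                        paste(names(deg)[deg < 1], collapse = ",")))
  if (any(deg > 38))
    bad <- c(bad, paste("degree > 38 for neurons:",
                        paste(names(deg)[deg > 38], collapse = ",")))
  cc <- cc_linear(network)
  out_lo <- cc$cc_max < cc_bounds[1] - slack
  out_hi <- cc$cc_max > cc_bounds[2] + slack
  if (any(out_lo | out_hi))
    bad <- c(bad, sprintf("CC outside [%g, %g] for %d junction(s)",
                          cc_bounds[1], cc_bounds[2], sum(out_lo | out_hi)))
  intra_deg <- network$meta$intra_degree
  if (!is.null(intra_deg)) {
    ji <- network$junctions[network$junctions$kind == "intra", ]
    for (cl in unique(network$neurons$cluster)) {
      ids <- network$neurons$id[network$neurons$cluster == cl]
      d <- table(factor(c(ji$a[ji$a %in% ids | ji$b %in% ids],
                          ji$b[ji$a %in% ids | ji$b %in% ids]),
                        levels = ids))
      want <- min(intra_deg, length(ids) - 1)
      if (any(d != want))
        bad <- c(bad, sprintf("cluster %s: intra-cluster degree != %d", cl,
                              want))
    }
  }
  if (length(bad))
    stop("network constraint violations:\n  ",
         paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

#' Serialize a network to JSON
#'
#' Writes the complete network (neurons, clusters, junctions, kinetics
#' constants and provenance metadata) as a single JSON document. The
#' round trip through [read_network()] is lossless.
#'
#' @param network An `io_network`.
#' @param path Output file path.
#' @export
write_network <- function(network, path) {
  doc <- list(neurons = network$neurons, junctions = network$junctions,
              clusters = network$clusters,
              kinetics = unclass(network$kinetics),
              meta = network$meta)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  kin <- doc$kinetics
  kin$version <- kin$version %||% NA
  class(kin) <- "gating_kinetics"
  clusters <- if (is.null(doc$clusters) || !length(doc$clusters)) NULL
              else as.data.frame(doc$clusters)
  io_network(as.data.frame(doc$neurons), as.data.frame(doc$junctions),
             clusters, kin, as.list(doc$meta))
}
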