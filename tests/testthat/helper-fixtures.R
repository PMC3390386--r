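# Shared fixtures. Heavy objects (boundary curve, generated networks,
# reference simulations) are built once per session and cached.

fixtures <- new.env(parent = emptyenv())

test_kin <- function() {
  if (is.null(fixtures$kin)) fixtures$kin <- gating_kinetics()
  fixtures$kin
}

# an oscillatory single-cell parameter point (well inside the region)
osc_params <- function() neuron_params(g_l = 0.25, g_Ca = 0.7)

# a quiescent point (below the onset boundary)
quiet_params <- function() neuron_params(g_l = 0.35, g_Ca = 0.3)

# two identical passive neurons joined by one junction
passive_pair <- function(g_l = 0.25, g_gap = 2) {
  nn <- data.frame(id = 1:2, cluster = 1L, g_l = g_l, g_Ca = 0,
                   E_l = -63, E_Ca = 120, Cm = 1, area = 1e-4)
  jj <- data.frame(a = 1L, b = 2L, g_gap = g_gap, kind = "intra")
  io_network(nn, jj, kinetics = test_kin())
}

# passive three-cell chain A-B-C
passive_chain <- function(g_l = c(0.2, 0.25, 0.3), g_gap = c(2, 3)) {
  nn <- data.frame(id = 1:3, cluster = 1L, g_l = g_l, g_Ca = 0,
                   E_l = -63, E_Ca = 120, Cm = 1, area = 1e-4)
  jj <- data.frame(a = c(1L, 2L), b = c(2L, 3L), g_gap = g_gap,
                   kind = "intra")
  io_network(nn, jj, kinetics = test_kin())
}

# calibrated two-cell network with active conductances
active_pair <- function(g_l, g_Ca, cc_target = 0.18, kin = test_kin()) {
  nn <- data.frame(id = 1:2, cluster = 1L, g_l = g_l, g_Ca = g_Ca,
                   E_l = -63, E_Ca = kin$E_Ca, Cm = 1, area = 1e-4)
  jj <- data.frame(a = 1L, b = 2L, g_gap = 2, kind = "intra",
                   cc_target = cc_target)
  olivenet:::calibrate_network(io_network(nn, jj, kinetics = kin))
}

# small generated network (2 clusters x 8), cached
small_net <- function() {
  if (is.null(fixtures$small_net))
    fixtures$small_net <- generate_network(
      generator_spec(n_clusters = 2, cluster_size = 8, seed = 7), test_kin())
  fixtures$small_net
}

# reference-style 4 x 12 network and a 5 s simulation of it, cached
ref_net <- function() {
  if (is.null(fixtures$ref_net))
    fixtures$ref_net <- generate_network(generator_spec(seed = 11),
                                         test_kin())
  fixtures$ref_net
}

ref_result <- function() {
  if (is.null(fixtures$ref_result))
    fixtures$ref_result <- simulate_network(ref_net(), 5000, seed = 11)
  fixtures$ref_result
}

# synthetic sinusoidal voltage trace (mV), fs in Hz, f in Hz, t in s
sine_trace <- function(f, duration_s = 5, fs = 1000, amplitude = 5,
                       phase = 0, baseline = -60) {
  t <- seq(0, duration_s, by = 1 / fs)
  baseline + amplitude * sin(2 * pi * f * t + phase)
}
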