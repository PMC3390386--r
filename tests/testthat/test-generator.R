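test_that("network generation is bit-reproducible for a fixed seed", {
  sp <- generator_spec(n_clusters = 2, cluster_size = 8, seed = 7)
  a <- generate_network(sp, test_kin())
  b <- generate_network(sp, test_kin())
  expect_identical(a$neurons, b$neurons)
  expect_identical(a$junctions, b$junctions)
  expect_identical(a$clusters, b$clusters)
  sp2 <- generator_spec(n_clusters = 2, cluster_size = 8, seed = 8)
  c_ <- generate_network(sp2, test_kin())
  expect_false(identical(a$junctions$g_gap, c_$junctions$g_gap))
})

test_that("generator specs enforce the anatomical bounds", {
  expect_error(generator_spec(cluster_size = 7, seed = 1), "cluster_size")
  expect_error(generator_spec(cluster_size = 17, seed = 1), "cluster_size")
  expect_error(generator_spec(seed = 1, cc_inter_range = c(0.02, 0.5)))
  expect_error(generator_spec())  # seed mandatory
})

test_that("cluster conductance sampling is a truncated normal", {
  centre <- c(0.25, 0.7)
  draws <- lapply(1:100, function(i)
    sample_cluster_conductances(centre, 12, seed = i))
  all_g <- do.call(rbind, draws)
  expect_true(all(all_g$g_l >= 0.15 & all_g$g_l <= 0.40))
  expect_true(all(all_g$g_Ca >= 0.20 & all_g$g_Ca <= 1.40))
  # sample spread close to the nominal sigmas (3 standard errors)
  se_l <- 0.005 / sqrt(2 * (nrow(all_g) - 1))
  se_ca <- 0.01 / sqrt(2 * (nrow(all_g) - 1))
  expect_lt(abs(sd(all_g$g_l) - 0.005), 3 * se_l)
  expect_lt(abs(sd(all_g$g_Ca) - 0.01), 3 * se_ca)
  # a center several spreads outside the box cannot be sampled
  expect_error(sample_cluster_conductances(c(0.12, 0.7), 12, seed = 1,
                                           spread = c(0.005, 0.01)),
               "box edge")
})

test_that("intra-cluster graphs are regular, connected and seeded", {
  e <- build_intra_connections(101:112, degree = 4, seed = 3)
  deg <- table(c(e$a, e$b))
  expect_true(all(deg == 4))
  expect_length(deg, 12)
  g <- igraph::graph_from_edgelist(cbind(match(e$a, 101:112),
                                         match(e$b, 101:112)),
                                   directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_identical(e, build_intra_connections(101:112, degree = 4, seed = 3))
  # size 5 at degree 4 forces the complete graph
  k5 <- build_intra_connections(1:5, degree = 4, seed = 1)
  expect_equal(nrow(k5), 10)
  expect_error(build_intra_connections(1:4, degree = 4, seed = 1),
               "infeasible")
})

test_that("inter-cluster pairing follows the 80% one-per-neuron rule", {
  e <- build_inter_connections(1:12, 13:24, fraction = 0.8, seed = 5)
  expect_equal(nrow(e), 9)             # floor(0.8 * 12)
  expect_false(anyDuplicated(e$a) > 0)
  expect_false(anyDuplicated(e$b) > 0)
  expect_true(all(e$a %in% 1:12) && all(e$b %in% 13:24))
  expect_identical(e, build_inter_connections(1:12, 13:24, 0.8, seed = 5))
  expect_equal(nrow(build_inter_connections(1:12, 13:24, 0, seed = 1)), 0)
  expect_error(build_inter_connections(1:12, 13:15, 0.8, seed = 1),
               "not enough target")
})

test_that("boundary-placed centers straddle the oscillation onset curve", {
  kin <- test_kin()
  sp <- generator_spec(seed = 42)
  cen <- sample_cluster_centers(sp, kin, seed = 42)
  expect_equal(nrow(cen), 4)
  bd <- oscillation_boundary(kin)
  on_curve <- approx(bd$g_l, bd$g_Ca, xout = cen[, "g_l"], rule = 2)$y
  off <- cen[, "g_Ca"] - on_curve
  expect_true(all(off >= -0.25 - 1e-9 & off <= 0.35 + 1e-9))
  expect_true(any(off > 0) && any(off < 0))  # stratified halves
  expect_identical(cen, sample_cluster_centers(sp, kin, seed = 42))
})

test_that("generated networks satisfy every architectural constraint", {
  kin <- test_kin()
  seeds <- 1:10
  for (s in seeds) {
    sp <- generator_spec(n_clusters = sample(2:4, 1), cluster_size = 8,
                         inter_scheme = sample(c("reference", "random"), 1),
                         seed = s)
    net <- generate_network(sp, kin)
    expect_silent(validate_network(net))
    deg <- neuron_degrees(net)
    expect_true(all(deg >= 1 & deg <= 38))
    cc <- cc_linear(net)
    expect_true(all(cc$cc_max >= 0.02 - 1e-3 & cc$cc_max <= 0.20 + 1e-3))
    expect_lt(max(abs(cc$cc_max - net$junctions$cc_target)), 1e-4)
  }
})

test_that("roughly half the members of reference networks self-oscillate", {
  kin <- test_kin()
  fracs <- vapply(c(11, 22, 33), function(s) {
    net <- generate_network(generator_spec(seed = s), kin)
    mean(olivenet:::classify_cells(net$neurons$g_l, net$neurons$g_Ca,
                                   kin)$oscillating)
  }, numeric(1))
  expect_true(all(fracs >= 0.3 & fracs <= 0.7))
})

test_that("sevenfold modulation keeps factors and CCs within bounds", {
  net <- small_net()
  sch <- modulation_schedule(net, "sevenfold", seed = 9)
  expect_length(sch, 1)
  f <- sch[[1]]$factors
  expect_true(all(f >= 1 / 7 - 1e-9 & f <= 7 + 1e-9))
  net2 <- net
  net2$junctions$g_gap[sch[[1]]$junction] <-
    net2$junctions$g_gap[sch[[1]]$junction] * f
  cc0 <- cc_linear(net)$cc_max
  cc <- cc_linear(net2)$cc_max
  expect_true(all(cc <= pmax(0.20, cc0) + 1e-5))
})

test_that("CC-ratio modulation changes coupling by 20% to 400%", {
  net <- small_net()
  sch <- modulation_schedule(net, "cc_ratio", seed = 9)
  idx <- sch[[1]]$junction
  net2 <- net
  net2$junctions$g_gap[idx] <- net2$junctions$g_gap[idx] * sch[[1]]$factors
  pre <- cc_linear(net)$cc_max[idx]
  post <- cc_linear(net2)$cc_max[idx]
  ratio <- post / pre
  expect_true(all(ratio >= 0.2 - 1e-6 & ratio <= 4 + 1e-6))
  expect_true(all(post <= 0.20 + 1e-5))
})

test_that("the identity rule produces an empty schedule", {
  expect_identical(modulation_schedule(small_net(), "identity"), list())
})
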