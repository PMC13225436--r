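ring_adj <- function(n) igraph::as_adjacency_matrix(igraph::make_ring(n))

test_that("degenerate configurations freeze or fire deterministically", {
  adj <- ring_adj(8)
  # nothing disturbed and all escape rates zero: absorbing
  st <- rep(1L, 8); st[3] <- 3L; st[6] <- 0L
  set.seed(1)
  expect_identical(quenched_step(st, adj, raw_params(beta = 0.7)), st)

  # certain transmission: every neighbor of the single disturbed node flips
  st2 <- rep(1L, 8); st2[1] <- 2L
  nxt <- quenched_step(st2, adj, raw_params(beta = 1 - 1e-12))
  expect_equal(which(nxt == 2L), c(1L, 2L, 8L))

  # certain recovery / memory loss chain
  st3 <- c(2L, 3L, rep(1L, 6))
  nxt3 <- quenched_step(st3, adj, raw_params(sigma = 1 - 1e-12, delta = 1 - 1e-12))
  expect_equal(nxt3[1], 3L)
  expect_equal(nxt3[2], 1L)
})

test_that("multi-neighbor exposure follows 1 - (1-beta)^m", {
  # center of a 4-star with 2 disturbed leaves: infection probability 0.75
  g <- igraph::make_star(5, mode = "undirected")
  adj <- igraph::as_adjacency_matrix(g)
  st <- c(1L, 2L, 2L, 1L, 1L)
  set.seed(42)
  hits <- sum(replicate(4000, quenched_step(st, adj, raw_params(beta = 0.5))[1] == 2L))
  p_hat <- hits / 4000
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / 4000) + 0.005)
})

test_that("states always partition the node set", {
  g <- generate_configuration_network(inverse_degree_dist(), 120, seed = 2)
  p <- sirs_params(0.05, 0.05, 0.05, 0.25, 0.25, 0.3)
  run <- quenched_run(g, p, steps = 200, burn_in = 100, replicates = 1, seed = 5)
  sums <- with(run$densities, S + I + R + E)
  expect_equal(sums, rep(1, nrow(run$densities)), tolerance = 1e-12)
})

test_that("without transmission the disturbed pool drains to zero", {
  g <- igraph::make_ring(50)
  run <- quenched_run(g, raw_params(b = 0.1, mu = 0.1, gamma = 0.1,
                                    sigma = 0.5, delta = 0.5, beta = 0),
                      steps = 400, burn_in = 300, replicates = 2, seed = 9)
  expect_equal(run$I_inf, 0)
})

test_that("runs are bit-reproducible under a fixed seed", {
  g <- generate_configuration_network(inverse_degree_dist(), 100, seed = 4)
  p <- sirs_params(0.05, 0.05, 0.05, 0.25, 0.25, 0.3)
  r1 <- quenched_run(g, p, steps = 150, burn_in = 50, replicates = 2, seed = 21)
  r2 <- quenched_run(g, p, steps = 150, burn_in = 50, replicates = 2, seed = 21)
  expect_identical(r1$densities, r2$densities)
  r3 <- quenched_run(g, p, steps = 150, burn_in = 50, replicates = 2, seed = 22)
  expect_false(identical(r1$densities, r3$densities))
})

test_that("with no losses or returns the occupied set cannot grow", {
  g <- igraph::make_ring(40)
  p <- raw_params(b = 0, mu = 0.2, gamma = 0.1, sigma = 0.5, delta = 0, beta = 0)
  run <- quenched_run(g, p, steps = 100, burn_in = 50, replicates = 1, seed = 2)
  occupied <- 1 - run$densities$E
  expect_true(all(diff(occupied) <= 1e-12))
})

test_that("stationary density on a large random graph tracks the mean-field aggregate", {
  # All six rates scaled by 0.1: the reproduction number and the equilibrium
  # fractions are invariant under a uniform time rescaling, while the per-step
  # chain becomes a faithful discretization of the continuous flow. Residual
  # disagreement is the annealed-vs-quenched (pair correlation) gap; 20%
  # relative tolerance per the documented cross-check design.
  d <- inverse_degree_dist()
  g <- generate_configuration_network(d, 1200, seed = 42)
  dn <- degree_distribution_net(g)
  eq <- endemic_equilibrium(sirs_params(0.1, 0.1, 0.1, 0.5, 0.5, 0.8), dn)
  sc <- 0.1
  p <- sirs_params(0.1 * sc, 0.1 * sc, 0.1 * sc, 0.5 * sc, 0.5 * sc, 0.8 * sc)
  run <- quenched_run(g, p, steps = 3000, burn_in = 1500, replicates = 2, seed = 7)
  expect_lt(abs(run$I_inf - eq$I) / eq$I, 0.20)
})

test_that("the bifurcation scan separates sub- and supercritical regimes", {
  d <- inverse_degree_dist()
  g <- generate_configuration_network(d, 400, seed = 11)
  sc <- 0.5
  p <- sirs_params(0.1 * sc, 0.1 * sc, 0.1 * sc, 0.5 * sc, 0.5 * sc, 0.5)
  grid <- c(0.02, 0.05, 0.30, 0.40)
  scan <- bifurcation_scan(g, p, grid, steps = 1500, burn_in = 750,
                           replicates = 2, seed = 3)
  tab <- scan$table
  # deep subcritical tail is extinct; supercritical densities are positive
  # and increase with beta
  expect_lte(tab$I_inf[1], scan$extinction_tol)
  expect_gt(tab$I_inf[3], scan$extinction_tol)
  expect_gt(tab$I_inf[4], tab$I_inf[3])
  expect_true(scan$critical_beta %in% grid)

  # a grid that never leaves the subcritical regime warns and returns NA
  expect_warning(
    low <- bifurcation_scan(g, p, c(0.01, 0.02), steps = 300, burn_in = 150,
                            replicates = 1, seed = 3),
    "never exceeded")
  expect_true(is.na(low$critical_beta))
})

test_that("the mean-field stationary branch crosses zero at the analytic threshold", {
  # annealed oracle for the scan: on a grid straddling beta_c the endemic
  # aggregate is zero below and positive above, within one grid step
  p <- sirs_params(0.1, 0.1, 0.1, 0.5, 0.5, 0.5)
  d <- inverse_degree_dist()
  bc <- critical_beta(p, d)
  grid <- seq(0.02, 0.20, by = 0.02)
  I_star <- vapply(grid, function(b) {
    pb <- p; pb$beta <- b
    if (basic_reproduction_number(pb, d) <= 1) 0 else endemic_equilibrium(pb, d)$I
  }, numeric(1))
  first_pos <- grid[min(which(I_star > 0))]
  expect_lte(abs(first_pos - bc), 0.02 + 1e-12)
  expect_true(all(diff(I_star) >= 0))
})
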