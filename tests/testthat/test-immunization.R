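test_that("uniform protection scales the reproduction number linearly", {
  p <- sirs_params(0.1, 0.1, 0.1, 0.5, 0.5, 0.8)
  om <- degree_moments(5.36, 62.66)
  rho <- basic_reproduction_number(p, om)
  expect_equal(uniform_rho(p, om, 0.2), 0.8 * rho, tolerance = 1e-12)
  expect_equal(uniform_rho(p, om, 0.2), 5.344, tolerance = 1e-3)
  expect_error(uniform_rho(p, om, 0), "phi")
  expect_error(uniform_rho(p, om, 1), "phi")
  set.seed(3)
  for (phi in runif(10, 0.01, 0.99))
    expect_lt(uniform_rho(p, om, phi), rho)
})

test_that("the top-down schedule spends the budget exactly", {
  d <- degree_dist(c(0.8, 0, 0, 0.2))
  s <- targeted_schedule(d, 0.3)
  expect_equal(s$kappa, 1)
  expect_equal(s$c, 0.125)
  expect_equal(s$phi_k, c(0.125, 1, 1, 1))
  expect_equal(sum(s$phi_k * d$p), 0.3, tolerance = 1e-12)

  # budget equal to the top-class mass: protect exactly that class
  s2 <- targeted_schedule(d, 0.2)
  expect_equal(s2$kappa, 4)
  expect_equal(s2$c, 1)

  # recomputing phi_bar from any returned schedule reproduces the target
  set.seed(8)
  for (i in 1:20) {
    dd <- rand_dist()
    tgt <- runif(1, 0.02, 0.9)
    ss <- targeted_schedule(dd, tgt)
    expect_equal(sum(ss$phi_k * dd$p), tgt, tolerance = 1e-12)
    expect_true(ss$c > 0 && ss$c <= 1)
    # all-or-nothing except at the boundary class
    expect_true(all(ss$phi_k[-ss$kappa] %in% c(0, 1)))
  }
  expect_error(targeted_schedule(d, 1), "phi_bar")
})

test_that("targeted protection dominates uniform at equal budget", {
  p <- sirs_params(0.1, 0.1, 0.1, 0.5, 0.5, 0.8)
  d <- inverse_degree_dist()

  # constant profile reduces to the uniform formula with zero covariance
  s_const <- uniform_scheme(0.3, d)
  r2c <- targeted_rho(p, d, s_const)
  expect_equal(as.numeric(r2c), uniform_rho(p, d, 0.3), tolerance = 1e-12)
  expect_equal(attr(r2c, "covariance"), 0, tolerance = 1e-12)

  # full protection extinguishes transmission
  s_all <- uniform_scheme(1 - 1e-12, d)
  expect_lt(as.numeric(targeted_rho(p, d, s_all)), 1e-9)

  # top-down beats uniform, with non-negative covariance
  set.seed(12)
  for (i in 1:50) {
    dd <- rand_dist()
    pp <- rand_params()
    tgt <- runif(1, 0.05, 0.8)
    ss <- targeted_schedule(dd, tgt)
    r2 <- targeted_rho(pp, dd, ss)
    expect_gte(attr(r2, "covariance"), -1e-12)
    expect_lte(as.numeric(r2), uniform_rho(pp, dd, tgt) + 1e-12)
  }
})

test_that("active protection shortens the disturbed period and lowers rho", {
  p <- sirs_params(0.1, 0.1, 0.1, 0.5, 0.5, 0.8)
  d <- inverse_degree_dist()
  rho <- basic_reproduction_number(p, d)
  s <- active_scheme(d, 0.2)
  expect_gt(s$phi_bar_k, 0)
  r3 <- active_rho(p, d, s)
  expect_lt(r3, rho)
  expect_equal(r3, rho * 0.7 / (0.7 + s$phi_bar_k), tolerance = 1e-12)

  # vanishing budget: all strategies approach the unprotected rho
  tiny <- 1e-4
  expect_equal(uniform_rho(p, d, tiny), rho, tolerance = 1e-3)
  expect_equal(as.numeric(targeted_rho(p, d, targeted_schedule(d, tiny))), rho,
               tolerance = 1e-2)
  expect_equal(active_rho(p, d, active_scheme(d, tiny)), rho, tolerance = 1e-2)
})

test_that("uniform immunized dynamics equal the substitution oracle", {
  p <- sirs_params(0.1, 0.1, 0.1, 0.5, 0.5, 0.8)
  d <- rand_dist(5)
  phi <- 0.35
  times <- seq(0, 150, by = 1)
  tr1 <- simulate_immunized(uniform_scheme(phi, d), p, d, t_end = 150,
                            times = times, reltol = 1e-11, abstol = 1e-13)
  p_sub <- sirs_params(p$b, p$mu, p$gamma, p$sigma, p$delta, p$beta * (1 - phi))
  tr2 <- simulate_sirs(p_sub, d, t_end = 150, times = times,
                       reltol = 1e-11, abstol = 1e-13)
  expect_lt(max(abs(tr1$I - tr2$I)), 1e-10)
  expect_lt(max(abs(tr1$S - tr2$S)), 1e-10)
})

test_that("near-total uniform protection extinguishes the disturbance", {
  p <- sirs_params(0.1, 0.1, 0.1, 0.5, 0.5, 0.8)
  d <- inverse_degree_dist()
  tr <- simulate_immunized(uniform_scheme(0.999, d), p, d, t_end = 500)
  expect_lt(tr$aggregates$I[length(tr$times)], 1e-6)
})

test_that("immunized endemic states are fixed points of the protected dynamics", {
  p <- sirs_params(0.1, 0.1, 0.1, 0.5, 0.5, 0.8)
  d <- inverse_degree_dist()
  for (s in list(uniform_scheme(0.2, d), targeted_schedule(d, 0.2),
                 active_scheme(d, 0.2))) {
    eq <- endemic_equilibrium(p, d, s)
    st <- sirs_state(eq$S_inf, eq$I_inf, eq$R_inf)
    expect_lt(max(abs(unlist(sirs_rhs(st, p, d, s)))), 1e-8)
    tr <- simulate_immunized(s, p, d, t_end = 2000)
    expect_lt(max(abs(tr$I[nrow(tr$I), ] - eq$I_inf)), 1e-6)
  }
})

test_that("a large enough budget protects every strategy below threshold", {
  p <- sirs_params(0.1, 0.1, 0.1, 0.5, 0.5, 0.8)
  d <- degree_dist(c(0.5, 0.3, 0.2))  # mild heterogeneity: rho just above 1
  expect_gt(basic_reproduction_number(p, d), 1)
  cmp <- compare_strategies(p, d, 0.9, check_ordering = FALSE)
  expect_true(all(cmp$I_star[c("uniform", "targeted", "active")] == 0))
})

test_that("the strategy report is internally consistent at the reference budget", {
  p <- sirs_params(0.1, 0.1, 0.1, 0.5, 0.5, 0.8)
  d <- inverse_degree_dist()
  cmp <- suppressWarnings(compare_strategies(p, d, 0.2))
  expect_equal(cmp$rho, basic_reproduction_number(p, d))
  expect_equal(cmp$rho1, uniform_rho(p, d, 0.2), tolerance = 1e-12)
  expect_equal(cmp$rho2, as.numeric(targeted_rho(p, d, cmp$schemes$targeted)),
               tolerance = 1e-12)
  expect_equal(cmp$rho3, active_rho(p, d, cmp$schemes$active), tolerance = 1e-12)
  # every protection lowers both the threshold and the endemic burden
  expect_true(all(c(cmp$rho1, cmp$rho2, cmp$rho3) < cmp$rho))
  expect_true(all(cmp$I_star[c("uniform", "targeted", "active")] <=
                    cmp$I_star["none"] + 1e-12))
  # uniform is never better than either informed strategy
  expect_lte(cmp$rho2, cmp$rho1 + 1e-12)
  expect_lte(cmp$rho3, cmp$rho1 + 1e-12)
  expect_lte(cmp$I_star[["targeted"]], cmp$I_star[["uniform"]] + 1e-12)
  expect_lte(cmp$I_star[["active"]], cmp$I_star[["uniform"]] + 1e-12)
})
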