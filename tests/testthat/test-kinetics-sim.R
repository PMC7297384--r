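test_that("closed-form kinetics agree with the numerical integrator", {
  g <- simulation_grid(dose_grid_log(7, 1e-2, 1e4),
                       time_grid_log(25, 1e-3, 1e3))
  p_nc <- nc_params(1.3, 0.7, 0.2)
  s1 <- suppressWarnings(simulate_ode(p_nc, g))
  s2 <- suppressWarnings(simulate_ode(p_nc, g, method = "lsoda"))
  expect_lt(max(abs(s1$theta - s2$theta)), 1e-6)
  p_ib <- ib_params(2, 0.3, 0.5, 1.1)
  s3 <- suppressWarnings(simulate_ode(p_ib, g))
  s4 <- suppressWarnings(simulate_ode(p_ib, g, method = "lsoda"))
  expect_lt(max(abs(s3$theta - s4$theta)), 1e-6)
})

test_that("deterministic trajectories start empty and reach equilibrium", {
  g <- simulation_grid(dose_grid_log(10, 1e-2, 1e4),
                       c(0, 10^seq(-3, 3, 0.5)))
  p <- nc_params(1, 1, 0.5)
  s <- simulate_ode(p, g)
  expect_equal(s$theta[, 1], rep(0, 10))
  # long-time limit matches the equilibrium expression at every dose
  expect_equal(s$theta[, ncol(s$theta)], theta_eq(p, g$doses),
               tolerance = 1e-6)
  # NC at L = 1, omega = 0.5 equilibrates at 3/7
  expect_equal(s$theta[which.min(abs(g$doses - 1)), ncol(s$theta)],
               0.42857, tolerance = 1e-4)
  # monotone approach under a step input (no depletion)
  expect_true(all(apply(s$theta, 1, function(x) all(diff(x) >= -1e-9))))
  q <- ib_params(0.8, 2, 1.5, 0.2)
  s2 <- suppressWarnings(simulate_ode(q, g))
  expect_equal(s2$theta[, ncol(s2$theta)], theta_eq(q, g$doses),
               tolerance = 1e-6)
})

test_that("identical independent sites relax with the single-site rate", {
  # theta(t) = 0.5 (1 - exp(-(kL + l) t)) summed over two identical sites
  tt <- c(0, 0.1, 0.5, 1, 2)
  g <- simulation_grid(c(0.5, 1), tt)
  s <- suppressWarnings(simulate_ode(ib_params(1, 1, 1, 1), g))
  expect_equal(s$theta[2, ], 0.5 * (1 - exp(-2 * tt)), tolerance = 1e-12)
})

test_that("receptor conservation holds along the full state trajectory", {
  st <- ode_states(nc_params(2, 0.5, 0.1), dose = 3, times = 10^seq(-2, 2))
  expect_true(all(rowSums(st) <= 1 + 1e-8))
  expect_true(all(st >= -1e-8))
  st2 <- ode_states(ib_params(1, 3, 0.2, 0.7), dose = 0.5,
                    times = 10^seq(-2, 2))
  expect_true(all(rowSums(st2) <= 1 + 1e-8))
})

test_that("stochastic simulation is seeded, bounded and single-receptor-quantised", {
  p <- nc_params(1, 1, 0.5)
  g1 <- simulation_grid(c(0.5, 1, 2), c(0, 0.5, 1, 5, 1000), R0 = 1)
  s <- simulate_gillespie(p, g1, seed = 3)
  # one receptor: occupancy can only be 0, 1/2 or 1
  expect_true(all(s$theta %in% c(0, 0.5, 1)))
  expect_identical(s$theta, simulate_gillespie(p, g1, seed = 3)$theta)
  expect_false(identical(s$theta, simulate_gillespie(p, g1, seed = 4)$theta))
  expect_error(simulate_gillespie(p, simulation_grid(1, c(0, 1)), seed = 1),
               "finite")
})

test_that("stochastic equilibrium mean sits inside the binomial band", {
  p <- nc_params(1, 1, 0.5)
  g <- simulation_grid(1, c(0, 1000), R0 = 1000)
  m <- vapply(1:100, function(i) {
    simulate_gillespie(p, g, seed = 5000 + i)$theta[1, 2]
  }, numeric(1))
  eq <- theta_eq_nc(1, 1, 0.5)
  # mean of 100 runs of 2000 Bernoulli sites
  band <- 3 * sqrt(eq * (1 - eq) / 1000) / sqrt(100)
  expect_lt(abs(mean(m) - eq), band * 2)
})

test_that("exact interval sampler matches the literal direct-method SSA", {
  p <- nc_params(1, 1, 0.5)
  g <- simulation_grid(1, c(0, 0.3, 1, 3), R0 = 50)
  nrep <- 200
  me <- rowMeans(vapply(1:nrep, function(i) {
    simulate_gillespie(p, g, seed = 100 + i, method = "exact")$theta[1, ]
  }, numeric(4)))
  md <- rowMeans(vapply(1:nrep, function(i) {
    simulate_gillespie(p, g, seed = 7000 + i, method = "direct")$theta[1, ]
  }, numeric(4)))
  ode <- suppressWarnings(simulate_ode(p, simulation_grid(1, c(0, 0.3, 1, 3))))
  # both stochastic means converge on the mass-action solution
  se <- sqrt(0.25 / (100 * nrep))  # generous per-time bound
  expect_true(all(abs(me - ode$theta[1, ]) < 5 * se))
  expect_true(all(abs(md - ode$theta[1, ]) < 5 * se))
})
# (the equilibrium warning for the single-dose grids above is expected)

test_that("replicate averaging converges towards the deterministic surface", {
  p <- ib_params(1, 0.5, 1, 2)
  g <- simulation_grid(c(0.5, 2, 8), c(0, 0.5, 2, 50), R0 = 100)
  s <- simulate_gillespie(p, g, seed = 9, replicates = 200)
  det <- suppressWarnings(simulate_ode(p, simulation_grid(g$doses, g$times)))
  expect_lt(max(abs(s$theta - det$theta)), 0.02)
})

test_that("moving-average smoothing matches its direct definition", {
  y <- c(0, 1, 4, 9, 16)
  expect_identical(smooth_dose_curve(y, 1), y)
  expect_equal(smooth_dose_curve(rep(0.3, 7), 5), rep(0.3, 7))
  # shrinking centred window at the boundaries
  expect_equal(smooth_dose_curve(y, 3), c(0, 5 / 3, 14 / 3, 29 / 3, 16))
  expect_error(smooth_dose_curve(y, 4))
  expect_error(smooth_dose_curve(y, 7))
  # noiseless smooth curve is barely perturbed on a fine grid
  L <- dose_grid_log(1000, 1e-3, 1e5)
  th <- theta_eq_nc(L, 1, 0.5)
  expect_lt(max(abs(smooth_dose_curve(th, 5) - th)), 1e-3)
})

test_that("grid and dataset constructors validate their invariants", {
  expect_error(simulation_grid(c(1, 0.5), c(0, 1)), "increasing")
  expect_error(simulation_grid(c(-1, 1), c(0, 1)), "positive")
  expect_error(simulation_grid(c(1, 2), c(1, 0.5)), "increasing")
  expect_error(simulation_grid(c(1, 2), c(0, 1), R0 = 2.5))
  expect_error(timecourse_dataset(matrix(1.5, 2, 2), c(1, 2), c(1, 2)))
  expect_error(timecourse_dataset(matrix(c(0.2, 0, 0, 0), 2, 2),
                                  c(1, 2), c(0, 1)),
               "t = 0")
})
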