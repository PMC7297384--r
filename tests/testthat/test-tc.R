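test_that("equilibrium fit recovers generating constants from clean data", {
  g <- benchmark_grid(Inf)
  d <- suppressWarnings(simulate_ode(nc_params(1, 1, 0.1), g))
  eq <- fit_equilibrium(d)
  expect_equal(eq$K, 1, tolerance = 0.01)
  expect_equal(eq$omega, 0.1, tolerance = 0.01)
  # derived IB constants satisfy the manifold conditions
  expect_equal(eq$K10 * eq$K01, eq$K^2 / eq$omega_clamped, tolerance = 1e-6)
  # single-site-like data sit at the degenerate corner
  d1 <- suppressWarnings(simulate_ode(nc_params(1, 1, 1), g))
  eq1 <- fit_equilibrium(d1)
  expect_equal(eq1$omega_clamped, 1, tolerance = 0.05)
  expect_equal(eq1$K10, eq1$K01, tolerance = 0.2)
  # a non-saturating dose grid is a hard error
  low <- suppressWarnings(simulate_ode(
    nc_params(1, 1, 0.5),
    simulation_grid(dose_grid_log(20, 1e-3, 0.5), time_grid_log(21))))
  expect_error(fit_equilibrium(low), class = "coop_saturation_error")
})

test_that("constrained kinetic fits recover rates and satisfy constraints", {
  g <- benchmark_grid(Inf)
  d <- suppressWarnings(simulate_ode(nc_params(1, 1, 0.5), g))
  eq <- fit_equilibrium(d)
  kin <- fit_kinetics(d, eq)
  expect_equal(kin$l_nc, 1, tolerance = 0.01)
  expect_lt(kin$sse_nc, 1e-8)
  # association rates are slaved to the dissociation constants exactly
  expect_equal(kin$l_nc / kin$k_nc, eq$K, tolerance = 1e-12)
  expect_equal(kin$l10 / kin$k10, eq$K10, tolerance = 1e-12)
  expect_equal(kin$l01 / kin$k01, eq$K01, tolerance = 1e-12)
  # the wrong model keeps a structural residual on NC data
  expect_gt(kin$sse_ib, 100 * kin$sse_nc)

  pairs <- lhs_scan(3, seed = 42)
  di <- det_dataset(pairs, 1, "ib")
  eqi <- fit_equilibrium(di)
  kii <- fit_kinetics(di, eqi)
  expect_equal(kii$l10, pairs$l10[1], tolerance = 0.02)
  expect_equal(kii$l01, pairs$l01[1], tolerance = 0.02)
  expect_lt(kii$sse_ib, 1e-8)
})

test_that("equilibrium-only data cannot separate the models", {
  g <- simulation_grid(dose_grid_log(20, 1e-3, 1e7), c(0, 1e4))
  pairs <- lhs_scan(2, seed = 13)
  d <- suppressWarnings(simulate_ode(pair_nc(pairs, 1), g))
  eq <- suppressWarnings(fit_equilibrium(d))
  kin <- fit_kinetics(d, eq)
  expect_lt(kin$sse_nc, 1e-6)
  expect_lt(kin$sse_ib, 1e-6)
})

test_that("the C statistic reproduces its three limiting behaviours", {
  # comparable fits: C near 1/2, and never favouring IB at equal SSE
  expect_equal(compute_C(1, 1, 1000), 0.5, tolerance = 0.02)
  expect_lte(compute_C(1, 1, 1000), 0.5)
  # far better IB fit: C -> 1; far better NC fit: C -> 0
  expect_gt(compute_C(1e-8, 1, 1000), 0.999)
  expect_lt(compute_C(1, 1e-8, 1000), 0.001)
  # exact-zero edge cases
  expect_equal(compute_C(0, 1, 100), 1)
  expect_equal(compute_C(1, 0, 100), 0)
  expect_equal(compute_C(0, 0, 100), 0.5)
  # invariance to a uniform rescaling of both SSEs
  expect_equal(compute_C(0.3, 0.7, 500), compute_C(3, 7, 500),
               tolerance = 1e-12)
})

test_that("C thresholds partition the verdicts", {
  expect_identical(tc_decide(0.9), "IB")
  expect_identical(tc_decide(0.1), "NC")
  expect_identical(tc_decide(0.5), "undecided")
  expect_identical(tc_decide(2 / 3), "IB")
  expect_identical(tc_decide(1 / 3), "NC")
})

test_that("the full TC run is decisive on clean kinetic data", {
  pairs <- lhs_scan(4, seed = 90)
  fit_nc <- tc_fit(det_dataset(pairs, 1, "nc"))
  expect_identical(fit_nc$verdict, "NC")
  expect_lt(fit_nc$C, 1 / 3)
  fit_ib <- tc_fit(det_dataset(pairs, 2, "ib"))
  expect_identical(fit_ib$verdict, "IB")
  expect_gt(fit_ib$C, 2 / 3)
})

test_that("stochastic parameter recovery stays within quoted error", {
  # median relative error over repeated R0 = 1000 simulations
  g <- benchmark_grid(1000)
  errs <- vapply(1:8, function(i) {
    d <- simulate_gillespie(nc_params(1, 1, 0.1), g, seed = 300 + i)
    eq <- fit_equilibrium(d)
    kin <- fit_kinetics(d, eq)
    max(abs(eq$K - 1), abs(eq$omega - 0.1) / 0.1, abs(kin$l_nc - 1))
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})
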