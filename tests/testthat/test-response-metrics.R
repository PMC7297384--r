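test_that("occupancy counts doubly bound receptors twice", {
  expect_equal(occupancy(0, 0, 0, 100), 0)
  expect_equal(occupancy(0, 0, 100, 100), 1)
  expect_equal(occupancy(10, 20, 35, 100), 0.5)
  expect_error(occupancy(60, 60, 0, 100), "conservation")
  expect_error(occupancy(-1, 0, 0, 10))
})

test_that("EC levels invert the single-site isotherm", {
  L <- dose_grid_log(200, 1e-4, 1e4)
  th <- L / (1 + L)
  expect_equal(ec_level(th, L, 0.5), 1, tolerance = 1e-3)
  expect_equal(ec_level(th, L, 0.1), 1 / 9, tolerance = 1e-2)
  expect_equal(ec_level(th, L, 0.9), 9, tolerance = 1e-2)
  # the monotone interpolant is far more accurate on a coarse grid
  Lc <- dose_grid_log(20, 1e-4, 1e4)
  thc <- Lc / (1 + Lc)
  expect_equal(ec_level(thc, Lc, 0.9, method = "monotone"), 9,
               tolerance = 5e-3)
  # absolute level never reached -> undefined signal, not an error
  expect_true(is.na(ec_level(0.6 * th, L, 0.9)))
  # already above the level at the lowest dose -> undefined
  expect_true(is.na(ec_level(seq(0.5, 0.99, length.out = 20),
                             dose_grid_log(20, 1, 10), 0.1)))
})

test_that("dynamic range reproduces printed reference values", {
  # single site: EC90/EC10 = 81
  expect_equal(dynr(1 / 9, 9), log10(81))
  expect_equal(dynr(1 / 9, 9), 1.908, tolerance = 1e-3)
  expect_equal(dynr(2, 2), 0)
  expect_true(is.na(dynr(NA, 5)))
  # NC with K = 1, omega = 0.01: quadratic-root oracle for both levels
  ec_nc <- function(th, K = 1, w = 0.01) {
    a <- w * (1 - th); b <- K * (1 - 2 * th); cc <- -th * K^2
    (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  }
  expect_equal(ec_nc(0.1), 0.12483, tolerance = 1e-4)
  expect_equal(ec_nc(0.9), 801.12, tolerance = 1e-4)
  d <- dynr(ec_nc(0.1), ec_nc(0.9))
  expect_equal(d, 3.807, tolerance = 1e-3)
})

test_that("Hill coefficient follows the ln(81)/DynR relation", {
  expect_equal(hill_from_dynr(log10(81)), 1, tolerance = 1e-12)
  expect_equal(hill_from_dynr(3.807), 0.501, tolerance = 1e-3)
  expect_equal(hill_from_dynr(log10(81) / 2), 2, tolerance = 1e-12)
  expect_error(hill_from_dynr(0))
})

test_that("single-site-like target curve has the analytic limits", {
  # two identical independent sites = one-site response in occupancy;
  # irreversible-limit oracle gives DynR(t->0) = log10(ln 0.1/ln 0.9)
  g <- simulation_grid(dose_grid_log(60, 1e-4, 1e6), time_grid_log(41))
  tc <- target_curve(simulate_ode(nc_params(1, 1, 1), g))
  expect_equal(tc$features$dynr_final, log10(81), tolerance = 5e-3)
  expect_equal(tc$features$dynr_initial, log10(log(0.1) / log(0.9)),
               tolerance = 2e-2)
  expect_identical(tc$features$shape, "increasing")
  expect_true(tc$features$dynr_initial_reliable)
})

test_that("strong negative cooperativity widens the equilibrium range", {
  g <- simulation_grid(dose_grid_log(80, 1e-4, 1e7), time_grid_log(41))
  tc <- target_curve(suppressWarnings(simulate_ode(nc_params(1, 1, 0.01), g)))
  expect_equal(tc$features$dynr_final, 3.807, tolerance = 5e-3)
  expect_identical(tc$features$shape, "increasing")
  # non-decreasing in time for NC (noiseless)
  v <- tc$dynr[tc$valid]
  expect_true(all(diff(v) > -0.02))
})

test_that("NC temporal curves are ordered by omega at equilibrium", {
  g <- simulation_grid(dose_grid_log(60, 1e-4, 1e7), time_grid_log(31))
  finals <- vapply(c(0.02, 0.1, 0.5, 1), function(w) {
    target_curve(suppressWarnings(
      simulate_ode(nc_params(1, 1, w), g)))$features$dynr_final
  }, numeric(1))
  expect_true(all(diff(finals) < 0))
})

test_that("shape classification separates the three regimes", {
  expect_identical(classify_shape(seq(1, 3, length.out = 20)), "increasing")
  expect_identical(classify_shape(seq(3, 1, length.out = 20)), "decreasing")
  expect_identical(classify_shape(c(seq(1, 3, length.out = 10),
                                    seq(3, 1, length.out = 10))), "biphasic")
  expect_identical(classify_shape(rep(2, 10)), "increasing")  # flat
  expect_true(is.na(classify_shape(c(1, 2, 3))))
  # noisy but strongly rising curve stays increasing
  set.seed(21)
  v <- seq(1.5, 3.5, length.out = 40) + rnorm(40, 0, 0.15)
  expect_identical(classify_shape(v, noisy = TRUE), "increasing")
  # noisy clear decrease is still detected
  expect_identical(classify_shape(rev(v), noisy = TRUE), "decreasing")
})

test_that("inflection time is exact on a log-time logistic", {
  tt <- 10^seq(-3, 3, length.out = 61)
  curve <- function(tau) 2 + 1 / (1 + (tt / tau)^(-1))
  expect_equal(inflection_time(tt, curve(1)), 1, tolerance = 1e-2)
  expect_equal(inflection_time(tt, curve(0.1)), 0.1, tolerance = 1e-2)
  # time rescaling covariance
  s <- 7.3
  expect_equal(inflection_time(tt * s, curve(1)[seq_along(tt)]),
               s * inflection_time(tt, curve(1)), tolerance = 1e-6)
  # the noisy sigmoid-fit estimator agrees on clean input
  expect_equal(inflection_time(tt, curve(1), noisy = TRUE), 1,
               tolerance = 5e-2)
})

test_that("faster unbinding moves the NC inflection earlier", {
  g <- simulation_grid(dose_grid_log(60, 1e-3, 1e7), time_grid_log(51))
  tips <- vapply(c(0.1, 1, 10), function(l) {
    target_curve(suppressWarnings(
      simulate_ode(nc_params(1, l, 0.05), g)))$features$t_ip
  }, numeric(1))
  expect_true(all(diff(tips) < 0))
  # roughly inverse scaling with l
  expect_equal(tips[1] / tips[3], 100, tolerance = 0.5)
})

test_that("target curve flags validity and early reliability", {
  g <- simulation_grid(dose_grid_log(40, 1e-3, 1e5), time_grid_log(31))
  d <- suppressWarnings(simulate_ode(nc_params(1, 1, 0.3), g))
  tc <- target_curve(d)
  expect_false(tc$valid[1])            # t = 0 never valid
  expect_true(any(tc$valid))
  expect_true(all(tc$dynr[tc$valid] > 0))
  r <- dynr_initial(tc)
  expect_equal(r$value, tc$features$dynr_initial)
  # too-coarse input is rejected
  tiny <- timecourse_dataset(matrix(0.5, 3, 3, byrow = TRUE) *
                               matrix(rep(c(0.1, 0.5, 0.9), 3), 3, 3),
                             c(1, 2, 3), c(1, 2, 3))
  expect_error(target_curve(tiny), "at least 5")
  # dataset that never reaches 90% occupancy -> empty-curve error
  low <- suppressWarnings(simulate_ode(
    nc_params(1, 1, 0.5),
    simulation_grid(dose_grid_log(10, 1e-3, 0.1), time_grid_log(11))))
  expect_error(target_curve(low), class = "coop_empty_curve_error")
})
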