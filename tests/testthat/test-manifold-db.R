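test_that("LHS scan covers the prescribed log-uniform ranges", {
  pairs <- lhs_scan(10000, seed = 1)
  expect_equal(nrow(pairs), 10000)
  expect_true(all(pairs$k >= 1e-2 & pairs$k <= 1e2))
  expect_true(all(pairs$l10 >= 1e-2 & pairs$l10 <= 1e2))
  expect_true(all(pairs$omega >= 1e-2 & pairs$omega <= 1))
  # expected window fractions of a log-uniform LHS sample
  f_l <- mean(pairs$l > 0.9 & pairs$l < 1.1)
  expect_equal(f_l, log10(1.1 / 0.9) / 4, tolerance = 0.25)
  f_w <- mean(pairs$omega > 0.010 & pairs$omega < 0.011)
  expect_equal(f_w, log10(1.1) / 2, tolerance = 0.25)
  # determinism under seed
  expect_identical(pairs, lhs_scan(10000, seed = 1))
  expect_false(identical(lhs_scan(50, seed = 1), lhs_scan(50, seed = 2)))
})

test_that("every scanned pair lies on the non-identifiability manifold", {
  pairs <- lhs_scan(300, seed = 8)
  L <- dose_grid_log(50, 1e-4, 1e8)
  worst <- 0
  for (i in seq_len(nrow(pairs))) {
    dev <- max(abs(theta_eq_nc(L, pairs$K[i], pairs$omega[i]) -
                     theta_eq_ib(L, pairs$K10[i], pairs$K01[i])))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-10)
  # completed rates respect their dissociation constants exactly
  expect_equal(pairs$l10 / pairs$k10, pairs$K10, tolerance = 1e-12)
  expect_equal(pairs$l01 / pairs$k01, pairs$K01, tolerance = 1e-12)
  # effective omega of the IB member equals the NC omega
  eff <- 4 * pairs$K10 * pairs$K01 / (pairs$K10 + pairs$K01)^2
  expect_equal(eff, pairs$omega, tolerance = 1e-10)
})

test_that("database features capture the known model asymmetries", {
  db <- small_db()
  fn <- db$features[db$features$model == "nc" & is.na(db$features$error), ]
  fi <- db$features[db$features$model == "ib" & is.na(db$features$error), ]
  # NC target curves are always increasing; IB curves are not
  expect_true(all(fn$shape == "increasing"))
  expect_gt(sum(fi$shape %in% c("decreasing", "biphasic")), 0.2 * nrow(fi))
  # equilibrium DynR identical within each pair (shared equilibrium curve)
  m <- merge(fn[, c("pair", "dynr_final")], fi[, c("pair", "dynr_final")],
             by = "pair")
  expect_lt(max(abs(m$dynr_final.x - m$dynr_final.y)), 1e-2)
  # the single-site corner: dynr_final -> log10(81) as omega -> 1
  corner <- fn$dynr_final[fn$omega > 0.9]
  expect_true(all(abs(corner - log10(81)) < 0.15))
})

test_that("lookup curves are monotone and inversely scaled as expected", {
  db <- small_db()
  # DynR(t->0) decreasing in omega for NC
  expect_true(all(diff(db$lookups$dynr0_nc$med) <= 1e-6))
  expect_gt(predict_dynr0_nc(db, 0.01) - predict_dynr0_nc(db, 1), 1)
  # DynR(t->0) increasing in |log ratio| for IB, symmetric in ratio <-> 1/ratio
  expect_equal(predict_dynr0_ib(db, 10), predict_dynr0_ib(db, 0.1),
               tolerance = 1e-12)
  expect_gt(predict_dynr0_ib(db, 100), predict_dynr0_ib(db, 1))
  # both collapse to the same irreversible single-site limit at the corner
  expect_equal(predict_dynr0_nc(db, 1), log10(log(0.1) / log(0.9)),
               tolerance = 0.06)
  expect_equal(predict_dynr0_ib(db, 1), log10(log(0.1) / log(0.9)),
               tolerance = 0.06)
  # inflection time scales roughly as 1/l
  r <- predict_tip_nc(db, 0.1) / predict_tip_nc(db, 10)
  expect_equal(log10(r), 2, tolerance = 0.35)
  expect_true(all(diff(db$lookups$tip_nc$med) <= 1e-6))
})

test_that("calibrated thresholds are positive and beat blind defaults", {
  db <- small_db()
  th <- db$thresholds
  expect_true(th$calibrated)
  expect_true(th$delta_dynr0_nc > 0 && th$delta_dynr0_ib > 0 &&
                th$delta_tip > 0)
  expect_gte(th$balanced_accuracy, 0.5)
  defs <- db_threshold_defaults(db)
  expect_true(all(unlist(defs) > 0))
})

test_that("database persists to plain text and reloads identically", {
  db <- small_db()
  dir <- file.path(tempdir(), "coopdb")
  write_manifold_db(db, dir)
  db2 <- read_manifold_db(dir)
  expect_equal(db2$lookups$dynr0_nc$med, db$lookups$dynr0_nc$med,
               tolerance = 1e-12)
  expect_equal(db2$thresholds$delta_tip, db$thresholds$delta_tip,
               tolerance = 1e-12)
  expect_equal(nrow(db2$pairs), nrow(db$pairs))
  om <- c(0.02, 0.2, 0.9)
  expect_equal(predict_dynr0_nc(db2, om), predict_dynr0_nc(db, om),
               tolerance = 1e-10)
  unlink(dir, recursive = TRUE)
})

test_that("database construction is reproducible under a fixed seed", {
  p1 <- lhs_scan(30, seed = 77)
  db1 <- build_database(p1, db_default_grid(50, 33))
  db2 <- build_database(lhs_scan(30, seed = 77), db_default_grid(50, 33))
  expect_identical(db1$features$dynr0, db2$features$dynr0)
  expect_identical(db1$features$t_ip, db2$features$t_ip)
})
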