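# shared fixtures, built once per test session (database construction and
# threshold calibration are the expensive steps)
.fixture_env <- new.env(parent = emptyenv())

fixture_get <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# moderate database for module-level tests
small_db <- function() {
  fixture_get("small_db", function() {
    db <- build_database(lhs_scan(300, seed = 42), db_default_grid(70, 45))
    calibrate_thresholds(db, r0 = 1000, n_cal = 12, seed = 7)
  })
}

# full-size (1000-pair) database for the acceptance suite
big_db <- function() {
  fixture_get("big_db", function() {
    db <- build_database(lhs_scan(1000, seed = 101), db_default_grid())
    calibrate_thresholds(db, r0 = 1000, n_cal = 30, seed = 11)
  })
}

# deterministic benchmark-grid dataset for a manifold pair row
det_dataset <- function(pairs, i, model, n_times = 41) {
  p <- if (model == "nc") pair_nc(pairs, i) else pair_ib(pairs, i)
  suppressWarnings(simulate_ode(p, benchmark_grid(Inf, n_times)))
}
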