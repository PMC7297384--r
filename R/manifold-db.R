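#' Latin hypercube scan of the non-identifiability manifold
#'
#' Draws `n` paired NC/IB parameter sets that share the same equilibrium
#' dose-response curve. The NC rates `k`, `l` and the IB dissociation rates
#' `l10`, `l01` are sampled log10-uniformly on `[1e-2, 1e2]` and the
#' cooperativity factor `omega` log10-uniformly on `[1e-2, 1]`, by Latin
#' hypercube sampling. The remaining IB association rates are completed
#' from the manifold conditions: `(K10, K01) = nc_to_ib(l/k, omega)`, then
#' `k10 = l10/K10`, `k01 = l01/K01`.
#'
#' @param n number of pairs (>= 1).
#' @param seed integer RNG seed.
#' @param rate_range log10 range for `k`, `l`, `l10`, `l01`
#'   (default `c(-2, 2)`).
#' @param omega_range log10 range for `omega` (default `c(-2, 0)`).
#' @return A data frame of class `manifold_pairs` with one row per pair and
#'   columns `k, l, omega, K, K10, K01, k10, k01, l10, l01, ratio`
#'   (`ratio = k10/k01`).
#' @examples
#' head(lhs_scan(5, seed = 1))
#' @export
lhs_scan <- function(n, seed, rate_range = c(-2, 2), omega_range = c(-2, 0)) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n, 5)
  k   <- 10^(rate_range[1] + diff(rate_range) * u[, 1])
  l   <- 10^(rate_range[1] + diff(rate_range) * u[, 2])
  l10 <- 10^(rate_range[1] + diff(rate_range) * u[, 3])
  l01 <- 10^(rate_range[1] + diff(rate_range) * u[, 4])
  omega <- 10^(omega_range[1] + diff(omega_range) * u[, 5])
  K <- l / k
  s <- sqrt(pmax(1 - omega, 0))
  K10 <- (K / omega) * (1 + s)
  K01 <- (K / omega) * (1 - s)
  k10 <- l10 / K10
  k01 <- l01 / K01
  out <- data.frame(k = k, l = l, omega = omega, K = K,
                    K10 = K10, K01 = K01, k10 = k10, k01 = k01,
                    l10 = l10, l01 = l01, ratio = k10 / k01)
  class(out) <- c("manifold_pairs", "data.frame")
  out
}

#' Extract the NC member of a manifold pair
#' @param pairs a `manifold_pairs` data frame.
#' @param i row index.
#' @return An [nc_params()] object.
#' @export
pair_nc <- function(pairs, i) nc_params(pairs$k[i], pairs$l[i], pairs$omega[i])

#' Extract the IB member of a manifold pair
#' @param pairs a `manifold_pairs` data frame.
#' @param i row index.
#' @return An [ib_params()] object.
#' @export
pair_ib <- function(pairs, i) {
  ib_params(pairs$k10[i], pairs$k01[i], pairs$l10[i], pairs$l01[i])
}

#' Default deterministic grid for database construction
#'
#' Doses span `[1e-6, 1e8]`: the top is wide enough that every scanned
#' parameter set saturates past 90% occupancy, and the bottom low enough
#' that the 10% crossing stays inside the grid even for the smallest
#' dissociation constants the scan can produce (`K01` down to `~5e-5`,
#' EC10 down to `~1e-5`) — otherwise late times would lose their validity
#' mask and equilibrium features would be read pre-equilibrium. Times span
#' `[1e-4, 1e4]`, bracketing the pre-equilibrium (`t < 1e-3`) and
#' equilibrium (`t > 1e3`) regimes of the scanned rate ranges.
#'
#' @param n_doses,n_times grid sizes.
#' @return A [simulation_grid()] with `R0 = Inf`.
#' @export
db_default_grid <- function(n_doses = 141, n_times = 65) {
  simulation_grid(dose_grid_log(n_doses, 1e-6, 1e8),
                  time_grid_log(n_times, 1e-4, 1e4), R0 = Inf)
}

## binned-median lookup table with 5-95% envelope over the scatter
.binned_lookup <- function(x, y, nbins = 40) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("too few points for a lookup table")
  br <- seq(min(x), max(x), length.out = nbins + 1)
  bin <- findInterval(x, br, rightmost.closed = TRUE)
  idx <- sort(unique(bin))
  bf <- factor(bin, levels = idx)        # numeric level order, not character
  centers <- (br[-1] + br[-length(br)]) / 2
  data.frame(
    x = centers[idx],
    med = as.numeric(tapply(y, bf, stats::median)),
    q05 = as.numeric(tapply(y, bf, stats::quantile, probs = 0.05,
                            names = FALSE)),
    q95 = as.numeric(tapply(y, bf, stats::quantile, probs = 0.95,
                            names = FALSE)),
    n = as.numeric(tapply(y, bf, length)))
}

.lookup_eval <- function(tab, x, what = "med") {
  stats::approx(tab$x, tab[[what]], xout = x, rule = 2)$y
}

#' Build the paired DynR(t) feature database
#'
#' Simulates both members of every manifold pair deterministically,
#' extracts the target-curve features of each, and fits the three numerical
#' lookup curves that drive the checkpoints: `DynR(t->0)` versus `omega`
#' for NC, `DynR(t->0)` versus `k10/k01` for IB (symmetric in the ratio and
#' its inverse, so tabulated against `|log10 ratio|`), and the inflection
#' time `t_ip` versus `l` for NC. Lookups are binned medians over the
#' scatter with 5th-95th percentile envelopes. Feature-extraction failures
#' are recorded per pair, not fatal.
#'
#' @param pairs a [lhs_scan()] result (>= 200 pairs recommended for usable
#'   lookups).
#' @param grid deterministic [simulation_grid()]
#'   (default [db_default_grid()]).
#' @param nbins bins per lookup axis (default 40).
#' @return An object of class `manifold_db`: the pair table, the per-pair
#'   per-model feature table, the three lookup tables, and decision
#'   thresholds initialised to the envelope-width defaults (see
#'   [calibrate_thresholds()]).
#' @export
build_database <- function(pairs, grid = db_default_grid(), nbins = 40) {
  stopifnot(inherits(pairs, "manifold_pairs"), inherits(grid, "sim_grid"))
  n <- nrow(pairs)
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    for (m in c("nc", "ib")) {
      p <- if (m == "nc") pair_nc(pairs, i) else pair_ib(pairs, i)
      rec <- list(pair = i, model = m, omega = pairs$omega[i],
                  ratio = pairs$ratio[i], l = pairs$l[i],
                  dynr0 = NA_real_, dynr0_reliable = NA,
                  dynr_final = NA_real_, t_ip = NA_real_,
                  shape = NA_character_, error = NA_character_)
      res <- tryCatch({
        sim <- suppressWarnings(simulate_ode(p, grid))
        tc <- target_curve(sim)
        f <- tc$features
        rec$dynr0 <- f$dynr_initial
        rec$dynr0_reliable <- f$dynr_initial_reliable
        rec$dynr_final <- f$dynr_final
        rec$t_ip <- f$t_ip
        rec$shape <- f$shape
        rec
      }, error = function(e) {
        rec$error <- conditionMessage(e)
        rec
      })
      rows[[2L * (i - 1L) + (if (m == "nc") 1L else 2L)]] <- res
    }
  }
  features <- do.call(rbind, lapply(rows, as.data.frame))
  fn <- features[features$model == "nc" & is.na(features$error), ]
  fi <- features[features$model == "ib" & is.na(features$error), ]
  lookups <- list(
    dynr0_nc = .binned_lookup(log10(fn$omega), fn$dynr0, nbins),
    dynr0_ib = .binned_lookup(abs(log10(fi$ratio)), fi$dynr0, nbins),
    tip_nc = .binned_lookup(log10(fn$l[!is.na(fn$t_ip)]),
                            log10(fn$t_ip[!is.na(fn$t_ip)]), nbins))
  db <- structure(list(pairs = pairs, features = features, lookups = lookups,
                       grid = list(doses = grid$doses, times = grid$times),
                       thresholds = NULL),
                  class = "manifold_db")
  db$thresholds <- c(db_threshold_defaults(db),
                     list(calibrated = FALSE, r0 = NA_real_))
  db
}

#' Envelope-based default decision thresholds
#'
#' Fallback thresholds when no calibration has been run: for each lookup
#' curve, the median over bins of half the 5th-95th percentile envelope
#' width (a dataset is "inside the band" if it deviates from the median
#' curve by less than the typical envelope half-width).
#'
#' @param db a [build_database()] result.
#' @return List with `delta_dynr0_nc`, `delta_dynr0_ib`, `delta_tip`
#'   (the latter in log10-time units).
#' @export
db_threshold_defaults <- function(db) {
  half <- function(tab) stats::median((tab$q95 - tab$q05) / 2)
  list(delta_dynr0_nc = max(half(db$lookups$dynr0_nc), 0.02),
       delta_dynr0_ib = max(half(db$lookups$dynr0_ib), 0.02),
       delta_tip = max(half(db$lookups$tip_nc), 0.02))
}

#' @export
print.manifold_db <- function(x, ...) {
  cat(sprintf("Manifold DynR(t) database: %d pairs (%d feature rows, %d failed)\n",
              nrow(x$pairs), nrow(x$features), sum(!is.na(x$features$error))))
  th <- x$thresholds
  cat(sprintf("  thresholds: dDynR0_NC = %.3f, dDynR0_IB = %.3f, dtip = %.3f [%s]\n",
              th$delta_dynr0_nc, th$delta_dynr0_ib, th$delta_tip,
              if (isTRUE(th$calibrated)) sprintf("calibrated at R0 = %g", th$r0)
              else "envelope defaults"))
  invisible(x)
}

#' Predicted NC DynR(t->0) at a cooperativity factor
#'
#' Evaluates the database lookup `DynR(t->0)` versus `omega` (NC model).
#'
#' @param db a [build_database()] result.
#' @param omega cooperativity factor(s) (> 0; values above 1 are clamped to
#'   1, the single-site corner).
#' @param what `"med"` (default), `"q05"` or `"q95"`.
#' @return Predicted DynR value(s).
#' @export
predict_dynr0_nc <- function(db, omega, what = "med") {
  .lookup_eval(db$lookups$dynr0_nc, log10(pmin(pmax(omega, 1e-12), 1)), what)
}

#' Predicted IB DynR(t->0) at an association-rate ratio
#'
#' Evaluates the database lookup `DynR(t->0)` versus `k10/k01` (IB model);
#' the lookup is symmetric under inverting the ratio.
#'
#' @param db a [build_database()] result.
#' @param ratio association-rate ratio(s) `k10/k01` (> 0).
#' @param what `"med"` (default), `"q05"` or `"q95"`.
#' @return Predicted DynR value(s).
#' @export
predict_dynr0_ib <- function(db, ratio, what = "med") {
  .lookup_eval(db$lookups$dynr0_ib, abs(log10(ratio)), what)
}

#' Predicted NC inflection time at an unbinding rate
#'
#' Evaluates the database lookup `t_ip` versus `l` (NC model).
#'
#' @param db a [build_database()] result.
#' @param l unbinding rate(s) (> 0).
#' @param what `"med"` (default), `"q05"` or `"q95"`.
#' @return Predicted inflection time(s), in time units.
#' @export
predict_tip_nc <- function(db, l, what = "med") {
  10^.lookup_eval(db$lookups$tip_nc, log10(l), what)
}

#' Calibrate the checkpoint thresholds on simulated data
#'
#' Chooses the three checkpoint thresholds (`delta_dynr0_nc`,
#' `delta_dynr0_ib`, `delta_tip`) by grid search, maximising the balanced
#' classification accuracy of the full cascade on freshly simulated
#' calibration datasets at a reference receptor copy number (`r0 = 1000`
#' by default; undecided verdicts count as errors). `r0 = Inf` calibrates
#' on deterministic data. The per-dataset audit quantities are computed
#' once, so the search over threshold combinations is cheap. With too few
#' calibration datasets the envelope defaults are kept.
#'
#' @param db a [build_database()] result.
#' @param r0 receptor copy number for the calibration simulations.
#' @param n_cal calibration datasets per model (default 30).
#' @param seed integer RNG seed.
#' @param n_candidates log-spaced candidate values per threshold
#'   (default 20).
#' @param grid analysis grid for the calibration datasets (defaults to the
#'   benchmark grid: 20 doses in `[1e-3, 1e7]`, times in `[1e-4, 1e4]`).
#' @return The database with `thresholds` replaced by the calibrated values
#'   (and calibration metadata).
#' @export
calibrate_thresholds <- function(db, r0 = 1000, n_cal = 30, seed = 1,
                                 n_candidates = 20, grid = NULL) {
  stopifnot(inherits(db, "manifold_db"))
  if (n_cal < 5) {
    warning("too few calibration datasets; keeping envelope defaults")
    return(db)
  }
  if (is.null(grid)) {
    grid <- simulation_grid(dose_grid_log(20, 1e-3, 1e7),
                            time_grid_log(41, 1e-4, 1e4), R0 = r0)
  }
  pairs <- lhs_scan(n_cal, seed = .subseed(seed, 101))
  audits <- vector("list", 2L * n_cal)
  for (i in seq_len(n_cal)) {
    for (m in c("nc", "ib")) {
      p <- if (m == "nc") pair_nc(pairs, i) else pair_ib(pairs, i)
      data <- if (is.finite(r0)) {
        simulate_gillespie(p, grid, seed = .subseed(seed, 1000L + 2L * i +
                                                      (m == "ib")))
      } else {
        suppressWarnings(simulate_ode(p, grid))
      }
      a <- discrimination_audit(data, db)
      a$truth <- m
      audits[[2L * (i - 1L) + (if (m == "nc") 1L else 2L)]] <- a
    }
  }
  A <- do.call(rbind, lapply(audits, as.data.frame))
  ## quantile anchors: each band should contain the true model's own
  ## deviation with high probability at this noise level
  qa <- function(x, fallback) {
    x <- x[is.finite(x)]
    if (length(x) < 5) fallback else
      max(stats::quantile(x, 0.95, names = FALSE), 0.02)
  }
  defs <- db_threshold_defaults(db)
  anchor <- c(
    qa(abs(A$dynr0 - A$pred_nc)[A$truth == "nc"], defs$delta_dynr0_nc),
    qa(abs(A$dynr0 - A$pred_ib)[A$truth == "ib"], defs$delta_dynr0_ib),
    qa(A$dlog_tip[A$truth == "nc"], defs$delta_tip))
  ## grid search around the anchors, maximising balanced cascade accuracy;
  ## ties (within half a dataset) broken towards the anchors so the flat
  ## regions of the objective cannot pull the bands to arbitrary extremes
  span <- seq(-1, 1, length.out = n_candidates)
  cand <- lapply(anchor, function(a) pmax(a * 10^span, 0.01))
  combos <- expand.grid(d1 = cand[[1]], d2 = cand[[2]], d3 = cand[[3]])
  combos$score <- vapply(seq_len(nrow(combos)), function(r) {
    v <- .cascade_vectorised(A, combos$d1[r], combos$d2[r], combos$d3[r])
    (mean(v[A$truth == "nc"] == "NC") +
       mean(v[A$truth == "ib"] == "IB")) / 2
  }, numeric(1))
  combos$dist <- (log10(combos$d1) - log10(anchor[1]))^2 +
    (log10(combos$d2) - log10(anchor[2]))^2
  top <- combos[combos$score >= max(combos$score) - 0.5 / nrow(A), ]
  ## flat directions of the objective are resolved by the stages' roles:
  ## the two DynR(t->0) bands are rejection tests (kept at the anchors,
  ## i.e. just containing the true model's own deviations), while the
  ## terminal inflection-time comparison accepts NC unless grossly
  ## inconsistent (most permissive near-optimal value)
  top <- top[top$d3 >= max(top$d3) - 1e-12, ]
  best <- top[which.min(top$dist), ]
  db$thresholds <- list(delta_dynr0_nc = best$d1, delta_dynr0_ib = best$d2,
                        delta_tip = best$d3, calibrated = TRUE, r0 = r0,
                        n_cal = n_cal, balanced_accuracy = best$score,
                        anchors = anchor)
  db
}

## deterministic derived sub-seed, kept below 2^31
.subseed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

## vectorised cascade over an audit table, given candidate thresholds
.cascade_vectorised <- function(A, d1, d2, d3, lo = 1/3, hi = 2/3) {
  v <- rep("undecided", nrow(A))
  tc_ib <- !is.na(A$C) & A$C >= hi
  tc_nc <- !is.na(A$C) & A$C <= lo
  v[tc_ib] <- "IB"; v[tc_nc] <- "NC"
  open <- v == "undecided"
  bad_shape <- open & (is.na(A$shape))
  nonmono <- open & !is.na(A$shape) & A$shape != "increasing"
  v[nonmono] <- "IB"
  open <- open & !nonmono & !bad_shape
  cp2 <- open & A$dynr0_reliable %in% TRUE &
    !is.na(A$pred_nc) & !is.na(A$pred_ib)
  fail_nc <- cp2 & abs(A$dynr0 - A$pred_nc) > d1
  v[fail_nc] <- "IB"
  fail_ib <- cp2 & !fail_nc & abs(A$dynr0 - A$pred_ib) > d2
  v[fail_ib] <- "NC"
  open <- open & !(cp2 & (fail_nc | fail_ib))
  cp3 <- open & !is.na(A$dlog_tip)
  v[cp3 & A$dlog_tip > d3] <- "IB"
  v[cp3 & A$dlog_tip <= d3] <- "NC"
  v
}

#' Write a manifold database to a directory
#'
#' Persists the database as plain text: `pairs.csv`, `features.csv` and
#' `lookups.json` (lookup tables, thresholds and grid).
#'
#' @param db a [build_database()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_manifold_db <- function(db, dir) {
  stopifnot(inherits(db, "manifold_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(db$pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  utils::write.csv(db$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  meta <- list(lookups = db$lookups, thresholds = db$thresholds,
               grid = db$grid)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"),
             file.path(dir, "lookups.json"))
  invisible(dir)
}

#' Read a manifold database written by [write_manifold_db()]
#'
#' @param dir directory containing `pairs.csv`, `features.csv`,
#'   `lookups.json`.
#' @return A `manifold_db` object.
#' @export
read_manifold_db <- function(dir) {
  pairs <- utils::read.csv(file.path(dir, "pairs.csv"))
  class(pairs) <- c("manifold_pairs", "data.frame")
  features <- utils::read.csv(file.path(dir, "features.csv"))
  meta <- jsonlite::fromJSON(file.path(dir, "lookups.json"))
  structure(list(pairs = pairs, features = features,
                 lookups = lapply(meta$lookups, as.data.frame),
                 grid = meta$grid, thresholds = meta$thresholds),
            class = "manifold_db")
}
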