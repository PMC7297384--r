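## ---- file formats, configuration, fixtures --------------------------------

#' Write a time-course dataset to long-format CSV
#'
#' Comma-separated, '.' decimal, mandatory header `time,ligand,theta`; one
#' row per (time, dose) cell (missing cells are omitted). A JSON sidecar
#' `<path>.json` records provenance (model tag, parameters, `R0`, seed,
#' stochastic flag).
#'
#' @param data a [timecourse_dataset()].
#' @param path output CSV path.
#' @param sidecar write the provenance sidecar? (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(data, path, sidecar = TRUE) {
  stopifnot(inherits(data, "timecourse"))
  long <- expand.grid(ligand = data$doses, time = data$times)
  long$theta <- as.vector(data$theta)
  long <- long[!is.na(long$theta), c("time", "ligand", "theta")]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    prov <- list(model = data$model, R0 = if (is.finite(data$R0)) data$R0
                 else "Inf",
                 seed = data$seed, stochastic = data$stochastic,
                 params = if (!is.null(data$params)) unclass(data$params))
    writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"),
               paste0(path, ".json"))
  }
  invisible(path)
}

#' Read a time-course dataset from long-format CSV
#'
#' Expects the header `time,ligand,theta` (any column order). The
#' (dose x time) coverage may be ragged: missing cells are masked as `NA`.
#' Occupancy values outside `[0, 1]` and non-numeric cells raise a parse
#' error naming the offending data row. If a `<path>.json` provenance
#' sidecar exists it is honoured.
#'
#' @param path CSV path.
#' @return A [timecourse_dataset()].
#' @export
read_timecourse <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "ligand", "theta")
  if (!all(need %in% names(raw))) {
    stop(sprintf("malformed header: need columns %s, found %s",
                 paste(need, collapse = ", "),
                 paste(names(raw), collapse = ", ")))
  }
  for (cn in need) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   cn, bad))
    }
  }
  bad <- which(raw$theta < -1e-9 | raw$theta > 1 + 1e-9)
  if (length(bad)) {
    stop(sprintf("theta = %g out of [0, 1] at data row %d",
                 raw$theta[bad[1]], bad[1]))
  }
  doses <- sort(unique(raw$ligand))
  times <- sort(unique(raw$time))
  theta <- matrix(NA_real_, length(doses), length(times))
  i <- match(raw$ligand, doses)
  j <- match(raw$time, times)
  theta[cbind(i, j)] <- raw$theta
  meta <- list(model = "unknown", R0 = Inf, seed = NA_integer_,
               stochastic = FALSE)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    prov <- jsonlite::fromJSON(sc)
    meta$model <- prov$model %||% "unknown"
    r0 <- prov$R0 %||% Inf
    meta$R0 <- if (identical(r0, "Inf")) Inf else as.numeric(r0)
    meta$seed <- prov$seed %||% NA_integer_
    meta$stochastic <- isTRUE(prov$stochastic)
  }
  timecourse_dataset(theta, doses, times, R0 = meta$R0, model = meta$model,
                     seed = meta$seed, stochastic = meta$stochastic)
}

#' Generate a labelled synthetic dataset
#'
#' Convenience generator for tests and demos, covering the four corners of
#' the two-binding-site space: `"nc"` (identical cooperative sites, a
#' random manifold draw), `"ib"` (different independent sites, its paired
#' counterpart), `"equal_sites"` (independent sites with `K10 = K01` but
#' different kinetics, the `omega = 1` corner where both descriptions are
#' correct), and `"single_site"` (identical independent sites — exactly
#' the one-site response in occupancy).
#'
#' @param kind one of `"nc"`, `"ib"`, `"single_site"`, `"equal_sites"`.
#' @param r0 receptor copy number (`Inf` = deterministic, the default).
#' @param seed integer RNG seed (drives both the parameter draw and any
#'   stochastic simulation).
#' @param n_times time points (default 41).
#' @return A [timecourse_dataset()].
#' @export
make_fixture <- function(kind = c("nc", "ib", "single_site", "equal_sites"),
                         r0 = Inf, seed = 1, n_times = 41) {
  kind <- match.arg(kind)
  pairs <- lhs_scan(1, seed = .subseed(seed, 71))
  params <- switch(kind,
    nc = pair_nc(pairs, 1),
    ib = pair_ib(pairs, 1),
    single_site = nc_params(pairs$k[1], pairs$l[1], 1),
    equal_sites = {
      K <- pairs$K[1]
      ib_params(k10 = pairs$l10[1] / K, k01 = pairs$l01[1] / K,
                l10 = pairs$l10[1], l01 = pairs$l01[1])
    })
  grid <- benchmark_grid(r0, n_times)
  if (is.finite(r0)) {
    simulate_gillespie(params, grid, seed = .subseed(seed, 72))
  } else {
    suppressWarnings(simulate_ode(params, grid))
  }
}

#' Assemble and validate a run configuration
#'
#' A validated bag of pipeline settings with a content hash for
#' provenance; every CLI output embeds the hash so runs can be traced to
#' their exact configuration.
#'
#' @param dose_range,n_doses dose grid settings.
#' @param time_range,n_times time grid settings.
#' @param r0 receptor copy number (or `Inf`).
#' @param seed integer RNG seed.
#' @param window smoothing window (odd).
#' @param thresholds optional named overrides for the database thresholds.
#' @return An object of class `run_config` (list plus `hash`).
#' @export
run_config <- function(dose_range = c(1e-3, 1e7), n_doses = 20,
                       time_range = c(1e-4, 1e4), n_times = 41,
                       r0 = Inf, seed = 1, window = 5, thresholds = NULL) {
  stopifnot(length(dose_range) == 2, dose_range[1] > 0,
            dose_range[2] > dose_range[1], n_doses >= 5,
            length(time_range) == 2, time_range[1] > 0,
            time_range[2] > time_range[1], n_times >= 5,
            window >= 1, window %% 2 == 1)
  cfg <- list(dose_range = dose_range, n_doses = n_doses,
              time_range = time_range, n_times = n_times, r0 = r0,
              seed = as.integer(seed), window = window,
              thresholds = thresholds)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

#' Content hash of an R object
#'
#' MD5 of the deparsed object (via [tools::md5sum()] on a temporary file);
#' used to stamp outputs with the configuration that produced them.
#'
#' @param x any serialisable R object.
#' @return A 32-character hex string.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}

#' Grid from a run configuration
#' @param cfg a [run_config()].
#' @return A [simulation_grid()].
#' @export
config_grid <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  simulation_grid(
    dose_grid_log(cfg$n_doses, cfg$dose_range[1], cfg$dose_range[2]),
    time_grid_log(cfg$n_times, cfg$time_range[1], cfg$time_range[2]),
    R0 = cfg$r0)
}
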