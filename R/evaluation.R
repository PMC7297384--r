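## ---- benchmarking harness -------------------------------------------------

#' Default benchmark analysis grid
#'
#' The experimental-like grid used for performance studies: 20 doses
#' log-spaced on `[1e-3, 1e7]` (wide enough that every scanned parameter
#' set passes 90% occupancy) and times log-spaced on `[1e-4, 1e4]` with
#' `t = 0` prepended.
#'
#' @param r0 receptor copy number (or `Inf`).
#' @param n_times number of positive time points (default 41).
#' @return A [simulation_grid()].
#' @export
benchmark_grid <- function(r0 = Inf, n_times = 41) {
  simulation_grid(dose_grid_log(20, 1e-3, 1e7),
                  time_grid_log(n_times, 1e-4, 1e4), R0 = r0)
}

## simulate + discriminate one panel of n_per_model pairs at one R0 level;
## returns a per-dataset record table
.run_panel <- function(db, n_per_model, r0, seed, n_times = 41) {
  grid <- benchmark_grid(r0, n_times)
  pairs <- lhs_scan(n_per_model, seed = .subseed(seed, 17))
  out <- vector("list", 2L * n_per_model)
  for (i in seq_len(n_per_model)) {
    for (m in c("nc", "ib")) {
      p <- if (m == "nc") pair_nc(pairs, i) else pair_ib(pairs, i)
      data <- if (is.finite(r0)) {
        simulate_gillespie(p, grid,
                           seed = .subseed(seed, 5000L + 2L * i + (m == "ib")))
      } else {
        suppressWarnings(simulate_ode(p, grid))
      }
      d <- discriminate(data, db)
      stage <- if (length(d$path)) d$path[[length(d$path)]]$stage else "error"
      out[[2L * (i - 1L) + (if (m == "nc") 1L else 2L)]] <- data.frame(
        pair = i, truth = toupper(m), r0 = r0,
        verdict = d$verdict, stage = stage,
        tc_verdict = d$audit$tc_verdict %||% NA_character_,
        C = d$audit$C, error = d$audit$error,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Benchmark the TC and TC+DR algorithms across stochasticity levels
#'
#' Draws `n_per_model` manifold pairs per receptor-copy-number level,
#' simulates both members of each pair (Gillespie for finite `R0`,
#' deterministic otherwise) on the benchmark grid, runs the full pipeline,
#' and tabulates the accuracy of the TC algorithm alone (its undecided
#' verdicts counted as errors, the conservative convention) and of the
#' combined TC+DR cascade, together with the fraction of datasets resolved
#' at each stage and the checkpoint-3 residual error (both denominators).
#'
#' @param db a calibrated [build_database()] result.
#' @param n_per_model parameter sets per model per level (default 40).
#' @param r0_levels receptor copy numbers (default `c(10, 100, 1000, Inf)`).
#' @param seed integer RNG seed.
#' @param n_times time points per dataset (default 41).
#' @return An object of class `benchmark_report`: a summary table, the
#'   per-dataset records, and the seed.
#' @export
benchmark <- function(db, n_per_model = 40, r0_levels = c(10, 100, 1000, Inf),
                      seed = 1, n_times = 41) {
  stopifnot(inherits(db, "manifold_db"), n_per_model >= 10)
  recs <- lapply(seq_along(r0_levels), function(j) {
    .run_panel(db, n_per_model, r0_levels[j], .subseed(seed, 31L * j),
               n_times)
  })
  records <- do.call(rbind, recs)
  summary <- do.call(rbind, lapply(r0_levels, function(r0) {
    r <- records[records$r0 == r0, ]
    n <- nrow(r)
    reach3 <- sum(r$stage == "cp3")
    cp3_wrong <- sum(r$stage == "cp3" & r$truth == "IB" & r$verdict == "NC")
    data.frame(
      r0 = r0, n_datasets = n,
      acc_tc = mean(r$tc_verdict == r$truth, na.rm = FALSE),
      acc_tcdr = mean(r$verdict == r$truth),
      frac_tc = mean(r$stage == "tc"),
      frac_cp1 = mean(r$stage == "cp1"),
      frac_cp2 = mean(r$stage == "cp2"),
      frac_cp3 = mean(r$stage == "cp3"),
      frac_undecided = mean(r$verdict == "undecided"),
      cp3_error_reaching = if (reach3 > 0) cp3_wrong / reach3 else NA_real_,
      cp3_error_all = cp3_wrong / n)
  }))
  summary$acc_tc[is.na(summary$acc_tc)] <- 0
  structure(list(summary = summary, records = records, seed = seed,
                 n_per_model = n_per_model),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark: %d datasets per model per level (seed %s)\n",
              x$n_per_model, format(x$seed)))
  s <- x$summary
  cat(sprintf("%10s %6s %8s %9s %9s %9s\n", "R0", "n", "acc TC",
              "acc TC+DR", "cp3 err", "undecided"))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%10s %6d %7.1f%% %8.1f%% %9s %9.1f%%\n",
                if (is.finite(s$r0[i])) format(s$r0[i]) else "determ.",
                s$n_datasets[i], 100 * s$acc_tc[i], 100 * s$acc_tcdr[i],
                if (is.na(s$cp3_error_reaching[i])) "--"
                else sprintf("%.1f%%", 100 * s$cp3_error_reaching[i]),
                100 * s$frac_undecided[i]))
  }
  invisible(x)
}

#' Residual error rate of the terminal checkpoint-3 NC conclusion
#'
#' Among datasets that reach checkpoint 3 (both fits comparable, target
#' curve increasing, both early-time bands passed), the fraction that are
#' IB-generated yet concluded NC — the cascade's only structural failure
#' mode. Reported relative to the datasets reaching checkpoint 3 (the
#' primary convention) and relative to all datasets, with a binomial
#' standard error.
#'
#' @param db a calibrated [build_database()] result.
#' @param n_per_model parameter sets per model.
#' @param r0 receptor copy number (`Inf` = deterministic limit).
#' @param seed integer RNG seed.
#' @param n_times time points per dataset (default 41).
#' @return List with `error_fraction` (reaching-cp3 denominator),
#'   `error_fraction_all`, `n_reaching`, `n_total`, `se` (binomial), and
#'   the per-dataset records.
#' @export
checkpoint3_error <- function(db, n_per_model, r0, seed = 1, n_times = 41) {
  records <- .run_panel(db, n_per_model, r0, seed, n_times)
  reach <- records$stage == "cp3"
  n_reach <- sum(reach)
  if (n_reach == 0) {
    return(list(error_fraction = NA_real_, error_fraction_all = 0,
                n_reaching = 0L, n_total = nrow(records), se = NA_real_,
                records = records))
  }
  wrong <- sum(reach & records$truth == "IB" & records$verdict == "NC")
  p <- wrong / n_reach
  list(error_fraction = p, error_fraction_all = wrong / nrow(records),
       n_reaching = n_reach, n_total = nrow(records),
       se = sqrt(p * (1 - p) / n_reach), records = records)
}

#' Standalone resolving power of checkpoint 2
#'
#' Applies the single most informative feature of the cascade — the
#' `DynR(t->0)`-versus-`omega` comparison — alone, with no TC decision and
#' no shape gate, to deterministically simulated members of freshly drawn
#' manifold pairs. Each dataset's observed early-time dynamic range is
#' compared with the NC database prediction at the equilibrium-fitted
#' `omega`: inside the band resolves NC, outside resolves IB (because the
#' NC target curves are strictly ordered by `omega`, an NC dataset must
#' land on the curve, while an IB dataset's `DynR(t->0)` is set by its
#' unrelated rate ratio `k10/k01`). Unreliable `DynR(t->0)` estimates are
#' unresolved. The reported fraction is resolved-and-correct over all
#' datasets.
#'
#' @param db a calibrated [build_database()] result.
#' @param n_pairs number of manifold pairs (both members are analysed).
#' @param seed integer RNG seed.
#' @param n_times time points per dataset (default 41).
#' @return List with `resolved_correct_pairs` (fraction of pairs whose
#'   two members are both correctly resolved — the pairwise
#'   indistinguishability problem is solved), `resolved_correct` (the
#'   same fraction over individual datasets), `resolved` (fraction
#'   receiving any verdict), `n`, and the per-dataset records.
#' @export
checkpoint2_standalone <- function(db, n_pairs = 200, seed = 1,
                                   n_times = 41) {
  stopifnot(inherits(db, "manifold_db"))
  grid <- benchmark_grid(Inf, n_times)
  pairs <- lhs_scan(n_pairs, seed = .subseed(seed, 53))
  out <- vector("list", 2L * n_pairs)
  for (i in seq_len(n_pairs)) {
    for (m in c("nc", "ib")) {
      p <- if (m == "nc") pair_nc(pairs, i) else pair_ib(pairs, i)
      data <- suppressWarnings(simulate_ode(p, grid))
      a <- discrimination_audit(data, db)
      cp2v <- if (!is.na(a$error)) {
        "error"
      } else if (!isTRUE(a$dynr0_reliable)) {
        "unresolved"
      } else if (abs(a$dynr0 - a$pred_nc) > db$thresholds$delta_dynr0_nc) {
        "IB"
      } else {
        "NC"
      }
      out[[2L * (i - 1L) + (if (m == "nc") 1L else 2L)]] <- data.frame(
        pair = i, truth = toupper(m), cp2_verdict = cp2v,
        dynr0 = a$dynr0, omega_hat = a$omega_hat, ratio_hat = a$ratio_hat,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, out)
  resolved <- records$cp2_verdict %in% c("IB", "NC")
  correct <- resolved & records$cp2_verdict == records$truth
  pair_ok <- tapply(correct, records$pair, all)
  list(resolved_correct_pairs = mean(pair_ok),
       resolved_correct = mean(correct),
       resolved = mean(resolved), n = nrow(records), records = records)
}
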