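## ---- the DynR checkpoint cascade (TC+DR) ----------------------------------

#' Checkpoint 1: global shape of the target curve
#'
#' A `DynR(t)` curve that is decreasing or biphasic can only arise from the
#' IB model (NC target curves are always increasing), so those shapes are
#' terminal IB verdicts; an increasing curve continues down the cascade.
#'
#' @param shape shape class from [classify_shape()] (or `NA`).
#' @return List with `verdict` (`"IB"`, `"continue"` or `"undecided"`) and
#'   the inspected `shape`.
#' @export
checkpoint1 <- function(shape) {
  verdict <- if (is.na(shape)) "undecided"
  else if (shape %in% c("decreasing", "biphasic")) "IB"
  else "continue"
  list(stage = "cp1", verdict = verdict, shape = shape)
}

#' Checkpoint 2: the DynR(t->0) band comparisons
#'
#' Compares the observed early-time dynamic range with the database
#' predictions at the fitted control parameters. If the data deviate from
#' the NC prediction at the estimated `omega` by more than
#' `delta_dynr0_nc`, the data cannot be NC: verdict IB. Otherwise, if they
#' deviate from the IB prediction at the estimated `k10/k01` by more than
#' `delta_dynr0_ib`, verdict NC. If both bands contain the observation the
#' checkpoint is inconclusive (`"continue"`). An unreliable `DynR(t->0)`
#' estimate skips the checkpoint (`"skip"`).
#'
#' @param dynr0_data observed `DynR` at the earliest valid time.
#' @param reliable reliability flag from the target curve.
#' @param omega_hat fitted cooperativity factor (Step 1).
#' @param ratio_hat fitted `k10/k01` (Step 2).
#' @param db a calibrated [build_database()] result.
#' @return List with `verdict` (`"IB"`, `"NC"`, `"continue"` or `"skip"`)
#'   and the compared quantities.
#' @export
checkpoint2 <- function(dynr0_data, reliable, omega_hat, ratio_hat, db) {
  th <- db$thresholds
  if (!isTRUE(reliable) || is.na(dynr0_data)) {
    return(list(stage = "cp2", verdict = "skip", dynr0_data = dynr0_data,
                reliable = isTRUE(reliable)))
  }
  pred_nc <- predict_dynr0_nc(db, omega_hat)
  dev_nc <- abs(dynr0_data - pred_nc)
  if (dev_nc > th$delta_dynr0_nc) {
    return(list(stage = "cp2", verdict = "IB", dynr0_data = dynr0_data,
                pred_nc = pred_nc, dev_nc = dev_nc,
                delta_nc = th$delta_dynr0_nc))
  }
  pred_ib <- predict_dynr0_ib(db, ratio_hat)
  dev_ib <- abs(dynr0_data - pred_ib)
  verdict <- if (dev_ib > th$delta_dynr0_ib) "NC" else "continue"
  list(stage = "cp2", verdict = verdict, dynr0_data = dynr0_data,
       pred_nc = pred_nc, dev_nc = dev_nc, delta_nc = th$delta_dynr0_nc,
       pred_ib = pred_ib, dev_ib = dev_ib, delta_ib = th$delta_dynr0_ib)
}

#' Checkpoint 3: the inflection-time comparison (terminal)
#'
#' Compares the observed inflection time of the target curve with the NC
#' database prediction at the fitted unbinding rate, on a log10-time axis.
#' A deviation above `delta_tip` rules out NC (verdict IB); otherwise the
#' data are concluded NC. This is the cascade's terminal stage and its NC
#' conclusion is the algorithm's only structural failure mode (IB data
#' whose target curve mimics NC throughout).
#'
#' @param tip_data observed inflection time (may be `NA`).
#' @param l_hat fitted NC unbinding rate (Step 2).
#' @param db a calibrated [build_database()] result.
#' @return List with `verdict` (`"IB"`, `"NC"` or `"undecided"` when
#'   `tip_data` is undefined) and the compared quantities.
#' @export
checkpoint3 <- function(tip_data, l_hat, db) {
  if (is.na(tip_data)) {
    return(list(stage = "cp3", verdict = "undecided", tip_data = NA_real_))
  }
  pred <- predict_tip_nc(db, l_hat)
  dev <- abs(log10(tip_data) - log10(pred))
  list(stage = "cp3",
       verdict = if (dev > db$thresholds$delta_tip) "IB" else "NC",
       tip_data = tip_data, pred_tip = pred, dev_log10 = dev,
       delta_tip = db$thresholds$delta_tip)
}

#' Per-dataset audit of every discrimination quantity
#'
#' Runs the TC fits and the target-curve analysis once and returns all the
#' quantities the cascade compares (C, shape, `DynR(t->0)` and its two
#' database predictions, the inflection-time deviation, the fitted control
#' parameters). [discriminate()], threshold calibration and the benchmark
#' harness all consume this record, so the expensive fits are done exactly
#' once per dataset.
#'
#' @param data a [timecourse_dataset()].
#' @param db a [build_database()] result.
#' @param window smoothing window for stochastic data.
#' @return A one-row list/record; `error` is `NA` on success.
#' @export
discrimination_audit <- function(data, db, window = 5) {
  rec <- list(C = NA_real_, tc_verdict = NA_character_,
              shape = NA_character_, dynr0 = NA_real_,
              dynr0_reliable = NA, pred_nc = NA_real_, pred_ib = NA_real_,
              tip_data = NA_real_, pred_tip = NA_real_, dlog_tip = NA_real_,
              omega_hat = NA_real_, K_hat = NA_real_, ratio_hat = NA_real_,
              l_hat = NA_real_, sse_nc = NA_real_, sse_ib = NA_real_,
              n_obs = NA_real_, error = NA_character_)
  tryCatch({
    tc <- tc_fit(data)
    rec$C <- tc$C
    rec$tc_verdict <- tc$verdict
    rec$omega_hat <- tc$equilibrium$omega_clamped
    rec$K_hat <- tc$equilibrium$K
    rec$ratio_hat <- tc$kinetics$ratio
    rec$l_hat <- tc$kinetics$l_nc
    rec$sse_nc <- tc$kinetics$sse_nc
    rec$sse_ib <- tc$kinetics$sse_ib
    rec$n_obs <- tc$kinetics$n_obs
    crv <- target_curve(data, window)
    f <- crv$features
    rec$shape <- f$shape
    rec$dynr0 <- f$dynr_initial
    rec$dynr0_reliable <- f$dynr_initial_reliable
    rec$pred_nc <- predict_dynr0_nc(db, rec$omega_hat)
    rec$pred_ib <- predict_dynr0_ib(db, rec$ratio_hat)
    rec$tip_data <- f$t_ip
    if (!is.na(f$t_ip)) {
      rec$pred_tip <- predict_tip_nc(db, rec$l_hat)
      rec$dlog_tip <- abs(log10(f$t_ip) - log10(rec$pred_tip))
    }
    rec
  }, error = function(e) {
    rec$error <- conditionMessage(e)
    rec
  })
}

#' Discriminate NC from IB on a time-course dataset (TC+DR)
#'
#' The end-to-end decision pipeline: the TC algorithm (equilibrium fit,
#' constrained kinetic fits, C statistic) decides outright when `C` is
#' extreme; otherwise the `DynR(t)` target curve is analysed through the
#' three checkpoints in order (shape, early-time band comparisons,
#' inflection time), short-circuiting at the first conclusion. The
#' returned decision carries the complete audit trail of every stage
#' traversed with the quantities it compared. Deterministic given data and
#' database.
#'
#' @param data a [timecourse_dataset()].
#' @param db a [build_database()] (ideally [calibrate_thresholds()]-ed)
#'   result.
#' @param window smoothing window for stochastic data (default 5).
#' @param lo,hi C thresholds (defaults 1/3, 2/3).
#' @return An object of class `coop_decision`: `verdict` (`"IB"`, `"NC"`
#'   or `"undecided"`), `path` (ordered stage records), and the underlying
#'   audit record.
#' @examples
#' \donttest{
#' pairs <- lhs_scan(200, seed = 1)
#' db <- build_database(pairs, db_default_grid(60, 45))
#' g <- simulation_grid(dose_grid_log(20), time_grid_log(31))
#' d <- simulate_ode(nc_params(1, 1, 0.1), g)
#' discriminate(d, db)
#' }
#' @export
discriminate <- function(data, db, window = 5, lo = 1/3, hi = 2/3) {
  stopifnot(inherits(data, "timecourse"), inherits(db, "manifold_db"))
  a <- discrimination_audit(data, db, window)
  path <- list()
  mk <- function(verdict, flags = character()) {
    structure(list(verdict = verdict, path = path, audit = a,
                   thresholds = db$thresholds, flags = flags),
              class = "coop_decision")
  }
  if (!is.na(a$error)) {
    path[["tc"]] <- list(stage = "tc", verdict = "undecided", error = a$error)
    return(mk("undecided", flags = "stage_error"))
  }
  tcv <- tc_decide(a$C, lo, hi)
  path[["tc"]] <- list(stage = "tc", verdict = tcv, C = a$C,
                       sse_nc = a$sse_nc, sse_ib = a$sse_ib)
  if (tcv != "undecided") return(mk(tcv))
  cp1 <- checkpoint1(a$shape)
  path[["cp1"]] <- cp1
  if (cp1$verdict == "IB") return(mk("IB"))
  if (cp1$verdict == "undecided") return(mk("undecided", "shape_undefined"))
  cp2 <- checkpoint2(a$dynr0, a$dynr0_reliable, a$omega_hat, a$ratio_hat, db)
  path[["cp2"]] <- cp2
  if (cp2$verdict %in% c("IB", "NC")) return(mk(cp2$verdict))
  flags <- if (cp2$verdict == "skip") "dynr0_unreliable" else character()
  cp3 <- checkpoint3(a$tip_data, a$l_hat, db)
  path[["cp3"]] <- cp3
  mk(cp3$verdict, flags = c(flags,
                            if (cp3$verdict == "undecided") "tip_undefined"))
}

#' @export
print.coop_decision <- function(x, ...) {
  cat(sprintf("Decision: %s (via %s)\n", x$verdict,
              paste(vapply(x$path, `[[`, "", "stage"), collapse = " -> ")))
  a <- x$audit
  if (is.na(a$error)) {
    cat(sprintf("  C = %.4f; omega_hat = %.4g, k10/k01_hat = %.4g, l_hat = %.4g\n",
                a$C, a$omega_hat, a$ratio_hat, a$l_hat))
    cat(sprintf("  DynR(t->0) = %.4g (NC pred %.4g, IB pred %.4g); t_ip = %s\n",
                a$dynr0, a$pred_nc, a$pred_ib,
                if (is.na(a$tip_data)) "NA" else format(a$tip_data,
                                                        digits = 4)))
  } else {
    cat(sprintf("  stage error: %s\n", a$error))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
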