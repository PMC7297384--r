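## ---- the time-course (TC) fitting algorithm -------------------------------

## pick the equilibrium time slice: latest time whose dose-response differs
## from the previous time's by < 0.5% sup-norm; stochastic data use the last
## time (the stability rule is meaningless under noise)
.equilibrium_slice_index <- function(data, tol = 0.005) {
  nt <- length(data$times)
  if (data$stochastic || nt < 2) return(nt)
  stable <- which(vapply(2:nt, function(j) {
    max(abs(data$theta[, j] - data$theta[, j - 1]), na.rm = TRUE) < tol
  }, logical(1))) + 1L
  if (length(stable) == 0) {
    warning("no equilibrated time slice found; using the last time")
    return(nt)
  }
  max(stable)
}

#' Step 1: equilibrium dose-response fit
#'
#' Fits the equilibrium slice of the data (`theta` versus dose at the
#' latest equilibrated time) with the NC equilibrium expression by
#' least squares in log-parameters (multi-start Nelder-Mead), yielding
#' `(K, omega)`; the equivalent independent-site constants `(K10, K01)`
#' are then derived through the manifold mapping [nc_to_ib()]. A fitted
#' `omega > 1` (possible under noise near the single-site corner, or for
#' genuinely positive-cooperative data, which is outside the method's
#' scope) is flagged and clamped to 1 for the mapping.
#'
#' @param data a [timecourse_dataset()] whose equilibrium curve reaches at
#'   least 0.9 occupancy.
#' @param n_starts number of Nelder-Mead starts (default 8).
#' @return List with `K`, `omega`, `K10`, `K01`, `omega_clamped`,
#'   `no_ib_counterpart`, `sse_eq`, `eq_time_index`.
#' @export
fit_equilibrium <- function(data, n_starts = 8) {
  stopifnot(inherits(data, "timecourse"))
  j <- .equilibrium_slice_index(data)
  if (data$stochastic) {
    ## average the stationary tail to denoise the equilibrium curve (the
    ## cooperativity factor is weakly identified from one noisy slice)
    nt <- length(data$times)
    jj <- max(j - max(2, floor(nt / 10)), 1):j
    y <- rowMeans(data$theta[, jj, drop = FALSE], na.rm = TRUE)
  } else {
    y <- data$theta[, j]
  }
  ok <- !is.na(y)
  y <- y[ok]; L <- data$doses[ok]
  if (max(y) < 0.9) {
    stop(errorCondition(
      sprintf("equilibrium curve saturates at %.3f < 0.9; dose grid too narrow",
              max(y)),
      class = c("coop_saturation_error", "error", "condition")))
  }
  obj <- function(p) {
    K <- 10^p[1]; w <- 10^p[2]
    sum((theta_eq_nc(L, K, w) - y)^2)
  }
  ## EC50-style initial guess for K
  i50 <- which(y >= 0.5)[1]
  logK0 <- log10(L[max(i50, 2)])
  starts <- expand.grid(logK = logK0 + c(-0.7, 0.7),
                        logw = c(-2, -1.3, -0.7, 0))
  starts <- starts[seq_len(min(n_starts, nrow(starts))), ]
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[s, ]), obj, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$value < best$value - 1e-15 ||
         (abs(fit$value - best$value) <= 1e-15 &&
          sum(fit$par^2) < sum(best$par^2)))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("equilibrium fit failed from every start")
  K <- 10^best$par[1]
  omega <- 10^best$par[2]
  omega_c <- min(omega, 1)
  KK <- nc_to_ib(K, omega_c)
  list(K = K, omega = omega, omega_clamped = omega_c,
       K10 = unname(KK["K10"]), K01 = unname(KK["K01"]),
       no_ib_counterpart = omega > 1,
       sse_eq = best$value, eq_time_index = j)
}

#' Step 2: constrained kinetic fits of both models
#'
#' Fits the full `theta(L, t)` surface with both models, holding the
#' dissociation constants at their Step-1 values so that association rates
#' are slaved to the fitted unbinding rates (`k = l/K` for NC;
#' `k10 = l10/K10`, `k01 = l01/K01` for IB). The NC model then has one free
#' parameter (`l`) and the IB model two (`l10`, `l01`); both are optimised
#' in log10 space and the minimised residual sums of squares are returned.
#' The NC fit uses a deterministic coarse log-grid scan refined by Brent's
#' method; the IB fit uses multi-start Nelder-Mead (8 perimeter starts
#' spanning `[1e-3, 1e3]` plus one start at the NC solution), ties broken
#' towards the smaller parameter vector. The `t = 0` column carries no
#' information (both models predict exactly zero) and is excluded from the
#' residuals.
#'
#' @param data a [timecourse_dataset()].
#' @param eq a [fit_equilibrium()] result.
#' @param l_range log10 search range for unbinding rates
#'   (default `c(-4, 4)`).
#' @return List with `l_nc`, `k_nc`, `sse_nc`, `l10`, `l01`, `k10`, `k01`,
#'   `ratio` (`= k10/k01`), `sse_ib`, `n_obs`.
#' @export
fit_kinetics <- function(data, eq, l_range = c(-4, 4)) {
  stopifnot(inherits(data, "timecourse"))
  use <- data$times > 0
  times <- data$times[use]
  target <- data$theta[, use, drop = FALSE]
  obs_mask <- !is.na(target)
  n_obs <- sum(obs_mask)
  doses <- data$doses
  K <- eq$K; w <- eq$omega_clamped
  K10 <- eq$K10; K01 <- eq$K01

  sse_nc_fun <- function(log10l) {
    l <- 10^log10l
    th <- .nc_theta_analytic(l / K, l, w, doses, times)
    sum((th[obs_mask] - target[obs_mask])^2)
  }
  lg <- seq(l_range[1], l_range[2], length.out = 33)
  vals <- vapply(lg, sse_nc_fun, numeric(1))
  i <- which.min(vals)
  lo <- lg[max(i - 1, 1)]; hi <- lg[min(i + 1, length(lg))]
  opt_nc <- stats::optimize(sse_nc_fun, c(lo, hi), tol = 1e-8)
  l_nc <- 10^opt_nc$minimum
  sse_nc <- opt_nc$objective

  sse_ib_fun <- function(p) {
    l10 <- 10^p[1]; l01 <- 10^p[2]
    th <- .ib_theta_analytic(l10 / K10, l01 / K01, l10, l01, doses, times)
    sum((th[obs_mask] - target[obs_mask])^2)
  }
  perim <- rbind(c(-2, -2), c(-2, 0), c(-2, 2), c(0, -2), c(0, 2),
                 c(2, -2), c(2, 0), c(2, 2))
  starts <- rbind(perim, c(log10(l_nc), log10(l_nc)))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], sse_ib_fun, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$value < best$value - 1e-15 ||
         (abs(fit$value - best$value) <= 1e-15 &&
          sum(fit$par^2) < sum(best$par^2)))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("IB kinetic fit failed from every start")
  l10 <- 10^best$par[1]; l01 <- 10^best$par[2]
  list(l_nc = l_nc, k_nc = l_nc / K, sse_nc = sse_nc,
       l10 = l10, l01 = l01, k10 = l10 / K10, k01 = l01 / K01,
       ratio = (l10 / K10) / (l01 / K01), sse_ib = best$value,
       n_obs = n_obs)
}

#' The model-comparison statistic C
#'
#' Compares the constrained IB and NC fits through a variance-ratio
#' F statistic with per-model residual degrees of freedom:
#' `C = pf((sse_nc/(n - p_nc)) / (sse_ib/(n - p_ib)), n - p_nc, n - p_ib)`,
#' where the IB model carries one extra free parameter (`p_ib = 2`,
#' `p_nc = 1`). `C` is near 1 when the IB fit is far better, near 0 when
#' the NC fit is far better, and near 1/2 when the two are comparable;
#' at exactly equal SSEs the extra-parameter penalty keeps `C` slightly
#' below 1/2 (it never favours IB for free).
#'
#' @param sse_ib,sse_nc minimised residual sums of squares (>= 0).
#' @param n_obs number of fitted observations (> `p_ib`).
#' @param p_ib,p_nc free-parameter counts (defaults 2 and 1).
#' @return `C` in `[0, 1]`.
#' @examples
#' compute_C(1, 1, 1000)      # ~0.5
#' compute_C(1e-8, 1, 1000)   # ~1
#' @export
compute_C <- function(sse_ib, sse_nc, n_obs, p_ib = 2, p_nc = 1) {
  stopifnot(sse_ib >= 0, sse_nc >= 0, n_obs > p_ib)
  if (sse_ib == 0 && sse_nc == 0) return(0.5)
  if (sse_ib == 0) return(1)
  if (sse_nc == 0) return(0)
  f <- (sse_nc / (n_obs - p_nc)) / (sse_ib / (n_obs - p_ib))
  stats::pf(f, n_obs - p_nc, n_obs - p_ib)
}

#' Verdict from the C statistic
#'
#' `C >= hi` declares IB, `C <= lo` declares NC, anything between is
#' undecided and hands over to the target-curve checkpoints. The default
#' thresholds are 1/3 and 2/3.
#'
#' @param C the statistic from [compute_C()].
#' @param lo,hi decision thresholds (defaults 1/3, 2/3).
#' @return `"IB"`, `"NC"` or `"undecided"`.
#' @export
tc_decide <- function(C, lo = 1/3, hi = 2/3) {
  stopifnot(C >= 0, C <= 1, lo < hi)
  if (C >= hi) "IB" else if (C <= lo) "NC" else "undecided"
}

#' Run the full TC algorithm (Steps 1-3)
#'
#' Equilibrium fit, constrained kinetic fits of both models, and the
#' F-statistic comparison, bundled with the verdict from [tc_decide()].
#'
#' @param data a [timecourse_dataset()].
#' @param lo,hi C thresholds (defaults 1/3, 2/3).
#' @return An object of class `tc_fit`: the Step-1 and Step-2 estimates,
#'   `C`, and `verdict`.
#' @export
tc_fit <- function(data, lo = 1/3, hi = 2/3) {
  eq <- fit_equilibrium(data)
  kin <- fit_kinetics(data, eq)
  C <- compute_C(kin$sse_ib, kin$sse_nc, kin$n_obs)
  structure(list(equilibrium = eq, kinetics = kin, C = C,
                 verdict = tc_decide(C, lo, hi)),
            class = "tc_fit")
}

#' @export
print.tc_fit <- function(x, ...) {
  cat(sprintf("TC fit: C = %.4f -> %s\n", x$C, x$verdict))
  cat(sprintf("  Step 1: K = %.4g, omega = %.4g (K10 = %.4g, K01 = %.4g)\n",
              x$equilibrium$K, x$equilibrium$omega,
              x$equilibrium$K10, x$equilibrium$K01))
  cat(sprintf("  Step 2: l = %.4g (sse %.3g) | l10 = %.4g, l01 = %.4g (sse %.3g), k10/k01 = %.4g\n",
              x$kinetics$l_nc, x$kinetics$sse_nc, x$kinetics$l10,
              x$kinetics$l01, x$kinetics$sse_ib, x$kinetics$ratio))
  invisible(x)
}
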