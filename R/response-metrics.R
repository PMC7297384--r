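#' Occupancy fraction from receptor state counts
#'
#' `theta = (R10 + R01 + 2 R11) / (2 R0)`: the fraction of *sites* occupied,
#' counting the doubly bound configuration twice.
#'
#' @param R10,R01,R11 counts (or concentrations) of the singly and doubly
#'   bound configurations, all >= 0 (vectorised).
#' @param R0 total receptor count (> 0).
#' @return Occupancy fraction(s) in `[0, 1]`.
#' @examples
#' occupancy(10, 20, 35, 100)  # 0.5
#' @export
occupancy <- function(R10, R01, R11, R0) {
  .check_scalar_pos(R0, "R0")
  if (any(R10 < 0) || any(R01 < 0) || any(R11 < 0)) {
    stop("state counts must be non-negative")
  }
  if (any(R10 + R01 + R11 > R0 * (1 + 1e-9))) {
    stop("receptor conservation violated: R10 + R01 + R11 > R0")
  }
  (R10 + R01 + 2 * R11) / (2 * R0)
}

#' Effective-concentration level of a dose-response curve
#'
#' Finds the ligand concentration at which the curve crosses an *absolute*
#' occupancy level (e.g. 0.1 or 0.9 of full site occupation, not of the
#' curve's current maximum), by linear interpolation in (log10 dose, theta).
#' If the curve never reaches the level within the dose grid the value is
#' undefined and `NA` is returned (a signal, not an error), which
#' downstream code records in the validity mask.
#'
#' @param theta occupancy values at each dose (assumed monotone after
#'   smoothing; the first upward crossing is used).
#' @param doses positive, strictly increasing dose grid.
#' @param level target occupancy in (0, 1).
#' @param method `"linear"` (default; robust under residual noise) or
#'   `"monotone"` (monotone cubic Hermite through the curve, far more
#'   accurate on coarse dose grids; noiseless curves only).
#' @return The interpolated dose, or `NA_real_` if the level is not
#'   bracketed by the curve.
#' @examples
#' L <- dose_grid_log(100, 1e-3, 1e3)
#' ec_level(L / (1 + L), L, 0.5)  # ~1 (EC50 = K)
#' @export
ec_level <- function(theta, doses, level,
                     method = c("linear", "monotone")) {
  stopifnot(length(theta) == length(doses), level > 0, level < 1)
  method <- match.arg(method)
  ok <- !is.na(theta)
  theta <- theta[ok]; doses <- doses[ok]
  if (length(theta) < 2) return(NA_real_)
  idx <- which(theta >= level)
  if (length(idx) == 0) return(NA_real_)       # level not reached
  if (idx[1] == 1) return(NA_real_)            # already above at lowest dose
  x <- log10(doses)
  if (method == "monotone" && length(theta) >= 4) {
    th <- cummax(theta)                        # guard tiny non-monotone dips
    f <- stats::splinefun(x, th, method = "hyman")
    root <- tryCatch(
      stats::uniroot(function(z) f(z) - level, range(x), tol = 1e-12)$root,
      error = function(e) NA_real_)
    if (!is.na(root)) return(10^root)
  }
  i <- idx[1]
  fr <- (level - theta[i - 1]) / (theta[i] - theta[i - 1])
  10^(x[i - 1] + fr * (x[i] - x[i - 1]))
}

#' Dynamic range of a dose-response curve
#'
#' `DynR = log10(EC90 / EC10)`: the fold change in dose (in decades) needed
#' to drive the response from 10% to 90% absolute occupancy. A single
#' binding site gives `log10(81) = 1.908`, the classic reference value;
#' negative cooperativity widens it. Undefined EC inputs (`NA`) propagate.
#'
#' @param ec10,ec90 dose levels from [ec_level()] (ec90 >= ec10 > 0 when
#'   both defined).
#' @return Dynamic range in log10 units, or `NA`.
#' @examples
#' dynr(1/9, 9)  # log10(81)
#' @export
dynr <- function(ec10, ec90) {
  if (is.na(ec10) || is.na(ec90)) return(NA_real_)
  if (ec10 <= 0 || ec90 <= 0) stop("EC levels must be positive")
  log10(ec90 / ec10)
}

#' Hill coefficient implied by a dynamic range
#'
#' One definition of the Hill coefficient is `n_H = ln(81) / ln(EC90/EC10)`.
#' For a base-10 dynamic range this is `ln(81) / (DynR * ln(10))`; the
#' single-site value `DynR = log10(81)` gives `n_H = 1`.
#'
#' @param dynr_value base-10 dynamic range (> 0).
#' @return The Hill coefficient.
#' @examples
#' hill_from_dynr(log10(81))  # 1
#' @export
hill_from_dynr <- function(dynr_value) {
  if (!is.numeric(dynr_value) || any(dynr_value <= 0)) {
    stop("dynr_value must be positive")
  }
  log(81) / (dynr_value * log(10))
}

#' Classify the shape of a dynamic-range-versus-time curve
#'
#' Noise-robust, fit-free classification of `DynR(t)` into `"increasing"`,
#' `"decreasing"` or `"biphasic"`. The curve is lightly smoothed, a noise
#' scale is estimated from the smoothing residuals, and a rise (run-up) or
#' fall (drawdown) only counts if it exceeds
#' `max(tau_mono * noise MAD, rel_floor * range)`. A flat curve (neither
#' significant) is reported as `"increasing"` (non-decreasing), so a
#' single-site-like constant curve continues through the cascade. Fewer
#' than 5 usable points give `NA` (undefined signal).
#'
#' @param dynr_values curve values at increasing times (NAs dropped).
#' @param noisy logical: estimate a noise scale from smoothing residuals
#'   (for stochastic data)?
#' @param tau_mono multiplier on the residual MAD (default 3).
#' @param rel_floor fraction of the smoothed curve's range used as a
#'   minimal significance floor (default 0.02).
#' @param abs_floor absolute significance floor in DynR (log10-dose)
#'   units, covering the EC-interpolation ripple of the dose grid; callers
#'   that know the grid pass `~0.2 * (log10 dose spacing)^2` (see
#'   [target_curve()]).
#' @param window smoothing window (odd, default 5).
#' @return `"increasing"`, `"decreasing"`, `"biphasic"`, or `NA_character_`.
#' @export
classify_shape <- function(dynr_values, noisy = FALSE, tau_mono = 3,
                           rel_floor = 0.02, abs_floor = 0.01, window = 5) {
  v <- dynr_values[!is.na(dynr_values)]
  if (length(v) < 5) return(NA_character_)
  if (noisy) {
    ## block medians: point noise is too heavy at small receptor numbers
    ## for a pointwise drawdown test (41 comparisons of sd-0.3 values);
    ## medians of ~n/5 points make the monotonicity test multiplicity-aware
    nb <- min(5L, length(v) %/% 3)
    if (nb < 3) return(NA_character_)
    cuts <- cut(seq_along(v), nb, labels = FALSE)
    med <- as.numeric(tapply(v, cuts, stats::median))
    resid <- v - med[cuts]
    se <- 1.4826 * stats::mad(resid) / sqrt(mean(tabulate(cuts)))
    tol <- max(tau_mono * se, abs_floor, 1e-9)
    vs <- med
  } else {
    w <- min(window, if (length(v) %% 2 == 1) length(v) else length(v) - 1)
    vs <- smooth_dose_curve(v, w)
    tol <- max(rel_floor * diff(range(vs)), abs_floor, 1e-9)
  }
  drawdown <- max(cummax(vs) - vs)
  runup <- max(vs - cummin(vs))
  dec <- drawdown > tol
  inc <- runup > tol
  if (inc && dec) "biphasic" else if (dec) "decreasing" else "increasing"
}

#' Inflection time of an increasing target curve
#'
#' The time at which `DynR(t)` rises fastest against `log10(t)` (the zero
#' of the second derivative of the sigmoid-like target curve). Noiseless
#' curves use centred finite differences of the lightly smoothed curve on
#' the `(log10 t, DynR)` axes with parabolic refinement of the peak slope;
#' noisy curves instead fit a logistic sigmoid in `log10(t)` (a
#' point-derivative estimate is noise-dominated there) and return its
#' midpoint.
#'
#' @param times positive times (increasing).
#' @param dynr_values curve values at those times (NAs allowed).
#' @param window smoothing window (odd, default 5).
#' @param noisy logical: stochastic data? (selects the sigmoid-fit
#'   estimator).
#' @return The inflection time `t_ip`, or `NA_real_` if fewer than 5 valid
#'   points remain.
#' @export
inflection_time <- function(times, dynr_values, window = 5, noisy = FALSE) {
  ok <- !is.na(dynr_values) & times > 0
  tt <- times[ok]; v <- dynr_values[ok]
  if (length(v) < 5) return(NA_real_)
  u <- log10(tt)
  if (noisy) return(.tip_sigmoid_fit(u, v))
  w <- min(window, if (length(v) %% 2 == 1) length(v) else length(v) - 1)
  vs <- smooth_dose_curve(v, w)
  n <- length(vs)
  i2 <- 2:(n - 1)
  slope <- (vs[i2 + 1] - vs[i2 - 1]) / (u[i2 + 1] - u[i2 - 1])
  ip <- which.max(slope)
  u_peak <- u[i2[ip]]
  if (ip > 1 && ip < length(slope)) {
    ## quadratic through the three (u, slope) points around the peak
    x <- u[i2[(ip - 1):(ip + 1)]]
    y <- slope[(ip - 1):(ip + 1)]
    d <- (y[1] - 2 * y[2] + y[3])
    if (is.finite(d) && d < 0) {
      h <- mean(diff(x))
      u_peak <- x[2] + 0.5 * h * (y[1] - y[3]) / d
    }
  }
  10^u_peak
}

## least-squares logistic a + b/(1 + 10^(-s (u - u0))) on the (log10 t,
## DynR) curve; u0 is the inflection point on the log-time axis. The
## asymptotes are pinned to the early/late plateau medians (both well
## estimated even under heavy noise), leaving only midpoint and slope
## free — this keeps the midpoint variance small on noisy curves.
.tip_sigmoid_fit <- function(u, v) {
  m <- min(5, max(3, length(v) %/% 4))
  a <- stats::median(v[seq_len(m)])
  b <- stats::median(v[seq(length(v) - m + 1, length(v))]) - a
  if (b <= 0) return(NA_real_)          # no net rise: no inflection
  fit_once <- function(uu, vv) {
    obj <- function(p) {
      pred <- a + b / (1 + 10^(-exp(p[2]) * (uu - p[1])))
      sum((pred - vv)^2)
    }
    ## global grid search over midpoint x slope, then local polish
    grid <- expand.grid(u0 = seq(min(uu), max(uu), length.out = 25),
                        logs = log(c(0.5, 1, 2, 4)))
    vals <- vapply(seq_len(nrow(grid)), function(r) {
      obj(c(grid$u0[r], grid$logs[r]))
    }, numeric(1))
    start <- as.numeric(grid[which.min(vals), ])
    fit <- tryCatch(
      stats::optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    fit$par
  }
  par <- fit_once(u, v)
  if (is.null(par)) return(NA_real_)
  ## one trimmed re-fit: noise excursions must not set the midpoint
  pred <- a + b / (1 + 10^(-exp(par[2]) * (u - par[1])))
  res <- v - pred
  keep <- abs(res) <= 3 * stats::mad(res) + 1e-12
  if (sum(keep) >= 5 && any(!keep)) {
    par2 <- fit_once(u[keep], v[keep])
    if (!is.null(par2)) par <- par2
  }
  u0 <- par[1]
  ## midpoint outside the observed window means no interior inflection
  if (u0 < u[1] - 1 || u0 > u[length(u)] + 1) return(NA_real_)
  unname(10^u0)
}

## both EC levels from one curve, building the interpolant once; the
## monotone path inverts a Hyman spline resampled at 12 points per dose
## interval (inversion error negligible against the spline error itself)
.ec_pair <- function(theta, doses, levels, method) {
  ok <- !is.na(theta)
  y <- theta[ok]; x <- log10(doses[ok])
  out <- rep(NA_real_, length(levels))
  if (length(y) < 2) return(out)
  if (method == "monotone" && length(y) >= 4) {
    f <- stats::splinefun(x, cummax(y), method = "hyman")
    xf <- seq(x[1], x[length(x)], length.out = 12L * length(x))
    yf <- f(xf)
  } else {
    xf <- x; yf <- y
  }
  for (s in seq_along(levels)) {
    lev <- levels[s]
    idx <- which(yf >= lev)
    if (length(idx) == 0 || idx[1] == 1) next
    i <- idx[1]
    fr <- (lev - yf[i - 1]) / (yf[i] - yf[i - 1])
    out[s] <- 10^(xf[i - 1] + fr * (xf[i] - xf[i - 1]))
  }
  out
}

#' Dynamic-range-versus-time target curve
#'
#' The central observable of the discrimination method: for each
#' observation time the dose-response curve `theta(L, t0)` is (optionally)
#' smoothed, its absolute EC10 and EC90 are extracted, and
#' `DynR(t0) = log10(EC90/EC10)` is recorded. Times at which either level
#' is not reached within the dose grid are marked invalid. The curve's
#' diagnostic features are attached: the earliest-time value
#' `dynr_initial` (with an early-plateau reliability flag), the
#' equilibrium value `dynr_final`, the shape class, and the inflection
#' time `t_ip` (increasing curves only).
#'
#' @param data a [timecourse_dataset()] with at least 5 doses and 5 times.
#' @param window smoothing window for stochastic data (odd, default 5);
#'   deterministic data are not smoothed.
#' @param plateau_tol relative spread of the first three valid values below
#'   which `dynr_initial` is flagged reliable (default 0.05).
#' @return An object of class `target_curve`: a list with `times`, `dynr`,
#'   `valid`, and a `features` list (`dynr_initial`, `dynr_initial_reliable`,
#'   `dynr_final`, `t_ip`, `shape`).
#' @examples
#' g <- simulation_grid(dose_grid_log(30, 1e-3, 1e4), time_grid_log(21))
#' tc <- target_curve(simulate_ode(nc_params(1, 1, 0.2), g))
#' tc$features$dynr_final
#' @export
target_curve <- function(data, window = 5, plateau_tol = 0.05) {
  stopifnot(inherits(data, "timecourse"))
  if (length(data$doses) < 5 || length(data$times) < 5) {
    stop("need at least 5 doses and 5 times")
  }
  nt <- length(data$times)
  dy <- rep(NA_real_, nt)
  ec_method <- if (data$stochastic) "linear" else "monotone"
  lx <- log10(data$doses)
  for (j in seq_len(nt)) {
    y <- data$theta[, j]
    if (all(is.na(y))) next
    if (data$stochastic) {
      ## isotonic regression over dose: monotone denoising with no
      ## broadening bias (a boxcar several dose decades wide would
      ## inflate DynR)
      ok <- !is.na(y)
      if (sum(ok) >= 4) y[ok] <- stats::isoreg(lx[ok], y[ok])$yf
      y <- pmin(pmax(y, 0), 1)
    }
    ec <- .ec_pair(y, data$doses, c(0.1, 0.9), ec_method)
    if (!anyNA(ec)) dy[j] <- dynr(ec[1], ec[2])
  }
  valid <- !is.na(dy) & data$times > 0
  if (!any(valid)) {
    stop(errorCondition("no time point has both EC10 and EC90 defined",
                        class = c("coop_empty_curve_error", "error",
                                  "condition")))
  }
  iv <- which(valid)
  first3 <- dy[iv[seq_len(min(3, length(iv)))]]
  reliable <- length(first3) >= 3 &&
    (max(first3) / min(first3) - 1) < plateau_tol
  ## residual EC-interpolation ripple scales with the squared dose spacing
  dx <- stats::median(diff(log10(data$doses)))
  shape <- classify_shape(dy[iv], noisy = data$stochastic,
                          abs_floor = 0.2 * dx^2,
                          window = if (data$stochastic) 9 else window)
  t_ip <- if (identical(shape, "increasing")) {
    inflection_time(data$times[iv], dy[iv], noisy = data$stochastic)
  } else NA_real_
  structure(list(
    times = data$times, dynr = dy, valid = valid,
    features = list(
      dynr_initial = dy[iv[1]],
      dynr_initial_reliable = reliable,
      dynr_final = dy[iv[length(iv)]],
      t_ip = t_ip,
      shape = shape)),
    class = "target_curve")
}

#' @export
print.target_curve <- function(x, ...) {
  f <- x$features
  cat(sprintf(
    "DynR(t) target curve: %d/%d valid times; shape = %s\n",
    sum(x$valid), length(x$times), f$shape %||% NA))
  cat(sprintf("  DynR(t->0) = %.4f (%sreliable), DynR(t->inf) = %.4f, t_ip = %s\n",
              f$dynr_initial, if (f$dynr_initial_reliable) "" else "un",
              f$dynr_final,
              if (is.na(f$t_ip)) "NA" else format(f$t_ip, digits = 4)))
  invisible(x)
}

#' Earliest-time dynamic range with a reliability flag
#'
#' Reads the `DynR` value at the earliest valid time from a target curve
#' and reports whether the curve's early shape supports treating it as an
#' estimate of the `t -> 0` limit (the first three valid values must agree
#' pairwise within `plateau_tol` relative).
#'
#' @param curve a [target_curve()] object.
#' @param plateau_tol relative early-plateau tolerance (default 0.05).
#' @return List with `value` and `reliable`.
#' @export
dynr_initial <- function(curve, plateau_tol = 0.05) {
  stopifnot(inherits(curve, "target_curve"))
  iv <- which(curve$valid)
  first3 <- curve$dynr[iv[seq_len(min(3, length(iv)))]]
  list(value = curve$dynr[iv[1]],
       reliable = length(first3) >= 3 &&
         (max(first3) / min(first3) - 1) < plateau_tol)
}
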