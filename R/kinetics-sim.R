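#' Dose x time simulation grid
#'
#' Bundles the ligand concentrations, observation times and total receptor
#' copy number used by the simulators. `R0 = Inf` means the deterministic
#' (mass-action) limit; a finite integer `R0` selects stochastic simulation.
#'
#' @param doses strictly increasing, positive ligand concentrations.
#' @param times strictly increasing observation times, all >= 0.
#' @param R0 total receptor count: a positive integer, or `Inf` for the
#'   deterministic limit (default).
#' @return An object of class `sim_grid`.
#' @seealso [dose_grid_log()], [time_grid_log()]
#' @export
simulation_grid <- function(doses, times, R0 = Inf) {
  stopifnot(is.numeric(doses), length(doses) >= 1, all(is.finite(doses)))
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly increasing")
  }
  stopifnot(is.numeric(times), length(times) >= 1, all(is.finite(times)))
  if (any(times < 0)) stop("times must be >= 0")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (!(identical(R0, Inf) ||
        (is.numeric(R0) && length(R0) == 1 && R0 >= 1 && R0 == round(R0)))) {
    stop("R0 must be a positive integer or Inf")
  }
  structure(list(doses = as.numeric(doses), times = as.numeric(times),
                 R0 = R0),
            class = "sim_grid")
}

#' Log-spaced dose grid
#'
#' @param n number of doses.
#' @param lo,hi range endpoints (positive); points are uniform in log10.
#' @return Numeric vector of doses.
#' @export
dose_grid_log <- function(n = 20, lo = 1e-3, hi = 1e7) {
  stopifnot(n >= 2, lo > 0, hi > lo)
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Log-spaced time grid (with t = 0 prepended)
#'
#' The default spans well below the fastest pre-equilibrium regime and
#' beyond equilibration of the slowest scanned rates.
#'
#' @param n number of positive time points.
#' @param lo,hi range endpoints (positive); points are uniform in log10.
#' @param t0 include time zero first? (default `TRUE`).
#' @return Numeric vector of times.
#' @export
time_grid_log <- function(n = 41, lo = 1e-4, hi = 1e4, t0 = TRUE) {
  stopifnot(n >= 2, lo > 0, hi > lo)
  tt <- 10^seq(log10(lo), log10(hi), length.out = n)
  if (t0) c(0, tt) else tt
}

#' Construct a time-course occupancy dataset
#'
#' The central data container: occupancy fraction `theta` on a dose x time
#' grid, plus provenance (generating model, parameters, seed, stochastic or
#' deterministic origin). Values are validated to lie in `[0, 1]` and to be
#' zero at `t = 0`.
#'
#' @param theta numeric matrix, `length(doses)` rows x `length(times)`
#'   columns; `NA` marks missing cells.
#' @param doses,times grid axes (doses positive increasing, times
#'   non-negative increasing).
#' @param R0 total receptor count used (or `Inf`).
#' @param model generating model tag (`"nc"`, `"ib"` or `"unknown"`).
#' @param params generating parameter object or `NULL`.
#' @param seed RNG seed used (or `NA`).
#' @param stochastic logical: was the data stochastically simulated?
#' @return An object of class `timecourse`.
#' @export
timecourse_dataset <- function(theta, doses, times, R0 = Inf,
                               model = "unknown", params = NULL,
                               seed = NA_integer_, stochastic = FALSE) {
  theta <- as.matrix(theta)
  if (nrow(theta) != length(doses) || ncol(theta) != length(times)) {
    stop("theta must be a length(doses) x length(times) matrix")
  }
  rng <- range(theta, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("theta values must lie in [0, 1]")
  }
  theta <- pmin(pmax(theta, 0), 1)
  if (times[1] == 0 && any(theta[, 1] > 1e-9, na.rm = TRUE)) {
    stop("theta at t = 0 must be zero (empty initial condition)")
  }
  structure(list(theta = theta, doses = as.numeric(doses),
                 times = as.numeric(times), R0 = R0, model = model,
                 params = params, seed = seed, stochastic = stochastic),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf(
    "Time-course occupancy dataset: %d doses x %d times, R0 = %s, %s (%s)\n",
    length(x$doses), length(x$times),
    if (is.finite(x$R0)) format(x$R0) else "Inf", toupper(x$model),
    if (x$stochastic) sprintf("stochastic, seed %s", format(x$seed))
    else "deterministic"))
  cat(sprintf("  doses in [%g, %g], times in [%g, %g]\n",
              min(x$doses), max(x$doses), min(x$times), max(x$times)))
  invisible(x)
}

## ---- closed-form solutions of the linear mass-action kinetics -------------

## NC model reduced by site symmetry (R10 = R01 from an empty start) to the
## 2-state system in x = (R10+R01)/R0, y = R11/R0:
##   x' = -(2a + l + b) x + 2(l - a) y + 2a,   y' = b x - 2 l y
## with a = k L, b = omega k L. Detailed balance makes both eigenvalues real.
## Returns theta = (x + 2 y)/2 as a doses x times matrix.
.nc_theta_analytic <- function(k, l, omega, doses, times) {
  a <- k * doses
  b <- omega * k * doses
  A11 <- -(2 * a + l + b); A12 <- 2 * (l - a)
  A21 <- b;                A22 <- -2 * l
  det <- A11 * A22 - A12 * A21          # = 4al + 2l^2 + 2ab > 0
  zx <- 4 * a * l / det                 # steady state of x
  zy <- 2 * a * b / det                 # steady state of y
  tr <- A11 + A22
  disc <- pmax(tr^2 - 4 * det, 0)
  sq <- sqrt(disc)
  lam1 <- (tr + sq) / 2
  lam2 <- (tr - sq) / 2
  degenerate <- sq < 1e-9 * abs(tr)
  ## eigenvectors v_i = (lam_i + 2l, b); solve [v1 v2] alpha = -(zx, zy)
  v1x <- lam1 + 2 * l; v2x <- lam2 + 2 * l
  detM <- b * (lam1 - lam2)
  detM[degenerate] <- NA                # handled by fallback below
  al1 <- (-zx * b + v2x * zy) / detM
  al2 <- (v1x * (-zy) + zx * b) / detM
  E1 <- exp(outer(lam1, times))
  E2 <- exp(outer(lam2, times))
  x <- zx + (al1 * v1x) * E1 + (al2 * v2x) * E2
  y <- zy + (al1 * b) * E1 + (al2 * b) * E2
  theta <- (x + 2 * y) / 2
  if (any(degenerate)) {
    for (i in which(degenerate)) {
      theta[i, ] <- .nc_theta_lsoda_one(k, l, omega, doses[i], times)
    }
  }
  pmin(pmax(theta, 0), 1)
}

## IB model: sites fill independently, p_j(t) = L/(K_j+L) (1 - exp(-(k_j L + l_j) t))
.ib_theta_analytic <- function(k10, k01, l10, l01, doses, times) {
  K10 <- l10 / k10; K01 <- l01 / k01
  p10 <- (doses / (K10 + doses)) * (1 - exp(outer(-(k10 * doses + l10), times)))
  p01 <- (doses / (K01 + doses)) * (1 - exp(outer(-(k01 * doses + l01), times)))
  pmin(pmax((p10 + p01) / 2, 0), 1)
}

## full 3-state right-hand sides (used by the lsoda cross-check path)
.binding_rhs <- function(params, L) {
  if (inherits(params, "nc_params")) {
    k <- params$k; l <- params$l; w <- params$omega
    rates <- list(kA = k * L, kB = k * L, kA2 = w * k * L, kB2 = w * k * L,
                  lA = l, lB = l, lA2 = l, lB2 = l)
  } else {
    rates <- list(kA = params$k10 * L, kB = params$k01 * L,
                  kA2 = params$k10 * L, kB2 = params$k01 * L,
                  lA = params$l10, lB = params$l01,
                  lA2 = params$l10, lB2 = params$l01)
  }
  ## states y = (R10, R01, R11) as fractions of R0; R00 = 1 - sum(y)
  function(t, y, parms) {
    r00 <- 1 - y[1] - y[2] - y[3]
    d10 <- rates$kA * r00 - rates$lA * y[1] - rates$kB2 * y[1] + rates$lB2 * y[3]
    d01 <- rates$kB * r00 - rates$lB * y[2] - rates$kA2 * y[2] + rates$lA2 * y[3]
    d11 <- rates$kB2 * y[1] + rates$kA2 * y[2] - (rates$lA2 + rates$lB2) * y[3]
    list(c(d10, d01, d11))
  }
}

.nc_theta_lsoda_one <- function(k, l, omega, dose, times) {
  st <- ode_states(nc_params(k, l, omega), dose, times)
  (st[, "R10"] + st[, "R01"] + 2 * st[, "R11"]) / 2
}

#' Solve the full three-state kinetics at one dose
#'
#' Integrates the mass-action system for the receptor configurations
#' `R10`, `R01`, `R11` (fractions of `R0`, empty start) at a single constant
#' ligand concentration, using `deSolve::lsoda`. Mainly a cross-check and
#' fallback for the closed-form path used by [simulate_ode()].
#'
#' @param params `nc_params` or `ib_params`.
#' @param dose single ligand concentration (> 0).
#' @param times non-negative, increasing times.
#' @param rtol,atol integrator tolerances.
#' @return Matrix with columns `R10`, `R01`, `R11` (rows = times).
#' @export
ode_states <- function(params, dose, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "binding_params"), dose > 0)
  rhs <- .binding_rhs(params, dose)
  t_in <- times
  prepend <- t_in[1] > 0
  if (prepend) t_in <- c(0, t_in)
  out <- deSolve::lsoda(c(R10 = 0, R01 = 0, R11 = 0), t_in, rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  res <- out[, c("R10", "R01", "R11"), drop = FALSE]
  if (prepend) res <- res[-1, , drop = FALSE]
  res
}

#' Deterministic simulation of a binding model
#'
#' Integrates the mass-action kinetics of the NC or IB model at every dose
#' of the grid, with the ligand concentration held constant (step input, no
#' depletion) and all receptors initially empty. Because the system is
#' linear with constant coefficients at fixed `L`, the default method
#' evaluates the exact closed-form solution (site-symmetry reduction for
#' NC, independent-site product form for IB); `method = "lsoda"` integrates
#' the full three-state system numerically instead, which is slower and
#' serves as an independent check.
#'
#' @param params `nc_params` or `ib_params`.
#' @param grid a [simulation_grid()]; `R0` is ignored here (deterministic
#'   limit).
#' @param method `"analytic"` (default) or `"lsoda"`.
#' @return A [timecourse_dataset()] with `stochastic = FALSE`.
#' @examples
#' g <- simulation_grid(dose_grid_log(10), time_grid_log(11))
#' sim <- simulate_ode(nc_params(1, 1, 0.5), g)
#' @export
simulate_ode <- function(params, grid, method = c("analytic", "lsoda")) {
  stopifnot(inherits(params, "binding_params"), inherits(grid, "sim_grid"))
  method <- match.arg(method)
  doses <- grid$doses; times <- grid$times
  if (method == "analytic") {
    theta <- if (inherits(params, "nc_params")) {
      .nc_theta_analytic(params$k, params$l, params$omega, doses, times)
    } else {
      .ib_theta_analytic(params$k10, params$k01, params$l10, params$l01,
                         doses, times)
    }
  } else {
    theta <- matrix(NA_real_, length(doses), length(times))
    for (i in seq_along(doses)) {
      st <- ode_states(params, doses[i], times)
      theta[i, ] <- (st[, "R10"] + st[, "R01"] + 2 * st[, "R11"]) / 2
    }
    theta <- pmin(pmax(theta, 0), 1)
  }
  eq_top <- theta_eq(params, max(doses))
  if (eq_top < 0.9) {
    warning(sprintf(
      "top dose reaches only %.3f equilibrium occupancy (< 0.9); widen the dose grid",
      eq_top))
  }
  timecourse_dataset(theta, doses, times, R0 = Inf,
                     model = if (inherits(params, "nc_params")) "nc" else "ib",
                     params = params, stochastic = FALSE)
}

## ---- stochastic simulation ------------------------------------------------

## 4-state generator over (R00, R10, R01, R11) at one dose
.binding_generator <- function(params, L) {
  Q <- matrix(0, 4, 4)
  if (inherits(params, "nc_params")) {
    a <- params$k * L; b <- params$omega * params$k * L; l <- params$l
    Q[1, 2] <- a;  Q[1, 3] <- a
    Q[2, 1] <- l;  Q[2, 4] <- b
    Q[3, 1] <- l;  Q[3, 4] <- b
    Q[4, 2] <- l;  Q[4, 3] <- l
  } else {
    Q[1, 2] <- params$k10 * L; Q[1, 3] <- params$k01 * L
    Q[2, 1] <- params$l10;     Q[2, 4] <- params$k01 * L
    Q[3, 1] <- params$l01;     Q[3, 4] <- params$k10 * L
    Q[4, 2] <- params$l01;     Q[4, 3] <- params$l10
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## transition matrices exp(Q * dt) for all dt, via the detailed-balance
## symmetrisation (the chain is reversible, so eigenvalues are real)
.transition_mats <- function(Q, dts) {
  ## stationary weights from detailed balance, state 1 as reference
  w <- c(1,
         Q[1, 2] / Q[2, 1],
         Q[1, 3] / Q[3, 1],
         (Q[1, 2] / Q[2, 1]) * (Q[2, 4] / Q[4, 2]))
  s <- sqrt(w)
  S <- Q * outer(s, 1 / s)
  S <- (S + t(S)) / 2                   # symmetric up to roundoff
  eg <- eigen(S, symmetric = TRUE)
  V <- eg$vectors
  left <- (1 / s) * V                   # D^-1/2 V
  right <- t(V * s)                     # V' D^1/2
  lapply(dts, function(dt) {
    P <- left %*% (exp(eg$values * dt) * right)
    P[P < 0] <- 0
    P / rowSums(P)
  })
}

#' Stochastic simulation of a binding model (Gillespie-equivalent)
#'
#' Simulates the chemical master equation of the four receptor
#' configurations (empty, site-10 bound, site-01 bound, doubly bound) at
#' constant ligand concentration per dose, for a finite receptor copy
#' number `R0`. The default `method = "exact"` draws the state counts at
#' each observation time from the exact transition probabilities of the
#' Markov jump process (matrix exponential of the generator over each
#' inter-observation interval, multinomial propagation of counts); this is
#' identical in distribution to running Gillespie's direct-method SSA and
#' recording at the grid times, at a cost independent of the number of
#' reaction events. `method = "direct"` runs the literal event-by-event
#' SSA and is used as a cross-check (slow for fast rates or long horizons).
#'
#' @param params `nc_params` or `ib_params`.
#' @param grid a [simulation_grid()] with finite `R0`.
#' @param seed integer RNG seed (required, for reproducibility).
#' @param method `"exact"` (default) or `"direct"`.
#' @param replicates number of independent realisations to average
#'   (default 1, matching a single experimental run).
#' @param max_events safety cap on events per dose for `method = "direct"`.
#' @return A [timecourse_dataset()] with `stochastic = TRUE`.
#' @examples
#' g <- simulation_grid(dose_grid_log(8), time_grid_log(9), R0 = 100)
#' sim <- simulate_gillespie(nc_params(1, 1, 0.5), g, seed = 1)
#' @export
simulate_gillespie <- function(params, grid, seed,
                               method = c("exact", "direct"),
                               replicates = 1, max_events = 5e7) {
  stopifnot(inherits(params, "binding_params"), inherits(grid, "sim_grid"))
  method <- match.arg(method)
  if (!is.finite(grid$R0)) stop("R0 must be finite for stochastic simulation")
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is required")
  R0 <- as.integer(grid$R0)
  doses <- grid$doses; times <- grid$times
  set.seed(as.integer(seed))
  acc <- matrix(0, length(doses), length(times))
  for (r in seq_len(replicates)) {
    for (i in seq_along(doses)) {
      Q <- .binding_generator(params, doses[i])
      occ <- if (method == "exact") {
        .ssa_exact_one(Q, R0, times)
      } else {
        .ssa_direct_one(Q, R0, times, max_events)
      }
      acc[i, ] <- acc[i, ] + occ
    }
  }
  timecourse_dataset(acc / replicates, doses, times, R0 = R0,
                     model = if (inherits(params, "nc_params")) "nc" else "ib",
                     params = params, seed = as.integer(seed),
                     stochastic = TRUE)
}

## exact interval sampling: counts n (length 4) propagated by multinomials
.ssa_exact_one <- function(Q, R0, times) {
  t_in <- times
  prepend <- t_in[1] > 0
  if (prepend) t_in <- c(0, t_in)
  dts <- diff(t_in)
  Ps <- .transition_mats(Q, dts)
  n <- c(R0, 0L, 0L, 0L)
  occ <- numeric(length(t_in))
  occ[1] <- 0
  for (j in seq_along(dts)) {
    P <- Ps[[j]]
    nn <- integer(4)
    for (s in 1:4) {
      if (n[s] > 0) nn <- nn + as.integer(stats::rmultinom(1, n[s], P[s, ]))
    }
    n <- nn
    occ[j + 1] <- (n[2] + n[3] + 2 * n[4]) / (2 * R0)
  }
  if (prepend) occ <- occ[-1]
  occ
}

## literal direct-method SSA over aggregated state counts
.ssa_direct_one <- function(Q, R0, times, max_events) {
  moves <- which(Q > 0, arr.ind = TRUE)
  rates <- Q[moves]
  n <- c(R0, 0L, 0L, 0L)
  t_now <- 0
  occ <- numeric(length(times))
  j <- 1L
  while (j <= length(times) && times[j] <= 0) {
    occ[j] <- (n[2] + n[3] + 2 * n[4]) / (2 * R0)
    j <- j + 1L
  }
  ev <- 0L
  while (j <= length(times)) {
    prop <- rates * n[moves[, 1]]
    tot <- sum(prop)
    t_next <- if (tot > 0) t_now + stats::rexp(1, tot) else Inf
    while (j <= length(times) && times[j] < t_next) {
      occ[j] <- (n[2] + n[3] + 2 * n[4]) / (2 * R0)
      j <- j + 1L
    }
    if (j > length(times) || !is.finite(t_next)) break
    t_now <- t_next
    pick <- sample.int(length(prop), 1, prob = prop)
    n[moves[pick, 1]] <- n[moves[pick, 1]] - 1L
    n[moves[pick, 2]] <- n[moves[pick, 2]] + 1L
    ev <- ev + 1L
    if (ev > max_events) stop("direct SSA exceeded max_events; use method = 'exact'")
  }
  while (j <= length(times)) {          # unreachable absorbing guard
    occ[j] <- (n[2] + n[3] + 2 * n[4]) / (2 * R0)
    j <- j + 1L
  }
  occ
}

#' Moving-average smoothing of a dose-response curve
#'
#' Centred moving average over a curve ordered by (log) dose, with the
#' window shrinking symmetrically at the boundaries (the behaviour of the
#' classic `smooth` span filter). Used to reduce stochastic noise in
#' `theta(L, t0)` before extracting EC levels.
#'
#' @param y numeric curve values (ordered by dose).
#' @param window odd positive integer window width (default 5);
#'   `window = 1` is the identity.
#' @return Smoothed numeric vector, same length as `y`.
#' @examples
#' smooth_dose_curve(c(0, 0.2, 0.1, 0.6, 0.9), 3)
#' @export
smooth_dose_curve <- function(y, window = 5) {
  stopifnot(is.numeric(y), length(y) >= 1)
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window %% 2 != 1) {
    stop("window must be a positive odd integer")
  }
  n <- length(y)
  if (window > n) stop("window larger than the curve length")
  if (window == 1) return(y)
  k <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    h <- min(k, i - 1, n - i)
    mean(y[(i - h):(i + h)])
  }, numeric(1))
}
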