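#' coopdiscern: telling negative cooperativity from independent binding sites
#'
#' A receptor with two ligand-binding sites can produce a graded equilibrium
#' dose-response curve either because its two identical sites interact with
#' negative cooperativity (NC) or because the two sites are independent but
#' have different affinities (IB). The two mechanisms give *identical*
#' equilibrium curves whenever the cooperativity factor satisfies
#' `omega < 1`, so equilibrium data alone cannot separate them. They differ
#' before equilibrium: the dynamic range of the dose-response curve,
#' `DynR(t) = log10(EC90(t)/EC10(t))`, evolves in time in mechanism-specific
#' ways. This package simulates both mechanisms, extracts `DynR(t)` and its
#' diagnostic features, and runs a sequential discrimination algorithm
#' (constrained kinetic fits plus database checkpoints) that returns an
#' audited IB/NC verdict.
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Parameters of the negative-cooperativity (NC) binding model
#'
#' The NC receptor has two identical sites with association rate `k`
#' (1/(concentration x time)) and dissociation rate `l` (1/time); once one
#' site is occupied, the association rate of the second becomes `omega * k`.
#' `omega < 1` is negative cooperativity, `omega = 1` reduces to identical
#' independent sites. The macroscopic dissociation constant is `K = l / k`.
#'
#' @param k association rate of the first binding (> 0).
#' @param l dissociation rate of either site (> 0).
#' @param omega dimensionless cooperativity factor (> 0).
#' @return An object of class `nc_params` with fields `k`, `l`, `omega` and
#'   the derived `K = l/k`.
#' @examples
#' p <- nc_params(k = 1, l = 1, omega = 0.5)
#' p$K
#' @export
nc_params <- function(k, l, omega) {
  .check_scalar_pos(k, "k")
  .check_scalar_pos(l, "l")
  .check_scalar_pos(omega, "omega")
  structure(list(k = k, l = l, omega = omega, K = l / k),
            class = c("nc_params", "binding_params"))
}

#' Parameters of the independent-binding (IB) model
#'
#' Two non-interacting sites, labelled 10 and 01, with association rates
#' `k10`, `k01` and dissociation rates `l10`, `l01`. Swapping the two labels
#' yields an equivalent model (reflection symmetry). Derived dissociation
#' constants are `K10 = l10/k10` and `K01 = l01/k01`.
#'
#' @param k10,k01 association rates (> 0).
#' @param l10,l01 dissociation rates (> 0).
#' @return An object of class `ib_params` with the four rates and derived
#'   `K10`, `K01`.
#' @examples
#' ib_params(1, 2, 1, 0.5)
#' @export
ib_params <- function(k10, k01, l10, l01) {
  .check_scalar_pos(k10, "k10")
  .check_scalar_pos(k01, "k01")
  .check_scalar_pos(l10, "l10")
  .check_scalar_pos(l01, "l01")
  structure(list(k10 = k10, k01 = k01, l10 = l10, l01 = l01,
                 K10 = l10 / k10, K01 = l01 / k01),
            class = c("ib_params", "binding_params"))
}

#' @export
print.nc_params <- function(x, ...) {
  cat(sprintf("NC binding model: k = %g, l = %g, omega = %g (K = %g)\n",
              x$k, x$l, x$omega, x$K))
  invisible(x)
}

#' @export
print.ib_params <- function(x, ...) {
  cat(sprintf(
    "IB binding model: k10 = %g, l10 = %g (K10 = %g); k01 = %g, l01 = %g (K01 = %g)\n",
    x$k10, x$l10, x$K10, x$k01, x$l01, x$K01))
  invisible(x)
}

#' Equilibrium occupancy of the IB model
#'
#' Fraction of occupied sites at equilibrium for two independent sites: the
#' average of two Langmuir isotherms,
#' `theta = 0.5 * (L/(K10 + L) + L/(K01 + L))`.
#'
#' @param L ligand concentration(s), >= 0 (vectorised).
#' @param K10,K01 dissociation constants (> 0).
#' @return Occupancy fraction(s) in `[0, 1]`.
#' @examples
#' theta_eq_ib(1, 1, 1)  # 0.5
#' @export
theta_eq_ib <- function(L, K10, K01) {
  .check_scalar_pos(K10, "K10")
  .check_scalar_pos(K01, "K01")
  stopifnot(is.numeric(L), all(L >= 0))
  0.5 * (L / (K10 + L) + L / (K01 + L))
}

#' Equilibrium occupancy of the NC model
#'
#' Fraction of occupied sites at equilibrium for two identical sites with
#' cooperativity factor `omega`:
#' `theta = (K*L + omega*L^2) / (K^2 + 2*K*L + omega*L^2)`.
#'
#' @param L ligand concentration(s), >= 0 (vectorised).
#' @param K dissociation constant of the first binding (> 0).
#' @param omega cooperativity factor (> 0).
#' @return Occupancy fraction(s) in `[0, 1]`.
#' @examples
#' theta_eq_nc(1, 1, 0.5)
#' @export
theta_eq_nc <- function(L, K, omega) {
  .check_scalar_pos(K, "K")
  .check_scalar_pos(omega, "omega")
  stopifnot(is.numeric(L), all(L >= 0))
  (K * L + omega * L^2) / (K^2 + 2 * K * L + omega * L^2)
}

#' Equilibrium occupancy for a parameter object
#'
#' @param params an `nc_params` or `ib_params` object.
#' @param L ligand concentration(s).
#' @return Occupancy fraction(s).
#' @export
theta_eq <- function(params, L) UseMethod("theta_eq")

#' @export
theta_eq.nc_params <- function(params, L) theta_eq_nc(L, params$K, params$omega)

#' @export
theta_eq.ib_params <- function(params, L) theta_eq_ib(L, params$K10, params$K01)

#' Map NC dissociation constants to the equivalent IB pair
#'
#' For `omega < 1` there is a unique (up to site relabelling) pair of
#' independent-site dissociation constants with exactly the same equilibrium
#' dose-response curve, obtained from the non-identifiability conditions
#' `K10 * K01 = K^2 / omega` and `(K10 + K01)/2 = K / omega`:
#' `K10 = (K/omega) * (1 + sqrt(1 - omega))`,
#' `K01 = (K/omega) * (1 - sqrt(1 - omega))`.
#' For `omega > 1` the roots are complex and no IB counterpart exists
#' (positive cooperativity cannot be mimicked by independent sites).
#' The returned pair is canonically ordered with `K10 >= K01`.
#'
#' @param K NC dissociation constant (> 0).
#' @param omega cooperativity factor in `(0, 1]`.
#' @return Named numeric vector `c(K10 = , K01 = )`.
#' @examples
#' nc_to_ib(1, 0.5)
#' @export
nc_to_ib <- function(K, omega) {
  .check_scalar_pos(K, "K")
  .check_scalar_pos(omega, "omega")
  if (omega > 1) {
    stop(errorCondition(
      sprintf("omega = %g > 1: the roots are complex, no IB counterpart exists",
              omega),
      class = c("coop_identifiability_error", "error", "condition")))
  }
  s <- sqrt(1 - omega)
  c(K10 = (K / omega) * (1 + s), K01 = (K / omega) * (1 - s))
}

#' Map IB dissociation constants to the effective NC pair
#'
#' Inverse of [nc_to_ib()]: `K = 2*K10*K01/(K10 + K01)` (harmonic mean) and
#' `omega = 4*K10*K01/(K10 + K01)^2`. By the AM-GM inequality the effective
#' cooperativity factor always lies in `(0, 1]`, with equality iff
#' `K10 = K01`.
#'
#' @param K10,K01 dissociation constants (> 0).
#' @return Named numeric vector `c(K = , omega = )`.
#' @examples
#' ib_to_nc(9, 1)  # K = 1.8, omega = 0.36
#' @export
ib_to_nc <- function(K10, K01) {
  .check_scalar_pos(K10, "K10")
  .check_scalar_pos(K01, "K01")
  s <- K10 + K01
  c(K = 2 * K10 * K01 / s, omega = 4 * K10 * K01 / s^2)
}

#' Serialize binding parameters to JSON
#'
#' Writes a JSON object with an explicit `"model"` variant tag (`"NC"` or
#' `"IB"`) so parameter files are self-describing.
#'
#' @param params an `nc_params` or `ib_params` object.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly if written to file.
#' @export
params_to_json <- function(params, path = NULL) {
  tag <- if (inherits(params, "nc_params")) "NC" else if
    (inherits(params, "ib_params")) "IB" else
      stop("not a binding parameter object")
  obj <- c(list(model = tag), unclass(params))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read binding parameters from JSON
#'
#' @param path file path or a JSON string produced by [params_to_json()].
#' @return An `nc_params` or `ib_params` object, according to the `"model"`
#'   tag.
#' @export
params_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$model)) stop("JSON is missing the 'model' variant tag")
  switch(toupper(obj$model),
    NC = nc_params(obj$k, obj$l, obj$omega),
    IB = ib_params(obj$k10, obj$k01, obj$l10, obj$l01),
    stop(sprintf("unknown model tag '%s'", obj$model)))
}
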