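# Gas constant in kcal/(mol K); activation energies are reported in kcal/mol
# throughout, so all Arrhenius exponents are formed on that scale.
R_GAS_KCAL <- 1.98720425e-3

# Intended storage condition, 5 degrees Celsius, in Kelvin.
T_REF_DEFAULT <- 278.15

#' Convert between Celsius and Kelvin
#'
#' Stability files carry storage temperatures in degrees Celsius; all rate-law
#' computations run in Kelvin.
#'
#' @param temp_c,temp_k temperature in degrees Celsius / Kelvin.
#' @return numeric vector of converted temperatures.
#' @export
celsius_to_kelvin <- function(temp_c) temp_c + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(temp_k) temp_k - 273.15

#' Kinetic parameters of the first-order degradation model
#'
#' Bundles the three free parameters of the model: the activation energy
#' `Ea` (kcal/mol), the degradation rate constant `k_ref` (1/month) at the
#' reference temperature `T_ref` (Kelvin, default 278.15 K, i.e. the intended
#' 5 degree storage condition), and the fitted initial level `level0`
#' (percent of total; the initial purity for decreasing attributes or the
#' initial impurity level for increasing ones).
#'
#' @param Ea activation energy, kcal/mol; must be >= 0.
#' @param k_ref rate constant at `T_ref`, 1/month; must be >= 0.
#' @param level0 initial level, percent in \[0, 100\].
#' @param T_ref reference temperature, Kelvin.
#' @return an object of class `kinetic_params`.
#' @examples
#' kinetic_params(Ea = 25, k_ref = 3e-4, level0 = 10)
#' @export
kinetic_params <- function(Ea, k_ref, level0, T_ref = T_REF_DEFAULT) {
  stopifnot(length(Ea) == 1, length(k_ref) == 1, length(level0) == 1)
  if (!is.finite(Ea) || Ea < 0) stop("'Ea' must be a finite value >= 0")
  if (!is.finite(k_ref) || k_ref < 0) stop("'k_ref' must be a finite value >= 0")
  if (!is.finite(level0) || level0 < 0 || level0 > 100)
    stop("'level0' must lie in [0, 100] percent")
  if (!is.finite(T_ref) || T_ref <= 0) stop("'T_ref' must be positive (Kelvin)")
  structure(
    list(Ea = Ea, k_ref = k_ref, level0 = level0, T_ref = T_ref),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (first-order Arrhenius model)\n")
  cat(sprintf("  Ea     : %.4g kcal/mol\n", x$Ea))
  cat(sprintf("  k(Tref): %.4g /month at %.2f K (%.1f C)\n",
              x$k_ref, x$T_ref, kelvin_to_celsius(x$T_ref)))
  cat(sprintf("  level0 : %.4g %%\n", x$level0))
  invisible(x)
}

#' Arrhenius rate constant
#'
#' Temperature dependence of the degradation rate constant in the
#' reference-temperature parameterization used for fitting:
#' `k(T) = k_ref * exp(-(Ea/R) * (1/T - 1/T_ref))`. This is algebraically
#' identical to the frequency-factor form (see [arrhenius_rate_classic()])
#' with `A_f = k_ref * exp(Ea / (R * T_ref))`, but better conditioned
#' numerically because `k_ref` is on the scale of the data.
#'
#' @param temp_k absolute temperature(s), Kelvin; must be > 0.
#' @param params a [kinetic_params()] object.
#' @return rate constant(s), 1/month.
#' @export
arrhenius_rate <- function(temp_k, params) {
  if (any(!is.finite(temp_k)) || any(temp_k <= 0))
    stop("temperature must be positive (Kelvin)")
  params$k_ref * exp(-(params$Ea / R_GAS_KCAL) * (1 / temp_k - 1 / params$T_ref))
}

#' Arrhenius rate constant, frequency-factor form
#'
#' The classical parameterization `k(T) = A_f * exp(-Ea / (R * T))`.
#' Kept alongside [arrhenius_rate()] so the equivalence of the two
#' parameterizations can be asserted; fitting always uses the
#' reference-temperature form.
#'
#' @param temp_k absolute temperature(s), Kelvin.
#' @param A_f frequency factor, 1/month.
#' @param Ea activation energy, kcal/mol.
#' @return rate constant(s), 1/month.
#' @export
arrhenius_rate_classic <- function(temp_k, A_f, Ea) {
  if (any(!is.finite(temp_k)) || any(temp_k <= 0))
    stop("temperature must be positive (Kelvin)")
  A_f * exp(-Ea / (R_GAS_KCAL * temp_k))
}

#' Frequency factor implied by a reference-temperature parameterization
#'
#' @param params a [kinetic_params()] object.
#' @return `A_f = k_ref * exp(Ea / (R * T_ref))`, 1/month.
#' @export
frequency_factor <- function(params) {
  params$k_ref * exp(params$Ea / (R_GAS_KCAL * params$T_ref))
}

#' First-order degradation trajectories
#'
#' Closed-form solutions of the first-order degradation model on the percent
#' scale. For a decreasing (purity-like) attribute the level follows
#' `A(t, T) = level0 * exp(-k(T) t)`. For an increasing (impurity-like)
#' attribute, conservation of total material gives
#' `B(t, T) = 100 - (100 - level0) * exp(-k(T) t)`, which rises monotonically
#' towards the 100% asymptote. `trajectory()` dispatches on `direction`.
#'
#' @param t time(s), months; must be >= 0.
#' @param temp_k absolute temperature(s), Kelvin.
#' @param params a [kinetic_params()] object; `level0` is the initial purity
#'   for `purity_trajectory()` and the initial impurity for
#'   `impurity_trajectory()`.
#' @param direction `"decreasing"` (purity-like) or `"increasing"`
#'   (impurity-like).
#' @return predicted level(s), percent.
#' @examples
#' p <- kinetic_params(Ea = 22, k_ref = 1.3e-4, level0 = 0.5)
#' impurity_trajectory(c(0, 12, 36), celsius_to_kelvin(5), p)
#' @export
purity_trajectory <- function(t, temp_k, params) {
  if (any(!is.finite(t)) || any(t < 0)) stop("time must be >= 0 months")
  params$level0 * exp(-arrhenius_rate(temp_k, params) * t)
}

#' @rdname purity_trajectory
#' @export
impurity_trajectory <- function(t, temp_k, params) {
  if (any(!is.finite(t)) || any(t < 0)) stop("time must be >= 0 months")
  100 - (100 - params$level0) * exp(-arrhenius_rate(temp_k, params) * t)
}

#' @rdname purity_trajectory
#' @export
trajectory <- function(t, temp_k, params, direction) {
  direction <- match.arg(direction, c("increasing", "decreasing"))
  if (direction == "increasing") impurity_trajectory(t, temp_k, params)
  else purity_trajectory(t, temp_k, params)
}
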