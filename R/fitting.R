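#' Parameter bounds for the kinetic fit
#'
#' Box constraints for the bounded Levenberg-Marquardt solver. The defaults
#' comfortably cover activation energies observed for mAb degradation
#' processes (roughly 20-45 kcal/mol) and any physically plausible rate at
#' the 5 degree reference condition.
#'
#' @param Ea,k_ref,level0 length-2 numeric `c(lower, upper)` vectors for the
#'   activation energy (kcal/mol), reference rate (1/month) and initial level
#'   (percent).
#' @return list of bounds.
#' @export
kinetic_bounds <- function(Ea = c(0, 100), k_ref = c(0, 10),
                           level0 = c(0, 100)) {
  b <- list(Ea = Ea, k_ref = k_ref, level0 = level0)
  for (nm in names(b))
    if (length(b[[nm]]) != 2 || diff(b[[nm]]) <= 0)
      stop("bound for '", nm, "' must be c(lower, upper) with lower < upper")
  b
}

#' Default starting values for the kinetic fit
#'
#' Ea starts at 20 kcal/mol; the initial level starts at the t = 0
#' measurement (mean of t = 0 rows, or the overall mean when no t = 0 row
#' exists); the reference rate starts from a two-point log-linear estimate of
#' the rate at the highest temperature, translated to the reference
#' temperature through the starting Ea.
#'
#' @param dataset a [stability_dataset()].
#' @param T_ref reference temperature, Kelvin.
#' @return a [kinetic_params()] starting point.
#' @export
kinetic_start <- function(dataset, T_ref = T_REF_DEFAULT) {
  m <- dataset$measurements
  ea0 <- 20
  y0 <- if (any(m$time == 0)) mean(m$value[m$time == 0]) else mean(m$value)
  y0 <- min(max(y0, 0), 100)
  hi <- max(m$temperature[m$time > 0])
  sub <- m[m$temperature == hi & m$time > 0, , drop = FALSE]
  t_last <- max(sub$time)
  y_last <- mean(sub$value[sub$time == t_last])
  k_hi <- if (dataset$direction == "increasing") {
    num <- 100 - y_last; den <- 100 - y0
    if (num > 0 && den > 0 && num < den) -log(num / den) / t_last else 1e-4
  } else {
    if (y_last > 0 && y0 > 0 && y_last < y0) -log(y_last / y0) / t_last else 1e-4
  }
  k_hi <- min(max(k_hi, 1e-8), 10)
  t_hi <- celsius_to_kelvin(hi)
  k_ref0 <- k_hi * exp((ea0 / R_GAS_KCAL) * (1 / t_hi - 1 / T_ref))
  k_ref0 <- min(max(k_ref0, 1e-10), 10)
  kinetic_params(Ea = ea0, k_ref = k_ref0, level0 = y0, T_ref = T_ref)
}

# Residuals y - p(theta) and their analytic Jacobian for nls.lm.
# theta = c(Ea, k_ref, level0); t, temp_k, y are the measurement vectors.
.kin_residuals <- function(theta, t, temp_k, y, T_ref, increasing) {
  k <- theta[2] * exp(-(theta[1] / R_GAS_KCAL) * (1 / temp_k - 1 / T_ref))
  e <- exp(-k * t)
  p <- if (increasing) 100 - (100 - theta[3]) * e else theta[3] * e
  y - p
}

.kin_jacobian <- function(theta, t, temp_k, y, T_ref, increasing) {
  invdiff <- 1 / temp_k - 1 / T_ref
  k <- theta[2] * exp(-(theta[1] / R_GAS_KCAL) * invdiff)
  e <- exp(-k * t)
  dk_dEa <- -k * invdiff / R_GAS_KCAL
  dk_dkref <- if (theta[2] > 0) k / theta[2] else
    exp(-(theta[1] / R_GAS_KCAL) * invdiff)
  if (increasing) {
    # p = 100 - (100 - L) e^{-kt}
    dp_dk <- (100 - theta[3]) * t * e
    dp_dL <- e
  } else {
    # p = L e^{-kt}
    dp_dk <- -theta[3] * t * e
    dp_dL <- e
  }
  # residual = y - p, so the Jacobian is -dp/dtheta
  cbind(-(dp_dk * dk_dEa), -(dp_dk * dk_dkref), -dp_dL)
}

#' Joint multi-temperature kinetic fit
#'
#' Estimates the activation energy, reference-temperature rate constant and
#' initial level of the first-order degradation model by nonlinear least
#' squares over all measurements at all temperatures simultaneously. A single
#' model is fitted jointly in time and temperature via the Arrhenius
#' relation, which is what makes extrapolation beyond the measured window
#' robust. The single t = 0 measurement enters the residual sum once. The
#' solver is bounded Levenberg-Marquardt ([minpack.lm::nls.lm()]) with an
#' analytic Jacobian; on non-convergence up to `n_restarts` deterministic
#' jittered restarts are attempted and the best converged solution kept.
#'
#' @param dataset a [stability_dataset()] with at least 3 distinct
#'   temperatures among the t > 0 measurements and at least 4 points overall.
#' @param bounds from [kinetic_bounds()].
#' @param start optional [kinetic_params()] starting point; default
#'   [kinetic_start()].
#' @param T_ref reference temperature, Kelvin (default 278.15 K = 5 C).
#' @param n_restarts maximum jittered restarts on non-convergence.
#' @return object of class `kinetic_fit`: fields `params`
#'   ([kinetic_params()]), `r2`, `ss_res`, `n_points`, `temperatures_used`
#'   (Celsius), `converged`, `direction`, `message`.
#' @examples
#' study <- simulate_study(preset("classic"))
#' fit <- fit_kinetic(restrict_dataset(study$datasets[[1]], max_time = 6))
#' fit
#' @export
fit_kinetic <- function(dataset, bounds = kinetic_bounds(), start = NULL,
                        T_ref = T_REF_DEFAULT, n_restarts = 10) {
  stopifnot(inherits(dataset, "stability_dataset"))
  m <- dataset$measurements
  temps <- sort(unique(m$temperature[m$time > 0]))
  if (length(temps) < 3)
    stop("kinetic fitting requires measurements at >= 3 distinct temperatures",
         " (got ", length(temps), ")")
  if (nrow(m) < 4)
    stop("kinetic fitting requires >= 4 measurements including t = 0")
  if (is.null(start)) start <- kinetic_start(dataset, T_ref)
  increasing <- dataset$direction == "increasing"
  t <- m$time
  temp_k <- celsius_to_kelvin(m$temperature)
  y <- m$value
  lower <- vapply(bounds, `[`, 0, 1)
  upper <- vapply(bounds, `[`, 0, 2)
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-13,
                                     gtol = 0, maxiter = 1000)

  run <- function(theta0) {
    theta0 <- pmin(pmax(theta0, lower), upper)
    minpack.lm::nls.lm(
      par = theta0, lower = lower, upper = upper,
      fn = .kin_residuals, jac = .kin_jacobian,
      t = t, temp_k = temp_k, y = y, T_ref = T_ref, increasing = increasing,
      control = ctrl
    )
  }

  theta0 <- c(start$Ea, start$k_ref, start$level0)
  best <- run(theta0)
  # info codes 1-4 indicate convergence in ftol/xtol/gtol terms
  ok <- function(f) f$info %in% 1:4
  if (!ok(best) && n_restarts > 0) {
    # deterministic jitter grid over rate scale and activation energy
    grid <- expand.grid(kf = c(0.01, 0.1, 10, 100, 1),
                        ea = c(10, 30, 50, 20, 5))
    for (i in seq_len(min(n_restarts, nrow(grid)))) {
      cand <- run(c(grid$ea[i], theta0[2] * grid$kf[i], theta0[3]))
      if (ok(cand) && (!ok(best) || cand$deviance < best$deviance)) best <- cand
      if (ok(best)) break
    }
  }
  theta <- best$par
  pred <- y - .kin_residuals(theta, t, temp_k, y, T_ref, increasing)
  structure(
    list(
      params = kinetic_params(theta[1], theta[2], theta[3], T_ref),
      r2 = goodness_of_fit(y, pred),
      ss_res = best$deviance,
      n_points = nrow(m),
      temperatures_used = sort(unique(m$temperature)),
      converged = ok(best),
      direction = dataset$direction,
      message = best$message
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit (%s attribute), %d points at %s C\n",
              x$direction, x$n_points,
              paste(x$temperatures_used, collapse = "/")))
  cat(sprintf("  Ea = %.4g kcal/mol, k(Tref) = %.4g /month, level0 = %.4g %%\n",
              x$params$Ea, x$params$k_ref, x$params$level0))
  cat(sprintf("  R2 = %.6g, SSres = %.4g, converged: %s\n",
              x$r2, x$ss_res, x$converged))
  invisible(x)
}

#' Predicted trajectory from a kinetic fit
#'
#' @param fit a `kinetic_fit`.
#' @param t times, months.
#' @param temperature storage temperature, Celsius.
#' @return predicted levels, percent.
#' @export
predict_kinetic <- function(fit, t, temperature) {
  stopifnot(inherits(fit, "kinetic_fit"))
  trajectory(t, celsius_to_kelvin(temperature), fit$params, fit$direction)
}

#' Coefficient of determination
#'
#' `R2 = 1 - SS_res / SS_tot`, the normalised goodness-of-fit score with
#' maximum 1 when the model reproduces the measurements exactly. Computed
#' over all fitted points pooled across temperatures. When all measurements
#' are identical (`SS_tot = 0`) the score is undefined and `NA` is returned
#' rather than a division error.
#'
#' @param measurements observed values.
#' @param predictions model values, same length.
#' @return R-squared, or `NA_real_` when undefined.
#' @export
goodness_of_fit <- function(measurements, predictions) {
  if (length(measurements) != length(predictions))
    stop("'measurements' and 'predictions' must have equal length")
  if (length(measurements) < 2)
    stop("R2 requires at least 2 measurements")
  ss_tot <- sum((measurements - mean(measurements))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((measurements - predictions)^2) / ss_tot
}
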