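#' ICH-style linear regression at the intended storage condition
#'
#' Ordinary least squares of the measured level against time using only the
#' data at one storage temperature (default the intended 5 C condition),
#' the baseline shelf-life model of ICH stability evaluation. The shared
#' t = 0 measurement belongs to every temperature series and is included.
#'
#' @param dataset a [stability_dataset()].
#' @param temperature storage temperature whose series is fitted, Celsius.
#' @return object of class `linear_fit`: `intercept` (percent), `slope`
#'   (percent/month), `residual_sd`, `n`, `x_mean`, `s_xx`, `temperature`.
#' @examples
#' study <- simulate_study(preset("classic"))
#' fit_linear(study$datasets[[1]])
#' @export
fit_linear <- function(dataset, temperature = 5) {
  stopifnot(inherits(dataset, "stability_dataset"))
  m <- dataset$measurements
  sel <- m$temperature == temperature | m$time == 0
  t <- m$time[sel]
  y <- m$value[sel]
  n <- length(t)
  if (n < 3)
    stop("linear fit requires >= 3 points at ", temperature, " C (got ", n, ")")
  s_xx <- sum((t - mean(t))^2)
  if (s_xx == 0) stop("degenerate design: all pull times identical")
  slope <- sum((t - mean(t)) * (y - mean(y))) / s_xx
  intercept <- mean(y) - slope * mean(t)
  resid <- y - (intercept + slope * t)
  structure(
    list(intercept = intercept, slope = slope,
         residual_sd = sqrt(sum(resid^2) / (n - 2)),
         n = n, x_mean = mean(t), s_xx = s_xx, temperature = temperature),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit at %g C: level = %.4g %+.4g * t (months), n = %d\n",
              x$temperature, x$intercept, x$slope, x$n))
  cat(sprintf("  residual sd %.4g %%\n", x$residual_sd))
  invisible(x)
}

#' Prediction interval of the linear baseline
#'
#' Two-sided pointwise prediction interval for a future individual
#' measurement under the OLS model: central value `intercept + slope * t`
#' with half-width `qt((1+level)/2, n-2) * residual_sd *
#' sqrt(1 + 1/n + (t - x_mean)^2 / s_xx)`. The interval is symmetric about
#' the central line and widens with distance from the design centre.
#'
#' @param fit a [fit_linear()] result.
#' @param t time(s), months.
#' @param level probability (default 0.95).
#' @return data.frame with columns `time`, `lower`, `central`, `upper`.
#' @export
linear_prediction_interval <- function(fit, t, level = 0.95) {
  stopifnot(inherits(fit, "linear_fit"))
  if (fit$n < 3) stop("prediction interval requires n >= 3")
  central <- fit$intercept + fit$slope * t
  half <- qt((1 + level) / 2, df = fit$n - 2) * fit$residual_sd *
    sqrt(1 + 1 / fit$n + (t - fit$x_mean)^2 / fit$s_xx)
  data.frame(time = t, lower = central - half, central = central,
             upper = central + half)
}

#' Head-to-head comparison: kinetic model versus linear extrapolation
#'
#' Fits both models on data up to `cut_months` (the kinetic model uses all
#' temperatures; the linear baseline uses the target-temperature series
#' only), evaluates both 95% bands at the horizon and reports their widths
#' and ratio. This is the comparison behind the claim that Arrhenius kinetic
#' modelling yields usable shelf-life intervals many months earlier than
#' linear extrapolation.
#'
#' @param dataset a [stability_dataset()] with multi-temperature data through
#'   `cut_months` and a target-temperature series.
#' @param cut_months training cut-off, months (e.g. 3, 6, 12, 18, 24).
#' @param horizon evaluation time, months (default 36).
#' @param target_temp target storage temperature, Celsius.
#' @param level band probability.
#' @param n_replicates Monte-Carlo replicates for the kinetic band.
#' @param seed seed for the kinetic band.
#' @return object of class `model_comparison`: `cut_months`, `horizon`,
#'   `kinetic` and `linear` sub-records (each with `lower`, `upper`, `width`
#'   at the horizon, or a `reason` string when that arm is ineligible) and
#'   `ratio_kinetic_over_linear`.
#' @export
compare_kinetic_vs_linear <- function(dataset, cut_months, horizon = 36,
                                      target_temp = 5, level = 0.95,
                                      n_replicates = 399, seed = 1) {
  stopifnot(inherits(dataset, "stability_dataset"))
  train <- restrict_dataset(dataset, max_time = cut_months)

  kin <- tryCatch({
    band <- monte_carlo_band(train, target_temp = target_temp,
                             horizon = horizon, level = level,
                             n_replicates = n_replicates, seed = seed)
    e <- evaluate_band(band, horizon)
    list(lower = e$lower, upper = e$upper, width = e$upper - e$lower)
  }, error = function(e) list(reason = conditionMessage(e)))

  lin <- tryCatch({
    f <- fit_linear(train, temperature = target_temp)
    pi <- linear_prediction_interval(f, horizon, level)
    list(lower = pi$lower, upper = pi$upper, width = pi$upper - pi$lower)
  }, error = function(e) list(reason = conditionMessage(e)))

  ratio <- if (!is.null(kin$width) && !is.null(lin$width) && lin$width > 0)
    kin$width / lin$width else NA_real_
  structure(
    list(cut_months = cut_months, horizon = horizon,
         target_temp = target_temp, level = level,
         kinetic = kin, linear = lin,
         ratio_kinetic_over_linear = ratio),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Kinetic vs linear at %d months (fit on <= %g months, %g C)\n",
              x$horizon, x$cut_months, x$target_temp))
  for (arm in c("kinetic", "linear")) {
    a <- x[[arm]]
    if (is.null(a$width))
      cat(sprintf("  %-7s: ineligible (%s)\n", arm, a$reason))
    else
      cat(sprintf("  %-7s: [%.4g, %.4g], width %.4g %%\n",
                  arm, a$lower, a$upper, a$width))
  }
  if (!is.na(x$ratio_kinetic_over_linear))
    cat(sprintf("  width ratio kinetic/linear: %.3g\n",
                x$ratio_kinetic_over_linear))
  invisible(x)
}
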