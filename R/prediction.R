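# Run fn() under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Monte-Carlo confidence / prediction band for the extrapolated trajectory
#'
#' Builds the 95% probability band for the trajectory at a target storage
#' temperature by parametric bootstrap: `n_replicates` perturbed copies of the
#' study are generated by adding independent Gaussian noise (sd =
#' `dataset$accuracy_sd`, the assay accuracy) to every measurement, the model
#' is refitted to each copy, and the replicate trajectories are evaluated on
#' the time grid. Pointwise 2.5th and 97.5th percentiles (for `level = 0.95`)
#' of the replicate trajectories give the confidence band; the prediction
#' band additionally adds an independent measurement-error draw to every
#' replicate trajectory point before taking percentiles, accounting for the
#' dispersion of a future individual measurement. Lower and upper bounds are
#' computed separately, so the band can be asymmetric. The single shared
#' t = 0 measurement is one row of the dataset and is therefore perturbed
#' once per replicate; perturbed values are clipped to the physical \[0, 100\]
#' percent range before refitting.
#'
#' @param dataset a [stability_dataset()] with `accuracy_sd` set.
#' @param fit a converged [fit_kinetic()] result for `dataset`; fitted here
#'   when `NULL`.
#' @param target_temp target storage temperature, Celsius (default 5).
#' @param horizon extrapolation horizon, months (default 36).
#' @param times evaluation grid, months; default monthly steps 0..horizon.
#' @param level band probability (default 0.95).
#' @param n_replicates number of perturbed datasets (default 399).
#' @param kind `"prediction"` (default) or `"confidence"`.
#' @param seed integer seed for the perturbations; with the same seed the two
#'   kinds share identical replicate fits.
#' @return object of class `prediction_band`: a data.frame with columns
#'   `time`, `central`, `lower`, `upper` and attributes `target_temp`,
#'   `level`, `kind`, `n_replicates`, `n_failed`, `accuracy_sd`, `seed`.
#'   More than 5% failed replicate fits is an error; occasional failures are
#'   dropped and counted in `n_failed`.
#' @examples
#' study <- simulate_study(preset("classic"))
#' d6 <- restrict_dataset(study$datasets[[1]], max_time = 6)
#' band <- monte_carlo_band(d6, n_replicates = 99, seed = 1)
#' evaluate_band(band, 36)
#' @export
monte_carlo_band <- function(dataset, fit = NULL, target_temp = 5,
                             horizon = 36, times = NULL, level = 0.95,
                             n_replicates = 399,
                             kind = c("prediction", "confidence"),
                             seed = 1) {
  stopifnot(inherits(dataset, "stability_dataset"))
  kind <- match.arg(kind)
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  if (is.null(fit)) fit <- fit_kinetic(dataset)
  if (!fit$converged)
    stop("kinetic fit did not converge; no band can be constructed")
  if (is.null(times)) times <- seq(0, horizon, by = 1)
  times <- sort(unique(times))
  sd <- dataset$accuracy_sd
  temp_k <- celsius_to_kelvin(target_temp)
  central <- trajectory(times, temp_k, fit$params, fit$direction)

  m <- dataset$measurements
  n <- nrow(m)
  res <- .with_seed(seed, function() {
    traj <- matrix(NA_real_, n_replicates, length(times))
    failed <- 0L
    for (r in seq_len(n_replicates)) {
      pert <- dataset
      pert$measurements$value <- pmin(pmax(m$value + rnorm(n, 0, sd), 0), 100)
      fr <- tryCatch(
        fit_kinetic(pert, start = fit$params, n_restarts = 2),
        error = function(e) NULL
      )
      if (is.null(fr) || !fr$converged) {
        failed <- failed + 1L
      } else {
        traj[r, ] <- trajectory(times, temp_k, fr$params, fr$direction)
      }
    }
    # future-measurement dispersion, drawn after all refits so that both band
    # kinds share identical replicate trajectories under the same seed
    meas <- matrix(rnorm(n_replicates * length(times), 0, sd),
                   n_replicates, length(times))
    list(traj = traj, meas = meas, failed = failed)
  })
  if (res$failed > 0.05 * n_replicates)
    stop(sprintf("%d of %d replicate fits failed (> 5%%): %s",
                 res$failed, n_replicates,
                 "prediction band not reliable for this dataset"))
  ok_rows <- !is.na(res$traj[, 1])
  samples <- if (kind == "prediction")
    res$traj[ok_rows, , drop = FALSE] + res$meas[ok_rows, , drop = FALSE]
  else res$traj[ok_rows, , drop = FALSE]
  alpha <- (1 - level) / 2
  lower <- apply(samples, 2, quantile, probs = alpha, names = FALSE)
  upper <- apply(samples, 2, quantile, probs = 1 - alpha, names = FALSE)
  band <- data.frame(time = times, central = central,
                     lower = pmin(lower, central), upper = pmax(upper, central))
  structure(band,
            class = c("prediction_band", "data.frame"),
            target_temp = target_temp, level = level, kind = kind,
            n_replicates = n_replicates, n_failed = res$failed,
            accuracy_sd = sd, seed = seed)
}

#' @export
print.prediction_band <- function(x, ...) {
  cat(sprintf("%s band (%.0f%%) at %g C, %d replicates (%d failed)\n",
              attr(x, "kind"), 100 * attr(x, "level"), attr(x, "target_temp"),
              attr(x, "n_replicates"), attr(x, "n_failed")))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ... ", nrow(x), "grid points to",
                       max(x$time), "months\n")
  invisible(x)
}

#' Evaluate a band at arbitrary times
#'
#' Linear interpolation of the central curve and both bounds between grid
#' points.
#'
#' @param band a [monte_carlo_band()] result.
#' @param t time(s), months; must lie within the band's grid range.
#' @return data.frame with columns `time`, `lower`, `central`, `upper`.
#' @export
evaluate_band <- function(band, t) {
  stopifnot(inherits(band, "prediction_band"))
  if (any(t < min(band$time)) || any(t > max(band$time)))
    stop("time outside the band's grid range [", min(band$time), ", ",
         max(band$time), "] months")
  data.frame(
    time = t,
    lower = approx(band$time, band$lower, xout = t)$y,
    central = approx(band$time, band$central, xout = t)$y,
    upper = approx(band$time, band$upper, xout = t)$y
  )
}

#' Band width at a given time
#'
#' @param band a [monte_carlo_band()] result (or any object accepted by
#'   [evaluate_band()]).
#' @param at time, months.
#' @return `upper - lower` at `at`, percent.
#' @export
band_width <- function(band, at) {
  e <- evaluate_band(band, at)
  e$upper - e$lower
}

#' Export a band to CSV
#'
#' @param band a [monte_carlo_band()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_band <- function(band, path) {
  out <- data.frame(time_months = band$time, central = band$central,
                    lower = band$lower, upper = band$upper,
                    level = attr(band, "level"), kind = attr(band, "kind"),
                    target_temperature_C = attr(band, "target_temp"))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
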