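# Effective degradation rate including an optional second pathway that is
# active above a threshold temperature: k_eff(T) = k1(T) for T <= T_switch,
# k1(T) + k_share * k1(T_switch) * exp(-(Ea_high/R)(1/T - 1/T_switch)) above.
.effective_rate <- function(temp_c, params, switch = NULL) {
  k <- arrhenius_rate(celsius_to_kelvin(temp_c), params)
  if (is.null(switch)) return(k)
  hot <- temp_c > switch$T_switch
  if (any(hot)) {
    t_sw <- celsius_to_kelvin(switch$T_switch)
    k_at_sw <- arrhenius_rate(t_sw, params)
    k2 <- switch$k_share * k_at_sw *
      exp(-(switch$Ea_high / R_GAS_KCAL) *
            (1 / celsius_to_kelvin(temp_c) - 1 / t_sw))
    k <- k + ifelse(hot, k2, 0)
  }
  k
}

.true_value <- function(t, temp_c, Ea, k_ref, level0, direction,
                        switch = NULL, T_ref = T_REF_DEFAULT) {
  p <- kinetic_params(Ea, k_ref, level0, T_ref)
  k <- .effective_rate(temp_c, p, switch)
  if (direction == "increasing") 100 - (100 - level0) * exp(-k * t)
  else level0 * exp(-k * t)
}

#' Specification of a synthetic stability study
#'
#' Defines the ground truth and design of a simulated study: the quality
#' attributes with their true kinetic parameters, the pull schedule per
#' storage temperature, assay noise, optional between-batch variability of
#' the rate constant, and an optional mechanism change (a second, steeper
#' first-order degradation pathway active above a threshold temperature,
#' which inflates the apparent activation energy of fits that include the
#' hottest conditions).
#'
#' @param attributes data.frame with columns `name`, `direction`
#'   (`"increasing"`/`"decreasing"`), `method`, `Ea` (kcal/mol), `k_ref`
#'   (1/month at 278.15 K), `level0` (percent) and optionally `accuracy_sd`
#'   (percent; defaults to the method registry value; 0 gives noise-free
#'   data).
#' @param schedule data.frame with columns `temperature` (Celsius) and `time`
#'   (months); must include time 0. The single t = 0 measurement is shared by
#'   all temperature series.
#' @param n_batches number of batches.
#' @param switch optional list `(T_switch, Ea_high, k_share)`: above
#'   `T_switch` Celsius a second pathway with activation energy `Ea_high`
#'   contributes `k_share` times the primary rate at `T_switch`.
#' @param batch_variation standard deviation of the between-batch jitter on
#'   `log(k_ref)` (production-process variability perturbs the rate, not the
#'   activation energy).
#' @param seed default RNG seed for [simulate_study()].
#' @return object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(attributes, schedule, n_batches = 1,
                                 switch = NULL, batch_variation = 0,
                                 seed = 1) {
  req <- c("name", "direction", "method", "Ea", "k_ref", "level0")
  if (!all(req %in% names(attributes)))
    stop("attributes must have columns: ", paste(req, collapse = ", "))
  if (!all(c("temperature", "time") %in% names(schedule)))
    stop("schedule must have columns temperature, time")
  if (!any(schedule$time == 0)) stop("schedule must include a t = 0 pull")
  if (any(attributes$Ea < 0) || any(attributes$k_ref < 0))
    stop("true rates and activation energies must be >= 0")
  if (length(unique(schedule$temperature)) < 3)
    stop("a fit-eligible design needs >= 3 distinct temperatures")
  if (!is.null(switch) &&
      !all(c("T_switch", "Ea_high", "k_share") %in% names(switch)))
    stop("switch must be list(T_switch, Ea_high, k_share)")
  structure(
    list(attributes = as.data.frame(attributes),
         schedule = as.data.frame(schedule),
         n_batches = as.integer(n_batches), switch = switch,
         batch_variation = batch_variation, seed = seed),
    class = "synthetic_study_spec"
  )
}

#' @export
print.synthetic_study_spec <- function(x, ...) {
  cat(sprintf("Synthetic study: %d batch(es), %d attribute(s), %d temperatures\n",
              x$n_batches, nrow(x$attributes),
              length(unique(x$schedule$temperature))))
  cat("  temperatures (C):",
      paste(sort(unique(x$schedule$temperature)), collapse = ", "), "\n")
  if (!is.null(x$switch))
    cat(sprintf("  mechanism switch above %g C (Ea_high %g kcal/mol)\n",
                x$switch$T_switch, x$switch$Ea_high))
  invisible(x)
}

#' Simulate a stability study with known ground truth
#'
#' Generates measurements from the first-order Arrhenius model (plus the
#' optional high-temperature pathway), with one shared t = 0 draw per
#' dataset, independent Gaussian assay noise at the method accuracy, and
#' values clipped to the physical \[0, 100\] percent range. Fully
#' reproducible from the seed.
#'
#' @param spec a [synthetic_study_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return list with `datasets` (named list of [stability_dataset()]),
#'   `truth` (data.frame of per-batch true parameters: `batch_id`,
#'   `attribute`, `direction`, `method`, `Ea`, `k_ref` after batch jitter,
#'   `level0`, `accuracy_sd`) and `spec`.
#' @examples
#' study <- simulate_study(preset("classic"))
#' names(study$datasets)
#' @export
simulate_study <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  acc_registry <- method_accuracies()
  sched <- spec$schedule
  t0_temp <- min(sched$temperature[sched$time == 0])
  # one shared t = 0 row; remaining schedule rows with t > 0
  rows_t0 <- data.frame(temperature = t0_temp, time = 0)
  rows_gt0 <- sched[sched$time > 0, c("temperature", "time")]

  .with_seed(seed, function() {
    datasets <- list()
    truth <- list()
    for (b in seq_len(spec$n_batches)) {
      bid <- sprintf("batch%02d", b)
      for (a in seq_len(nrow(spec$attributes))) {
        at <- spec$attributes[a, ]
        sd_a <- if ("accuracy_sd" %in% names(spec$attributes) &&
                    !is.na(at$accuracy_sd)) at$accuracy_sd
                else unname(acc_registry[[at$method]])
        if (is.null(sd_a))
          stop("method '", at$method, "' not in the accuracy registry and no ",
               "accuracy_sd given")
        k_b <- at$k_ref * exp(rnorm(1, 0, spec$batch_variation))
        rows <- rbind(rows_t0, rows_gt0)
        true_vals <- .true_value(rows$time, rows$temperature, at$Ea, k_b,
                                 at$level0, at$direction, spec$switch)
        vals <- pmin(pmax(true_vals + rnorm(nrow(rows), 0, sd_a), 0), 100)
        ds <- stability_dataset(
          batch_id = bid, attribute = at$name, direction = at$direction,
          measurements = data.frame(method = at$method,
                                    temperature = rows$temperature,
                                    time = rows$time, value = vals),
          accuracy_sd = sd_a
        )
        datasets[[paste(bid, at$name, sep = "/")]] <- ds
        truth[[length(truth) + 1L]] <- data.frame(
          batch_id = bid, attribute = at$name, direction = at$direction,
          method = at$method, Ea = at$Ea, k_ref = k_b, level0 = at$level0,
          accuracy_sd = sd_a, stringsAsFactors = FALSE)
      }
    }
    list(datasets = datasets, truth = do.call(rbind, truth), spec = spec)
  })
}

#' Built-in study designs
#'
#' Named synthetic-study specifications emulating common accelerated
#' stability designs:
#' * `"classic"` — 5/25/40 C with pulls at 0, 1, 2, 3 and 6 months plus a
#'   long-term 5 C extension (9, 12, 18, 24, 36 months) held out for
#'   verification; three attributes (SEC sum of aggregates, CEX sum of acid
#'   variants, nrCE-SDS purity) with activation energies of 22-25 kcal/mol
#'   and 5 C rates giving fractions of a percent change per year.
#' * `"rapid"` — a four-week study at 25-60 C with weekly pulls (fractional
#'   months, week = 12/52 month).
#' * `"switch"` — the rapid design extended to 7 temperatures with a second
#'   aggregation pathway active above 45 C, for exercising the temperature
#'   sub-sampling analysis.
#' * `"multibatch"` — the classic design for 23 batches with between-batch
#'   rate variability.
#'
#' @param name preset name; `presets()` returns the full named list.
#' @return a [synthetic_study_spec()] (or named list of them).
#' @export
preset <- function(name = c("classic", "rapid", "switch", "multibatch")) {
  name <- match.arg(name)
  presets()[[name]]
}

#' @rdname preset
#' @export
presets <- function() {
  week <- 12 / 52
  classic_attrs <- data.frame(
    name = c("SEC sum of aggregates", "CEX sum of acid variants",
             "nrCE-SDS purity"),
    direction = c("increasing", "increasing", "decreasing"),
    method = c("SEC aggregates", "CEX", "nrCE-SDS purity"),
    Ea = c(22, 25, 25),
    k_ref = c(1.3e-4, 3e-4, 1.7e-4),
    level0 = c(0.5, 10, 98),
    stringsAsFactors = FALSE
  )
  classic_schedule <- rbind(
    data.frame(temperature = 5, time = c(0, 1, 2, 3, 6, 9, 12, 18, 24, 36)),
    data.frame(temperature = 25, time = c(1, 2, 3, 6)),
    data.frame(temperature = 40, time = c(1, 2, 3, 6))
  )
  rapid_schedule <- do.call(rbind, lapply(c(25, 40, 50, 60), function(tc)
    data.frame(temperature = tc, time = c(if (tc == 25) 0, (1:4) * week))))
  switch_schedule <- do.call(rbind, lapply(c(25, 35, 40, 45, 50, 55, 60),
    function(tc)
      data.frame(temperature = tc, time = c(if (tc == 25) 0, (1:4) * week))))
  agg <- classic_attrs[1, ]
  acid <- classic_attrs[2, ]
  list(
    classic = synthetic_study_spec(classic_attrs, classic_schedule, seed = 1),
    rapid = synthetic_study_spec(acid, rapid_schedule, seed = 1),
    switch = synthetic_study_spec(
      agg, switch_schedule,
      switch = list(T_switch = 45, Ea_high = 60, k_share = 0.5), seed = 1),
    multibatch = synthetic_study_spec(classic_attrs, classic_schedule,
                                      n_batches = 23, batch_variation = 0.1,
                                      seed = 1)
  )
}
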