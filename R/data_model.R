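#' Analytical method accuracy registry
#'
#' Maps analytical method names to the assay standard deviation (percent)
#' used for Monte-Carlo perturbation and for simulated noise. Defaults are
#' the conservative (upper) end of the accuracy range quoted for each assay:
#' size-exclusion chromatography 0.1% for the sum of aggregates and 0.2% for
#' purity, cation-exchange chromatography 1.5% for charge variants,
#' non-reducing CE-SDS 0.3% for fragments and 0.5% for purity, and 10% for
#' relative potency by cell-based bioassay.
#'
#' @param ... named `method = sd` pairs that override or extend the defaults.
#' @return named numeric vector of standard deviations, percent.
#' @examples
#' method_accuracies()
#' method_accuracies("iCIEF" = 1.0)
#' @export
method_accuracies <- function(...) {
  defaults <- c(
    "SEC aggregates"      = 0.1,
    "SEC purity"          = 0.2,
    "CEX"                 = 1.5,
    "nrCE-SDS fragments"  = 0.3,
    "nrCE-SDS purity"     = 0.5,
    "potency"             = 10
  )
  extra <- c(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == ""))
      stop("accuracy overrides must be named 'method = sd' pairs")
    if (any(!is.finite(extra)) || any(extra <= 0))
      stop("method accuracy sd must be > 0")
    defaults[names(extra)] <- extra
  }
  defaults
}

#' Specification limit for a quality attribute
#'
#' Platform (generic) acceptance limits. For two-sided limits the width is
#' `upper - lower`. One-sided limits are converted to a width against the
#' natural range of a percent-scale measurement: a missing upper bound is
#' taken as 100 and a missing lower bound as 0, so purity >= 90 gives width
#' 10, aggregates <= 5 gives width 5, and potency 50-150 gives width 100.
#'
#' @param attribute attribute name.
#' @param lower,upper limits in percent; at least one must be given.
#' @return object of class `spec_limit` with fields `attribute`, `lower`,
#'   `upper`, `width`.
#' @examples
#' spec_limit("SEC sum of aggregates", upper = 5)
#' spec_limit("relative potency", lower = 50, upper = 150)
#' @export
spec_limit <- function(attribute, lower = NA_real_, upper = NA_real_) {
  if (is.na(lower) && is.na(upper))
    stop("at least one of 'lower'/'upper' must be given")
  width <- (if (is.na(upper)) 100 else upper) - (if (is.na(lower)) 0 else lower)
  if (!is.finite(width) || width <= 0) stop("specification width must be > 0")
  structure(
    list(attribute = attribute, lower = lower, upper = upper, width = width),
    class = "spec_limit"
  )
}

#' @export
print.spec_limit <- function(x, ...) {
  cat(sprintf("Specification limit for %s: [%s, %s], width %.4g %%\n",
              x$attribute,
              if (is.na(x$lower)) "-" else format(x$lower),
              if (is.na(x$upper)) "-" else format(x$upper),
              x$width))
  invisible(x)
}

#' Charge-variant specification limit from the initial value
#'
#' Charge-variant profiles have no fixed platform limit; the acceptance
#' criterion is set relative to the initial level, rounded to the nearest
#' five: "less than initial + 10%" for an increasing variant sum and "more
#' than initial - 10%" for the amount of main variant.
#'
#' @param attribute attribute name.
#' @param initial mean initial level across batches, percent.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return a [spec_limit()].
#' @examples
#' charge_variant_limit("CEX sum of acid variants", initial = 11, direction = "increasing")
#' @export
charge_variant_limit <- function(attribute, initial, direction) {
  direction <- match.arg(direction, c("increasing", "decreasing"))
  anchor <- 5 * round(initial / 5)
  if (direction == "increasing") spec_limit(attribute, upper = anchor + 10)
  else spec_limit(attribute, lower = anchor - 10)
}

#' Platform specification registry
#'
#' Generic first-in-human acceptance limits for mAb products, as a named list
#' of [spec_limit()] objects.
#'
#' @return named list of `spec_limit`.
#' @export
platform_specifications <- function() {
  sp <- list(
    spec_limit("SEC sum of aggregates", upper = 5),
    spec_limit("SEC purity", lower = 90),
    spec_limit("nrCE-SDS purity", lower = 90),
    spec_limit("nrCE-SDS sum of fragments", upper = 5),
    spec_limit("relative potency", lower = 50, upper = 150)
  )
  setNames(sp, vapply(sp, `[[`, "", "attribute"))
}

.study_columns <- c("batch_id", "attribute", "direction", "method",
                    "temperature_C", "time_months", "value_percent")

#' Stability dataset for one batch and one quality attribute
#'
#' Holds all measurements of one quality attribute for one batch across
#' storage temperatures and pull times, plus the assay standard deviation.
#' A study design has a single analytical measurement at t = 0 that serves
#' as the initial value for every temperature series, so a dataset normally
#' contains exactly one t = 0 row.
#'
#' @param batch_id batch identifier.
#' @param attribute quality-attribute name (e.g. "SEC sum of aggregates").
#' @param direction `"increasing"` (impurity-like) or `"decreasing"`
#'   (purity-like).
#' @param measurements data.frame with columns `method`, `temperature`
#'   (Celsius), `time` (months), `value` (percent).
#' @param accuracy_sd assay standard deviation, percent.
#' @return object of class `stability_dataset`.
#' @export
stability_dataset <- function(batch_id, attribute, direction, measurements,
                              accuracy_sd) {
  direction <- match.arg(direction, c("increasing", "decreasing"))
  req <- c("method", "temperature", "time", "value")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns: ", paste(req, collapse = ", "))
  m <- as.data.frame(measurements)[req]
  bad <- which(!is.finite(m$time) | m$time < 0)
  if (length(bad)) stop("negative or missing pull time in row(s) ",
                        paste(bad, collapse = ", "))
  bad <- which(!is.finite(m$value) | m$value < 0 | m$value > 100)
  if (length(bad)) stop("value outside [0, 100] percent in row(s) ",
                        paste(bad, collapse = ", "))
  bad <- which(!is.finite(m$temperature) | m$temperature < -80 | m$temperature > 80)
  if (length(bad)) stop("temperature outside [-80, 80] C in row(s) ",
                        paste(bad, collapse = ", "))
  if (!is.finite(accuracy_sd) || accuracy_sd < 0)
    stop("'accuracy_sd' must be a non-negative number (percent)")
  if (sum(m$time == 0) == 0)
    warning("dataset has no t = 0 measurement; the initial level will be ",
            "estimated from later pull points only")
  m <- m[order(m$temperature, m$time), , drop = FALSE]
  rownames(m) <- NULL
  structure(
    list(batch_id = as.character(batch_id), attribute = as.character(attribute),
         direction = direction, measurements = m, accuracy_sd = accuracy_sd),
    class = "stability_dataset"
  )
}

#' @export
print.stability_dataset <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("Stability dataset: batch %s, %s (%s)\n",
              x$batch_id, x$attribute, x$direction))
  cat(sprintf("  %d measurements at %d temperature(s): %s C\n",
              nrow(m), length(unique(m$temperature)),
              paste(sort(unique(m$temperature)), collapse = ", ")))
  cat(sprintf("  pull times %s months; assay sd %.3g %%\n",
              paste(range(m$time), collapse = " to "), x$accuracy_sd))
  invisible(x)
}

#' Restrict a stability dataset in time or temperature
#'
#' Used to emulate a shorter study (fit on data up to a cut-off) or to select
#' a temperature subset. The shared t = 0 measurement is always retained.
#'
#' @param dataset a [stability_dataset()].
#' @param max_time keep pull times <= this many months (NULL keeps all).
#' @param temperatures keep these storage temperatures, Celsius (NULL keeps
#'   all). Rows at t = 0 are kept regardless, since the single initial
#'   measurement is shared by every temperature series.
#' @return a restricted `stability_dataset`.
#' @export
restrict_dataset <- function(dataset, max_time = NULL, temperatures = NULL) {
  stopifnot(inherits(dataset, "stability_dataset"))
  m <- dataset$measurements
  keep <- rep(TRUE, nrow(m))
  if (!is.null(max_time)) keep <- keep & m$time <= max_time
  if (!is.null(temperatures))
    keep <- keep & (m$temperature %in% temperatures | m$time == 0)
  stability_dataset(dataset$batch_id, dataset$attribute, dataset$direction,
                    m[keep, , drop = FALSE], dataset$accuracy_sd)
}

#' Read a long-format stability study CSV
#'
#' Expects a UTF-8 CSV with header columns `batch_id`, `attribute`,
#' `direction`, `method`, `temperature_C`, `time_months`, `value_percent`.
#' Rows are grouped into one [stability_dataset()] per (batch, attribute)
#' pair; the assay standard deviation is attached from the accuracy registry
#' by method name. Duplicate (temperature, time) rows are retained as
#' replicates.
#'
#' @param path CSV file path.
#' @param accuracies named vector from [method_accuracies()].
#' @return named list of `stability_dataset` (names `batch/attribute`);
#'   empty list (with a warning) for a file without data rows.
#' @export
read_study <- function(path, accuracies = method_accuracies()) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.study_columns, names(df))
  if (length(missing_cols))
    stop("study CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) {
    warning("study file '", path, "' contains no measurements")
    return(list())
  }
  bad <- which(!is.finite(df$value_percent) |
                 df$value_percent < 0 | df$value_percent > 100)
  if (length(bad))
    stop("value_percent outside [0, 100] in row(s) ",
         paste(bad, collapse = ", "), " of ", path)
  unknown <- setdiff(unique(df$method), names(accuracies))
  if (length(unknown))
    stop("method(s) not in the accuracy registry: ",
         paste(unknown, collapse = ", "))
  key <- paste(df$batch_id, df$attribute, sep = "/")
  out <- lapply(split(df, key), function(g) {
    stability_dataset(
      batch_id = g$batch_id[1], attribute = g$attribute[1],
      direction = g$direction[1],
      measurements = data.frame(method = g$method,
                                temperature = g$temperature_C,
                                time = g$time_months,
                                value = g$value_percent),
      accuracy_sd = unname(accuracies[[g$method[1]]])
    )
  })
  out[order(names(out))]
}

#' Write stability datasets to a long-format CSV
#'
#' Inverse of [read_study()]: emits the same dialect, rows sorted by batch,
#' attribute, temperature and time, values at full precision so that a
#' written study re-reads identically.
#'
#' @param datasets list of [stability_dataset()] (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_study <- function(datasets, path) {
  if (inherits(datasets, "stability_dataset")) datasets <- list(datasets)
  rows <- do.call(rbind, lapply(datasets, function(d) {
    m <- d$measurements
    data.frame(batch_id = d$batch_id, attribute = d$attribute,
               direction = d$direction, method = m$method,
               temperature_C = m$temperature, time_months = m$time,
               value_percent = m$value, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- as.data.frame(setNames(rep(list(character(0)), 7), .study_columns))
  ord <- order(rows$batch_id, rows$attribute, rows$temperature_C, rows$time_months)
  rows <- rows[ord, , drop = FALSE]
  # as.character() on doubles keeps 15 significant digits: lossless round trip
  # at the 1e-9 level for percent-scale data and fractional-month pull times.
  write.csv(rows, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
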