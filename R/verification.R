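#' Coverage of a prediction band by held-out long-term data
#'
#' Classifies every target-temperature measurement taken after the training
#' window (and within the band's horizon) as inside or outside the band,
#' using linear interpolation between band grid points. Points exactly on a
#' bound count as inside (closed interval). Verification of the extrapolation
#' is the fraction of such held-out points inside the 95% probability
#' prediction interval; fits are only considered trustworthy when the
#' goodness of fit of the underlying (unperturbed, full-training-data) model
#' passes the R2 gate.
#'
#' @param dataset the full [stability_dataset()] including long-term data.
#' @param band a [monte_carlo_band()] built from the training window.
#' @param train_window training cut-off, months; points with
#'   `time > train_window` at the band's target temperature are held out.
#' @param fit optional [fit_kinetic()] result on the training data, used for
#'   the R2 gate columns.
#' @param r2_gate threshold on the training-fit R2 (default 0.9).
#' @return object of class `coverage_report`: `batch_id`, `attribute`,
#'   `n_heldout`, `n_inside`, `fraction_inside` (percent, `NA` when no
#'   held-out points), `r2_of_fit`, `passed_r2_gate`.
#' @export
coverage <- function(dataset, band, train_window, fit = NULL, r2_gate = 0.9) {
  stopifnot(inherits(dataset, "stability_dataset"),
            inherits(band, "prediction_band"))
  m <- dataset$measurements
  held <- m[m$temperature == attr(band, "target_temp") &
              m$time > train_window & m$time <= max(band$time), , drop = FALSE]
  if (nrow(held) == 0)
    warning("no held-out points after ", train_window, " months at ",
            attr(band, "target_temp"), " C")
  inside <- if (nrow(held)) {
    e <- evaluate_band(band, held$time)
    held$value >= e$lower & held$value <= e$upper
  } else logical(0)
  r2 <- if (is.null(fit)) NA_real_ else fit$r2
  structure(
    list(batch_id = dataset$batch_id, attribute = dataset$attribute,
         n_heldout = nrow(held), n_inside = sum(inside),
         fraction_inside = if (nrow(held)) 100 * sum(inside) / nrow(held)
                           else NA_real_,
         r2_of_fit = r2,
         passed_r2_gate = is.null(fit) || (!is.na(r2) && r2 >= r2_gate)),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage: batch %s, %s: %d/%d held-out points inside (%s%%)\n",
              x$batch_id, x$attribute, x$n_inside, x$n_heldout,
              if (is.na(x$fraction_inside)) "-"
              else sprintf("%.1f", x$fraction_inside)))
  if (!is.na(x$r2_of_fit))
    cat(sprintf("  training fit R2 = %.4g (gate %s)\n", x$r2_of_fit,
                if (x$passed_r2_gate) "passed" else "failed"))
  invisible(x)
}

#' Prediction-interval width relative to the specification width
#'
#' Ratio (in percent) of the prediction-band width at a given time point to
#' the width of the platform specification for the attribute, e.g. a band
#' width of 0.9% against the 5% aggregates limit gives 18%.
#'
#' @param band a [monte_carlo_band()] result, or directly a numeric band
#'   width in percent.
#' @param spec a [spec_limit()].
#' @param at evaluation time, months (default 36); ignored when `band` is
#'   already a width.
#' @return object of class `width_report`: `attribute`, `band_width`,
#'   `spec_width`, `ratio` (percent).
#' @examples
#' width_ratio(0.9, spec_limit("SEC sum of aggregates", upper = 5))
#' @export
width_ratio <- function(band, spec, at = 36) {
  stopifnot(inherits(spec, "spec_limit"))
  w <- if (is.numeric(band)) band else band_width(band, at)
  if (!is.finite(w) || w < 0) stop("band width must be a non-negative number")
  structure(
    list(attribute = spec$attribute, band_width = w, spec_width = spec$width,
         ratio = 100 * w / spec$width),
    class = "width_report"
  )
}

#' @export
print.width_report <- function(x, ...) {
  cat(sprintf("%s: band width %.4g / spec width %.4g = %.3g%%\n",
              x$attribute, x$band_width, x$spec_width, x$ratio))
  invisible(x)
}

#' Pooled coverage summary across batches
#'
#' Aggregates [coverage()] reports per attribute the way a multi-batch
#' verification table is built: the pooled fraction is the sum of inside
#' counts over the sum of held-out counts (not a mean of per-batch
#' fractions), with batches failing the R2 gate excluded and counted.
#'
#' @param reports list of `coverage_report`.
#' @return data.frame with one row per attribute: `attribute`, `n_batches`,
#'   `n_gated_out`, `n_heldout`, `n_inside`, `percent_inside` (`NA` when no
#'   batch passes the gate).
#' @export
study_summary <- function(reports) {
  if (inherits(reports, "coverage_report")) reports <- list(reports)
  if (!length(reports)) stop("at least one coverage report is required")
  attrs <- vapply(reports, `[[`, "", "attribute")
  rows <- lapply(split(reports, attrs), function(rs) {
    gated <- vapply(rs, `[[`, TRUE, "passed_r2_gate")
    eligible <- rs[gated]
    n_in <- sum(vapply(eligible, function(r) as.numeric(r$n_inside), 0))
    n_h <- sum(vapply(eligible, function(r) as.numeric(r$n_heldout), 0))
    data.frame(attribute = rs[[1]]$attribute, n_batches = length(rs),
               n_gated_out = sum(!gated), n_heldout = n_h, n_inside = n_in,
               percent_inside = if (n_h > 0) 100 * n_in / n_h else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
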