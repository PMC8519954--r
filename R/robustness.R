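#' Enumerate temperature subsets
#'
#' All subsets of the available storage temperatures containing at least
#' `min_size` distinct temperatures, in deterministic order (by size, then
#' lexicographically). For m temperatures this yields
#' `2^m - 1 - m - m(m-1)/2` subsets at the default `min_size = 3`: 5 subsets
#' for 4 temperatures, 42 for 6 and 219 for 8.
#'
#' @param temperatures distinct storage temperatures, Celsius.
#' @param min_size minimum subset size (default 3, the smallest design that
#'   identifies the Arrhenius relation).
#' @return list of numeric vectors (sorted temperatures).
#' @examples
#' length(enumerate_subsets(c(5, 25, 40, 50)))  # 5
#' @export
enumerate_subsets <- function(temperatures, min_size = 3) {
  temps <- sort(unique(temperatures))
  m <- length(temps)
  if (m < min_size)
    stop("need at least ", min_size, " distinct temperatures (got ", m, ")")
  out <- list()
  for (size in min_size:m)
    out <- c(out, combn(temps, size, simplify = FALSE))
  out
}

#' Temperature sub-sampling analysis
#'
#' Fits the kinetic model to every temperature subset of at least `min_size`
#' temperatures (each subset keeps all pull points at its temperatures plus
#' the shared t = 0 measurement) and records the fitted activation energy,
#' reference rate and goodness of fit. If the fitted parameters agree across
#' subsets and with the full-data fit, the degradation follows a single
#' Arrhenius mechanism over the whole temperature range; subsets whose
#' highest temperature reaches into a regime with an additional degradation
#' pathway show inflated activation energies and/or R2 below the threshold.
#'
#' @param dataset a fit-eligible [stability_dataset()].
#' @param r2_threshold pass/fail threshold on R2 (default 0.9).
#' @param min_size minimum subset size.
#' @return data.frame of class `subset_analysis` with columns `subset`
#'   (label), `n_temps`, `t_max` (Celsius), `Ea`, `k_ref`, `r2`, `converged`,
#'   `passes`, plus a list attribute `temperatures`. Individual subset
#'   non-convergence is recorded, not fatal.
#' @examples
#' study <- simulate_study(preset("classic"))
#' subset_analysis(restrict_dataset(study$datasets[[1]], max_time = 6))
#' @export
subset_analysis <- function(dataset, r2_threshold = 0.9, min_size = 3) {
  stopifnot(inherits(dataset, "stability_dataset"))
  temps <- sort(unique(dataset$measurements$temperature[
    dataset$measurements$time > 0]))
  subsets <- enumerate_subsets(temps, min_size)
  rows <- lapply(subsets, function(s) {
    fit <- tryCatch(fit_kinetic(restrict_dataset(dataset, temperatures = s)),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(subset = paste(s, collapse = "/"), n_temps = length(s),
                        t_max = max(s), Ea = NA_real_, k_ref = NA_real_,
                        r2 = NA_real_, converged = FALSE, passes = FALSE))
    data.frame(subset = paste(s, collapse = "/"), n_temps = length(s),
               t_max = max(s), Ea = fit$params$Ea, k_ref = fit$params$k_ref,
               r2 = fit$r2, converged = fit$converged,
               passes = fit$converged && !is.na(fit$r2) &&
                 fit$r2 >= r2_threshold)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("subset_analysis", "data.frame"),
            temperatures = subsets, r2_threshold = r2_threshold)
}

#' Maximal temperature of Arrhenius behaviour
#'
#' Estimates, from a [subset_analysis()], the highest storage temperature up
#' to which degradation follows a single Arrhenius mechanism: the largest
#' subset-maximum temperature such that all passing subsets whose highest
#' temperature does not exceed it have activation energies within
#' `tolerance` (relative) of their median.
#'
#' @param results a [subset_analysis()] data.frame.
#' @param tolerance relative spread of Ea tolerated within one mechanism
#'   (default 0.2).
#' @return the temperature in Celsius, or `NA` with attribute
#'   `reason = "no Arrhenius range"` when no passing subsets exist or even
#'   the lowest subsets disagree.
#' @export
max_arrhenius_temperature <- function(results, tolerance = 0.2) {
  stopifnot(inherits(results, "subset_analysis"))
  pass <- results[results$passes, , drop = FALSE]
  if (nrow(pass) == 0)
    return(structure(NA_real_, reason = "no Arrhenius range"))
  best <- NA_real_
  for (tm in sort(unique(pass$t_max))) {
    ea <- pass$Ea[pass$t_max <= tm]
    med <- median(ea)
    if (max(abs(ea - med)) <= tolerance * abs(med)) best <- tm else break
  }
  if (is.na(best)) structure(NA_real_, reason = "no Arrhenius range") else best
}

#' Export a subset analysis to CSV
#'
#' The data behind an activation-energy versus highest-temperature scatter.
#'
#' @param results a [subset_analysis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subset_analysis <- function(results, path) {
  out <- data.frame(subset = results$subset, t_max = results$t_max,
                    Ea_kcal_mol = results$Ea,
                    k_ref_per_month = results$k_ref,
                    r2 = results$r2, passes = results$passes)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
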