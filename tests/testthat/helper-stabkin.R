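# Shared fixtures, all built in code.

# Noise-free dataset generated directly from the closed-form model: one shared
# t = 0 row plus the stated pull times at each temperature.
noise_free_dataset <- function(Ea = 25, k_ref = 3e-4, level0 = 10,
                               direction = "increasing",
                               temps = c(5, 25, 40), times = c(1, 2, 3, 6),
                               attribute = "CEX sum of acid variants",
                               method = "CEX", accuracy_sd = 1.5,
                               batch_id = "b1") {
  p <- kinetic_params(Ea, k_ref, level0)
  rows <- rbind(
    data.frame(temperature = min(temps), time = 0),
    expand.grid(time = times, temperature = temps)[, c("temperature", "time")]
  )
  vals <- trajectory(rows$time, celsius_to_kelvin(rows$temperature), p, direction)
  stability_dataset(batch_id, attribute, direction,
                    data.frame(method = method, temperature = rows$temperature,
                               time = rows$time, value = vals),
                    accuracy_sd)
}

# Single-attribute "classic" spec (SEC aggregates, assay sd 0.1) used by the
# coverage and comparison ensembles.
classic_aggregates_spec <- function() {
  spec <- preset("classic")
  spec$attributes <- spec$attributes[spec$attributes$name ==
                                       "SEC sum of aggregates", ]
  spec
}

# Hand-built band with known geometry, for interpolation/coverage arithmetic.
manual_band <- function(time, central, lower, upper, target_temp = 5,
                        kind = "prediction") {
  structure(data.frame(time = time, central = central, lower = lower,
                       upper = upper),
            class = c("prediction_band", "data.frame"),
            target_temp = target_temp, level = 0.95, kind = kind,
            n_replicates = 0L, n_failed = 0L, accuracy_sd = NA_real_,
            seed = NA_integer_)
}

# Bracketed (width / specification-width) pairs printed in the multi-molecule
# interval-width table, with the percent alongside each pair.
table2_pairs <- function() {
  data.frame(
    attribute = c(rep("CEX amount of main variants", 4),
                  rep("CEX sum of acid variants", 4),
                  rep("nrCE-SDS purity", 4),
                  "nrCE-SDS sum of fragments",
                  rep("relative potency", 3),
                  rep("SEC purity", 4),
                  rep("SEC sum of aggregates", 4)),
    width = c(13.3, 6.4, 10.4, 9.5,  8.5, 6.6, 6.4, 6.7,
              2.0, 2.4, 1.9, 2.6,  1.2,  46.0, 75.0, 74.0,
              4.0, 3.8, 2.4, 4.7,  0.9, 0.7, 0.5, 0.9),
    spec_width = c(45, 40, 45, 30,  35, 20, 25, 20,  10, 10, 10, 10,  5,
                   100, 100, 100,  10, 10, 10, 10,  5, 5, 5, 5),
    printed = c(30, 16, 23, 32,  24, 32, 25, 33,  20, 24, 19, 26,  25,
                46, 75, 74,  40, 38, 24, 47,  18, 14, 11, 17)
  )
}
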