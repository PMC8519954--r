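test_that("coverage classifies held-out points with closed bounds", {
  band <- manual_band(time = c(0, 12, 24, 36),
                      central = c(1, 2, 3, 4),
                      lower = c(0.5, 1.5, 2.5, 3.5),
                      upper = c(1.5, 2.5, 3.5, 4.5))
  d <- stability_dataset(
    "b1", "SEC sum of aggregates", "increasing",
    data.frame(method = "SEC aggregates", temperature = 5,
               time = c(0, 3, 12, 24, 30, 36),
               # after the 6-month window: on-central, on-boundary, outside, inside
               value = c(1, 1, 2, 3.5, 1.0, 4.2)),
    0.1)
  rep <- coverage(d, band, train_window = 6)
  expect_equal(rep$n_heldout, 4)
  # t=12 central (in), t=24 exactly on the lower bound (in), t=30 far below
  # the interpolated band (out), t=36 inside
  expect_equal(rep$n_inside, 3)
  expect_equal(rep$fraction_inside, 75)
})

test_that("all points on the central curve give 100%; a zero-width band excludes noise", {
  band <- manual_band(time = c(0, 36), central = c(1, 2), lower = c(1, 2),
                      upper = c(1, 2))
  on_curve <- stability_dataset(
    "b", "a", "increasing",
    data.frame(method = "CEX", temperature = 5, time = c(0, 12, 24, 36),
               value = 1 + c(0, 12, 24, 36) / 36),
    1)
  expect_equal(coverage(on_curve, band, 6)$fraction_inside, 100)
  set.seed(8)
  noisy <- on_curve
  noisy$measurements$value <- noisy$measurements$value + rnorm(4, 0, 0.3)
  expect_lte(coverage(noisy, band, 6)$n_inside, 1)
  empty <- restrict_dataset(on_curve, max_time = 6)
  expect_warning(rep <- coverage(empty, band, 6), "no held-out")
  expect_equal(rep$n_heldout, 0)
  expect_true(is.na(rep$fraction_inside))
})

test_that("width ratios reproduce the printed interval-to-specification arithmetic", {
  expect_equal(width_ratio(0.9, spec_limit("SEC sum of aggregates", upper = 5))$ratio,
               18)
  pairs <- table2_pairs()
  for (i in seq_len(nrow(pairs))) {
    wr <- width_ratio(pairs$width[i],
                      spec_limit(pairs$attribute[i],
                                 upper = pairs$spec_width[i]))
    expect_equal(wr$ratio, 100 * pairs$width[i] / pairs$spec_width[i])
    # printed percentages were rounded from unrounded widths; agree within 1 point
    expect_lte(abs(wr$ratio - pairs$printed[i]), 1)
  }
  expect_equal(width_ratio(0, spec_limit("x", upper = 5))$ratio, 0)
  expect_equal(width_ratio(5, spec_limit("x", upper = 5))$ratio, 100)
})

test_that("study summary pools counts, not per-batch fractions", {
  mk <- function(batch, inside, total, r2 = 0.95, gate = TRUE) {
    structure(list(batch_id = batch, attribute = "SEC sum of aggregates",
                   n_heldout = total, n_inside = inside,
                   fraction_inside = 100 * inside / total,
                   r2_of_fit = r2, passed_r2_gate = gate),
              class = "coverage_report")
  }
  s <- study_summary(list(mk("b1", 10, 10), mk("b2", 8, 10)))
  expect_equal(s$percent_inside, 90)
  expect_equal(s$n_heldout, 20)

  # the R2 gate removes batches from the pool and counts them
  s2 <- study_summary(list(mk("b1", 10, 10), mk("b2", 0, 10, r2 = 0.5,
                                                gate = FALSE)))
  expect_equal(s2$percent_inside, 100)
  expect_equal(s2$n_gated_out, 1)

  s3 <- study_summary(list(mk("b1", 9, 10, gate = FALSE)))
  expect_true(is.na(s3$percent_inside))
  expect_error(study_summary(list()), "at least one")
})

test_that("multi-batch synthetic coverage pools near the nominal level", {
  spec <- classic_aggregates_spec()
  spec$n_batches <- 20L
  spec$batch_variation <- 0.1
  study <- simulate_study(spec, seed = 14)
  reports <- lapply(study$datasets, function(d) {
    train <- restrict_dataset(d, max_time = 6)
    fit <- fit_kinetic(train)
    band <- monte_carlo_band(train, fit = fit, n_replicates = 399,
                             seed = 100 + match(d$batch_id,
                                                sort(unique(study$truth$batch_id))))
    coverage(d, band, train_window = 6, fit = fit)
  })
  s <- study_summary(reports)
  expect_equal(s$n_batches, 20)
  expect_equal(s$n_gated_out + 0L,
               sum(!vapply(reports, `[[`, TRUE, "passed_r2_gate")))
  # 20 batches x 5 held-out points; binomial 95% band around 0.95 is wide
  expect_gte(s$percent_inside, 85)
})
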