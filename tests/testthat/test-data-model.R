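test_that("a study CSV round-trips losslessly through write and read", {
  spec <- preset("classic")
  spec$n_batches <- 2L
  study <- simulate_study(spec, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study(study$datasets, path)
  back <- read_study(path)

  expect_length(back, length(study$datasets))
  expect_setequal(names(back), names(study$datasets))
  for (nm in names(back)) {
    a <- study$datasets[[nm]]; b <- back[[nm]]
    expect_identical(b$batch_id, a$batch_id)
    expect_identical(b$attribute, a$attribute)
    expect_identical(b$direction, a$direction)
    expect_equal(b$accuracy_sd, a$accuracy_sd, tolerance = 1e-9)
    ma <- a$measurements[order(a$measurements$temperature, a$measurements$time), ]
    mb <- b$measurements
    expect_equal(mb$temperature, ma$temperature, tolerance = 1e-9)
    expect_equal(mb$time, ma$time, tolerance = 1e-9)
    expect_equal(mb$value, ma$value, tolerance = 1e-9)
  }
})

test_that("grouping partitions rows and a 3-temperature study has the expected count", {
  # 1 shared t=0 + 4 pulls per temperature at 3 temperatures = 13 rows
  d <- noise_free_dataset()
  expect_equal(nrow(d$measurements), 13)

  spec <- preset("classic")
  spec$n_batches <- 3L
  study <- simulate_study(spec, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study(study$datasets, path)
  raw <- read.csv(path)
  back <- read_study(path)
  expect_equal(sum(vapply(back, function(d) nrow(d$measurements), 0L)), nrow(raw))
  # every (batch, attribute) pair lands in exactly one dataset
  keys <- unique(paste(raw$batch_id, raw$attribute, sep = "/"))
  expect_setequal(names(back), keys)
})

test_that("written rows are sorted and fractional pull times keep full precision", {
  week <- 12 / 52
  d1 <- noise_free_dataset(batch_id = "zzz")
  d2 <- noise_free_dataset(batch_id = "aaa", times = week * (1:4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_study(list(d1, d2), path)
  raw <- read.csv(path)
  expect_false(is.unsorted(raw$batch_id))
  got <- sort(unique(raw$time_months[raw$batch_id == "aaa"]))
  expect_equal(got, c(0, week * (1:4)), tolerance = 1e-12)
})

test_that("read_study validates format, values and registry membership", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines("batch_id,attribute,direction,method,temperature_C,time_months", path)
  expect_error(read_study(path), "missing column")

  writeLines(c("batch_id,attribute,direction,method,temperature_C,time_months,value_percent"),
             path)
  expect_warning(res <- read_study(path), "no measurements")
  expect_identical(res, list())

  writeLines(c("batch_id,attribute,direction,method,temperature_C,time_months,value_percent",
               "b1,SEC sum of aggregates,increasing,SEC aggregates,5,0,0.4",
               "b1,SEC sum of aggregates,increasing,SEC aggregates,25,1,140"),
             path)
  expect_error(read_study(path), "row\\(s\\) 2")

  writeLines(c("batch_id,attribute,direction,method,temperature_C,time_months,value_percent",
               "b1,foo,increasing,mystery assay,5,0,0.4"), path)
  expect_error(read_study(path), "accuracy registry")
})

test_that("dataset constructor enforces physical invariants", {
  m <- data.frame(method = "CEX", temperature = 5, time = 0, value = 10)
  expect_error(stability_dataset("b", "a", "sideways", m, 1), "arg")
  m2 <- m; m2$time <- -1
  expect_error(stability_dataset("b", "a", "increasing", m2, 1), "pull time")
  m3 <- m; m3$temperature <- 95
  expect_error(stability_dataset("b", "a", "increasing", m3, 1), "temperature")
  m4 <- rbind(m, data.frame(method = "CEX", temperature = 25, time = 1, value = 11))
  expect_warning(
    stability_dataset("b", "a", "increasing", m4[m4$time > 0, , drop = FALSE], 1),
    "t = 0")
})

test_that("accuracy registry defaults are positive and overridable", {
  acc <- method_accuracies()
  expect_true(all(acc > 0))
  expect_equal(unname(method_accuracies("CEX" = 0.5)[["CEX"]]), 0.5)
  expect_error(method_accuracies(0.5), "named")
  expect_error(method_accuracies("CEX" = -1), "> 0")
})

test_that("specification widths follow the platform rules", {
  sp <- platform_specifications()
  expect_equal(sp[["SEC sum of aggregates"]]$width, 5)
  expect_equal(sp[["SEC purity"]]$width, 10)
  expect_equal(sp[["relative potency"]]$width, 100)
  # charge variants: anchored at the initial value rounded to the nearest 5
  acid <- charge_variant_limit("CEX sum of acid variants", initial = 11,
                               direction = "increasing")
  expect_equal(acid$width, 20)  # round(11 -> 10) + 10
  main <- charge_variant_limit("CEX amount of main variants", initial = 68,
                               direction = "decreasing")
  expect_equal(main$width, 100 - (70 - 10))
  expect_error(spec_limit("x"), "at least one")
  expect_error(spec_limit("x", lower = 50, upper = 40), "width")
})

test_that("restrict_dataset keeps the shared t = 0 row", {
  d <- noise_free_dataset(temps = c(5, 25, 40, 50))
  r <- restrict_dataset(d, temperatures = c(25, 40, 50))
  expect_true(any(r$measurements$time == 0))
  expect_setequal(unique(r$measurements$temperature[r$measurements$time > 0]),
                  c(25, 40, 50))
  r6 <- restrict_dataset(d, max_time = 3)
  expect_lte(max(r6$measurements$time), 3)
})
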