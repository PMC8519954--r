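test_that("rate law limits: reference temperature and zero activation energy", {
  p <- kinetic_params(Ea = 25, k_ref = 3e-4, level0 = 10)
  expect_identical(arrhenius_rate(p$T_ref, p), p$k_ref)
  p0 <- kinetic_params(Ea = 0, k_ref = 3e-4, level0 = 10)
  expect_equal(arrhenius_rate(celsius_to_kelvin(c(5, 25, 60)), p0),
               rep(3e-4, 3))
  # strictly increasing in temperature for Ea > 0
  k <- arrhenius_rate(celsius_to_kelvin(seq(5, 60, by = 5)), p)
  expect_true(all(diff(k) > 0))
  expect_error(arrhenius_rate(-1, p), "positive")
})

test_that("reference-temperature and frequency-factor parameterizations agree", {
  set.seed(11)
  for (i in 1:50) {
    p <- kinetic_params(Ea = runif(1, 5, 60), k_ref = 10^runif(1, -6, -1),
                        level0 = runif(1, 0, 100))
    temps <- celsius_to_kelvin(runif(8, 5, 60))
    k_ref_form <- arrhenius_rate(temps, p)
    k_af_form <- arrhenius_rate_classic(temps, frequency_factor(p), p$Ea)
    expect_equal(k_ref_form, k_af_form, tolerance = 1e-12)
  }
})

test_that("trajectory boundary behaviour", {
  p <- kinetic_params(Ea = 25, k_ref = 3e-4, level0 = 10)
  expect_equal(impurity_trajectory(0, 298.15, p), 10)
  expect_equal(purity_trajectory(0, 298.15, p), 10)
  frozen <- kinetic_params(Ea = 25, k_ref = 0, level0 = 10)
  expect_equal(impurity_trajectory(c(0, 6, 36), 313.15, frozen), rep(10, 3))
  # impurity tends to the 100% asymptote, purity to 0
  expect_equal(impurity_trajectory(1e6, 313.15, p), 100, tolerance = 1e-9)
  expect_true(all(diff(impurity_trajectory(0:36, 313.15, p)) > 0))
  expect_true(all(diff(purity_trajectory(0:36, 313.15, p)) < 0))
  expect_error(impurity_trajectory(-1, 313.15, p), ">= 0")
})

test_that("complementary purity and impurity trajectories conserve total material", {
  set.seed(12)
  for (i in 1:20) {
    ea <- runif(1, 5, 60); k <- 10^runif(1, -6, -1); b0 <- runif(1, 0, 100)
    pB <- kinetic_params(ea, k, b0)
    pA <- kinetic_params(ea, k, 100 - b0)
    t <- runif(10, 0, 48)
    temp <- celsius_to_kelvin(runif(10, 5, 60))
    expect_equal(purity_trajectory(t, temp, pA) + impurity_trajectory(t, temp, pB),
                 rep(100, 10), tolerance = 1e-9)
  }
})

test_that("first-order memorylessness: restarting from the trajectory is a semigroup", {
  p <- kinetic_params(Ea = 25, k_ref = 3e-4, level0 = 10)
  temp <- celsius_to_kelvin(40)
  t1 <- 4.5; t2 <- 13.25
  direct <- impurity_trajectory(t1 + t2, temp, p)
  mid <- impurity_trajectory(t1, temp, p)
  restarted <- impurity_trajectory(t2, temp,
                                   kinetic_params(p$Ea, p$k_ref, mid, p$T_ref))
  expect_equal(direct, restarted, tolerance = 1e-12)
})

test_that("closed forms match numerical integration of the rate equation", {
  skip_if_not_installed("deSolve")
  p <- kinetic_params(Ea = 25, k_ref = 3e-4, level0 = 10)
  times <- seq(0, 36, by = 3)
  for (tc in c(5, 25, 40, 60)) {
    k <- arrhenius_rate(celsius_to_kelvin(tc), p)
    # purity: d[A]/dt = -k [A]
    ode_A <- deSolve::lsoda(c(A = 100 - p$level0), times,
                            function(t, y, parms) list(-parms * y), k,
                            rtol = 1e-12, atol = 1e-12)
    pure <- kinetic_params(p$Ea, p$k_ref, 100 - p$level0)
    expect_equal(purity_trajectory(times, celsius_to_kelvin(tc), pure),
                 unname(ode_A[, "A"]), tolerance = 1e-8)
    # impurity: d[B]/dt = k [A], [A] = 100 - [B]
    ode_B <- deSolve::lsoda(c(B = p$level0), times,
                            function(t, y, parms) list(parms * (100 - y)), k,
                            rtol = 1e-12, atol = 1e-12)
    expect_equal(impurity_trajectory(times, celsius_to_kelvin(tc), p),
                 unname(ode_B[, "B"]), tolerance = 1e-8)
  }
})

test_that("parameter validation rejects unphysical values", {
  expect_error(kinetic_params(-1, 1e-4, 10), "Ea")
  expect_error(kinetic_params(25, -1e-4, 10), "k_ref")
  expect_error(kinetic_params(25, 1e-4, 101), "level0")
  expect_error(kinetic_params(25, 1e-4, 10, T_ref = -5), "T_ref")
})
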