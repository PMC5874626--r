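test_that("core-incubation flux follows the concentration change and sign convention", {
  # hand arithmetic: (14-10)*0.25 / (5.027e-3 * 0.1667) / 1000
  expect_equal(compute_flux(10, 14, 0.25, 5.027e-3, 0.1667),
               (4 * 0.25) / (5.027e-3 * 0.1667) / 1000, tolerance = 1e-12)
  expect_equal(compute_flux(10, 14, 0.25, 5.027e-3, 0.1667), 1.19,
               tolerance = 0.01)
  expect_identical(compute_flux(5, 5, 0.25, 5e-3, 0.2), 0)
  expect_lt(compute_flux(5, 4, 0.25, 5e-3, 0.2), 0)  # influx, not an error
  expect_error(compute_flux(5, 6, 0.25, 5e-3, 0), "duration")
  expect_error(compute_flux(5, 6, 0.25, 0, 0.2), "area")
})

test_that("DIN flux sums analytes and reports shares", {
  d <- compute_din_flux(6.3, 0.2)
  expect_equal(d$value, 6.5)
  expect_equal(d$nh4_share, 6.3 / 6.5, tolerance = 1e-12)
  z <- compute_din_flux(0, 0)
  expect_equal(z$value, 0)
  expect_true(is.na(z$nh4_share))
  expect_equal(compute_din_flux(-1, 2)$value, 1)
  expect_error(
    compute_din_flux(list(value = 1, core_id = "a"),
                     list(value = 1, core_id = "b")), "core_id")
})

test_that("jar regression matches the closed-form OLS oracle and gates on p", {
  r <- fit_jar_rate(c(0, 7, 14, 21, 28), c(100, 150, 200, 250, 300), 0.5)
  expect_equal(r$slope_uM_d, 50 / 7, tolerance = 1e-12)
  expect_equal(r$rate, 50 / 7 * 0.5, tolerance = 1e-12)
  expect_lt(r$p_value, 1e-10)
  expect_true(r$significant)

  # oracle equivalence on arbitrary noisy series
  set.seed(42)
  for (i in 1:20) {
    x <- sort(runif(6, 0, 30)); x <- x + seq_along(x) * 1e-6
    y <- 2 + 0.3 * x + rnorm(6)
    r <- fit_jar_rate(x, y, 0.7)
    o <- oracle_ols(x, y)
    expect_equal(r$slope_uM_d, unname(o$slope), tolerance = 1e-12)
    expect_equal(r$p_value, o$p, tolerance = 1e-12)
  }

  # negative slope passes through as consumption
  r <- fit_jar_rate(c(0, 1, 2), c(10, 8, 6), 0.5)
  expect_true(r$significant)
  expect_equal(r$rate, -1)

  expect_error(fit_jar_rate(c(0, 1), c(1, 2), 0.5), "3 time points")
  expect_error(fit_jar_rate(c(0, 1, 1), c(1, 2, 3), 0.5), "increasing")
  expect_error(fit_jar_rate(c(0, 1, 2), c(1, 2, 3), 0), "porosity")
})

test_that("non-significant jar slopes are withheld at close to the nominal rate", {
  set.seed(101)
  admitted <- replicate(1000, {
    fit_jar_rate(0:4, rnorm(5, 100, 5), 0.5)$significant
  })
  rate <- mean(admitted)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("depth integration interpolates the unmeasured layer and converts units", {
  const <- depth_integrate(data.frame(
    top_cm = c(0, 2, 5, 15), bottom_cm = c(2, 5, 10, 20), rate = 1))
  expect_equal(const$value, 0.2, tolerance = 1e-12)

  ar <- depth_integrate(data.frame(
    top_cm = c(0, 2, 5, 15), bottom_cm = c(2, 5, 10, 20),
    rate = c(8, 6, 4, 2)))
  # midpoints 7.5, 12.5, 17.5 are equally spaced -> interpolated rate 3
  expect_equal(ar$layers$rate[ar$layers$interpolated], 3)

  full <- depth_integrate(data.frame(
    top_cm = c(0, 2, 5, 10, 15), bottom_cm = c(2, 5, 10, 15, 20),
    rate = c(10, 5, 2, 1, 0.5)))
  expect_equal(full$value, 0.525, tolerance = 1e-12)  # hand sum

  # linearity: doubling all rates doubles the areal rate
  half <- depth_integrate(data.frame(
    top_cm = c(0, 2, 5, 15), bottom_cm = c(2, 5, 10, 20),
    rate = c(8, 6, 4, 2) / 2))
  expect_equal(2 * half$value, ar$value, tolerance = 1e-12)

  # a missing required layer propagates as incomplete, not dropped
  inc <- depth_integrate(data.frame(
    top_cm = c(0, 2, 5, 15), bottom_cm = c(2, 5, 10, 20),
    rate = c(8, NA, 4, 2)))
  expect_true(inc$incomplete)
  expect_true(is.na(inc$value))
})

test_that("porewater inventory integrates concentration x porosity x thickness", {
  prof <- data.frame(depth_top_cm = c(0, 1, 2, 5, 10, 15),
                     depth_bottom_cm = c(1, 2, 5, 10, 15, 20),
                     conc_mM = 1, porosity = 0.5)
  expect_equal(porewater_inventory(prof), 100, tolerance = 1e-12)
  prof0 <- prof; prof0$conc_mM <- 0
  expect_equal(porewater_inventory(prof0), 0)
  prof2 <- prof; prof2$conc_mM <- 2 * prof$conc_mM
  expect_equal(porewater_inventory(prof2), 2 * porewater_inventory(prof))
  gap <- prof[-3, ]
  expect_error(porewater_inventory(gap), "gap")
})

test_that("accumulation rate is the inventory difference per day", {
  prof <- function(c, day) data.frame(
    station = "S", time_point = day,
    depth_top_cm = c(0, 1, 2, 5, 10, 15),
    depth_bottom_cm = c(1, 2, 5, 10, 15, 20),
    conc_mM = c, porosity = 0.5)
  expect_equal(accumulation_rate(prof(1, 0), prof(1.6, 60)), 1.0,
               tolerance = 1e-12)
  expect_equal(accumulation_rate(prof(1, 0), prof(1, 60)), 0)
  expect_lt(accumulation_rate(prof(1, 0), prof(0.5, 60)), 0)
  expect_error(accumulation_rate(prof(1, 60), prof(1, 10)), "t2")
})

test_that("nitrogen budget follows the mass-balance definitions and clamps", {
  b <- nitrogen_budget(10, 3, 1, 1)
  expect_equal(b$denit, 6)
  expect_equal(b$nh4_oxidation, 7)
  expect_equal(b$denit_fraction, 0.6)
  expect_false(b$negligible)
  # budget identity holds by construction
  expect_equal(b$production - b$din_efflux - b$accumulation - b$denit_raw, 0)

  clean <- nitrogen_budget(2, 2, 0, 0)
  expect_equal(clean$denit, 0)
  expect_false(clean$negligible)
  expect_equal(clean$denit_fraction, 0)

  clamped <- nitrogen_budget(2, 2.5, 0, 0)
  expect_equal(clamped$denit_raw, -0.5)
  expect_equal(clamped$denit, 0)
  expect_true(clamped$negligible)

  inc <- nitrogen_budget(depth_integrate(data.frame(
    top_cm = c(0, 2, 5, 15), bottom_cm = c(2, 5, 10, 20),
    rate = c(1, NA, 1, 1))), 1, 1, 0)
  expect_true(inc$incomplete)
})

test_that("flux aggregation weights days and reports SEM across cores", {
  f <- data.frame(day = 5, core_id = 1:3, value = c(5, 6, 7))
  a <- aggregate_fluxes(f, c(0, 10))
  expect_equal(a$value, 6)
  expect_equal(a$sem, sd(c(5, 6, 7)) / sqrt(3), tolerance = 1e-12)

  single <- aggregate_fluxes(data.frame(day = 5, core_id = 1, value = 4),
                             c(0, 10))
  expect_equal(single$value, 4)
  expect_true(single$single_measurement)
  expect_true(is.na(single$sem))

  two <- aggregate_fluxes(
    data.frame(day = c(2, 6), core_id = 1, value = c(2, 4)), c(0, 8))
  expect_equal(two$value, 3)  # equal spacing -> equal weights

  expect_error(aggregate_fluxes(f, c(20, 30)), "window")
})
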