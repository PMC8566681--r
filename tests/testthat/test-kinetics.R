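test_that("the log-linear fit reproduces reference kinetic parameters", {
  almond <- fit_kinetics(data.frame(temperature_C = c(70, 90, 100),
                                    ip_hours = c(85.00, 20.62, 8.83)))
  expect_equal(almond$log_ip0, 4.2126)
  expect_equal(almond$k0, 0.0325)
  expect_equal(round(almond$r_squared, 4), 0.9979)

  pecan <- fit_kinetics(data.frame(temperature_C = c(70, 90, 100),
                                   ip_hours = c(151.00, 25.08, 10.11)))
  expect_equal(pecan$log_ip0, 4.9179)

  # exact generating law is recovered exactly
  exact <- fit_kinetics(data.frame(temperature_C = c(70, 90, 100),
                                   ip_hours = 10^(5 - 0.04 * c(70, 90, 100))))
  expect_equal(exact$log_ip0, 5.0000)
  expect_equal(exact$k0, 0.0400)
  expect_equal(exact$r_squared, 1)
})

test_that("all refittable packaged oils reproduce parameters and day counts", {
  kin <- oil_kinetics_reference()
  ips <- oil_induction_periods()
  for (oil in kin$oil_id) {
    sub <- ips[ips$oil_id == oil & !ips$censored, ]
    k <- kin[kin$oil_id == oil, ]
    law <- if (nrow(sub) >= 3) {
      fit <- fit_kinetics(sub)
      expect_equal(fit$log_ip0, k$log_ip0, label = paste(oil, "log_ip0"))
      expect_equal(fit$k0, k$k0, label = paste(oil, "k0"))
      expect_equal(fit$r_squared, k$r_squared, tolerance = 2e-4,
                   label = paste(oil, "R2"))
      fit
    } else {
      kinetic_law(k$log_ip0, k$k0)  # peanut: reported parameters
    }
    expect_identical(hours_to_days(law_ip(law, 20)), as.integer(k$shelf_life_20),
                     label = paste(oil, "20C"))
    expect_identical(hours_to_days(law_ip(law, 25)), as.integer(k$shelf_life_25),
                     label = paste(oil, "25C"))
  }
})

test_that("shelf-life extrapolation converts and rounds as reported", {
  almond <- fit_kinetics(data.frame(temperature_C = c(70, 90, 100),
                                    ip_hours = c(85.00, 20.62, 8.83)))
  est <- extrapolate_shelf_life(almond, 25)
  expect_identical(est$days, 105L)

  peanut <- kinetic_law(5.3799, 0.0385)
  expect_identical(extrapolate_shelf_life(peanut, 25)$days, 1089L)
  expect_identical(extrapolate_shelf_life(peanut, 20)$days, 1697L)

  constant <- kinetic_law(log10(24), 0)
  expect_identical(extrapolate_shelf_life(constant, 25)$days, 1L)

  # strictly decreasing in ambient temperature when k0 > 0
  days <- vapply(c(5, 15, 25, 35), function(T)
    10^(almond$log_ip0 - almond$k0 * T), 0)
  expect_true(all(diff(days) < 0))

  expect_error(extrapolate_shelf_life(almond, 70), "below the fitting range")
  expect_error(extrapolate_shelf_life(almond, 90), "below the fitting range")
})

test_that("censored and insufficient measurements are handled explicitly", {
  df <- data.frame(temperature_C = c(70, 90, 100),
                   ip_hours = c(NA, 81.52, 33.62),
                   censored = c(TRUE, FALSE, FALSE))
  expect_warning(expect_error(fit_kinetics(df), "insufficient data"),
                 "censored")
  expect_error(fit_kinetics(data.frame(temperature_C = c(70, 70, 90),
                                       ip_hours = c(10, 11, 5))),
               "insufficient data")
  expect_error(fit_kinetics(data.frame(temperature_C = c(70, 90, 100),
                                       ip_hours = c(10, -1, 5))),
               "positive")
})

test_that("fitting simulator output recovers the generating law", {
  law <- kinetic_law(4.2126, 0.0325)
  curves <- simulate_temperature_series(law, c(70, 90, 100),
                                        curve_params(noise_sd = 0))
  res <- pipeline_shelf_life(curves, ambient = 25)
  expect_lt(abs(res$fit$log_ip0_full - 4.2126) / 4.2126, 0.005)
  expect_lt(abs(res$fit$k0_full - 0.0325) / 0.0325, 0.005)
  expect_identical(res$estimates[[1]]$days, 105L)
})

test_that("pipeline errors identify the failing stage", {
  law <- kinetic_law(4.2126, 0.0325)
  curves <- simulate_temperature_series(law, c(90, 100),
                                        curve_params(noise_sd = 0))
  expect_error(suppressWarnings(pipeline_shelf_life(curves)),
               "kinetics stage")
  flat <- raw_curve(seq(0, 10, 0.05), rep(800, 201))
  expect_error(pipeline_shelf_life(list(flat, flat, flat)),
               "detection stage")
})

test_that("induction-period tables round-trip and validate their schema", {
  ips <- oil_induction_periods()
  expect_equal(nrow(ips), 30)
  expect_equal(sum(ips$censored), 1)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_ip_csv(ips, path)
  expect_equal(read_ip_csv(path), ips)

  bad <- tempfile(fileext = ".csv")
  on.exit(unlink(bad), add = TRUE)
  writeLines("oil_id,temperature_C", bad)
  expect_error(read_ip_csv(bad), "missing required column")
})
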