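test_that("correlation screen reproduces the reference coefficients", {
  rec <- oil_records()
  expect_equal(nrow(rec), 9)
  expect_false("Pumpkin seed oil" %in% rec$oil_id)  # exclusion rule honoured

  ufa <- pearson_with_significance(rec$ufa, rec$shelf_life_25)
  expect_within(ufa$r, -0.6951, 5e-4)
  expect_lt(ufa$p, 0.05)

  iv <- pearson_with_significance(rec$iodine_value, rec$shelf_life_25)
  expect_within(iv$r, -0.5320, 5e-4)
  expect_gt(iv$p, 0.05)

  # log IP rows reproduce once the censored peanut value is filled from its law
  cref <- oil_correlations_reference()
  for (v in c("log_ip_70", "log_ip_90", "log_ip_100", "ufa", "sfa", "pufa",
              "sfa_ufa_ratio", "smoke_point", "iodine_value")) {
    r20 <- pearson_with_significance(rec[[v]], rec$shelf_life_20)$r
    r25 <- pearson_with_significance(rec[[v]], rec$shelf_life_25)$r
    expect_within(r20, cref$r_20[cref$variable == v], 5e-4,
                  label = paste(v, "20C"))
    expect_within(r25, cref$r_25[cref$variable == v], 5e-4,
                  label = paste(v, "25C"))
  }
})

test_that("pearson_with_significance handles exact and degenerate inputs", {
  x <- 1:10
  exact <- pearson_with_significance(x, 2 * x + 1)
  expect_equal(exact$r, 1)
  expect_lt(exact$p, 1e-12)

  expect_error(pearson_with_significance(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_with_significance(1:4, 1:5), "equal length")
  expect_error(pearson_with_significance(1:2, 2:3), "n >= 3")
})

test_that("grouped regression reproduces the reference models", {
  rec <- oil_records()
  m <- fit_grouped_model(rec, "ufa", 25)
  expect_identical(c(m$b1_rounded, m$b2_rounded, m$b0_rounded),
                   c(-88, 347, 7868))
  expect_within(m$multiple_r, 0.8885, 5e-4)
  expect_within(m$p_value, 0.0093, 5e-4)

  sfa20 <- fit_grouped_model(rec, "sfa", 20)
  expect_within(sfa20$p_value, 0.0266, 5e-4)

  # multiple correlation and significance of every reference model
  mref <- oil_models_reference()
  for (i in seq_len(nrow(mref))) {
    fit <- fit_grouped_model(rec, mref$predictor[i], mref$response[i])
    expect_within(fit$multiple_r, mref$multiple_r[i], 5e-4,
                  label = paste(mref$predictor[i], mref$response[i], "r"))
    expect_within(fit$p_value, mref$p_value[i], 5e-4,
                  label = paste(mref$predictor[i], mref$response[i], "p"))
  }
})

test_that("grouped regression equals the normal-equations oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:15, 1)
    x1 <- runif(n, 5, 95)
    x2 <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both groups guaranteed
    y <- 500 - 4 * x1 + 300 * x2 + rnorm(n, 0, 25)
    rec <- data.frame(ufa = x1, group_x2 = x2, shelf_life_25 = y,
                      shelf_life_20 = y)
    fit <- fit_grouped_model(rec, "ufa", 25)
    oracle <- normal_equations_fit(x1, x2, y)
    expect_equal(fit$b0, oracle$b0, tolerance = 1e-9)
    expect_equal(fit$b1, oracle$b1, tolerance = 1e-9)
    expect_equal(fit$b2, oracle$b2, tolerance = 1e-9)
    expect_equal(fit$multiple_r, oracle$multiple_r, tolerance = 1e-9)
  }
})

test_that("degenerate designs are rejected or guarded", {
  rec <- data.frame(ufa = c(80, 85, 90, 95), group_x2 = c(0, 0, 0, 0),
                    shelf_life_25 = c(100, 200, 300, 400))
  expect_error(fit_grouped_model(rec, "ufa", 25), "one X2 group")

  rec$group_x2 <- c(0, 0, 1, 1)
  rec$ufa <- rec$group_x2 * 10 + 50  # collinear with the indicator
  expect_error(fit_grouped_model(rec, "ufa", 25), "collinear")

  rec <- data.frame(ufa = c(80, 85, 90, 95), group_x2 = c(0, 1, 0, 1),
                    shelf_life_25 = rep(250, 4))
  m <- fit_grouped_model(rec, "ufa", 25)
  expect_identical(m$multiple_r, 0)
  expect_identical(m$p_value, 1)
})

test_that("prediction applies the linear form and validates the indicator", {
  published <- grouped_regression_model(b0 = 7868, b1 = -88, b2 = 347,
                                        predictor_name = "ufa", response = 25)
  expect_identical(predict_shelf_life(published, 84.06, 1), 818L)

  flatm <- grouped_regression_model(b0 = 42, b1 = 0, b2 = 0)
  expect_identical(predict_shelf_life(flatm, c(10, 50, 90), c(0, 1, 0)),
                   rep(42L, 3))

  expect_error(predict_shelf_life(published, 84.06, 2), "x2 must be 0 or 1")
  expect_warning(predict_shelf_life(published, 200, 0), "negative prediction")
})

test_that("per-group simple regressions show the two-curve structure", {
  rec <- oil_records()
  lines <- simple_group_regressions(rec, "ufa", 25)
  expect_equal(nrow(lines), 2)
  expect_true(all(abs(lines$r) > 0.98))
  expect_true(all(lines$p < 0.05))

  # a group generated exactly on a line has |r| = 1
  exact <- data.frame(ufa = c(1:4, 1:4), group_x2 = rep(c(0, 1), each = 4),
                      shelf_life_25 = c(2 * (1:4) + 3, 30 - 5 * (1:4)))
  lines <- simple_group_regressions(exact, "ufa", 25)
  expect_equal(lines$r, c(1, -1))

  small <- data.frame(ufa = c(1, 2, 3, 4, 5), group_x2 = c(0, 0, 0, 1, 1),
                      shelf_life_25 = c(1, 2, 3, 4, 5))
  expect_error(simple_group_regressions(small, "ufa", 25),
               "insufficient data")
})
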