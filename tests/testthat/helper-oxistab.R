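# Shared test helpers.

# Independent brute-force oracle for the grouped regression: solve the
# normal equations directly (no lm).
normal_equations_fit <- function(x1, x2, y) {
  X <- cbind(1, x1, x2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  list(b0 = beta[1], b1 = beta[2], b2 = beta[3],
       multiple_r = sqrt(1 - rss / tss))
}

# A curve object built directly from vectors (bypassing the simulator).
raw_curve <- function(times, pressures, temperature = 90) {
  structure(list(times = times, pressures = pressures,
                 temperature = temperature, true_ip = NULL, params = NULL),
            class = "oxidation_curve")
}

# Absolute-tolerance comparison (expect_equal's tolerance is relative).
expect_within <- function(actual, expected, tol, label = NULL) {
  expect_lt(abs(actual - expected), tol + 1e-12, label = label)
}

# Random valid profile over a subset of the vocabulary (totals < 100).
random_profile <- function(id = "random oil") {
  codes <- sample(fa_vocabulary(), sample(3:8, 1))
  vals <- stats::runif(length(codes), 0, 100 / length(codes))
  fa_profile(id, stats::setNames(vals, codes))
}
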