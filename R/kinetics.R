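# Zero-order log-linear oxidation kinetics and ambient shelf-life
# extrapolation.

# Round half away from zero (the convention of shelf-life day counts;
# base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert an extrapolated induction period to whole days
#'
#' Hours are first rounded to the nearest whole hour, then divided by 24 and
#' rounded half away from zero. Reporting hours at integer precision before
#' the day conversion is the convention this package uses to reproduce
#' published day counts consistently (see the methods vignette).
#'
#' @param ip_hours Induction period, hours.
#' @return Integer days.
#' @export
hours_to_days <- function(ip_hours) {
  as.integer(round_half_away(round_half_away(ip_hours) / 24))
}

collect_measurements <- function(measurements) {
  if (is.data.frame(measurements)) {
    stopifnot(all(c("temperature_C", "ip_hours") %in% names(measurements)))
    data.frame(
      temperature_C = measurements$temperature_C,
      ip_hours = measurements$ip_hours,
      censored = if ("censored" %in% names(measurements))
        isTRUE_vec(measurements$censored) else FALSE
    )
  } else {
    stopifnot(all(vapply(measurements, inherits, TRUE, "ip_measurement")))
    data.frame(
      temperature_C = vapply(measurements, `[[`, 0, "temperature"),
      ip_hours = vapply(measurements, `[[`, 0, "ip"),
      censored = vapply(measurements, function(m) isTRUE(m$censored), TRUE)
    )
  }
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Fit the zero-order log-linear temperature law
#'
#' Ordinary least squares of `log10(IP)` on temperature (degC):
#' `log10(IP) = log_ip0 - k0 * T`. Censored measurements (induction period
#' beyond the instrument limit) are excluded with a warning. The fitted
#' parameters are stored at the 4-decimal reporting precision — the precision
#' at which such laws are published and at which downstream shelf-life tables
#' are reproducible — with full-precision copies alongside.
#'
#' @param measurements A data frame with columns `temperature_C`, `ip_hours`
#'   and optionally `censored`, or a list of `ip_measurement` objects.
#' @return Object of class `c("kinetic_fit", "kinetic_law")`: `log_ip0`,
#'   `k0`, `r_squared` (squared Pearson correlation of log10 IP with
#'   temperature), `n_points`, `temperatures_used`, plus `log_ip0_full`,
#'   `k0_full`.
#' @examples
#' fit_kinetics(data.frame(temperature_C = c(70, 90, 100),
#'                         ip_hours = c(85.00, 20.62, 8.83)))
#' @export
fit_kinetics <- function(measurements) {
  df <- collect_measurements(measurements)
  if (any(df$censored)) {
    warning(sum(df$censored), " censored measurement(s) excluded from the fit")
    df <- df[!df$censored, , drop = FALSE]
  }
  if (any(!is.finite(df$ip_hours) | df$ip_hours <= 0)) {
    stop("all induction periods must be positive and finite")
  }
  if (length(unique(df$temperature_C)) < 3L) {
    stop("insufficient data: need measurements at >= 3 distinct temperatures")
  }
  y <- log10(df$ip_hours)
  fit <- stats::lm(y ~ temperature_C, data = df)
  b <- stats::coef(fit)
  r2 <- stats::cor(y, df$temperature_C)^2
  structure(list(
    log_ip0 = round(unname(b[1]), 4),
    k0 = round(-unname(b[2]), 4),
    r_squared = r2,
    n_points = nrow(df),
    temperatures_used = sort(unique(df$temperature_C)),
    log_ip0_full = unname(b[1]),
    k0_full = -unname(b[2])
  ), class = c("kinetic_fit", "kinetic_law"))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> log10(IP) = %.4f - %.4f T  (R^2 = %.4f, n = %d at %s degC)\n",
    x$log_ip0, x$k0, x$r_squared, x$n_points,
    paste(x$temperatures_used, collapse = "/")))
  invisible(x)
}

#' @export
print.kinetic_law <- function(x, ...) {
  cat(sprintf("<kinetic_law> log10(IP) = %.4f - %.4f T\n", x$log_ip0, x$k0))
  invisible(x)
}

#' Extrapolate an ambient shelf-life from a fitted law
#'
#' Evaluates `IP = 10^(log_ip0 - k0 * T)` at an ambient temperature below the
#' fitting range and converts hours to whole days via [hours_to_days()].
#' Extrapolation is only meaningful downward in temperature: asking for a
#' temperature at or above the lowest fitted temperature is an error.
#'
#' @param fit A `kinetic_fit` (or a bare [kinetic_law()], e.g. built from
#'   published parameters, in which case no range check applies).
#' @param temperature Ambient temperature, degC.
#' @return Object of class `shelf_life_estimate`: `temperature`, `ip_hours`,
#'   `days`.
#' @examples
#' fit <- fit_kinetics(data.frame(temperature_C = c(70, 90, 100),
#'                                ip_hours = c(85.00, 20.62, 8.83)))
#' extrapolate_shelf_life(fit, 25)  # 105 days
#' @export
extrapolate_shelf_life <- function(fit, temperature) {
  stopifnot(inherits(fit, "kinetic_law"), is.numeric(temperature),
            length(temperature) == 1L)
  if (inherits(fit, "kinetic_fit") &&
      temperature >= min(fit$temperatures_used)) {
    stop("extrapolation must target a temperature below the fitting range (< ",
         min(fit$temperatures_used), " degC)")
  }
  ip_hours <- law_ip(fit, temperature)
  structure(list(temperature = temperature, ip_hours = ip_hours,
                 days = hours_to_days(ip_hours)),
            class = "shelf_life_estimate")
}

#' @export
print.shelf_life_estimate <- function(x, ...) {
  cat(sprintf("<shelf_life_estimate> %d days at %g degC (%.1f h)\n",
              x$days, x$temperature, x$ip_hours))
  invisible(x)
}

#' Full shelf-life pipeline: detect, fit, extrapolate
#'
#' Chains [two_tangent_ip()] over a set of curves at different temperatures,
#' [fit_kinetics()] on the detected induction periods, and
#' [extrapolate_shelf_life()] at the requested ambient temperatures. Errors
#' are re-signalled with the failing stage named.
#'
#' @param curves List of `oxidation_curve` at >= 3 distinct temperatures.
#' @param config A [detection_config()].
#' @param ambient Vector of ambient temperatures, degC (default 20 and 25).
#' @param censor_at Optional detection run limit in hours, passed through to
#'   [two_tangent_ip()].
#' @return List with `ips` (data frame of per-curve measurements), `fit`
#'   (the `kinetic_fit`) and `estimates` (list of `shelf_life_estimate`,
#'   one per ambient temperature).
#' @export
pipeline_shelf_life <- function(curves, config = detection_config(),
                                ambient = c(20, 25), censor_at = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, " stage: ", conditionMessage(e), call. = FALSE)
    })
  }
  measurements <- stage("detection", lapply(curves, two_tangent_ip,
                                            config = config,
                                            censor_at = censor_at))
  ips <- collect_measurements(measurements)
  fit <- stage("kinetics", fit_kinetics(ips))
  estimates <- stage("extrapolation",
                     lapply(ambient, function(T)
                       extrapolate_shelf_life(fit, T)))
  list(ips = ips, fit = fit, estimates = estimates)
}

#' Read / write an induction-period table
#'
#' Long format: columns `oil_id`, `temperature_C`, `ip_hours`, `censored`.
#' Censored entries have an empty `ip_hours` cell. `#` lines are comments.
#'
#' @param path CSV path.
#' @return Data frame with those four columns.
#' @export
read_ip_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  required <- c("oil_id", "temperature_C", "ip_hours", "censored")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df$ip_hours <- as.numeric(df$ip_hours)
  df$censored <- isTRUE_vec(df$censored)
  if (any(!df$censored & (is.na(df$ip_hours) | df$ip_hours <= 0))) {
    stop("non-censored rows must have positive ip_hours")
  }
  df[required]
}

#' @rdname read_ip_csv
#' @param df Data frame as returned by `read_ip_csv`.
#' @export
write_ip_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
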