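# Two-tangent induction-period detection on oxygen-pressure curves.
#
# The induction period is the time coordinate where the baseline tangent
# (least-squares line over the early, pre-oxidation part of the record)
# intersects the tangent at the steepest-descent point of the smoothed curve.

#' Detection configuration
#'
#' @param smoothing_window Samples per local-linear smoothing fit (an odd
#'   count of at least 3). Default `max(5, 0.5 h / dt)`, i.e. half-hour
#'   windows at the default sampling interval.
#' @param baseline_span Fraction pair `(start, end)` of the steepest-descent
#'   time defining the baseline-fit region. The default `(0.05, 0.5)` skips
#'   the first 5% of the pre-onset record to avoid equilibration transients.
#' @param tangent_halfwidth Samples on each side of the steepest-descent
#'   point used for the descent tangent. Default `max(5, 1%)` of the record.
#' @param min_slope_separation Minimum absolute slope difference (kPa/h)
#'   between the two tangents for an onset to count as detected.
#' @return Object of class `detection_config`.
#' @export
detection_config <- function(smoothing_window = NULL,
                             baseline_span = c(0.05, 0.5),
                             tangent_halfwidth = NULL,
                             min_slope_separation = 1) {
  stopifnot(length(baseline_span) == 2L,
            baseline_span[1] >= 0, baseline_span[1] < baseline_span[2],
            baseline_span[2] <= 1,
            min_slope_separation > 0)
  if (!is.null(smoothing_window)) {
    stopifnot(smoothing_window >= 3)
  }
  if (!is.null(tangent_halfwidth)) {
    stopifnot(tangent_halfwidth >= 1)
  }
  structure(list(smoothing_window = smoothing_window,
                 baseline_span = baseline_span,
                 tangent_halfwidth = tangent_halfwidth,
                 min_slope_separation = min_slope_separation),
            class = "detection_config")
}

# Least-squares slope and intercept of y on x.
ls_line <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  c(intercept = ym - slope * xm, slope = slope)
}

#' Smoothed derivative of a pressure curve
#'
#' Slope of the local least-squares line centred at each sample; the first
#' and last half-windows use one-sided windows. Local-linear slopes (rather
#' than raw finite differences) keep the derivative usable at the typical
#' instrument noise level.
#'
#' @param curve An `oxidation_curve`.
#' @param window Window size in samples (odd, >= 3, < record length).
#' @return Numeric vector of dP/dt values (kPa/h), one per sample.
#' @export
smoothed_derivative <- function(curve, window) {
  stopifnot(inherits(curve, "oxidation_curve"))
  n <- length(curve$times)
  if (window >= n) stop("window (", window, ") must be smaller than the series (", n, ")")
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  t <- curve$times; p <- curve$pressures
  h <- (window - 1L) %/% 2L
  dt <- t[2] - t[1]
  # interior: centred local-linear slope is a convolution with k = -h..h
  k <- seq(-h, h)
  denom <- dt * sum(k^2)
  sl <- stats::filter(p, rev(k) / denom, method = "convolution", sides = 2)
  sl <- as.numeric(sl)
  # one-sided endpoint windows
  for (i in seq_len(h)) {
    idx <- 1:(i + h)
    sl[i] <- ls_line(t[idx], p[idx])[["slope"]]
    idx <- (n - i - h + 1L):n
    sl[n - i + 1L] <- ls_line(t[idx], p[idx])[["slope"]]
  }
  sl
}

default_window <- function(config, dt, n) {
  w <- config$smoothing_window %||% max(5, round(0.5 / dt))
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  min(w, if (n %% 2L == 0L) n - 1L else n - 2L)
}

#' Two-tangent induction-period detection
#'
#' Implements the two-tangent reading of an oxygen-pressure record:
#' (1) smooth the curve by moving local-linear fits; (2) locate the time of
#' the most negative smoothed derivative (earliest sample on ties);
#' (3) fit the descent tangent over a window around that point; (4) fit the
#' baseline tangent over the `baseline_span` fraction of the pre-onset
#' record; (5) report the time coordinate of their intersection, rounded to
#' 2 decimals (the reporting precision of induction-period tables).
#'
#' @param curve An `oxidation_curve` with at least 50 samples.
#' @param config A [detection_config()].
#' @param censor_at Optional run limit in hours (instruments of this type
#'   cap runs, typically at 240 h). If no onset is detected, or the
#'   intersection falls beyond the limit, a censored measurement (`ip = NA`,
#'   `censored = TRUE`) is returned instead of an error.
#' @return Object of class `ip_measurement`: `ip` (h), `temperature`,
#'   `censored`, and `diagnostics` (tangent slopes/intercepts and the
#'   steepest-descent time).
#' @examples
#' cv <- simulate_curve(curve_params(t_c = 38.2, noise_sd = 0), 90)
#' two_tangent_ip(cv)$ip  # ~36.2
#' @export
two_tangent_ip <- function(curve, config = detection_config(),
                           censor_at = NULL) {
  stopifnot(inherits(curve, "oxidation_curve"),
            inherits(config, "detection_config"))
  n <- length(curve$times)
  if (n < 50L) stop("curve too short: need >= 50 samples, got ", n)
  t <- curve$times; p <- curve$pressures
  dt <- t[2] - t[1]

  censored <- function() {
    structure(list(ip = NA_real_, temperature = curve$temperature,
                   censored = TRUE,
                   diagnostics = list(censor_at = censor_at)),
              class = "ip_measurement")
  }
  onset_failure <- function(msg) {
    if (!is.null(censor_at)) return(censored())
    stop(msg, call. = FALSE)
  }

  w <- default_window(config, dt, n)
  deriv <- smoothed_derivative(curve, w)
  i_star <- which.min(deriv)            # earliest index on exact ties
  t_star <- t[i_star]

  # baseline region: fractions of t_star
  lo <- config$baseline_span[1] * t_star
  hi <- config$baseline_span[2] * t_star
  base_idx <- which(t >= lo & t <= hi)
  if (length(base_idx) < 3L) {
    res <- onset_failure("no oxidation onset detected (degenerate baseline region)")
    if (inherits(res, "ip_measurement")) return(res)
  }
  L1 <- ls_line(t[base_idx], p[base_idx])

  hw <- as.integer(config$tangent_halfwidth %||% max(5, ceiling(0.01 * n)))
  tan_idx <- max(1L, i_star - hw):min(n, i_star + hw)
  L2 <- ls_line(t[tan_idx], p[tan_idx])

  if (abs(L1[["slope"]] - L2[["slope"]]) < config$min_slope_separation) {
    res <- onset_failure("no oxidation onset detected (tangent slopes coincide)")
    if (inherits(res, "ip_measurement")) return(res)
  }

  ip <- (L1[["intercept"]] - L2[["intercept"]]) /
    (L2[["slope"]] - L1[["slope"]])
  if (!is.null(censor_at) && ip > censor_at) return(censored())
  if (!(ip > 0 && ip <= max(t))) {
    stop("breakpoint outside record: intersection at ", format(ip), " h",
         call. = FALSE)
  }
  structure(list(ip = round(ip, 2), temperature = curve$temperature,
                 censored = FALSE,
                 diagnostics = list(
                   baseline_intercept = L1[["intercept"]],
                   baseline_slope = L1[["slope"]],
                   tangent_intercept = L2[["intercept"]],
                   tangent_slope = L2[["slope"]],
                   t_star = t_star,
                   smoothing_window = w)),
            class = "ip_measurement")
}

#' @export
print.ip_measurement <- function(x, ...) {
  if (isTRUE(x$censored)) {
    cat("<ip_measurement> censored (no onset within record/limit)\n")
  } else {
    cat(sprintf("<ip_measurement> IP = %.2f h at %s degC\n", x$ip,
                format(x$temperature)))
  }
  invisible(x)
}
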