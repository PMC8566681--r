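# Seeded simulator of accelerated-oxidation oxygen-pressure curves.
#
# Model: a slow linear baseline consumption superimposed with a logistic
# accelerated-consumption phase,
#   P(t) = p0 - m1 t - d / (1 + exp(-s (t - t_c))) + noise.
# The two-tangent induction period of the noiseless curve has the closed form
# t_c - 2/s (intersection of the baseline line with the tangent at the
# steepest-descent point), independent of d and m1, which gives the simulator
# an exact ground truth against which detection can be validated.

#' Parameters of a simulated oxygen-pressure curve
#'
#' @param p0 Initial chamber pressure, kPa. Instruments of this type operate
#'   at 600-800 kPa; default 800.
#' @param m1 Baseline consumption slope, kPa/h (small, >= 0).
#' @param d Total pressure drop of the accelerated phase, kPa.
#' @param s Logistic steepness, 1/h.
#' @param t_c Logistic centre time, h. The ground-truth induction period is
#'   `t_c - 2/s`.
#' @param duration Record length, h; defaults to `1.5 * t_c`.
#' @param dt Sampling interval, h.
#' @param noise_sd Additive Gaussian noise, kPa. The default 0.5 kPa is about
#'   0.06% of the 800 kPa setpoint.
#' @param seed Integer seed for the noise, or `NULL` for unseeded noise.
#' @return Object of class `curve_params`.
#' @export
curve_params <- function(p0 = 800, m1 = 0.1, d = 200, s = 1, t_c = 40,
                         duration = NULL, dt = 0.05, noise_sd = 0.5,
                         seed = NULL) {
  if (is.null(duration)) duration <- 1.5 * t_c
  stopifnot(p0 > 0, m1 >= 0, d > 0, s > 0, dt > 0, noise_sd >= 0)
  if (!(t_c > 0 && t_c < duration)) {
    stop("t_c must lie strictly inside (0, duration)")
  }
  structure(list(p0 = p0, m1 = m1, d = d, s = s, t_c = t_c,
                 duration = duration, dt = dt, noise_sd = noise_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "curve_params")
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one oxygen-pressure curve
#'
#' @param params A [curve_params()] object.
#' @param temperature Chamber temperature, degC (instrument range 50-110).
#' @return Object of class `oxidation_curve`: list with `times` (h,
#'   starting at 0), `pressures` (kPa), `temperature`, `true_ip` (h,
#'   closed-form ground truth) and `params`.
#' @details Identical seeds reproduce identical curves bit for bit. The
#'   closed-form induction period `t_c - 2/s` must be positive, otherwise the
#'   parameters describe a curve whose onset precedes the record.
#' @examples
#' cv <- simulate_curve(curve_params(t_c = 38.2, noise_sd = 0, seed = 1), 90)
#' cv$true_ip  # 36.2
#' @export
simulate_curve <- function(params, temperature) {
  stopifnot(inherits(params, "curve_params"))
  check_temperature(temperature)
  true_ip <- params$t_c - 2 / params$s
  if (true_ip <= 0) {
    stop("induction period not representable: t_c - 2/s = ", format(true_ip))
  }
  times <- seq(0, params$duration, by = params$dt)
  if (length(times) < 50L) {
    stop("curve too short: need >= 50 samples, got ", length(times))
  }
  clean <- params$p0 - params$m1 * times -
    params$d / (1 + exp(-params$s * (times - params$t_c)))
  noise <- if (params$noise_sd > 0) {
    with_seed(params$seed, stats::rnorm(length(times), 0, params$noise_sd))
  } else {
    0
  }
  structure(list(times = times, pressures = clean + noise,
                 temperature = temperature, true_ip = true_ip,
                 params = params),
            class = "oxidation_curve")
}

check_temperature <- function(temperature) {
  if (!(is.numeric(temperature) && length(temperature) == 1L &&
        temperature >= 50 && temperature <= 110)) {
    stop("temperature must be a single value within 50-110 degC")
  }
  invisible(temperature)
}

#' @export
print.oxidation_curve <- function(x, ...) {
  cat(sprintf("<oxidation_curve> %d samples over %.1f h at %g degC",
              length(x$times), max(x$times), x$temperature))
  if (!is.null(x$true_ip)) cat(sprintf(", true IP %.2f h", x$true_ip))
  cat("\n")
  invisible(x)
}

#' Temperature law for induction periods
#'
#' The zero-order log-linear law of the oxidative-stability literature
#' (OSI convention): `log10(IP) = log_ip0 - k0 * T`, with T in degC.
#'
#' @param log_ip0 Intercept, log10 hours.
#' @param k0 Rate constant, per degC (positive for physically meaningful laws).
#' @return Object of class `kinetic_law`.
#' @export
kinetic_law <- function(log_ip0, k0) {
  stopifnot(is.numeric(log_ip0), is.numeric(k0))
  if (k0 < 0) warning("k0 < 0: induction period grows with temperature")
  structure(list(log_ip0 = log_ip0, k0 = k0), class = "kinetic_law")
}

#' Induction period implied by a temperature law
#'
#' @param law A `kinetic_law` (or `kinetic_fit`).
#' @param temperature degC.
#' @return IP in hours, `10^(log_ip0 - k0 * temperature)`.
#' @export
law_ip <- function(law, temperature) {
  stopifnot(inherits(law, "kinetic_law"))
  10^(law$log_ip0 - law$k0 * temperature)
}

#' Simulate curves across temperatures following a prescribed law
#'
#' For each temperature the logistic centre is placed at
#' `10^(log_ip0 - k0 * T) + 2/s`, so the ground-truth induction period equals
#' the law exactly; the record is auto-extended to at least `1.5 * t_c`.
#' Replicate curves get consecutive derived seeds when the template is seeded.
#'
#' @param law A [kinetic_law()].
#' @param temperatures Vector of degC values within 50-110.
#' @param template A [curve_params()] used for everything except `t_c` and
#'   `duration`.
#' @return List of `oxidation_curve`, one per temperature.
#' @examples
#' curves <- simulate_temperature_series(kinetic_law(4.2126, 0.0325),
#'                                       c(70, 90, 100),
#'                                       curve_params(noise_sd = 0, seed = 1))
#' sapply(curves, `[[`, "true_ip")
#' @export
simulate_temperature_series <- function(law, temperatures,
                                        template = curve_params()) {
  stopifnot(inherits(law, "kinetic_law"), inherits(template, "curve_params"))
  for (T in temperatures) check_temperature(T)
  lapply(seq_along(temperatures), function(i) {
    T <- temperatures[i]
    ip <- law_ip(law, T)
    t_c <- ip + 2 / template$s
    p <- template
    p$t_c <- t_c
    p$duration <- max(template$duration, 1.5 * t_c)
    if (!is.null(template$seed)) p$seed <- template$seed + i - 1L
    simulate_curve(p, T)
  })
}

#' Write / read a curve as CSV plus JSON sidecar
#'
#' The CSV holds two columns (`time_h`, `pressure_kPa`); the sidecar records
#' the generating parameters, temperature and ground-truth IP so a curve can
#' be reloaded with full provenance.
#'
#' @param curve An `oxidation_curve`.
#' @param prefix Path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_curve <- function(curve, prefix) {
  stopifnot(inherits(curve, "oxidation_curve"))
  utils::write.csv(data.frame(time_h = curve$times,
                              pressure_kPa = curve$pressures),
                   paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(temperature = curve$temperature, true_ip = curve$true_ip,
               params = unclass(curve$params))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_curve
#' @export
read_curve <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"))
  if (!all(c("time_h", "pressure_kPa") %in% names(df))) {
    stop("curve CSV must have columns time_h, pressure_kPa")
  }
  meta_path <- paste0(prefix, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  params <- if (!is.null(meta$params)) {
    do.call(curve_params, meta$params[!vapply(meta$params, is.null, TRUE)])
  } else {
    NULL
  }
  structure(list(times = df$time_h, pressures = df$pressure_kPa,
                 temperature = meta$temperature %||% NA_real_,
                 true_ip = meta$true_ip, params = params),
            class = "oxidation_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
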