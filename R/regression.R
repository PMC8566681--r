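# Correlation screen and grouped multiple-regression shelf-life models.
#
# The prediction model regresses shelf-life (days) on one saturation-class
# predictor X1 (SFA, UFA, SFA/UFA ratio, or PUFA) plus a binary group
# indicator X2 that parcels oil-type effects (tocopherol profile differences)
# not captured by the fatty-acid composition:
#   y = b0 + b1*X1 + b2*X2.

.predictor_columns <- c(
  sfa = "sfa", ufa = "ufa", pufa = "pufa", sfa_ufa_ratio = "sfa_ufa_ratio",
  SFAs = "sfa", UFAs = "ufa", PUFAs = "pufa", `SFAs/UFAs` = "sfa_ufa_ratio"
)

resolve_predictor <- function(predictor_name) {
  col <- .predictor_columns[predictor_name]
  if (is.na(col)) {
    stop("unknown predictor: ", predictor_name, " (use one of ",
         paste(unique(.predictor_columns), collapse = ", "), ")")
  }
  unname(col)
}

resolve_response <- function(response) {
  if (!response %in% c(20, 25)) stop("response must be 20 or 25 (degC)")
  paste0("shelf_life_", response)
}

#' Pearson correlation with a two-tailed significance test
#'
#' Sample Pearson r with the usual t-test on `n - 2` degrees of freedom
#' (`t = r * sqrt((n - 2) / (1 - r^2))`), as performed by
#' [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return List with `r`, `p` and `n`.
#' @export
pearson_with_significance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Construct or fit a grouped shelf-life regression model
#'
#' `fit_grouped_model()` fits `y = b0 + b1*X1 + b2*X2` by ordinary least
#' squares over a table of oil records; `grouped_regression_model()` builds
#' the same object directly from known (e.g. published) coefficients.
#' The overall significance is the F-test with `(2, n - 3)` degrees of
#' freedom; `multiple_r` is the square root of the coefficient of
#' determination.
#'
#' @param records Data frame of oil records with the predictor column,
#'   `shelf_life_20` / `shelf_life_25` and `group_x2` (0/1).
#' @param predictor_name One of `"sfa"`, `"ufa"`, `"pufa"`,
#'   `"sfa_ufa_ratio"` (the `"SFAs"`-style spellings are also accepted).
#' @param response Ambient temperature of the shelf-life response: 20 or 25.
#' @return Object of class `grouped_regression_model`: coefficients `b0`,
#'   `b1`, `b2` (unrounded), `multiple_r`, `p_value`, `n`, and the rounded
#'   coefficients (`b0_rounded`, ...) at the integer precision such
#'   equations are conventionally printed.
#' @examples
#' rec <- oil_records()
#' fit_grouped_model(rec, "ufa", 25)
#' @export
fit_grouped_model <- function(records, predictor_name, response) {
  col <- resolve_predictor(predictor_name)
  ycol <- resolve_response(response)
  stopifnot(is.data.frame(records), col %in% names(records),
            ycol %in% names(records), "group_x2" %in% names(records))
  if (nrow(records) < 4L) stop("need >= 4 records")
  x1 <- records[[col]]
  x2 <- records$group_x2
  y <- records[[ycol]]
  if (!all(x2 %in% c(0, 1))) stop("group_x2 must be 0 or 1")
  if (length(unique(x2)) < 2L) {
    stop("design degeneracy: only one X2 group present")
  }
  if (stats::var(x1) == 0) stop("predictor has zero variance")
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3L) stop("rank deficiency: predictor collinear with the group indicator")
  n <- length(y)
  if (stats::var(y) == 0) {
    # nothing to explain: guarded degenerate model
    return(new_grouped_model(b0 = mean(y), b1 = 0, b2 = 0, multiple_r = 0,
                             p_value = 1, n = n,
                             predictor_name = col, response = response))
  }
  fit <- stats::lm(y ~ x1 + x2)
  b <- stats::coef(fit)
  r2 <- summary(fit)$r.squared
  f <- summary(fit)$fstatistic
  p <- stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  new_grouped_model(b0 = unname(b[1]), b1 = unname(b[2]), b2 = unname(b[3]),
                    multiple_r = sqrt(r2), p_value = unname(p), n = n,
                    predictor_name = col, response = response)
}

new_grouped_model <- function(b0, b1, b2, multiple_r, p_value, n,
                              predictor_name, response) {
  structure(list(
    predictor_name = predictor_name, response = response,
    b0 = b0, b1 = b1, b2 = b2,
    b0_rounded = round_half_away(b0), b1_rounded = round_half_away(b1),
    b2_rounded = round_half_away(b2),
    multiple_r = multiple_r, p_value = p_value, n = n
  ), class = "grouped_regression_model")
}

#' @rdname fit_grouped_model
#' @param b0,b1,b2 Known coefficients (intercept, predictor slope, group
#'   offset in days).
#' @export
grouped_regression_model <- function(b0, b1, b2, predictor_name = "ufa",
                                     response = 25) {
  new_grouped_model(b0 = b0, b1 = b1, b2 = b2, multiple_r = NA_real_,
                    p_value = NA_real_, n = NA_integer_,
                    predictor_name = resolve_predictor(predictor_name),
                    response = response)
}

#' @export
print.grouped_regression_model <- function(x, ...) {
  cat(sprintf("<grouped_regression_model> y = %s*X1 %s %s*X2 %s %s  (%s, %d degC)\n",
              format(x$b1_rounded),
              if (x$b2_rounded < 0) "-" else "+", format(abs(x$b2_rounded)),
              if (x$b0_rounded < 0) "-" else "+", format(abs(x$b0_rounded)),
              x$predictor_name, x$response))
  if (!is.na(x$multiple_r)) {
    cat(sprintf("  multiple r = %.4f, p = %.4f, n = %d\n",
                x$multiple_r, x$p_value, x$n))
  }
  invisible(x)
}

#' Predict a shelf-life from a grouped model
#'
#' `y = b0 + b1*x1 + b2*x2`, using the model's unrounded coefficients,
#' reported to the nearest day. Negative predictions (outside the calibrated
#' range of the model) are flagged with a warning, never clamped silently.
#'
#' @param model A `grouped_regression_model`.
#' @param x1 Predictor value (class percentage or ratio).
#' @param x2 Group indicator, 0 or 1.
#' @return Predicted shelf-life in whole days (vectorised over `x1`/`x2`).
#' @export
predict_shelf_life <- function(model, x1, x2) {
  stopifnot(inherits(model, "grouped_regression_model"))
  if (!all(x2 %in% c(0, 1))) stop("x2 must be 0 or 1")
  y <- model$b0 + model$b1 * x1 + model$b2 * x2
  if (any(y < 0)) {
    warning("negative prediction: input outside the model's calibrated range")
  }
  as.integer(round_half_away(y))
}

#' Independent simple regressions per group
#'
#' Fits an ordinary least-squares line of shelf-life on the predictor within
#' each X2 group separately (the two-curve reading of the shelf-life versus
#' composition scatter), with per-group Pearson r and its p-value.
#'
#' @inheritParams fit_grouped_model
#' @return Data frame with one row per group: `group`, `n`, `slope`,
#'   `intercept`, `r`, `p`.
#' @export
simple_group_regressions <- function(records, predictor_name, response) {
  col <- resolve_predictor(predictor_name)
  ycol <- resolve_response(response)
  groups <- sort(unique(records$group_x2))
  rows <- lapply(groups, function(g) {
    sub <- records[records$group_x2 == g, , drop = FALSE]
    if (nrow(sub) < 3L) {
      stop("insufficient data: group ", g, " has n = ", nrow(sub), " (< 3)")
    }
    line <- ls_line(sub[[col]], sub[[ycol]])
    ct <- pearson_with_significance(sub[[col]], sub[[ycol]])
    data.frame(group = g, n = nrow(sub),
               slope = line[["slope"]], intercept = line[["intercept"]],
               r = ct$r, p = ct$p)
  })
  do.call(rbind, rows)
}
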