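# Packaged reference tables for the ten expeller-pressed oils and assembly
# of per-oil records for the correlation/regression stage.

oxistab_extdata <- function(file) {
  path <- system.file("extdata", file, package = "oxistab")
  if (!nzchar(path)) stop("missing packaged fixture: ", file)
  path
}

#' Packaged reference tables
#'
#' Loaders for the reference dataset of ten expeller-pressed seed oils that
#' ships with the package: fatty-acid compositions, physicochemical
#' properties with the regression group assignment, measured induction
#' periods at 70/90/100 degC, and the reported kinetic parameters,
#' shelf-lives, correlations and model coefficients used for
#' cross-validation by [reproduce_tables()].
#'
#' @return `oil_compositions()`: named list of `fa_profile`. The others:
#'   data frames.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
oil_compositions <- function() {
  read_composition_csv(oxistab_extdata("oil_fatty_acids.csv"))
}

#' @rdname reference_tables
#' @export
oil_reference <- function() {
  utils::read.csv(oxistab_extdata("oil_reference.csv"), comment.char = "#",
                  strip.white = TRUE)
}

#' @rdname reference_tables
#' @export
oil_induction_periods <- function() {
  read_ip_csv(oxistab_extdata("oil_induction_periods.csv"))
}

#' @rdname reference_tables
#' @export
oil_kinetics_reference <- function() {
  utils::read.csv(oxistab_extdata("oil_kinetics_reference.csv"),
                  comment.char = "#", strip.white = TRUE)
}

#' @rdname reference_tables
#' @export
oil_correlations_reference <- function() {
  utils::read.csv(oxistab_extdata("oil_correlations_reference.csv"),
                  comment.char = "#", strip.white = TRUE)
}

#' @rdname reference_tables
#' @export
oil_models_reference <- function() {
  utils::read.csv(oxistab_extdata("oil_models_reference.csv"),
                  comment.char = "#", strip.white = TRUE)
}

#' Assemble per-oil records for the correlation and regression stages
#'
#' Joins the packaged tables into one row per oil: computed saturation-class
#' aggregates and calculated iodine value from the composition table,
#' reported shelf-lives, smoke point, acid value, the group indicator, and
#' log10 induction periods at 70/90/100 degC. A censored induction period
#' (beyond the instrument run limit) is filled with the value implied by the
#' oil's reported kinetic law, the same substitution used when the published
#' correlations were computed; the `log_ip_filled` column flags such rows.
#'
#' @param include_excluded Keep oils flagged as excluded from the screens
#'   (pumpkin seed oil, whose chlorophyll content sets it apart)?
#'   Default `FALSE`.
#' @return Data frame with columns `oil_id`, `shelf_life_20`,
#'   `shelf_life_25`, `log_ip_70`, `log_ip_90`, `log_ip_100`,
#'   `log_ip_filled`, `smoke_point`, `acid_value`, `iodine_value`, `sfa`,
#'   `ufa`, `pufa`, `sfa_ufa_ratio`, `group_x2`.
#' @export
oil_records <- function(include_excluded = FALSE) {
  ref <- oil_reference()
  kin <- oil_kinetics_reference()
  ips <- oil_induction_periods()
  profiles <- oil_compositions()

  rows <- lapply(ref$oil_id, function(oil) {
    cls <- aggregate_classes(profiles[[oil]])
    iv <- iodine_value(profiles[[oil]])
    k <- kin[kin$oil_id == oil, ]
    ip <- ips[ips$oil_id == oil, ]
    law <- kinetic_law(k$log_ip0, k$k0)
    lip <- sapply(c(70, 90, 100), function(T) {
      row <- ip[ip$temperature_C == T, ]
      if (nrow(row) == 1L && !row$censored) log10(row$ip_hours)
      else log10(law_ip(law, T))
    })
    filled <- any(ip$censored)
    r <- ref[ref$oil_id == oil, ]
    data.frame(
      oil_id = oil,
      shelf_life_20 = k$shelf_life_20, shelf_life_25 = k$shelf_life_25,
      log_ip_70 = lip[1], log_ip_90 = lip[2], log_ip_100 = lip[3],
      log_ip_filled = filled,
      smoke_point = r$smoke_point, acid_value = r$acid_value,
      iodine_value = iv,
      sfa = cls$sfa, ufa = cls$ufa, pufa = cls$pufa,
      sfa_ufa_ratio = cls$sfa / cls$ufa,
      group_x2 = r$group_x2,
      excluded = r$excluded
    )
  })
  out <- do.call(rbind, rows)
  if (!include_excluded) out <- out[!out$excluded, , drop = FALSE]
  rownames(out) <- NULL
  out
}
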