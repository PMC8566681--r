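# Fatty-acid profiles, saturation-class aggregates and the calculated iodine value.

#' Known fatty-acid codes
#'
#' Vocabulary of fatty-acid codes accepted by [validate_profile()], in the
#' `Cx:y` notation (x carbon atoms, y double bonds).
#'
#' @return Character vector of codes.
#' @export
fa_vocabulary <- function() {
  c("C14:0", "C16:0", "C16:1", "C17:0", "C18:0", "C18:1",
    "C18:2", "C18:3", "C20:0", "C20:1", "C22:0", "C22:1")
}

# Calculated-IV weighting per unsaturated fatty acid (g I2 absorbed per gram,
# scaled to percent), AOCS calculated-iodine-value scheme.
.iv_coefficients <- c(
  "C16:1" = 0.950, "C18:1" = 0.860, "C18:2" = 1.732,
  "C18:3" = 2.616, "C20:1" = 0.785, "C22:1" = 0.723
)

#' Number of double bonds encoded in a fatty-acid code
#'
#' Parses the `y` of a `Cx:y` code. Class membership (SFA/MUFA/PUFA) is
#' derived from this count rather than from a hard-coded list, so extending
#' the vocabulary extends the classes for free.
#'
#' @param code Character vector of fatty-acid codes.
#' @return Integer vector of double-bond counts.
#' @export
double_bonds <- function(code) {
  ok <- grepl("^C[0-9]+:[0-9]+$", code)
  if (!all(ok)) {
    stop("malformed fatty-acid code(s): ", paste(code[!ok], collapse = ", "))
  }
  as.integer(sub("^C[0-9]+:", "", code))
}

#' Validate and normalise a raw fatty-acid composition
#'
#' Accepts a named numeric or character vector (or list) mapping fatty-acid
#' codes to percent of total FAMEs. Entries of `"ND"`, `""`, or `NA` (the
#' usual not-detected markers in composition tables) are mapped to 0.
#'
#' @param raw Named vector or list: fatty-acid code -> percent of total FAMEs.
#' @param oil_id Text label for the oil.
#' @return An object of class `fa_profile` with fields `oil_id` and
#'   `percentages` (named numeric over the full vocabulary; absent codes 0).
#' @details Validation rules: codes must belong to [fa_vocabulary()];
#'   percentages must be non-negative and parseable as numbers; the total
#'   must not exceed 101 (100 plus 1 unit of rounding slack on printed
#'   tables).
#' @examples
#' validate_profile(c("C18:0" = 50), oil_id = "stearin blend")
#' @export
validate_profile <- function(raw, oil_id = "oil") {
  raw <- unlist(as.list(raw))
  if (length(raw) == 0L) {
    vals <- stats::setNames(numeric(length(fa_vocabulary())), fa_vocabulary())
    return(structure(list(oil_id = oil_id, percentages = vals),
                     class = "fa_profile"))
  }
  codes <- names(raw)
  if (is.null(codes) || any(!nzchar(codes))) {
    stop("fatty-acid percentages must be named by code")
  }
  unknown <- setdiff(codes, fa_vocabulary())
  if (length(unknown) > 0L) {
    stop("unknown fatty-acid code(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(codes)) {
    stop("duplicated fatty-acid code(s): ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  if (is.character(raw)) {
    raw <- trimws(raw)
    nd <- raw %in% c("ND", "nd", "", "NA", "N.D.")
    num <- suppressWarnings(as.numeric(raw))
    num[nd] <- 0
    if (anyNA(num)) {
      stop("non-numeric percentage for: ",
           paste(codes[is.na(num)], collapse = ", "))
    }
  } else {
    num <- as.numeric(raw)
    num[is.na(num)] <- 0
  }
  if (any(num < 0)) {
    stop("negative percentage for: ", paste(codes[num < 0], collapse = ", "))
  }
  if (sum(num) > 101) {
    stop("percentages sum to ", format(sum(num)), " (> 101)")
  }
  vals <- stats::setNames(numeric(length(fa_vocabulary())), fa_vocabulary())
  vals[codes] <- num
  structure(list(oil_id = oil_id, percentages = vals), class = "fa_profile")
}

#' @rdname validate_profile
#' @param percentages As `raw` in `validate_profile`.
#' @export
fa_profile <- function(oil_id, percentages) {
  validate_profile(percentages, oil_id = oil_id)
}

#' @export
print.fa_profile <- function(x, ...) {
  cat("<fa_profile> ", x$oil_id, "\n", sep = "")
  nz <- x$percentages[x$percentages > 0]
  if (length(nz)) {
    print(round(nz, 2))
  } else {
    cat("  (empty profile)\n")
  }
  invisible(x)
}

#' Aggregate a profile into saturation classes
#'
#' Sums percentages by double-bond count: SFA (0 double bonds), MUFA (1),
#' PUFA (>= 2), UFA = MUFA + PUFA. Values are reported to 2 decimals, the
#' print precision of composition tables.
#'
#' @param profile An `fa_profile`.
#' @return Object of class `fa_class_summary`: list with `sfa`, `mufa`,
#'   `pufa`, `ufa` (percent of total FAMEs).
#' @examples
#' p <- fa_profile("walnut", c("C18:1" = 14.76, "C18:2" = 60.00, "C18:3" = 16.34))
#' aggregate_classes(p)
#' @export
aggregate_classes <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  db <- double_bonds(names(profile$percentages))
  p <- profile$percentages
  out <- list(
    sfa  = round(sum(p[db == 0]), 2),
    mufa = round(sum(p[db == 1]), 2),
    pufa = round(sum(p[db >= 2]), 2),
    ufa  = round(sum(p[db >= 1]), 2)
  )
  structure(out, class = "fa_class_summary")
}

#' @export
print.fa_class_summary <- function(x, ...) {
  cat(sprintf("SFA %.2f  MUFA %.2f  PUFA %.2f  UFA %.2f  (%% of FAMEs)\n",
              x$sfa, x$mufa, x$pufa, x$ufa))
  invisible(x)
}

#' Calculated iodine value of a fatty-acid profile
#'
#' Weighted sum of the unsaturated fatty-acid percentages using the AOCS
#' calculated-IV coefficients (0.95 C16:1, 0.86 C18:1, 1.732 C18:2,
#' 2.616 C18:3, 0.785 C20:1, 0.723 C22:1). Saturated acids contribute
#' nothing; absent acids contribute 0. The conventional reporting precision
#' is 1 decimal.
#'
#' @param profile An `fa_profile`.
#' @return Iodine value in g I2 per 100 g oil (full precision; round to 1
#'   decimal for reporting).
#' @examples
#' round(iodine_value(fa_profile("linolenin", c("C18:3" = 100))), 1)  # 261.6
#' @export
iodine_value <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  codes <- names(.iv_coefficients)
  sum(.iv_coefficients * profile$percentages[codes])
}

#' Read a fatty-acid composition table
#'
#' One row per oil; columns `oil_id` plus fatty-acid codes. `ND` and empty
#' cells are accepted as not detected. Lines starting with `#` are comments.
#'
#' @param path CSV file path.
#' @return Named list of `fa_profile` objects (names = `oil_id`).
#' @export
read_composition_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, comment.char = "#",
                    colClasses = "character", strip.white = TRUE),
    error = function(e) stop("empty or unreadable composition table: ", path))
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty composition table: ", path)
  if (!"oil_id" %in% names(df)) stop("missing required column: oil_id")
  if (anyDuplicated(df$oil_id)) {
    stop("duplicate oil_id: ",
         paste(unique(df$oil_id[duplicated(df$oil_id)]), collapse = ", "))
  }
  codes <- setdiff(names(df), "oil_id")
  profiles <- lapply(seq_len(nrow(df)), function(i) {
    validate_profile(stats::setNames(as.character(df[i, codes]), codes),
                     oil_id = df$oil_id[i])
  })
  stats::setNames(profiles, df$oil_id)
}

#' Write a composition table
#'
#' Inverse of [read_composition_csv()]: zero percentages are written as `ND`
#' so a round trip preserves the not-detected convention.
#'
#' @param profiles List of `fa_profile` objects.
#' @param path Output CSV path.
#' @export
write_composition_csv <- function(profiles, path) {
  stopifnot(length(profiles) > 0L)
  rows <- lapply(profiles, function(p) {
    v <- ifelse(p$percentages == 0, "ND",
                vapply(p$percentages, format, "", digits = 15))
    c(oil_id = p$oil_id, stats::setNames(v, names(p$percentages)))
  })
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = 1L)
  invisible(path)
}
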