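#' Construct a validated chemical table
#'
#' A chemical table holds one row per analyzed chemical: a display name, the
#' CAS registry number (the identity key), the mean air concentration in
#' ng/m^3, and a detection flag. Non-detected chemicals are retained but
#' excluded from all downstream totals, proportions and selections.
#'
#' @param name character vector of display names.
#' @param cas character vector of CAS registry numbers; must be unique.
#' @param concentration numeric vector of mean air concentrations (ng/m^3),
#'   non-negative.
#' @param detected logical; defaults to `concentration > 0`.
#' @return A data.frame of class `chemical_table` with columns
#'   `name`, `cas`, `concentration`, `detected`, in input order.
#' @export
#' @examples
#' chemical_table(c("naphthalene", "fluorene"),
#'                c("91-20-3", "86-73-7"), c(120, 35))
chemical_table <- function(name, cas, concentration,
                           detected = concentration > 0) {
  x <- data.frame(name = as.character(name),
                  cas = as.character(cas),
                  concentration = as.numeric(concentration),
                  detected = as.logical(detected),
                  stringsAsFactors = FALSE)
  validate_chemical_table(x)
}

validate_chemical_table <- function(x) {
  req <- c("name", "cas", "concentration", "detected")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("chemical table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dup <- unique(x$cas[duplicated(x$cas)])
  if (length(dup)) {
    stop("duplicate CAS in chemical table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyNA(x$concentration) || any(x$concentration < 0)) {
    bad <- x$cas[is.na(x$concentration) | x$concentration < 0]
    stop("negative or missing concentration for CAS: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(x$detected & x$concentration <= 0)) {
    bad <- x$cas[x$detected & x$concentration <= 0]
    stop("detected chemical with zero concentration: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(x) <- c("chemical_table", "data.frame")
  x
}

#' Read a chemical table from CSV
#'
#' Expects header columns `name`, `cas`, `concentration_ng_m3` and an
#' optional `detected` column (default: `concentration_ng_m3 > 0`). Row
#' order is preserved. Empty cells and `"NA"` are treated as missing.
#'
#' @param path path to a CSV file.
#' @return A [chemical_table()].
#' @export
read_chemical_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"), check.names = FALSE)
  req <- c("name", "cas", "concentration_ng_m3")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("chemical CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  det <- if ("detected" %in% names(raw)) {
    as.logical(raw$detected)
  } else {
    raw$concentration_ng_m3 > 0
  }
  chemical_table(raw$name, raw$cas, raw$concentration_ng_m3, det)
}

#' Write a chemical table to CSV
#'
#' Inverse of [read_chemical_table()]: columns `name`, `cas`,
#' `concentration_ng_m3`, `detected`; numeric values at full precision so a
#' round trip reproduces the table.
#'
#' @param x a [chemical_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chemical_table <- function(x, path) {
  stopifnot(inherits(x, "chemical_table"))
  out <- data.frame(name = x$name, cas = x$cas,
                    concentration_ng_m3 = format(x$concentration, digits = 15,
                                                 trim = TRUE, scientific = FALSE),
                    detected = x$detected, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Total concentration of the detected chemicals
#'
#' @param x a [chemical_table()].
#' @return Scalar sum of `concentration` over rows with `detected = TRUE`.
#' @export
total_concentration <- function(x) {
  stopifnot(inherits(x, "chemical_table"))
  sum(x$concentration[x$detected])
}
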