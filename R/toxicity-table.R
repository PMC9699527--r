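#' Construct a validated toxicity table
#'
#' A toxicity table is a chemical-by-metric grid of hazard values with
#' per-cell provenance. Numeric metrics (RfC, RfD, IUR, OSF, CPV, RPF, TEF,
#' BMC) hold doubles; IARC holds one of the ordinal categories from
#' [iarc_levels()]. Missing cells are allowed and carry provenance
#' `"missing"`; all other cells are `"empirical"` or `"qsar_predicted"`.
#'
#' @param cas character vector of CAS numbers (unique, defines row order).
#' @param values data.frame with one column per metric (a subset of the
#'   registry's `metric_id`s), rows aligned with `cas`. IARC as character.
#' @param provenance optional data.frame of the same shape with entries in
#'   `c("empirical", "qsar_predicted", "missing")`; defaults to
#'   `"empirical"` wherever a value is present.
#' @param registry metric registry, see [default_metric_registry()].
#' @return A list of class `toxicity_table` with elements `cas`, `values`,
#'   `provenance`, `registry`.
#' @export
toxicity_table <- function(cas, values, provenance = NULL,
                           registry = default_metric_registry()) {
  cas <- as.character(cas)
  if (anyDuplicated(cas)) {
    stop("duplicate CAS in toxicity table: ",
         paste(unique(cas[duplicated(cas)]), collapse = ", "), call. = FALSE)
  }
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (nrow(values) != length(cas)) {
    stop("values has ", nrow(values), " rows but ", length(cas),
         " CAS entries", call. = FALSE)
  }
  unknown <- setdiff(names(values), registry$metric_id)
  if (length(unknown)) {
    stop("unknown metric column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (m in names(values)) {
    dir <- metric_direction(m, registry)
    if (dir == "ordinal") {
      v <- as.character(values[[m]])
      bad <- v[!is.na(v) & !(v %in% iarc_levels())]
      if (length(bad)) {
        stop("IARC value(s) outside defined categories: ",
             paste(unique(bad), collapse = ", "), call. = FALSE)
      }
      values[[m]] <- v
    } else {
      v <- values[[m]]
      if (!is.numeric(v)) {
        vn <- suppressWarnings(as.numeric(v))
        if (any(!is.na(v) & is.na(vn) & v != "")) {
          stop("non-numeric value in metric ", m, call. = FALSE)
        }
        v <- vn
      }
      values[[m]] <- v
    }
  }
  present <- !is.na(as.matrix(values))
  if (is.null(provenance)) {
    provenance <- as.data.frame(ifelse(present, "empirical", "missing"),
                                stringsAsFactors = FALSE)
    names(provenance) <- names(values)
  } else {
    provenance <- as.data.frame(provenance, stringsAsFactors = FALSE)
    if (!identical(dim(provenance), dim(values)) ||
        !identical(names(provenance), names(values))) {
      stop("provenance must have the same shape and columns as values",
           call. = FALSE)
    }
    pm <- as.matrix(provenance)
    ok <- pm %in% c("empirical", "qsar_predicted", "missing")
    if (!all(ok)) {
      stop("provenance entries must be empirical, qsar_predicted or missing",
           call. = FALSE)
    }
    if (any((pm == "missing") != !present)) {
      stop("provenance 'missing' must coincide exactly with missing values",
           call. = FALSE)
    }
  }
  structure(list(cas = cas, values = values, provenance = provenance,
                 registry = registry),
            class = "toxicity_table")
}

#' @export
print.toxicity_table <- function(x, ...) {
  cat("toxicity_table:", length(x$cas), "chemicals x",
      ncol(x$values), "metrics\n")
  avail <- colSums(!is.na(as.matrix(x$values)))
  cat("available values:",
      paste(names(avail), avail, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a toxicity table from wide CSV
#'
#' Expects a `cas` column plus one column per metric (e.g. `RfC`, `RfD`,
#' `IUR`, `OSF`, `CPV`, `RPF`, `TEF`, `IARC`, `BMC`). Empty cells and
#' `"NA"` are missing. Optional `<metric>_provenance` columns carry
#' `empirical` or `qsar_predicted` (also accepted: `ctv`, mapped to
#' `qsar_predicted`); provenance defaults to `empirical` where a value is
#' present. Unknown columns are rejected unless listed in `ignore`.
#'
#' @param path path to a CSV file.
#' @param registry metric registry, see [default_metric_registry()].
#' @param ignore character vector of non-metric columns to drop silently.
#' @return A [toxicity_table()].
#' @export
read_toxicity_table <- function(path, registry = default_metric_registry(),
                                ignore = character()) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"), check.names = FALSE)
  if (!"cas" %in% names(raw)) {
    stop("toxicity CSV is missing the cas column", call. = FALSE)
  }
  prov_cols <- grep("_provenance$", names(raw), value = TRUE)
  metric_cols <- setdiff(names(raw), c("cas", prov_cols, ignore))
  unknown <- setdiff(metric_cols, registry$metric_id)
  if (length(unknown)) {
    stop("unknown metric column(s) in toxicity CSV: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  values <- raw[metric_cols]
  present <- !is.na(as.matrix(values))
  prov <- as.data.frame(ifelse(present, "empirical", "missing"),
                        stringsAsFactors = FALSE)
  names(prov) <- metric_cols
  for (pc in prov_cols) {
    m <- sub("_provenance$", "", pc)
    if (!m %in% metric_cols) next
    p <- tolower(as.character(raw[[pc]]))
    p[p %in% c("ctv", "qsar", "predicted", "qsar_predicted")] <- "qsar_predicted"
    keep <- !is.na(p) & present[, m]
    prov[[m]][keep] <- p[keep]
  }
  toxicity_table(raw$cas, values, prov, registry)
}

#' Write a toxicity table to wide CSV
#'
#' Columns `cas`, one per metric, and `<metric>_provenance` for every
#' metric. Missing cells are written as empty strings.
#'
#' @param x a [toxicity_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_toxicity_table <- function(x, path) {
  stopifnot(inherits(x, "toxicity_table"))
  out <- data.frame(cas = x$cas, stringsAsFactors = FALSE)
  for (m in names(x$values)) {
    v <- x$values[[m]]
    out[[m]] <- if (is.numeric(v)) {
      ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE,
                                  scientific = FALSE))
    } else ifelse(is.na(v), "", v)
  }
  for (m in names(x$values)) {
    p <- x$provenance[[m]]
    out[[paste0(m, "_provenance")]] <- ifelse(p == "missing", "", p)
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Count available (non-missing) toxicity values
#'
#' Per-metric counts of chemicals with a value, and per-group counts of
#' chemicals with at least one value among the group's member metrics
#' (e.g. `list("RfD|RfC" = c("RfD", "RfC"))` counts chemicals with either).
#'
#' @param x a [toxicity_table()].
#' @param groups named list of character vectors of metric ids.
#' @return A list of class `availability_summary` with `n_chemicals`,
#'   `per_metric` (named integer vector) and `per_group`.
#' @export
#' @examples
#' tt <- toxicity_table(c("a", "b"),
#'                      data.frame(RfD = c(1, NA), TEF = c(0.1, 0.2)))
#' availability_summary(tt, list(noncancer = c("RfD")))
availability_summary <- function(x, groups = list()) {
  stopifnot(inherits(x, "toxicity_table"))
  present <- !is.na(as.matrix(x$values))
  per_metric <- colSums(present)
  storage.mode(per_metric) <- "integer"
  per_group <- vapply(groups, function(g) {
    bad <- setdiff(g, colnames(present))
    if (length(bad)) {
      stop("availability group references undefined metric(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    as.integer(sum(rowSums(present[, g, drop = FALSE]) > 0))
  }, integer(1))
  structure(list(n_chemicals = length(x$cas),
                 per_metric = per_metric,
                 per_group = per_group),
            class = "availability_summary")
}

#' @export
print.availability_summary <- function(x, ...) {
  cat("availability over", x$n_chemicals, "chemicals\n")
  cat("  per metric:",
      paste(names(x$per_metric), x$per_metric, sep = "=", collapse = ", "),
      "\n")
  if (length(x$per_group)) {
    cat("  per group: ",
        paste(names(x$per_group), x$per_group, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}
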