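#' Proportion of total concentration per detected chemical
#'
#' Each detected chemical's share of the summed air concentration of all
#' detected chemicals. Non-detected chemicals get `NA` and contribute
#' nothing to the denominator.
#'
#' @param x a [chemical_table()].
#' @return Named numeric vector (names = CAS) summing to 1 over detected
#'   chemicals.
#' @export
#' @examples
#' ct <- chemical_table(c("a", "b"), c("1-1", "2-2"), c(10, 10))
#' proportion_of_total(ct)
proportion_of_total <- function(x) {
  stopifnot(inherits(x, "chemical_table"))
  total <- total_concentration(x)
  if (!any(x$detected) || total <= 0) {
    stop("no detected chemical with positive concentration", call. = FALSE)
  }
  p <- ifelse(x$detected, x$concentration / total, NA_real_)
  names(p) <- x$cas
  p
}

#' Potency scale for a metric column
#'
#' Maps raw metric values to a scale where larger always means more
#' hazardous: values pass through for higher-is-more-hazardous metrics,
#' are inverted (1/value) for lower-is-more-hazardous metrics (reference
#' doses and benchmark concentrations), and ordinal IARC categories map to
#' integer scores with the most hazardous category highest.
#'
#' @param values metric values (numeric, or character for IARC).
#' @param metric_id metric id, looked up in `registry`.
#' @param registry metric registry.
#' @return Numeric potency vector; `NA` propagates.
#' @keywords internal
potency_scale <- function(values, metric_id,
                          registry = default_metric_registry()) {
  dir <- metric_direction(metric_id, registry)
  switch(dir,
    higher = as.numeric(values),
    lower = {
      v <- as.numeric(values)
      if (any(!is.na(v) & v <= 0)) {
        stop("non-positive ", metric_id,
             " value cannot be inverted to a potency (index ",
             paste(which(!is.na(v) & v <= 0), collapse = ", "), ")",
             call. = FALSE)
      }
      1 / v
    },
    ordinal = {
      lev <- iarc_levels()
      v <- as.character(values)
      i <- match(v, lev)
      if (any(!is.na(v) & is.na(i))) {
        stop("IARC value outside defined categories", call. = FALSE)
      }
      # most hazardous category -> highest integer score
      as.numeric(length(lev) + 1 - i)
    }
  )
}

#' Abundance-weight a toxicity metric
#'
#' Multiplies each chemical's potency-scale value (see details) by its
#' proportion of the total mixture concentration, so that greater
#' environmental abundance always increases the hazard score. Metrics where
#' lower raw values mean more hazard (RfD, RfC, BMC) are first inverted to
#' a potency (1/value); IARC categories are mapped to an ordinal score
#' (most hazardous category = highest). `literal = TRUE` multiplies the raw
#' value instead, without the potency transform; for lower-is-more-hazardous
#' metrics this makes abundant chemicals look safer, so it is off by
#' default and warns when used on such a metric.
#'
#' @param values per-chemical metric values (numeric, or IARC categories).
#' @param proportions per-chemical proportions from
#'   [proportion_of_total()], same length.
#' @param metric_id metric id; must be weightable in the registry.
#' @param registry metric registry.
#' @param literal multiply the raw value without the potency transform.
#' @return Numeric vector of weighted hazard scores; `NA` propagates.
#' @export
#' @examples
#' weight_metric(0.01, 0.5, "TEF")   # 0.005
#' weight_metric(0.02, 0.5, "RfD")   # 0.5 / 0.02 = 25
weight_metric <- function(values, proportions, metric_id,
                          registry = default_metric_registry(),
                          literal = FALSE) {
  i <- match(metric_id, registry$metric_id)
  if (is.na(i)) stop("unknown metric id: ", metric_id, call. = FALSE)
  if (!registry$weightable[i]) {
    stop("metric ", metric_id, " is not weightable", call. = FALSE)
  }
  if (length(values) != length(proportions)) {
    stop("values and proportions differ in length", call. = FALSE)
  }
  base <- if (literal) {
    if (metric_direction(metric_id, registry) == "lower") {
      warning("literal weighting of a lower-is-more-hazardous metric (",
              metric_id, ") makes abundant chemicals score safer")
    }
    if (metric_direction(metric_id, registry) == "ordinal") {
      potency_scale(values, metric_id, registry)
    } else as.numeric(values)
  } else {
    potency_scale(values, metric_id, registry)
  }
  proportions * base
}

#' Hazard-rank one metric column
#'
#' Rank 1 is the most hazardous chemical under the metric's direction
#' (e.g. the lowest benchmark concentration, or the highest oral slope
#' factor). Ties receive the mean of the ranks they span; missing values
#' receive missing ranks, and the non-missing ranks are a tie-averaged
#' permutation of `1..m` where `m` is the non-missing count.
#'
#' @param values per-chemical metric values.
#' @param metric_id metric id (sets the hazard direction).
#' @param registry metric registry.
#' @return Numeric rank vector with `NA` where `values` is `NA`.
#' @export
#' @examples
#' rank_metric(c(0.3, 0.1, 0.2), "BMC")  # 3 1 2
rank_metric <- function(values, metric_id,
                        registry = default_metric_registry()) {
  pot <- potency_scale(values, metric_id, registry)
  if (all(is.na(pot))) {
    stop("all values missing for metric ", metric_id, call. = FALSE)
  }
  r <- rep(NA_real_, length(pot))
  ok <- !is.na(pot)
  r[ok] <- rank(-pot[ok], ties.method = "average")
  r
}

#' Average of available ranks per chemical
#'
#' Row means of a rank matrix. With `denominator = "available"` (default)
#' each chemical's denominator is its own count of non-missing ranks, so
#' data-poor chemicals are not penalized; `"fixed"` divides the sum of
#' available ranks by the full metric count instead. Chemicals with no
#' available rank get `NA`.
#'
#' @param rank_matrix numeric matrix (chemicals x metrics) of ranks.
#' @param denominator `"available"` or `"fixed"`.
#' @return Numeric vector of average ranks, one per row.
#' @export
average_rank <- function(rank_matrix, denominator = c("available", "fixed")) {
  denominator <- match.arg(denominator)
  rank_matrix <- as.matrix(rank_matrix)
  s <- rowSums(rank_matrix, na.rm = TRUE)
  m <- rowSums(!is.na(rank_matrix))
  denom <- if (denominator == "available") m else ncol(rank_matrix)
  out <- ifelse(m > 0, s / denom, NA_real_)
  names(out) <- rownames(rank_matrix)
  out
}

# metric sets of the two rank-aggregation schemes
toxicity_scheme_metrics <- function(include_abundance = TRUE) {
  m <- c("ABUNDANCE", "RPF", "CPV", "IUR", "RfC", "OSF", "RfD", "BMC")
  if (!include_abundance) setdiff(m, "ABUNDANCE") else m
}
weighted_scheme_metrics <- function() {
  c("IARC", "TEF", "IUR", "RfC", "OSF", "RfD", "BMC")
}

#' Prioritize mixture components under one of three schemes
#'
#' Selects the `k` highest-priority chemicals from a mixture:
#' \describe{
#'   \item{`abundance`}{rank by air concentration, most abundant first.}
#'   \item{`toxicity`}{rank each of \{abundance, RPF, CPV, IUR, RfC, OSF,
#'     RfD, BMC\} by hazard, average each chemical's available ranks, and
#'     select the smallest averages.}
#'   \item{`weighted_toxicity`}{weight each of \{IARC, TEF, IUR, RfC, OSF,
#'     RfD, BMC\} by the chemical's proportion of total concentration (see
#'     [weight_metric()]), then rank, average, and select as above.}
#' }
#' Only detected chemicals are eligible. An exact tie in average rank at
#' the selection boundary is an error by default, so the choice of mixture
#' members is never silent; `tie_policy = "include_all"` admits every tied
#' chemical (possibly more than `k`) and `"cas"` breaks the tie by CAS
#' string order.
#'
#' @param chemicals a [chemical_table()].
#' @param tox a [toxicity_table()]; not needed for the abundance scheme.
#' @param scheme `"abundance"`, `"toxicity"` or `"weighted_toxicity"`.
#' @param k number of chemicals to select (default 7).
#' @param denominator see [average_rank()].
#' @param include_abundance include the abundance rank term in the
#'   `toxicity` scheme (default `TRUE`).
#' @param tie_policy `"error"`, `"include_all"` or `"cas"`.
#' @return A list of class `prioritization_result`: `scheme`,
#'   `rank_matrix` (chemicals x metrics, CAS rownames), `average_rank`,
#'   `selected` (CAS, ascending average rank), `k`.
#' @export
prioritize <- function(chemicals, tox = NULL,
                       scheme = c("abundance", "toxicity",
                                  "weighted_toxicity"),
                       k = 7,
                       denominator = c("available", "fixed"),
                       include_abundance = TRUE,
                       tie_policy = c("error", "include_all", "cas")) {
  scheme <- match.arg(scheme)
  denominator <- match.arg(denominator)
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(chemicals, "chemical_table"))

  det <- chemicals[chemicals$detected, , drop = FALSE]
  if (nrow(det) == 0) stop("no detected chemicals", call. = FALSE)

  if (scheme == "abundance") {
    rank_matrix <- matrix(rank_metric(det$concentration, "ABUNDANCE"),
                          ncol = 1,
                          dimnames = list(det$cas, "ABUNDANCE"))
  } else {
    if (is.null(tox)) stop("scheme ", scheme,
                           " requires a toxicity table", call. = FALSE)
    stopifnot(inherits(tox, "toxicity_table"))
    idx <- match(det$cas, tox$cas)
    if (anyNA(idx)) {
      stop("chemicals absent from toxicity table: ",
           paste(det$cas[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    registry <- tox$registry
    if (scheme == "toxicity") {
      metrics <- toxicity_scheme_metrics(include_abundance)
      cols <- lapply(metrics, function(m) {
        vals <- if (m == "ABUNDANCE") det$concentration
                else tox$values[[m]][idx]
        if (is.null(vals) || all(is.na(vals))) {
          rep(NA_real_, nrow(det))
        } else rank_metric(vals, m, registry)
      })
    } else {
      metrics <- weighted_scheme_metrics()
      props <- proportion_of_total(chemicals)[det$cas]
      cols <- lapply(metrics, function(m) {
        vals <- tox$values[[m]][idx]
        if (is.null(vals) || all(is.na(vals))) {
          return(rep(NA_real_, nrow(det)))
        }
        w <- weight_metric(vals, props, m, registry)
        # weighted scores are on the potency scale: higher = more hazardous
        r <- rep(NA_real_, length(w))
        ok <- !is.na(w)
        r[ok] <- rank(-w[ok], ties.method = "average")
        r
      })
    }
    rank_matrix <- do.call(cbind, cols)
    dimnames(rank_matrix) <- list(det$cas, metrics)
  }

  avg <- average_rank(rank_matrix, denominator)
  eligible <- names(avg)[!is.na(avg)]
  if (k > length(eligible)) {
    stop("k = ", k, " exceeds the ", length(eligible),
         " chemicals with at least one available rank", call. = FALSE)
  }
  ord <- eligible[order(avg[eligible], eligible)]
  selected <- ord[seq_len(k)]
  if (k < length(ord)) {
    boundary <- avg[ord[k]]
    tied <- eligible[avg[eligible] == boundary]
    if (length(setdiff(tied, selected)) > 0) {
      if (tie_policy == "error") {
        stop("tie in average rank at the selection boundary (rank ",
             format(boundary), "): ", paste(sort(tied), collapse = ", "),
             "; set tie_policy to resolve", call. = FALSE)
      } else if (tie_policy == "include_all") {
        selected <- ord[avg[ord] <= boundary]
      }
      # "cas": ord already breaks ties by CAS string order
    }
  }
  structure(list(scheme = scheme, rank_matrix = rank_matrix,
                 average_rank = avg, selected = selected, k = k),
            class = "prioritization_result")
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat("prioritization (", x$scheme, " scheme), top ", x$k, ":\n", sep = "")
  for (cas in x$selected) {
    cat(sprintf("  %-14s average rank %.3f\n", cas, x$average_rank[[cas]]))
  }
  invisible(x)
}
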