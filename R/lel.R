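#' Lowest effect level via ANOVA with Dunnett's post hoc test
#'
#' Tests each tested concentration against the vehicle control with
#' one-way ANOVA followed by Dunnett's many-to-one comparisons
#' (multivariate-t adjustment, equal-variance pooling across groups).
#' The lowest effect level (LEL) is the lowest concentration whose
#' adjusted p-value falls below `alpha`; when no concentration is
#' significant the LEL is `NA` (no observed-effect point of departure).
#' Replicates are pooled across plates.
#'
#' @param data data.frame with columns `concentration` (µM; vehicle wells
#'   at 0 or flagged by an `is_vehicle` column) and `response`.
#' @param alpha significance level (default 0.05).
#' @param pool_variance `TRUE` (default) for the classical pooled-variance
#'   Dunnett procedure; `FALSE` for per-comparison Welch t-tests with
#'   Bonferroni adjustment.
#' @return A list of class `pod_result`: `lel` (µM or `NA`),
#'   `significant_concentrations`, `p_values` (named by concentration),
#'   `alpha`.
#' @export
lel <- function(data, alpha = 0.05, pool_variance = TRUE) {
  stopifnot(all(c("concentration", "response") %in% names(data)))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  veh <- if ("is_vehicle" %in% names(data)) data$is_vehicle
         else data$concentration == 0
  if (!any(veh)) stop("no vehicle-control observations", call. = FALSE)
  concs <- sort(unique(data$concentration[!veh]))
  if (length(concs) < 1) stop("no treated concentrations", call. = FALSE)
  counts <- table(data$concentration[!veh])
  if (any(counts < 2) || sum(veh) < 2) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  grp <- factor(ifelse(veh, "vehicle", format(data$concentration)),
                levels = c("vehicle", format(concs)))
  if (pool_variance) {
    df <- data.frame(response = data$response, grp = grp)
    fit <- aov(response ~ grp, data = df)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"))
    p <- summary(gl)$test$pvalues
  } else {
    p <- vapply(format(concs), function(g) {
      stats::t.test(data$response[grp == g],
                    data$response[grp == "vehicle"])$p.value
    }, numeric(1))
    p <- pmin(1, p * length(concs))
  }
  p <- as.numeric(p)
  names(p) <- format(concs)
  sig <- concs[p < alpha]
  structure(list(lel = if (length(sig)) min(sig) else NA_real_,
                 significant_concentrations = sig,
                 p_values = p, alpha = alpha),
            class = "pod_result")
}

#' @export
print.pod_result <- function(x, ...) {
  if (is.na(x$lel)) {
    cat("no concentration significantly different from vehicle (alpha =",
        x$alpha, ")\n")
  } else {
    cat("LEL =", x$lel, "uM; significant at:",
        paste(x$significant_concentrations, collapse = ", "), "\n")
  }
  invisible(x)
}
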