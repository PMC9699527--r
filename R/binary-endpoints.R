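#' Zebrafish morphological endpoint registry
#'
#' The thirteen binary developmental endpoints scored per embryo: mortality
#' and spontaneous movement at 24 hpf, and eleven endpoints (mortality plus
#' ten morphological defects) at 120 hpf. Shipped as a plain-text data file
#' under `extdata`.
#'
#' @return data.frame with columns `endpoint`, `hpf`, `description`.
#' @export
zf_endpoint_registry <- function() {
  path <- system.file("extdata", "zf_endpoints.csv", package = "mixrank",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

zf_mortality_endpoints <- function() c("MO24", "MORT")

#' Percent incidence of a binary endpoint across replicate plates
#'
#' Aggregates per-animal Bernoulli outcomes into percent incidence per
#' concentration. `target` may be a single endpoint id, `"any_effect"`
#' (an animal counts once if positive for any of the thirteen endpoints,
#' including death), or `"mortality"` (dead at 24 or 120 hpf). For single
#' morphological endpoints, dead animals are excluded from the denominator
#' (a defect cannot be scored on a dead embryo); set
#' `exclude_dead = FALSE` to keep them.
#'
#' @param data data.frame with columns `plate`, `well`, `concentration`
#'   (µM; controls at 0), `endpoint`, `outcome` (0/1). One row per
#'   animal-endpoint pair; an animal is a (plate, well).
#' @param target endpoint id, `"any_effect"`, or `"mortality"`.
#' @param exclude_dead drop dead animals from single-endpoint denominators.
#' @return data.frame `concentration`, `affected`, `n`, `incidence` (%),
#'   ordered by concentration.
#' @export
incidence <- function(data, target = "any_effect", exclude_dead = TRUE) {
  req <- c("plate", "well", "concentration", "endpoint", "outcome")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  known <- c(zf_endpoint_registry()$endpoint)
  if (!target %in% c("any_effect", "mortality", known)) {
    stop("unknown endpoint id: ", target, call. = FALSE)
  }
  animal <- interaction(data$plate, data$well, drop = TRUE)
  conc <- tapply(data$concentration, animal, `[`, 1)
  dead <- tapply(data$outcome * (data$endpoint %in% zf_mortality_endpoints()),
                 animal, max)
  hit <- if (target == "any_effect") {
    tapply(data$outcome, animal, max)
  } else if (target == "mortality") {
    dead
  } else {
    h <- tapply(ifelse(data$endpoint == target, data$outcome, NA),
                animal, max, na.rm = TRUE)
    h[!is.finite(h)] <- NA  # animal not scored for this endpoint
    if (exclude_dead && !target %in% zf_mortality_endpoints()) {
      h[dead == 1] <- NA
    }
    h
  }
  keep <- !is.na(hit)
  agg <- aggregate(list(affected = hit[keep]),
                   by = list(concentration = conc[keep]), FUN = sum)
  agg$n <- as.vector(table(conc[keep])[as.character(agg$concentration)])
  agg$incidence <- 100 * agg$affected / agg$n
  agg[order(agg$concentration), , drop = FALSE]
}

#' Minimum significant count from the background incidence
#'
#' The smallest affected count `k` out of `n` animals whose exact binomial
#' upper-tail probability under the control (background) incidence falls
#' below `alpha`: the per-concentration significance threshold used to
#' flag effects against a non-zero background. A raw control incidence of
#' zero is replaced by add-one smoothing, `1 / (n + 2)`, so a single event
#' is never automatically significant against a clean control.
#'
#' @param control_incidence background incidence as a proportion in
#'   `[0, 1)`.
#' @param n number of animals at the tested concentration.
#' @param alpha significance level (default 0.01).
#' @return Integer threshold count in `1..n+1` (`n + 1` means no
#'   attainable count is significant).
#' @export
significance_threshold <- function(control_incidence, n, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (control_incidence < 0 || control_incidence >= 1) {
    stop("control incidence must be in [0, 1)", call. = FALSE)
  }
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  p0 <- if (control_incidence == 0) 1 / (n + 2) else control_incidence
  for (k in seq_len(n)) {
    tail <- pbinom(k - 1, n, p0, lower.tail = FALSE)  # P(X >= k)
    if (tail < alpha) return(k)
  }
  n + 1L
}

#' Fisher's exact test with Bonferroni family-wise correction
#'
#' Two-sided Fisher's exact test on the 2x2 table of affected/unaffected
#' animals in a treated concentration versus control, flagged significant
#' when the raw p-value beats the Bonferroni-corrected level `alpha / m`
#' for a family of `m` endpoint comparisons.
#'
#' @param treated_affected,treated_n affected count and total in the
#'   treated group.
#' @param control_affected,control_n affected count and total in control.
#' @param m family size (default 13 endpoints).
#' @param alpha family-wise level (default 0.01).
#' @param alternative passed to [stats::fisher.test()]
#'   (default `"two.sided"`).
#' @return list `p` (raw p-value) and `significant`.
#' @export
fisher_bonferroni <- function(treated_affected, treated_n,
                              control_affected, control_n,
                              m = 13, alpha = 0.01,
                              alternative = "two.sided") {
  counts <- c(treated_affected, treated_n, control_affected, control_n)
  if (any(counts < 0) || treated_affected > treated_n ||
      control_affected > control_n) {
    stop("invalid 2x2 counts", call. = FALSE)
  }
  if (m < 1) stop("family size m must be at least 1", call. = FALSE)
  tab <- matrix(c(treated_affected, treated_n - treated_affected,
                  control_affected, control_n - control_affected),
                nrow = 2)
  p <- fisher.test(tab, alternative = alternative)$p.value
  list(p = p, significant = p < alpha / m)
}

#' Flag control incidences more than three SD from the mean
#'
#' Single-pass screen: the mean and standard deviation are computed with
#' every candidate included, and values with `|x - mean| > 3 * SD` are
#' flagged. All-equal inputs (zero variance) yield no flags.
#'
#' @param values numeric vector of per-plate or per-well control
#'   incidences; at least 3.
#' @param k SD multiplier (default 3).
#' @return Logical vector of flags, same length as `values`.
#' @export
outlier_screen <- function(values, k = 3) {
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  s <- sd(values)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(values)))
  abs(values - mean(values)) > k * s
}

#' Plate-level quality-control gate
#'
#' A plate set passes when the negative controls show at most 20% combined
#' mortality and morbidity and the positive-control plate's EC50 lies
#' within 19.3 ± 4 µM (the reference response of the ethyl parathion
#' concentration series).
#'
#' @param negative_control_percent combined negative-control mortality and
#'   morbidity incidence, %.
#' @param positive_control_ec50 fitted positive-control EC50, µM.
#' @param max_negative maximum tolerated negative-control incidence, %
#'   (default 20).
#' @param positive_target,positive_tol positive-control EC50 window,
#'   `target ± tol` µM (defaults 19.3 and 4).
#' @return list `pass` (logical) and `reasons` (character, empty on pass).
#' @export
qc_gate <- function(negative_control_percent, positive_control_ec50,
                    max_negative = 20, positive_target = 19.3,
                    positive_tol = 4) {
  reasons <- character()
  if (negative_control_percent > max_negative) {
    reasons <- c(reasons, sprintf(
      "negative-control mortality/morbidity %.1f%% exceeds %.0f%%",
      negative_control_percent, max_negative))
  }
  lo <- positive_target - positive_tol
  hi <- positive_target + positive_tol
  if (is.na(positive_control_ec50) ||
      positive_control_ec50 < lo || positive_control_ec50 > hi) {
    reasons <- c(reasons, sprintf(
      "positive-control EC50 %s outside [%.1f, %.1f] uM",
      format(positive_control_ec50), lo, hi))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Quantal point of departure: LC50/EC50 and threshold-significant levels
#'
#' Computes percent incidence per concentration for a binary endpoint (or
#' the any-effect / mortality composite), fits the continuous candidate
#' model suite to incidence versus concentration to estimate the LC50
#' (mortality) or EC50, and lists the concentrations whose affected counts
#' meet the exact binomial significance threshold computed from the
#' control background (see [significance_threshold()]).
#'
#' @param data binary endpoint data, see [incidence()]; controls at
#'   concentration 0.
#' @param target endpoint id, `"any_effect"`, or `"mortality"`.
#' @param alpha level for the binomial threshold (default 0.01).
#' @return list of class `quantal_pod`: `target`, `incidence` (the
#'   per-concentration table with `threshold` and `significant` columns),
#'   `fit` (a [fit_dose_response()] result; non-converged for flat data),
#'   `ec50`, `ec50_se`, `significant_concentrations`.
#' @export
quantal_pod <- function(data, target = "any_effect", alpha = 0.01) {
  inc <- incidence(data, target)
  ctrl <- inc[inc$concentration == 0, , drop = FALSE]
  treated <- inc[inc$concentration > 0, , drop = FALSE]
  if (nrow(treated) < 3) {
    stop("incidence computable at fewer than 3 tested concentrations",
         call. = FALSE)
  }
  p0 <- if (nrow(ctrl)) ctrl$affected / ctrl$n else 0
  treated$threshold <- vapply(treated$n, function(n) {
    as.numeric(significance_threshold(p0, n, alpha))
  }, numeric(1))
  treated$significant <- treated$affected >= treated$threshold
  fit <- if (all(treated$incidence == treated$incidence[1])) {
    structure(list(converged = FALSE, model_id = NA_character_,
                   parameters = NULL, aic = NA_real_, ec50 = NA_real_,
                   ec50_se = NA_real_, candidates = numeric(0)),
              class = "fit_result")
  } else {
    fit_dose_response(data.frame(concentration = treated$concentration,
                                 response = treated$incidence))
  }
  structure(list(target = target, incidence = treated, fit = fit,
                 ec50 = fit$ec50, ec50_se = fit$ec50_se,
                 significant_concentrations =
                   treated$concentration[treated$significant]),
            class = "quantal_pod")
}

#' @export
print.quantal_pod <- function(x, ...) {
  cat("quantal POD for", x$target, "\n")
  if (x$fit$converged) {
    lab <- if (x$target == "mortality") "LC50" else "EC50"
    cat(sprintf("  %s = %.4g", lab, x$ec50))
    if (is.finite(x$ec50_se)) cat(sprintf(" (+/- %.3g)", x$ec50_se))
    cat(" [", x$fit$model_id, "]\n")
  } else {
    cat("  no curve could be fit\n")
  }
  if (length(x$significant_concentrations)) {
    cat("  above binomial threshold at:",
        paste(x$significant_concentrations, collapse = ", "), "uM\n")
  } else {
    cat("  no concentration above the binomial threshold\n")
  }
  invisible(x)
}
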