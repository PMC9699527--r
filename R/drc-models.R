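# Continuous concentration-response model suite.
#
# All models are parametrized on log-concentration lx = log(conc) with the
# location parameter as loge = log(e), which keeps the optimizer
# unconstrained while guaranteeing e > 0. `b` follows the convention that
# b > 0 gives a response decreasing in concentration.

dr_model_defs <- function() {
  list(
    LL.2 = list(
      desc = "log-logistic, 2 parameters (asymptotes fixed at 0/100)",
      pars = c("b", "loge"),
      f = function(lx, p) 100 / (1 + exp(p[["b"]] * (lx - p[["loge"]]))),
      ec50 = function(p) exp(p[["loge"]])),
    LL.3 = list(
      desc = "log-logistic, 3 parameters (lower asymptote fixed at 0)",
      pars = c("b", "d", "loge"),
      f = function(lx, p) p[["d"]] / (1 + exp(p[["b"]] * (lx - p[["loge"]]))),
      ec50 = function(p) exp(p[["loge"]])),
    LL.4 = list(
      desc = "log-logistic, 4 parameters",
      pars = c("b", "c", "d", "loge"),
      f = function(lx, p) p[["c"]] + (p[["d"]] - p[["c"]]) /
        (1 + exp(p[["b"]] * (lx - p[["loge"]]))),
      ec50 = function(p) exp(p[["loge"]])),
    LL.5 = list(
      desc = "log-logistic, 5 parameters (asymmetric)",
      pars = c("b", "c", "d", "loge", "g"),
      f = function(lx, p) p[["c"]] + (p[["d"]] - p[["c"]]) /
        (1 + exp(p[["b"]] * (lx - p[["loge"]])))^p[["g"]],
      # absolute EC50: halfway between the asymptotes
      ec50 = function(p) exp(p[["loge"]] +
                               log(2^(1 / p[["g"]]) - 1) / p[["b"]])),
    W1.4 = list(
      desc = "Weibull type I, 4 parameters",
      pars = c("b", "c", "d", "loge"),
      f = function(lx, p) p[["c"]] + (p[["d"]] - p[["c"]]) *
        exp(-exp(p[["b"]] * (lx - p[["loge"]]))),
      ec50 = function(p) exp(p[["loge"]] + log(log(2)) / p[["b"]])),
    W2.4 = list(
      desc = "Weibull type II, 4 parameters",
      pars = c("b", "c", "d", "loge"),
      f = function(lx, p) p[["c"]] + (p[["d"]] - p[["c"]]) *
        (1 - exp(-exp(p[["b"]] * (lx - p[["loge"]])))),
      ec50 = function(p) exp(p[["loge"]] + log(log(2)) / p[["b"]]))
  )
}

# Deterministic self-starting values: asymptotes from the per-concentration
# mean extremes, loge from the concentration nearest half-response, slope
# tried at +1 and -1 (both are fitted; the better SSE wins upstream).
dr_start_values <- function(model, lx, y, b0) {
  mu <- tapply(y, lx, mean)
  lev <- as.numeric(names(mu))
  d0 <- max(mu); c0 <- min(mu)
  half <- (c0 + d0) / 2
  loge0 <- lev[which.min(abs(mu - half))]
  start <- switch(model,
    LL.2 = c(b = b0, loge = loge0),
    LL.3 = c(b = b0, d = d0, loge = loge0),
    LL.4 = c(b = b0, c = c0, d = d0, loge = loge0),
    LL.5 = c(b = b0, c = c0, d = d0, loge = loge0, g = 1),
    W1.4 = c(b = b0, c = c0, d = d0, loge = loge0),
    W2.4 = c(b = b0, c = c0, d = d0, loge = loge0))
  as.list(start)
}

fit_one_model <- function(model_id, def, lx, y) {
  best <- NULL
  for (b0 in c(1, -1)) {
    start <- dr_start_values(model_id, lx, y, b0)
    fml <- switch(model_id,
      LL.2 = y ~ 100 / (1 + exp(b * (lx - loge))),
      LL.3 = y ~ d / (1 + exp(b * (lx - loge))),
      LL.4 = y ~ c + (d - c) / (1 + exp(b * (lx - loge))),
      LL.5 = y ~ c + (d - c) / (1 + exp(b * (lx - loge)))^g,
      W1.4 = y ~ c + (d - c) * exp(-exp(b * (lx - loge))),
      W2.4 = y ~ c + (d - c) * (1 - exp(-exp(b * (lx - loge)))))
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        fml, data = data.frame(lx = lx, y = y), start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(NULL)
  fit <- best$fit
  p <- coef(fit)
  ec50 <- tryCatch(def$ec50(as.list(p)), error = function(e) NA_real_)
  if (!is.finite(ec50) || ec50 <= 0) return(NULL)
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (!is.null(V) && all(is.finite(V))) {
    g <- numeric(length(p))
    h <- pmax(abs(p), 1) * 1e-6
    for (i in seq_along(p)) {
      up <- p; up[i] <- up[i] + h[i]
      dn <- p; dn[i] <- dn[i] - h[i]
      g[i] <- (def$ec50(as.list(up)) - def$ec50(as.list(dn))) / (2 * h[i])
    }
    v <- drop(t(g) %*% V %*% g)
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  } else NA_real_
  list(model_id = model_id, fit = fit, parameters = p,
       aic = AIC(fit), ec50 = ec50, ec50_se = se)
}

#' Fit the continuous concentration-response model suite
#'
#' Fits six candidate curves to normalized responses by least squares on
#' log-concentration — the 2-, 3-, 4- and 5-parameter log-logistic and the
#' two 4-parameter Weibull forms — and selects the fit with the lowest AIC
#' among the candidates that converge. EC50 is the concentration of
#' half-maximal effect (the absolute midpoint between the asymptotes) with
#' a delta-method standard error from the fitted covariance. Optimizer
#' starts are deterministic self-starting heuristics, so the same data
#' always yield the same selected model.
#'
#' Vehicle wells (`concentration` 0 or `is_vehicle` flag) anchor the
#' normalization only and are excluded from the regression.
#'
#' @param data data.frame with columns `concentration` (µM) and `response`
#'   (e.g. % control from [percent_control()]); optional `is_vehicle`.
#' @param models character vector of candidate model ids (default all six).
#' @return A list of class `fit_result`: `converged`, `model_id`,
#'   `parameters` (named; the location as `loge`), `aic`, `ec50`,
#'   `ec50_se`, and `candidates` (AIC per converged candidate). When no
#'   candidate converges, `converged` is `FALSE` and `ec50` is `NA`
#'   (non-bioactive / no curve could be fit).
#' @export
#' @examples
#' conc <- c(1, 5, 10, 50, 100, 500, 1000)
#' y <- 100 / (1 + (conc / 50)^2)  # 4PL, ec50 = 50, hill 2
#' fit_dose_response(data.frame(concentration = conc, response = y))
fit_dose_response <- function(data, models = names(dr_model_defs())) {
  stopifnot(all(c("concentration", "response") %in% names(data)))
  treated <- data$concentration > 0
  if ("is_vehicle" %in% names(data)) treated <- treated & !data$is_vehicle
  lx <- log(data$concentration[treated])
  y <- data$response[treated]
  ok <- is.finite(lx) & is.finite(y)
  lx <- lx[ok]; y <- y[ok]
  if (length(unique(lx)) < 2) {
    stop("need at least 2 distinct non-vehicle concentrations", call. = FALSE)
  }
  defs <- dr_model_defs()[models]
  fits <- list()
  for (m in names(defs)) {
    r <- fit_one_model(m, defs[[m]], lx, y)
    if (!is.null(r) && is.finite(r$aic)) fits[[m]] <- r
  }
  if (!length(fits)) {
    return(structure(list(converged = FALSE, model_id = NA_character_,
                          parameters = NULL, aic = NA_real_,
                          ec50 = NA_real_, ec50_se = NA_real_,
                          candidates = numeric(0)),
                     class = "fit_result"))
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[which.min(aics)]]
  structure(list(converged = TRUE, model_id = best$model_id,
                 parameters = best$parameters, aic = best$aic,
                 ec50 = best$ec50, ec50_se = best$ec50_se,
                 candidates = aics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!x$converged) {
    cat("concentration-response fit: no candidate model converged",
        "(non-bioactive or degenerate data)\n")
    return(invisible(x))
  }
  cat("concentration-response fit:", x$model_id,
      sprintf("(AIC %.2f)\n", x$aic))
  cat(sprintf("  EC50 = %.4g", x$ec50))
  if (is.finite(x$ec50_se)) cat(sprintf(" (+/- %.3g)", x$ec50_se))
  cat("\n")
  invisible(x)
}
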