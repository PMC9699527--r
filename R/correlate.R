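#' Pearson correlation of per-metric chemical rankings
#'
#' Correlates every pair of metric rank columns over the chemicals where
#' both ranks are present ("complete observations": pairwise by default,
#' or listwise across all metrics). Cells with fewer than 3 complete pairs,
#' or a constant column within the pairs, are undefined (`NA`) rather than
#' errors. p-values are two-sided from the t distribution with `n - 2`
#' degrees of freedom and are not multiplicity-adjusted; the significance
#' mask flags `p <= alpha` (non-significant cells are the ones rendered as
#' "X" on a correlation plot).
#'
#' @param rank_matrix numeric matrix (chemicals x metrics), e.g. the
#'   `rank_matrix` of a [prioritize()] result; `NA` for missing ranks.
#'   With `on_ranks = FALSE` raw metric values may be passed instead.
#' @param alpha significance level for the mask (default 0.05).
#' @param use `"pairwise"` (default) or `"listwise"` completeness.
#' @param on_ranks documentation flag only: the function correlates
#'   whatever columns it is given; keep `TRUE` when passing ranks.
#' @return A list of class `correlation_result`: `r`, `p`, `n_pairs`
#'   (metric x metric matrices), `significant` (logical mask), `alpha`.
#' @export
#' @examples
#' m <- cbind(a = 1:5, b = c(2, 1, 3, 5, 4))
#' rank_correlation(m)$r
rank_correlation <- function(rank_matrix, alpha = 0.05,
                             use = c("pairwise", "listwise"),
                             on_ranks = TRUE) {
  use <- match.arg(use)
  m <- as.matrix(rank_matrix)
  if (ncol(m) < 2) stop("need at least 2 metric columns", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("m", seq_len(ncol(m)))
  if (use == "listwise") m <- m[complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  n_pairs <- matrix(0L, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      n <- sum(ok)
      n_pairs[i, j] <- n
      if (i == j) {
        if (n > 0) { r[i, j] <- 1; p[i, j] <- 0 }
        next
      }
      if (n < 3) next
      xi <- m[ok, i]; xj <- m[ok, j]
      if (sd(xi) == 0 || sd(xj) == 0) next
      rij <- stats::cor(xi, xj)
      r[i, j] <- rij
      if (abs(rij) >= 1) {
        p[i, j] <- 0
      } else {
        tstat <- rij * sqrt((n - 2) / (1 - rij^2))
        p[i, j] <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
      }
    }
  }
  structure(list(r = r, p = p, n_pairs = n_pairs,
                 significant = !is.na(p) & p <= alpha, alpha = alpha),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, digits = 2, ...) {
  cat("pairwise Pearson correlations (alpha =", x$alpha, ")\n")
  disp <- ifelse(is.na(x$r), "  .",
                 ifelse(x$significant, sprintf("%5.2f", x$r), "    X"))
  dim(disp) <- dim(x$r); dimnames(disp) <- dimnames(x$r)
  print(disp, quote = FALSE)
  invisible(x)
}
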