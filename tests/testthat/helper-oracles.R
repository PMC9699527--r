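# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's code paths (and base rank()):
# ranks are computed by explicit counting, Pearson by the textbook sums,
# binomial tails by summing the pmf term by term.

oracle_rank <- function(values, direction,
                        ordinal_order = c("1", "2A", "2B", "3", "NC")) {
  score <- switch(direction,
    higher = as.numeric(values),
    lower = -as.numeric(values),
    ordinal = -match(as.character(values), ordinal_order))
  r <- rep(NA_real_, length(score))
  ok <- which(!is.na(score))
  for (i in ok) {
    more <- sum(score[ok] > score[i])
    ties <- sum(score[ok] == score[i])
    r[i] <- more + (ties + 1) / 2
  }
  r
}

# average-rank aggregation over a named list of metric value vectors,
# selection of the k smallest averages with CAS-string tie-break
oracle_prioritize <- function(cas, value_cols, directions, k) {
  ranks <- sapply(names(value_cols), function(m) {
    v <- value_cols[[m]]
    if (all(is.na(v))) rep(NA_real_, length(cas))
    else oracle_rank(v, directions[[m]])
  })
  rownames(ranks) <- cas
  avg <- apply(ranks, 1, function(z) {
    if (all(is.na(z))) NA_real_ else sum(z[!is.na(z)]) / sum(!is.na(z))
  })
  elig <- names(avg)[!is.na(avg)]
  ord <- elig[order(avg[elig], elig)]
  list(ranks = ranks, avg = avg, selected = ord[seq_len(min(k, length(ord)))])
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# smallest k with P(X >= k | n, p) < alpha, by explicit pmf summation
oracle_binom_threshold <- function(p, n, alpha) {
  pmf <- vapply(0:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
                numeric(1))
  for (k in 1:n) {
    if (sum(pmf[(k + 1):(n + 1)]) < alpha) return(k)
  }
  n + 1L
}

# two-sided Fisher exact p by exhaustive enumeration of the
# hypergeometric support, probabilities from binomial coefficients
oracle_fisher_two_sided <- function(a, n1, b, n2) {
  s <- a + b  # affected margin
  ks <- max(0, s - n2):min(n1, s)
  probs <- vapply(ks, function(k) {
    choose(n1, k) * choose(n2, s - k) / choose(n1 + n2, s)
  }, numeric(1))
  obs <- probs[ks == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

default_groups <- function() {
  list(`RfD|RfC` = c("RfD", "RfC"), `OSF|IUR` = c("OSF", "IUR"),
       IARC = "IARC", RPF = "RPF", TEF = "TEF", BMC = "BMC")
}
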