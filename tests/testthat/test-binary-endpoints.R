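make_binary_data <- function(outcomes_by_animal, conc = 10) {
  # outcomes_by_animal: named list animal -> named 0/1 vector per endpoint
  eps <- zf_endpoint_registry()$endpoint
  rows <- lapply(seq_along(outcomes_by_animal), function(i) {
    o <- rep(0L, length(eps)); names(o) <- eps
    hit <- outcomes_by_animal[[i]]
    o[names(hit)] <- hit
    data.frame(plate = 1, well = i, concentration = conc,
               endpoint = eps, outcome = unname(o))
  })
  do.call(rbind, rows)
}

test_that("incidence counts animals once regardless of endpoint multiplicity", {
  d <- make_binary_data(list(
    a1 = c(YSE = 1, PE = 1),   # two defects, one animal
    a2 = c(MORT = 1),
    a3 = integer(0),
    a4 = integer(0)))
  any_eff <- incidence(d, "any_effect")
  expect_equal(any_eff$affected, 2)
  expect_equal(any_eff$n, 4)
  expect_equal(any_eff$incidence, 50)
  mort <- incidence(d, "mortality")
  expect_equal(mort$incidence, 25)
  # union dominance: any_effect >= each component endpoint
  for (e in c("YSE", "PE", "MORT")) {
    expect_gte(any_eff$incidence, incidence(d, e)$incidence)
  }
  # dead animals leave single-endpoint denominators
  yse <- incidence(d, "YSE")
  expect_equal(yse$n, 3)
  yse_all <- incidence(d, "YSE", exclude_dead = FALSE)
  expect_equal(yse_all$n, 4)
  expect_error(incidence(d, "NOPE"), "unknown endpoint")
})

test_that("incidence saturates at 0 and 100", {
  d0 <- simulate_binary_endpoints(background = 0, upper = 1, ec50 = 1e6,
                                  hill = 8, seed = 2)
  inc0 <- incidence(d0, "any_effect")
  expect_true(all(inc0$incidence == 0))
  d1 <- make_binary_data(rep(list(c(MORT = 1)), 36))
  expect_equal(incidence(d1, "mortality")$incidence, 100)
})

test_that("binomial significance threshold matches exhaustive tail summation", {
  for (case in list(c(0.05, 36, 0.01), c(0.1, 36, 0.05),
                    c(0.02, 12, 0.01), c(0.3, 24, 0.001))) {
    expect_equal(
      significance_threshold(case[1], case[2], case[3]),
      oracle_binom_threshold(case[1], case[2], case[3]))
  }
  # alpha near 1: a single event suffices
  expect_equal(significance_threshold(0.05, 36, 1 - 1e-9), 1)
  # clean controls are smoothed so one event is never significant
  k0 <- significance_threshold(0, 36, 0.01)
  expect_gte(k0, 2)
  expect_equal(k0, oracle_binom_threshold(1 / 38, 36, 0.01))
  expect_error(significance_threshold(0.05, 36, 0), "alpha")
  expect_error(significance_threshold(1, 36, 0.01), "incidence")
})

test_that("threshold is monotone in alpha and in background incidence", {
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  ks <- vapply(alphas, function(a) significance_threshold(0.05, 36, a),
               numeric(1))
  expect_true(all(diff(ks) <= 0))
  p0s <- c(0.01, 0.05, 0.1, 0.3)
  ks <- vapply(p0s, function(p) significance_threshold(p, 36, 0.01),
               numeric(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("Fisher p-values match hypergeometric enumeration", {
  r <- fisher_bonferroni(12, 12, 0, 12)
  expect_equal(r$p, oracle_fisher_two_sided(12, 12, 0, 12))
  expect_true(r$significant)
  for (case in list(c(5, 12, 1, 12), c(8, 36, 2, 12), c(3, 10, 3, 14))) {
    expect_equal(
      fisher_bonferroni(case[1], case[2], case[3], case[4])$p,
      oracle_fisher_two_sided(case[1], case[2], case[3], case[4]),
      tolerance = 1e-10)
  }
  expect_equal(fisher_bonferroni(4, 12, 4, 12)$p, 1)
  expect_equal(fisher_bonferroni(0, 12, 0, 12)$p, 1)
  expect_error(fisher_bonferroni(-1, 12, 0, 12), "counts")
})

test_that("Fisher p is symmetric in group labels and Bonferroni gates at alpha/m", {
  a <- fisher_bonferroni(7, 12, 2, 12)
  b <- fisher_bonferroni(2, 12, 7, 12)
  expect_equal(a$p, b$p)
  expect_gt(a$p, 0); expect_lte(a$p, 1)
  # significance means the raw p beat alpha / m
  p <- fisher_bonferroni(10, 12, 1, 12, m = 13)$p
  expect_equal(p < 0.01 / 13, fisher_bonferroni(10, 12, 1, 12, m = 13)$significant)
})

test_that("outlier screen flags values beyond three single-pass SDs", {
  v <- c(0.05, 0.06, 0.05, 0.50)
  expected <- abs(v - mean(v)) > 3 * sd(v)
  expect_equal(outlier_screen(v), expected)
  expect_equal(outlier_screen(rep(0.3, 5)), rep(FALSE, 5))
  set.seed(33)
  v <- c(rnorm(20, 0.05, 0.005), 0.9)
  flags <- outlier_screen(v)
  expect_true(flags[21])
  expect_false(any(flags[1:20]))
  expect_error(outlier_screen(c(1, 2)), "at least 3")
})

test_that("QC gate enforces control mortality and positive-control EC50 limits", {
  expect_true(qc_gate(10, 19.3)$pass)
  g <- qc_gate(25, 19.3)
  expect_false(g$pass)
  expect_match(g$reasons, "negative-control")
  g <- qc_gate(10, 24.0)
  expect_false(g$pass)
  expect_match(g$reasons, "positive-control")
  expect_true(qc_gate(20, 15.3)$pass)  # boundary values pass
  expect_false(qc_gate(10, NA)$pass)
})

test_that("quantal fitting recovers a noiseless incidence curve", {
  conc <- c(5, 10, 20, 40, 80, 160, 320)
  inc <- 100 / (1 + (40 / conc)^4)
  fit <- fit_dose_response(data.frame(concentration = conc, response = inc))
  expect_true(fit$converged)
  expect_equal(fit$ec50, 40, tolerance = 1e-6)
})

test_that("flat zero incidence gives no fit and no significant levels", {
  d <- simulate_binary_endpoints(background = 0, ec50 = 1e9, hill = 8,
                                 seed = 3)
  pod <- quantal_pod(d, "mortality")
  expect_false(pod$fit$converged)
  expect_length(pod$significant_concentrations, 0)
})

test_that("quantal POD recovers the generating LC50 from Bernoulli draws", {
  errs <- vapply(1:20, function(s) {
    d <- simulate_binary_endpoints(ec50 = 40, hill = 4, seed = 5000 + s)
    pod <- quantal_pod(d, "mortality")
    if (!pod$fit$converged) return(NA_real_)
    abs(pod$ec50 - 40) / 40
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.15)
})

test_that("quantal POD flags concentrations above the binomial threshold", {
  d <- simulate_binary_endpoints(ec50 = 40, hill = 6, background = 0.02,
                                 seed = 17)
  pod <- quantal_pod(d, "mortality", alpha = 0.01)
  expect_true(all(pod$incidence$significant ==
                    (pod$incidence$affected >= pod$incidence$threshold)))
  # saturated top concentrations must be flagged, clean bottom ones not
  expect_true(320 %in% pod$significant_concentrations)
  expect_false(5 %in% pod$significant_concentrations)
})
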