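test_that("proportions of total are shares of detected concentration", {
  ct <- chemical_table(c("a", "b"), c("1-1", "2-2"), c(10, 10))
  expect_equal(unname(proportion_of_total(ct)), c(0.5, 0.5))

  ct <- chemical_table(letters[1:3], c("1-1", "2-2", "3-3"), c(97, 2, 1))
  expect_equal(unname(proportion_of_total(ct)), c(0.97, 0.02, 0.01))

  ct <- chemical_table("a", "1-1", 42)
  expect_equal(unname(proportion_of_total(ct)), 1)

  # non-detects drop out of both numerator and denominator
  ct <- chemical_table(c("a", "b"), c("1-1", "2-2"), c(10, 0),
                       detected = c(TRUE, FALSE))
  p <- proportion_of_total(ct)
  expect_equal(unname(p), c(1, NA_real_))

  ct <- chemical_table("a", "1-1", 0, detected = FALSE)
  expect_error(proportion_of_total(ct), "detected")
})

test_that("proportions always sum to one over detected chemicals", {
  for (seed in 1:20) {
    ct <- simulate_chemical_table(n_chemicals = 12, k_top = 3, seed = seed)
    expect_equal(sum(proportion_of_total(ct)), 1, tolerance = 1e-9)
  }
})

test_that("abundance weighting multiplies potency by proportion", {
  expect_equal(weight_metric(0.01, 0.5, "TEF"), 0.005)
  # lower-is-more-hazardous metrics invert to potency first
  expect_equal(weight_metric(0.02, 0.5, "RfD"), 25)
  expect_equal(weight_metric(NA_real_, 0.3, "TEF"), NA_real_)
  # IARC maps to its ordinal score (group 1 highest)
  expect_equal(weight_metric(c("1", "NC"), c(0.5, 0.5), "IARC"), c(2.5, 0.5))
  expect_error(weight_metric(0, 0.5, "RfD"), "non-positive")
  expect_error(weight_metric(1, 0.5, "ABUNDANCE"), "not weightable")
  expect_warning(weight_metric(0.02, 0.5, "RfD", literal = TRUE), "safer")
})

test_that("hazard ranking follows metric direction with tie-mean ranks", {
  expect_equal(rank_metric(c(0.3, 0.1, 0.2), "BMC"), c(3, 1, 2))
  expect_equal(rank_metric(c(1.0, 1.0, 0.5), "OSF"), c(1.5, 1.5, 3))
  expect_equal(rank_metric(c("2B", "3", "2B"), "IARC"), c(1.5, 3, 1.5))
  expect_equal(rank_metric(c(0.5, NA, 0.1), "RfD"), c(2, NA, 1))
  expect_error(rank_metric(c(NA_real_, NA_real_), "TEF"), "all values")
})

test_that("rank columns without ties or missingness are permutations", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:10, 1)
    v <- runif(n)
    r <- rank_metric(v, sample(c("TEF", "OSF", "BMC", "RfD"), 1))
    expect_setequal(r, seq_len(n))
  }
})

test_that("average rank uses the available-rank denominator by default", {
  m <- rbind(a = c(1, 3), b = c(2, NA))
  expect_equal(unname(average_rank(m)), c(2, 2))
  m <- rbind(a = c(2, NA, 4))
  expect_equal(unname(average_rank(m)), 3)
  expect_equal(unname(average_rank(m, denominator = "fixed")), 2)
  m <- rbind(a = c(NA, NA))
  expect_true(is.na(average_rank(m)))
})

test_that("abundance scheme selects the most concentrated chemicals", {
  ct <- chemical_table(letters[1:10], paste0(10:1, "-0"), 100 - 1:10)
  res <- prioritize(ct, scheme = "abundance", k = 3)
  expect_equal(res$selected, ct$cas[1:3])
  expect_equal(unname(res$average_rank[res$selected]), c(1, 2, 3))
})

test_that("a chemical dominant in every metric is selected first", {
  cas <- paste0(1:5, "-0")
  ct <- chemical_table(letters[1:5], cas, c(5, 4, 3, 2, 10))
  vals <- data.frame(RfD = c(1, 2, 3, 4, 0.001),
                     OSF = c(1, 2, 3, 4, 99),
                     BMC = c(5, 6, 7, 8, 0.01),
                     TEF = c(0.1, 0.2, 0.3, 0.4, 50))
  tt <- toxicity_table(cas, vals)
  res <- prioritize(ct, tt, scheme = "toxicity", k = 1)
  expect_equal(res$selected, "5-0")
  expect_equal(unname(res$average_rank[["5-0"]]), 1)
})

test_that("toxicity scheme matches the brute-force average-rank oracle", {
  dirs <- c(ABUNDANCE = "higher", RPF = "higher", CPV = "higher",
            IUR = "higher", RfC = "lower", OSF = "higher",
            RfD = "lower", BMC = "lower")
  grid <- c(0.01, 0.1, 1, 10, 100)
  for (seed in 1:40) {
    set.seed(1000 + seed)
    n <- sample(3:6, 1)
    metrics <- sample(c("RPF", "CPV", "IUR", "RfC", "OSF", "RfD", "BMC"),
                      sample(2:4, 1))
    cas <- paste0(seq_len(n), "-0")
    conc <- sample(grid, n, replace = TRUE)
    ct <- chemical_table(letters[seq_len(n)], cas, conc)
    vals <- as.data.frame(lapply(metrics, function(m) {
      v <- sample(grid, n, replace = TRUE)
      v[runif(n) < 0.3] <- NA
      v
    }))
    names(vals) <- metrics
    # keep every column at least partly observed
    for (m in metrics) if (all(is.na(vals[[m]]))) vals[[m]][1] <- grid[1]
    tt <- toxicity_table(cas, vals)
    k <- sample(1:n, 1)
    res <- prioritize(ct, tt, scheme = "toxicity", k = k,
                      tie_policy = "cas")
    cols <- c(list(ABUNDANCE = conc), as.list(vals))
    orc <- oracle_prioritize(cas, cols, dirs[names(cols)], k)
    used <- colnames(res$rank_matrix)[colSums(!is.na(res$rank_matrix)) > 0]
    expect_equal(res$rank_matrix[, used], orc$ranks[, used],
                 ignore_attr = TRUE)
    expect_equal(res$average_rank, orc$avg[names(res$average_rank)])
    expect_equal(res$selected, orc$selected)
  }
})

test_that("rankings and selections are invariant to concentration scaling", {
  ct <- simulate_chemical_table(n_chemicals = 12, k_top = 3, seed = 4)
  tt <- simulate_toxicity_table(ct, profile = list(), seed = 4)
  for (cscale in c(0.001, 7, 1e4)) {
    ct2 <- chemical_table(ct$name, ct$cas, ct$concentration * cscale)
    for (scheme in c("abundance", "toxicity", "weighted_toxicity")) {
      r1 <- prioritize(ct, tt, scheme = scheme, k = 5, tie_policy = "cas")
      r2 <- prioritize(ct2, tt, scheme = scheme, k = 5, tie_policy = "cas")
      expect_equal(r1$rank_matrix, r2$rank_matrix)
      expect_equal(r1$selected, r2$selected)
    }
    expect_equal(proportion_of_total(ct), proportion_of_total(
      chemical_table(ct$name, ct$cas, ct$concentration * cscale)))
  }
})

test_that("raising a chemical's hazard never worsens its rank", {
  set.seed(9)
  for (metric in c("TEF", "RfD", "BMC", "OSF")) {
    v <- runif(8, 0.1, 10)
    r0 <- rank_metric(v, metric)
    i <- 3
    dirn <- if (metric %in% c("RfD", "BMC")) 0.5 else 2
    v[i] <- v[i] * dirn  # more hazardous under the metric's direction
    r1 <- rank_metric(v, metric)
    expect_lte(r1[i], r0[i])
  }
})

test_that("uniform proportions leave weighted per-metric orderings unchanged", {
  set.seed(21)
  n <- 8
  props <- rep(1 / n, n)
  for (metric in c("TEF", "RfD", "BMC", "IUR")) {
    v <- runif(n, 0.01, 10)
    w <- weight_metric(v, props, metric)
    r_w <- rank(-w)
    r_u <- rank_metric(v, metric)
    expect_equal(r_w, r_u, ignore_attr = TRUE)
  }
})

test_that("boundary ties error by default and obey override policies", {
  cas <- paste0(1:4, "-0")
  ct <- chemical_table(letters[1:4], cas, c(10, 5, 5, 1))
  expect_error(prioritize(ct, scheme = "abundance", k = 2), "tie")
  res <- prioritize(ct, scheme = "abundance", k = 2,
                    tie_policy = "include_all")
  expect_equal(sort(res$selected), c("1-0", "2-0", "3-0"))
  res <- prioritize(ct, scheme = "abundance", k = 2, tie_policy = "cas")
  expect_equal(res$selected, c("1-0", "2-0"))
  expect_error(prioritize(ct, scheme = "abundance", k = 9), "exceeds")
})
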