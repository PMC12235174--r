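test_that("Kendall tau-b matches enumeration and the reference implementation", {
  expect_equal(as.numeric(kendallTau(1:3, 1:3)), 1)
  expect_equal(as.numeric(kendallTau(1:3, 3:1)), -1)
  expect_equal(as.numeric(kendallTau(1:4, c(1, 3, 2, 4))), 2 / 3)
  set.seed(21)
  for (i in 1:5) {
    x <- sample(1:6, 10, replace = TRUE)  # ties likely
    y <- rnorm(10)
    expect_equal(as.numeric(kendallTau(x, y)), bruteKendallTau(x, y),
                 tolerance = 1e-12)
    expect_equal(as.numeric(kendallTau(x, y)),
                 unname(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
  }
  expect_error(kendallTau(rep(1, 5), rnorm(5)), "all-tied")
})

test_that("the exact S null is a symmetric probability distribution", {
  for (groups in list(5, 8, c(3, 3, 3, 2), c(2, 2, 2, 2, 2, 2))) {
    null <- kendallSNull(groups)
    expect_equal(sum(null$prob), 1, tolerance = 1e-12)
    expect_equal(null$prob, rev(null$prob), tolerance = 1e-12)
    expect_equal(sum(null$s * null$prob), 0, tolerance = 1e-9)
  }
})

test_that("exact untied S null reproduces the classical Kendall test p-value", {
  set.seed(33)
  for (n in c(6, 8, 10)) {
    x <- rnorm(n); y <- rnorm(n)
    S <- attr(kendallTau(x, y), "S")
    null <- kendallSNull(n)
    pExact <- sum(null$prob[abs(null$s) >= abs(S) - 1e-9])
    ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = TRUE))
    expect_equal(pExact, ct$p.value, tolerance = 1e-12)
  }
})

test_that("a noiseless cosine with grid-aligned acrophase gives tau = 1", {
  tp <- seq(1, 45, by = 4)
  series <- data.frame(timepoint_h = tp,
                       rel = 2^cos(2 * pi * (tp - 8) / 24))
  r <- jtkCycle(series)
  expect_equal(r@bestPeriod, 24)
  expect_equal(r@bestLag, 8)
  expect_equal(r@tau, 1)
  expect_equal(r@method, "exact")
  # p_adj equals the minimal achievable value of the exact S null for the
  # winning template's tie structure, Bonferroni-corrected over the family
  ref <- round(cos(2 * pi * (tp - 8) / 24), 9)
  null <- kendallSNull(sort(as.integer(table(ref))))
  m <- nrow(r@table)
  expect_equal(r@pAdj, m * sum(null$prob[abs(null$s) >= max(null$s)]),
               tolerance = 1e-12)
  expect_lt(r@pAdj, 1e-4)
})

test_that("constant series yield p = 1 with undefined tau", {
  r <- jtkCycle(data.frame(timepoint_h = seq(1, 45, 4), rel = rep(3, 12)))
  expect_equal(r@pAdj, 1)
  expect_true(is.na(r@tau))
})

test_that("rank-based testing is invariant under monotone transforms", {
  tp <- seq(1, 69, by = 4)
  set.seed(14)
  y <- 2^(0.4 * cos(2 * pi * (tp - 5) / 24)) + abs(rnorm(18, 0, 0.05))
  a <- jtkCycle(data.frame(timepoint_h = tp, rel = y))
  b <- jtkCycle(data.frame(timepoint_h = tp, rel = exp(y)))
  expect_equal(a@table$tau, b@table$tau, tolerance = 1e-12)
  expect_equal(a@table$pAdj, b@table$pAdj, tolerance = 1e-12)
  expect_equal(a@bestPeriod, b@bestPeriod)
})

test_that("negating the series negates tau at every lag", {
  tp <- seq(1, 69, by = 4)
  set.seed(15)
  y <- cos(2 * pi * tp / 24) + rnorm(18, 0, 0.2)
  a <- jtkCycle(data.frame(timepoint_h = tp, rel = y))
  b <- jtkCycle(data.frame(timepoint_h = tp, rel = -y))
  expect_equal(a@table$tau, -b@table$tau, tolerance = 1e-12)
})

test_that("JTK detects planted rhythms and stays quiet on flat profiles", {
  tp <- seq(1, 69, by = 4)
  prof <- 2^(0.5 * cos(2 * pi * (tp - 5) / 24))  # 2-fold peak-to-trough
  hits <- falsePos <- 0L
  nPow <- 50; nNull <- 100  # reduced screen; full rates in acceptance tests
  for (i in 1:nPow) {
    e <- ddct(generateCtTable(prof, timepoints = tp, noiseSd = 0.25,
                              replicates = 4, seed = 40000 + i),
              "target", "reference")
    if (jtkCycle(e)@pAdj < 0.05) hits <- hits + 1L
  }
  for (i in 1:nNull) {
    e <- ddct(generateCtTable(rep(1, 18), timepoints = tp, noiseSd = 0.25,
                              seed = 50000 + i),
              "target", "reference")
    if (jtkCycle(e)@pAdj < 0.05) falsePos <- falsePos + 1L
  }
  expect_gte(hits / nPow, 0.9)
  expect_lte(falsePos / nNull, 0.05)
})
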