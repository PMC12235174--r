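test_that("noiseless cosinor recovery is exact across circadian periods", {
  for (tau in c(20, 24, 27, 30)) {
    tr <- makeCosTrace(tau, duration = 120, mesor = 5, amplitude = 2,
                       peak = 6, ztOffset = 0)
    fit <- cosinorFit(tr, periodInit = 24)
    expect_equal(mesor(fit), 5, tolerance = 1e-4)
    expect_equal(amplitude(fit), 2, tolerance = 1e-4)
    expect_equal(fittedPeriod(fit), tau, tolerance = tau * 1e-4)
    expect_equal(acrophase(fit), 6 %% tau, tolerance = 1e-3)
    expect_equal(rSquared(fit), 1, tolerance = 1e-6)
  }
})

test_that("negative linear amplitude is folded into the acrophase", {
  t <- seq(0, 119.5, by = 0.5)
  tr <- TraceSeries("w", times = t, values = 5 - 2 * cos(2 * pi * t / 24),
                    ztOffset = 0)
  fit <- cosinorFit(tr, periodInit = 24, freePeriod = FALSE)
  expect_gte(amplitude(fit), 0)
  expect_equal(amplitude(fit), 2, tolerance = 1e-9)
  expect_equal(acrophase(fit), 12, tolerance = 1e-6)
})

test_that("the free-period fit matches an exhaustive grid-search oracle", {
  tr <- makeCosTrace(24.7, duration = 120, mesor = 1, amplitude = 1,
                     peak = 9, ztOffset = 0, noiseSd = 0.2, seed = 123)
  t <- traceTimes(tr); y <- traceValues(tr)
  fit <- cosinorFit(tr, periodInit = 24)
  oracle <- gridCosinorOracle(t, y, tauGrid = seq(23.7, 25.7, by = 0.005),
                              phiStep = 0.05)
  # the continuous optimum can only undercut the grid; both agree closely
  expect_lte(fit@sse, oracle$sse + 1e-9)
  expect_lt(oracle$sse - fit@sse, 1e-3 * fit@sse)
  expect_equal(fittedPeriod(fit), oracle$tau, tolerance = 0.01)
  expect_equal(acrophase(fit), oracle$phi %% 24, tolerance = 0.06)
  expect_equal(mesor(fit), oracle$M, tolerance = 1e-2)
  expect_equal(amplitude(fit), abs(oracle$A), tolerance = 1e-2)
})

test_that("fixed-period closed form agrees with an iterative minimizer", {
  for (s in 1:3) {
    tr <- makeCosTrace(24, duration = 96, mesor = 2, amplitude = 1.5,
                       peak = 17, ztOffset = 0, noiseSd = 0.4, seed = s)
    fit <- cosinorFit(tr, periodInit = 24, freePeriod = FALSE)
    sseIter <- iterativeCosinorSse(
      traceTimes(tr), traceValues(tr), 24,
      start = c(mesor(fit) + 0.1, amplitude(fit) + 0.1,
                fit@acrophaseAbs + 0.05))
    expect_lt(abs(fit@sse - sseIter), 1e-8 * max(1, fit@sse))
  }
})

test_that("classification applies the period and fit-quality rules inclusively", {
  mkFit <- function(tau, r2)
    new("CosinorFit", mesor = 0, amplitude = 1, period = tau,
        acrophase = 0, acrophaseAbs = 0, rSquared = r2, sse = 1,
        n = 100L, freePeriod = TRUE)
  cases <- data.frame(
    tau = c(24.9, 24.9, 17.5, 18.0, 37.0, 37.1, 20.0, 20.0),
    r2  = c(0.8, 0.5, 0.9, 0.5, 0.5, 0.9, 0.49, 0.5),
    lab = c("Circadian", "Circadian", "Arrhythmic", "Circadian",
            "Circadian", "Arrhythmic", "Arrhythmic", "Circadian"))
  for (i in seq_len(nrow(cases)))
    expect_equal(rhythmLabel(classifyRhythm(mkFit(cases$tau[i],
                                                  cases$r2[i]),
                                            "freerun")),
                 cases$lab[i], info = paste("case", i))
  # entrained rule: ~24 h within tol24
  expect_equal(rhythmLabel(classifyRhythm(mkFit(24.9, 0.8), "entrained")),
               "Synchronized")
  expect_equal(rhythmLabel(classifyRhythm(mkFit(25.1, 0.8), "entrained")),
               "Arrhythmic")
  expect_equal(rhythmLabel(classifyRhythm(mkFit(25.1, 0.8), "entrained",
                                          tol24 = 2)),
               "Synchronized")
})

test_that("classification is monotone in fit quality at fixed period", {
  mkFit <- function(r2)
    new("CosinorFit", mesor = 0, amplitude = 1, period = 25,
        acrophase = 0, acrophaseAbs = 0, rSquared = r2, sse = 1,
        n = 100L, freePeriod = TRUE)
  labs <- vapply(seq(0, 1, by = 0.05), function(r2)
    rhythmLabel(classifyRhythm(mkFit(r2), "freerun")), character(1))
  firstRhythmic <- match("Circadian", labs)
  expect_false(any(labs[firstRhythmic:length(labs)] == "Arrhythmic"))
})

test_that("peak phases are read per cycle at the observed maximum", {
  tr <- makeCosTrace(24, duration = 120, peak = 18, ztOffset = 0)
  ph <- findPeakPhases(tr, window = c(0, 120))
  expect_length(ph, 5)
  expect_true(all(abs(ph - 18) <= 0.25 + 1e-9))
  # two-day window -> exactly two peaks; firstOnly -> one
  expect_length(findPeakPhases(tr, window = c(24, 72)), 2)
  expect_length(findPeakPhases(tr, window = c(24, 72), firstOnly = TRUE), 1)
  # ZT mapping honours the recording-start offset
  tr12 <- makeCosTrace(24, duration = 72, peak = 6, ztOffset = 12)
  ph12 <- findPeakPhases(tr12, window = c(0, 72))
  expect_true(all(abs(ph12 - 18) <= 0.25 + 1e-9))
  cst <- TraceSeries("w", times = seq(0, 47.5, 0.5), values = rep(1, 96))
  expect_error(findPeakPhases(cst, window = c(0, 48)), "no unique peak")
  expect_error(findPeakPhases(tr, window = c(0, 10)), "at least one day")
})

test_that("percent-rhythmic arithmetic reproduces printed study tallies", {
  expect_equal(percentRhythmic(c(rep("Circadian", 14),
                                 rep("Arrhythmic", 16)), digits = 0), 47)
  expect_equal(percentRhythmic(c(rep("Circadian", 9),
                                 rep("Arrhythmic", 17)), digits = 1), 34.6)
  expect_equal(percentRhythmic(c(rep("Circadian", 36),
                                 rep("Arrhythmic", 35)), digits = 0), 51)
  expect_equal(percentRhythmic(c(rep("Circadian", 20),
                                 rep("Arrhythmic", 25)), digits = 0), 44)
  expect_equal(percentRhythmic(rep("Arrhythmic", 10)), 0)
  expect_error(percentRhythmic(character(0)), "empty")
  # RhythmCall objects are accepted too
  calls <- list(classifyRhythm(new("CosinorFit", mesor = 0, amplitude = 1,
                                   period = 24, acrophase = 0,
                                   acrophaseAbs = 0, rSquared = 0.9,
                                   sse = 1, n = 10L, freePeriod = TRUE),
                               "freerun"))
  expect_equal(percentRhythmic(calls), 100)
})

test_that("free-period recovery holds at plate scale with the study design", {
  plate <- generatePlate(
    list(GenotypeSpec("control", periodFreerun = 24.2),
         GenotypeSpec("mutant", periodFreerun = 27.1)),
    nWells = 30, seed = 77)
  res <- runFullPipeline(plate)
  fr <- res$results[res$results$condition == "freerun" &
                      res$results$label == "Circadian", ]
  expect_lt(abs(mean(fr$period[fr$strain == "control"]) - 24.2), 0.3)
  expect_lt(abs(mean(fr$period[fr$strain == "mutant"]) - 27.1), 0.3)
  cmp <- res$comparisons$freerunBetweenStrains
  expect_lt(cmp@meanDiff, 0)   # control shorter than mutant
  expect_lt(cmp@p, 0.05)
})

test_that("degenerate cosinor inputs are rejected", {
  cst <- TraceSeries("w", times = seq(0, 71.5, 0.5), values = rep(1, 144))
  expect_error(cosinorFit(cst), "constant")
  expect_error(cosinorFit(makeCosTrace(24), periodInit = 40), "periodRange")
})
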