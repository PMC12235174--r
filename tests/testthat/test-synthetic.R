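proto0 <- ProtocolSchedule()

cleanGeno <- function(...) {
  args <- utils::modifyList(
    list(noiseSd = 0, dampingRate = 0, transientHours = 0,
         fractionRhythmic = 1, amplitude = 2, mesor = 5,
         periodEntrained = 24, periodFreerun = 24, acrophaseZt = 18),
    list(...))
  do.call(GenotypeSpec, args)
}

test_that("noiseless undamped traces are an exact cosine on the grid", {
  tr <- generateTrace(cleanGeno(), proto0, seed = 1)
  t <- traceTimes(tr)
  zt <- proto0@recordStartZt + t
  expect_equal(traceValues(tr), 5 + 2 * cos(2 * pi * (zt - 18) / 24),
               tolerance = 1e-12)
  # value at every sample nearest ZT18 is the exact peak mesor + amplitude
  peaks <- which(round(zt - 18) %% 24 == 0 & abs((zt - 18) %% 24) < 1e-9)
  expect_true(length(peaks) >= 5)
  expect_equal(traceValues(tr)[peaks], rep(7, length(peaks)))
})

test_that("zero-amplitude flat-trend traces are constant at the mesor", {
  g <- cleanGeno(amplitude = 0)
  tr <- generateTrace(g, proto0, seed = 3)
  expect_equal(traceValues(tr), rep(5, length(tr)))
})

test_that("trace generation is seed-deterministic and seed-sensitive", {
  g <- GenotypeSpec()  # defaults: noisy, damped, half rhythmic
  a <- generateTrace(g, proto0, seed = 11)
  b <- generateTrace(g, proto0, seed = 11)
  c <- generateTrace(g, proto0, seed = 12)
  expect_identical(traceValues(a), traceValues(b))
  expect_false(identical(traceValues(a), traceValues(c)))
})

test_that("the noiseless signal is phase-continuous at release", {
  g <- cleanGeno(periodFreerun = 27.1)
  tr <- generateTrace(g, proto0, seed = 1)
  y <- traceValues(tr)
  d <- abs(diff(y))
  iRel <- which(traceTimes(tr) == releaseTime(proto0))
  # the step across the transition is no larger than the steepest step of
  # the smooth cosine elsewhere
  expect_lt(d[iRel - 1], max(d) * 1.01)
  # and a phase offset at release produces a visible jump
  g2 <- cleanGeno(periodFreerun = 27.1, phaseOffsetAtRelease = 6)
  y2 <- traceValues(generateTrace(g2, proto0, seed = 1))
  expect_gt(abs(diff(y2))[iRel - 1], max(abs(diff(y))) * 2)
})

test_that("plate generation partitions wells by genotype with a truth table", {
  plate <- generatePlate(
    list(cleanGeno(label = "a"), cleanGeno(label = "b")),
    nWells = 10, proto0, seed = 5)
  expect_equal(ncol(plate), 20)
  tru <- plateTruth(plate)
  expect_equal(nrow(tru), 20)
  expect_equal(as.integer(table(tru$strain)[c("a", "b")]), c(10L, 10L))
  expect_false(anyDuplicated(tru$well) > 0)
})

test_that("plate rhythmic fraction behaves as a seeded Bernoulli draw", {
  g <- GenotypeSpec(fractionRhythmic = 0.5)
  plate <- generatePlate(g, nWells = 30, proto0, seed = 7)
  k <- sum(plateTruth(plate)$truthRhythmic)
  expect_gte(k, 8)   # ~Binomial(30, .5); far tails excluded
  expect_lte(k, 22)
  # exact count reproducible for the seed
  plate2 <- generatePlate(g, nWells = 30, proto0, seed = 7)
  expect_identical(plateTruth(plate2)$truthRhythmic,
                   plateTruth(plate)$truthRhythmic)
  expect_identical(SummarizedExperiment::assay(plate, "lum"),
                   SummarizedExperiment::assay(plate2, "lum"))
})

test_that("arrhythmic wells carry no cosine component on average", {
  g <- GenotypeSpec(fractionRhythmic = 0, noiseSd = 100, dampingRate = 0,
                    transientHours = 0)
  tpl <- NULL
  cors <- vapply(1:200, function(s) {
    tr <- generateTrace(g, proto0, seed = 5000 + s)
    t <- traceTimes(tr)
    if (is.null(tpl)) tpl <<- cos(2 * pi * (proto0@recordStartZt + t - 18) / 24)
    cor(traceValues(tr), tpl)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.02)
})

test_that("synthetic Ct tables encode the planted profile exactly", {
  tp <- seq(1, 21, by = 4)
  # flat profile, no noise: target and reference differ by the constant
  ct <- generateCtTable(rep(1, 6), timepoints = tp, noiseSd = 0, seed = 1,
                        referenceCt = 15, deltaConst = 4)
  expect_equal(unique(ct$ct[ct$gene == "target"]), 19)
  expect_equal(unique(ct$ct[ct$gene == "reference"]), 15)
  # doubling at one timepoint lowers the target Ct by exactly one cycle
  prof <- rep(1, 6); prof[3] <- 2
  ct2 <- generateCtTable(prof, timepoints = tp, noiseSd = 0, seed = 1)
  t3 <- ct2$ct[ct2$gene == "target" & ct2$timepoint_h == tp[3]]
  t1 <- ct2$ct[ct2$gene == "target" & ct2$timepoint_h == tp[1]]
  expect_equal(unique(t1) - unique(t3), 1)
  # seed determinism
  a <- generateCtTable(prof, timepoints = tp, noiseSd = 0.3, seed = 9)
  b <- generateCtTable(prof, timepoints = tp, noiseSd = 0.3, seed = 9)
  expect_identical(a, b)
  # invalid input
  expect_error(generateCtTable(c(1, 0, 1), seed = 1), "positive")
})

test_that("generator rejects invalid protocol and noise parameters", {
  expect_error(ProtocolSchedule(samplingInterval = 0))
  expect_error(GenotypeSpec(noiseSd = -1))
  expect_error(GenotypeSpec(fractionRhythmic = 1.5))
})
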