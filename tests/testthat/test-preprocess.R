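flatTrace <- function(value = 100, duration = 144, dt = 0.5) {
  t <- seq(0, duration - dt, by = dt)
  TraceSeries("w", times = t, values = rep(value, length(t)))
}

test_that("background subtraction shifts values and nothing else", {
  tr <- flatTrace(100)
  expect_equal(traceValues(subtractBackground(tr, 100)),
               rep(0, length(tr)))
  expect_equal(traceValues(subtractBackground(tr, 0)), traceValues(tr))
  t2 <- TraceSeries("w", times = c(0, 0.5), values = c(150, 130))
  expect_equal(traceValues(subtractBackground(t2, 20)), c(130, 110))
  expect_equal(traceTimes(subtractBackground(tr, 5)), traceTimes(tr))
  expect_error(subtractBackground(tr, -1))
})

test_that("transient trimming keeps absolute times and guards duration", {
  tr <- flatTrace(duration = 144)
  tt <- trimTransient(tr, 24)
  expect_equal(length(tt), 240)
  expect_equal(min(traceTimes(tt)), 24)
  expect_equal(max(traceTimes(tt)), 143.5)
  expect_equal(traceValues(trimTransient(tr, 0)), traceValues(tr))
  expect_error(trimTransient(tr, 130), "2 full days")
})

test_that("detrending removes lines exactly and constants entirely", {
  t <- seq(0, 143.5, by = 0.5)
  ramp <- TraceSeries("w", times = t, values = 3 * t + 7)
  res <- traceValues(detrendTrace(ramp, 24))
  interior <- t >= 12 & t <= max(t) - 12
  expect_lt(max(abs(res[interior])), 1e-9)
  cst <- flatTrace(5)
  expect_equal(traceValues(detrendTrace(cst, 24)), rep(0, length(cst)))
})

test_that("a 24 h cosine passes a 24 h detrend almost unchanged (interior)", {
  t <- seq(0, 143.5, by = 0.5)
  y <- cos(2 * pi * t / 24)
  tr <- TraceSeries("w", times = t, values = y)
  res <- traceValues(detrendTrace(tr, 24))
  interior <- t >= 12 & t <= max(t) - 12
  # the discrete symmetric window spans one period plus one sample, so the
  # residual is (1 + 1/k) times the cosine with k = 49 samples per window
  expect_lt(max(abs(res[interior] - y[interior])), 1.05 / 49)
})

test_that("moving-average operators match a brute-force oracle", {
  set.seed(42)
  t <- sort(c(seq(0, 71.5, by = 0.5), 100))  # include a gap
  y <- rnorm(length(t))
  tr <- TraceSeries("w", times = t, values = y)
  expect_equal(traceValues(smoothTrace(tr, 2)),
               bruteMovingAverage(t, y, 2), tolerance = 1e-12)
  expect_equal(traceValues(detrendTrace(tr, 24)),
               y - bruteMovingAverage(t, y, 24), tolerance = 1e-12)
})

test_that("smoothing a constant is the identity", {
  tr <- flatTrace(3)
  expect_equal(traceValues(smoothTrace(tr, 2)), traceValues(tr))
})

test_that("smoothing white noise divides the variance by the window size", {
  # window of 2 h at 0.5 h cadence -> k = 5 samples; var sigma^2/k at a
  # fixed interior sample across seeded replicates
  sigma <- 1
  k <- 5
  mid <- numeric(1000)
  t <- seq(0, 10, by = 0.5)
  for (r in 1:1000) {
    set.seed(r)
    y <- rnorm(length(t), 0, sigma)
    mid[r] <- traceValues(smoothTrace(
      TraceSeries("w", times = t, values = y), 2))[11]
  }
  expect_equal(var(mid), sigma^2 / k, tolerance = 0.15)
})

test_that("detrend + smooth attenuates a cosine by the Dirichlet-kernel gain", {
  tau <- 27.1; dt <- 0.5
  t <- seq(0, 143.5, by = dt)
  y <- 10 + 0.2 * t + 2 * cos(2 * pi * t / tau)  # mesor + trend + cosine
  tr <- TraceSeries("w", times = t, values = y)
  out <- traceValues(smoothTrace(detrendTrace(tr, 24), 2))
  # analytic gain of a symmetric k-point average at period tau
  gain <- function(k) sin(k * pi * dt / tau) / (k * sin(pi * dt / tau))
  expected <- 2 * (1 - gain(49)) * gain(5)
  interior <- t >= 20 & t <= max(t) - 20
  measured <- (max(out[interior]) - min(out[interior])) / 2
  expect_equal(measured, expected, tolerance = 0.01)
  # and the whole chain equals the independently coded convolution
  oracle <- bruteMovingAverage(t, y - bruteMovingAverage(t, y, 24), 2)
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("normalization fixes the initial-window maximum at exactly 1", {
  t <- seq(24, 143.5, by = 0.5)
  y <- 200 * cos(2 * pi * t / 24) + 300
  tr <- TraceSeries("w", times = t, values = y)
  nn <- normalizeInitialMax(tr, 24)
  expect_equal(max(traceValues(nn)[t < 48]), 1)
  expect_equal(traceValues(nn), y / max(y[t < 48]))
  expect_equal(traceValues(normalizeInitialMax(nn, 24)), traceValues(nn))
  expect_error(normalizeInitialMax(flatTrace(0), 24), "dead well")
})

test_that("the preprocessing chain matches its independently coded composition", {
  g <- GenotypeSpec(noiseSd = 0, fractionRhythmic = 1)
  tr <- generateTrace(g, ProtocolSchedule(), seed = 2)
  pp <- runPreprocess(tr, PreprocessParams(background = 10))
  # independent composition with brute-force operators
  t <- traceTimes(tr); y <- traceValues(tr) - 10
  keep <- t >= 24
  t2 <- t[keep]; y2 <- y[keep]
  y3 <- y2 - bruteMovingAverage(t2, y2, 24)
  y4 <- bruteMovingAverage(t2, y3, 2)
  y5 <- y4 / max(y4[t2 < t2[1] + 24])
  expect_equal(traceTimes(pp), t2)
  expect_equal(traceValues(pp), y5, tolerance = 1e-12)
  expect_equal(max(traceValues(pp)[t2 < t2[1] + 24]), 1)
})

test_that("a constant plate flags every well dead", {
  lum <- matrix(5, nrow = 288, ncol = 3)
  plate <- makePlateRecording(lum, times = seq(0, 143.5, by = 0.5),
                              wells = c("A", "B", "C"), strains = "s",
                              protocol = ProtocolSchedule())
  expect_error(runFullPipeline(plate), "no well produced results")
})

test_that("trim depth only rescales the shared retained interval", {
  g <- GenotypeSpec(noiseSd = 0, fractionRhythmic = 1, dampingRate = 0,
                    transientHours = 0)
  tr <- generateTrace(g, ProtocolSchedule(), seed = 2)
  p24 <- runPreprocess(tr, PreprocessParams(trimHours = 24))
  p12 <- runPreprocess(tr, PreprocessParams(trimHours = 12))
  # away from the differing detrend edges the two chains agree up to the
  # normalization constant
  sel24 <- traceTimes(p24) >= 40 & traceTimes(p24) <= 120
  sel12 <- traceTimes(p12) >= 40 & traceTimes(p12) <= 120
  a <- traceValues(p24)[sel24]; b <- traceValues(p12)[sel12]
  # proportionality (robust to zero crossings): a = c*b for one constant c
  cHat <- sum(a * b) / sum(b * b)
  expect_lt(max(abs(a - cHat * b)), 1e-9 * max(abs(a)))
})
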