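# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities by brute force / textbook formulas
# so they share no code with the package implementation.

# cosine trace on a regular grid
makeCosTrace <- function(period, duration = 120, dt = 0.5, mesor = 0,
                         amplitude = 1, peak = 0, ztOffset = 0,
                         noiseSd = 0, seed = NULL) {
  t <- seq(0, duration - dt, by = dt)
  y <- mesor + amplitude * cos(2 * pi * (t - peak) / period)
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(t), 0, noiseSd)
  }
  TraceSeries("w", times = t, values = y, ztOffset = ztOffset)
}

# classical DFT periodogram, Scargle-normalized, at frequency k/T cycles/h
dftPeriodogramOracle <- function(y, dt, k) {
  n <- length(y)
  yc <- y - mean(y)
  Mod(fft(yc)[k + 1])^2 / (n * var(y))
}

# brute-force double-loop centered moving average (same symmetric-inclusive
# time-window rule, independently coded)
bruteMovingAverage <- function(times, values, window) {
  sapply(seq_along(times), function(i) {
    sel <- abs(times - times[i]) <= window / 2 + 1e-9
    mean(values[sel])
  })
}

# exhaustive (tau, phi) grid search for the cosinor SSE; M and A by a
# 2-parameter linear fit per grid point
gridCosinorOracle <- function(t, y, tauGrid, phiStep = 0.05) {
  best <- list(sse = Inf)
  for (tau in tauGrid) {
    for (phi in seq(0, tau - phiStep, by = phiStep)) {
      X <- cbind(1, cos(2 * pi * (t - phi) / tau))
      f <- lm.fit(X, y)
      sse <- sum(f$residuals^2)
      if (sse < best$sse)
        best <- list(sse = sse, tau = tau, phi = phi,
                     M = f$coefficients[[1]], A = f$coefficients[[2]])
    }
  }
  best
}

# iterative minimizer of the same cosinor SSE (BFGS on M, A, phi)
iterativeCosinorSse <- function(t, y, tau, start) {
  f <- function(p) sum((y - (p[1] + p[2] *
                               cos(2 * pi * (t - p[3]) / tau)))^2)
  o <- optim(start, f, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  o$value
}

# Kendall tau-b by explicit enumeration of all pairs
bruteKendallTau <- function(x, y) {
  n <- length(x); C <- D <- n1 <- n2 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a == 0) n1 <- n1 + 1
    if (b == 0) n2 <- n2 + 1
    if (a != 0 && b != 0) {
      if (a == b) C <- C + 1 else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# textbook two-sample t statistics (Welch and pooled)
welchOracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
pooledOracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), na + nb - 2)
  list(t = t, df = na + nb - 2, p = p)
}
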