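#' @importFrom stats optimize lm.fit
NULL

# Closed-form cosinor at fixed period: linearize the cosine as
# y = M + b1*cos(wt) + b2*sin(wt) and solve by least squares.
# Returns M, b1, b2 and the SSE.
.cosinorClosed <- function(t, y, period) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  fit <- lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(M = cf[[1]], b1 = cf[[2]], b2 = cf[[3]],
       sse = sum(fit$residuals^2))
}

#' Cosinor fit of a circadian trace
#'
#' Fits `y = M + A * cos(2*pi*(t - phi)/tau)` by least squares. For a fixed
#' period the fit is obtained exactly in closed form through the
#' sine/cosine linearization; with `freePeriod = TRUE` the period is
#' profiled: the closed-form SSE is evaluated on a dense period grid over
#' `periodRange` (grid spacing `1/(oversampling * span)` in frequency,
#' matching the periodogram grid), and the best grid period is refined by a
#' local golden-section search. This avoids the initialization fragility of
#' generic nonlinear least squares while minimizing the identical
#' objective.
#'
#' The amplitude is reported non-negative, with the acrophase adjusted by
#' half a period when the linear solution has negative amplitude. The
#' acrophase is returned both in internal hours-from-start modulo tau
#' (`@acrophaseAbs`) and mapped through the trace's ZT offset to ZT/CT
#' hours modulo 24 (`acrophase()`).
#'
#' @param trace A [TraceSeries] with at least 8 samples.
#' @param periodInit Initial/fixed period in hours, typically the
#'   Lomb-Scargle peak (default 24). Must lie inside `periodRange` when
#'   `freePeriod`.
#' @param freePeriod Optimize the period (default TRUE)? If FALSE the
#'   period is held at `periodInit`.
#' @param periodRange Search bounds in hours (default `c(18, 37)`).
#' @param oversampling Density of the profile grid (default 30).
#' @return A [CosinorFit].
#' @examples
#' t <- seq(0, 119.5, by = 0.5)
#' tr <- TraceSeries("w", times = t,
#'                   values = 5 + 2 * cos(2 * pi * (t - 6) / 24),
#'                   ztOffset = 0)
#' cosinorFit(tr, periodInit = 24)
#' @export
cosinorFit <- function(trace, periodInit = 24, freePeriod = TRUE,
                       periodRange = c(18, 37), oversampling = 30) {
  t <- traceTimes(trace)
  y <- traceValues(trace)
  n <- length(y)
  if (n < 8) stop("need at least 8 samples for a cosinor fit")
  ssTot <- sum((y - mean(y))^2)
  if (ssTot <= 0)
    stop("constant trace: cosinor fit undefined for well ", wellId(trace))

  if (freePeriod) {
    if (periodInit < periodRange[1] || periodInit > periodRange[2])
      stop("periodInit must lie inside periodRange when freePeriod = TRUE")
    span <- max(t) - min(t)
    df <- 1 / (oversampling * span)
    f <- seq(1 / periodRange[2], 1 / periodRange[1], by = df)
    grid <- sort(unique(c(1 / f, periodInit)))
    sseGrid <- vapply(grid, function(p) .cosinorClosed(t, y, p)$sse,
                      numeric(1))
    i <- which.min(sseGrid)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    period <- if (lo < hi)
      optimize(function(p) .cosinorClosed(t, y, p)$sse,
               interval = c(lo, hi), tol = 1e-8)$minimum
    else grid[i]
    # keep the grid optimum if refinement did not actually improve
    if (.cosinorClosed(t, y, period)$sse > sseGrid[i]) period <- grid[i]
  } else period <- periodInit

  cc <- .cosinorClosed(t, y, period)
  A <- sqrt(cc$b1^2 + cc$b2^2)
  phiAbs <- if (A > 0) (atan2(cc$b2, cc$b1) * period / (2 * pi)) %% period
            else 0
  r2 <- max(0, min(1, 1 - cc$sse / ssTot))
  new("CosinorFit", mesor = cc$M, amplitude = A, period = period,
      acrophase = hoursMod24(ztOffset(trace) + phiAbs),
      acrophaseAbs = phiAbs, rSquared = r2, sse = cc$sse,
      n = as.integer(n), freePeriod = freePeriod)
}

#' Classify a fitted trace as Synchronized / Circadian / Arrhythmic
#'
#' Applies the rhythmicity rules: under the entrained condition a trace
#' with a ~24 h period (within `tol24` hours) and fit R2 >= `r2Threshold`
#' is "Synchronized"; under free run a trace with period inside
#' `periodRange` (bounds inclusive) and R2 >= `r2Threshold` is "Circadian";
#' anything else is "Arrhythmic". All thresholds applied are recorded in
#' the call's `criteria` slot.
#'
#' @param fit A [CosinorFit].
#' @param condition `"entrained"` or `"freerun"`.
#' @param tol24 Tolerance around 24 h for the Synchronized rule, hours
#'   (default 1; the rule's "24 h period" has no stated width, and
#'   sampling/grid resolution make exactly 24.00 h unattainable).
#' @param r2Threshold Minimum R2 (default 0.5, boundary inclusive).
#' @param periodRange Circadian period range for the free-run rule,
#'   hours (default `c(18, 37)`, bounds inclusive).
#' @return A [RhythmCall].
#' @examples
#' t <- seq(0, 71.5, by = 0.5)
#' tr <- TraceSeries("w", times = t, values = cos(2 * pi * t / 24.9))
#' classifyRhythm(cosinorFit(tr), condition = "freerun")  # Circadian
#' @export
classifyRhythm <- function(fit, condition = c("freerun", "entrained"),
                           tol24 = 1, r2Threshold = 0.5,
                           periodRange = c(18, 37)) {
  condition <- match.arg(condition)
  tau <- fit@period
  r2 <- fit@rSquared
  ok <- if (condition == "entrained")
    abs(tau - 24) <= tol24 && r2 >= r2Threshold
  else
    tau >= periodRange[1] && tau <= periodRange[2] && r2 >= r2Threshold
  label <- if (!ok) "Arrhythmic"
           else if (condition == "entrained") "Synchronized" else "Circadian"
  new("RhythmCall", label = label, condition = condition,
      criteria = list(period = tau, rSquared = r2, tol24 = tol24,
                      r2Threshold = r2Threshold, periodRange = periodRange))
}

#' Observed peak phases of a trace
#'
#' Returns, for each 24 h cycle inside `window`, the ZT/CT hour (mod 24) at
#' which the trace attains its maximum — the "bioluminescent peak" used for
#' Rayleigh plots. For summarizing the free run, only the first
#' post-release peak is conventionally used (`firstOnly = TRUE`).
#'
#' @param trace A (typically smoothed) [TraceSeries].
#' @param window Numeric length-2: hours-from-start interval `[t0, t1)` to
#'   scan; must span at least one day.
#' @param firstOnly Return only the first cycle's peak (default FALSE).
#' @return Numeric vector of peak phases in hours mod 24 (one per complete
#'   24 h cycle in the window).
#' @export
findPeakPhases <- function(trace, window, firstOnly = FALSE) {
  if (length(window) != 2 || diff(window) < 24)
    stop("window must span at least one day")
  tr <- subsetTrace(trace, window[1], window[2])
  if (!length(tr)) stop("window contains no samples")
  if (diff(range(traceValues(tr))) == 0)
    stop("constant trace: no unique peak in well ", wellId(trace))
  starts <- seq(window[1], window[2] - 24, by = 24)
  phases <- numeric(0)
  for (s in starts) {
    cyc <- subsetTrace(tr, s, s + 24)
    if (!length(cyc)) next
    i <- which.max(traceValues(cyc))
    phases <- c(phases, hoursMod24(ztOffset(cyc) + traceTimes(cyc)[i]))
    if (firstOnly) break
  }
  if (!length(phases)) stop("window contains no samples")
  phases
}

#' Percentage of rhythmic calls
#'
#' `100 * rhythmic / total` over a set of rhythm calls. Rhythmic means
#' "Circadian" or "Synchronized" (or restrict to one via `label`). The
#' exact percentage is returned by default; pass `digits` to round for
#' reporting (counts printed in the field are typically rounded to the
#' nearest integer, or one decimal for emphasis).
#'
#' @param calls A list of [RhythmCall] objects, or a character vector of
#'   labels.
#' @param label Labels counted as rhythmic (default both).
#' @param digits Optional rounding digits; `NA` (default) returns the exact
#'   value.
#' @return The percentage as a single number.
#' @examples
#' percentRhythmic(c(rep("Circadian", 14), rep("Arrhythmic", 16)),
#'                 digits = 0)  # 47
#' @export
percentRhythmic <- function(calls, label = c("Circadian", "Synchronized"),
                            digits = NA) {
  if (!length(calls)) stop("empty call list")
  labs <- if (is.character(calls)) calls
          else vapply(calls, rhythmLabel, character(1))
  pct <- 100 * sum(labs %in% label) / length(labs)
  if (!is.na(digits)) round(pct, digits) else pct
}
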