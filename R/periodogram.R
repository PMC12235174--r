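#' Lomb-Scargle periodogram of a luminescence trace
#'
#' Computes the classical variance-normalized Scargle periodogram with the
#' per-frequency time offset \eqn{\tau} that makes the estimate invariant
#' under time translation:
#'
#' \deqn{P(\omega) = \frac{1}{2 s^2} \left[
#'   \frac{\left(\sum_j y_j' \cos\omega(t_j-\tau)\right)^2}
#'        {\sum_j \cos^2\omega(t_j-\tau)} +
#'   \frac{\left(\sum_j y_j' \sin\omega(t_j-\tau)\right)^2}
#'        {\sum_j \sin^2\omega(t_j-\tau)} \right]}
#'
#' with \eqn{y' = y - \bar y}, \eqn{s^2} the sample variance of `y`, and
#' \eqn{\tan 2\omega\tau = \sum \sin 2\omega t_j / \sum \cos 2\omega t_j}.
#' Centering and variance normalization make the power invariant under
#' affine transforms `a*y + b` of the values. The frequency grid runs from
#' `1/periodMax` to `1/periodMin` in steps of
#' `1 / (oversampling * span)` (span = trace duration), inclusive of both
#' period bounds.
#'
#' @param trace A [TraceSeries] (at least 8 samples; duration at least
#'   `periodMin`).
#' @param spec A [PeriodogramSpec] (default: 18-37 h window, oversampling
#'   30).
#' @param frequencies Optional explicit frequency grid (cycles/hour)
#'   overriding the grid derived from `spec`.
#' @return A [Periodogram]; `peakPeriod(x)` gives the period of maximal
#'   power.
#' @examples
#' t <- seq(0, 119.5, by = 0.5)
#' tr <- TraceSeries("w", times = t, values = cos(2 * pi * t / 24))
#' peakPeriod(lombScargle(tr))  # ~24
#' @export
lombScargle <- function(trace, spec = PeriodogramSpec(), frequencies = NULL) {
  validObject(spec)
  t <- traceTimes(trace)
  y <- traceValues(trace)
  n <- length(y)
  if (n < 8) stop("need at least 8 samples for a periodogram")
  span <- max(t) - min(t)
  if (span < spec@periodMin)
    stop("trace duration (", span, " h) is shorter than periodMin")
  s2 <- var(y)
  if (!is.finite(s2) || s2 <= 0)
    stop("constant trace: periodogram undefined for well ", wellId(trace))

  if (is.null(frequencies)) {
    df <- 1 / (spec@oversampling * span)
    f <- seq(1 / spec@periodMax, 1 / spec@periodMin, by = df)
    if (f[length(f)] < 1 / spec@periodMin - 1e-12)
      f <- c(f, 1 / spec@periodMin)
  } else f <- frequencies

  yc <- y - mean(y)
  pw <- vapply(f, function(fi) {
    w <- 2 * pi * fi
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1))

  periods <- 1 / f
  new("Periodogram", periods = periods, power = pmax(pw, 0),
      peakPeriod = periods[which.max(pw)], spec = spec)
}
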