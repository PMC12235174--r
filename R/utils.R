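#' @importFrom stats rnorm runif sd var setNames
NULL

# Evaluate expr with a locally seeded Mersenne-Twister RNG, restoring the
# caller's RNG state afterwards so generators never perturb user code.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(expr)
}

# Deterministic per-well seed derived from a plate seed; kept below 2^31-1.
wellSeed <- function(plateSeed, wellIndex) {
  (as.numeric(plateSeed) * 10007 + as.numeric(wellIndex) * 7919) %% 2147483647
}

# Centered moving average over a *time* window (hours), tolerant of gaps:
# each output is the mean of all samples within window/2 of that timestamp.
# Edges average over the available part of the window. O(n) via cumsum.
movingAverage <- function(times, values, window) {
  stopifnot(length(times) == length(values))
  if (window <= 0) stop("'window' must be positive")
  n <- length(values)
  eps <- 1e-9
  lo <- findInterval(times - window / 2 - eps, times) + 1L
  hi <- findInterval(times + window / 2 + eps, times)
  cs <- cumsum(c(0, values))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

hoursMod24 <- function(h) ((h %% 24) + 24) %% 24
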