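#' @importFrom stats pnorm
NULL

#' Kendall's tau-b rank correlation
#'
#' Tau-b with the standard tie corrections:
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` where `C`/`D` are the
#' concordant/discordant pair counts, `n0 = n(n-1)/2`, and `n1`, `n2` are
#' the tied-pair counts in each vector. The raw Kendall score
#' `S = C - D` is attached as `attr(tau, "S")`.
#'
#' @param x,y Numeric vectors of equal length >= 2 (values or ranks; only
#'   orderings matter).
#' @return tau-b in `[-1, 1]` with attribute `"S"`.
#' @examples
#' kendallTau(1:3, c(3, 2, 1))  # -1
#' @export
kendallTau <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2) stop("x and y must have equal length >= 2")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  S <- sum(dx[up] * dy[up])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) stop("all-tied input: Kendall tau undefined")
  structure(S / den, S = S)
}

# polynomial helpers for the exact null (coefficient vectors, q^0 first)
.polyMulOneMinusQk <- function(p, k) {
  out <- c(p, numeric(k))
  out[(k + 1):length(out)] <- out[(k + 1):length(out)] - p
  out
}
.polyDivOneMinusQk <- function(p, k) {
  # exact synthetic division by (1 - q^k): running sums with stride k
  out <- p
  if (length(out) > k)
    for (j in (k + 1):length(out)) out[j] <- out[j] + out[j - k]
  # trailing zeros from an exact division are dropped
  nz <- which(abs(out) > 1e-9)
  out[seq_len(if (length(nz)) max(nz) else 1)]
}

# Gaussian binomial [m+n choose n]_q: generating function of the number of
# inversions between two blocks of sizes m and n.
.qbinomPoly <- function(m, n) {
  p <- 1
  if (n == 0 || m == 0) return(p)
  for (i in seq_len(n)) {
    p <- .polyMulOneMinusQk(p, m + i)
    p <- .polyDivOneMinusQk(p, i)
  }
  p
}

#' Exact null distribution of the Kendall score S
#'
#' Distribution of `S = C - D` between a fixed reference vector with the
#' given tie-group sizes and a uniformly random untied permutation of the
#' data. The number of discordant cross-group pairs is generated by the
#' Gaussian (q-)multinomial coefficient, built by inserting one tie group
#' at a time; `S = M - 2D` with `M` the number of cross-group pairs. For an
#' untied reference (`tieGroups = rep(1, n)`) this reduces to the classic
#' null of Kendall's tau. The distribution is symmetric about 0 and sums
#' to 1.
#'
#' @param tieGroups Integer sizes of the reference vector's tie groups
#'   (a single integer `n` is shorthand for an untied reference of length
#'   `n`).
#' @return data.frame with columns `s` (achievable scores, descending by
#'   absolute step of 2) and `prob`.
#' @examples
#' null3 <- kendallSNull(3)     # untied reference, n = 3
#' sum(null3$prob)              # 1
#' @export
kendallSNull <- function(tieGroups) {
  if (length(tieGroups) == 1 && tieGroups > 1)
    tieGroups <- rep(1L, tieGroups)
  tieGroups <- as.integer(tieGroups)
  if (any(tieGroups < 1)) stop("tie-group sizes must be positive")
  p <- 1
  m <- 0L
  for (g in tieGroups) {
    p <- if (m == 0) .qbinomPoly(0, g) else {
      q <- .qbinomPoly(m, g)
      # polynomial product (convolution)
      out <- numeric(length(p) + length(q) - 1)
      for (j in seq_along(q))
        if (q[j] != 0)
          out[j:(j + length(p) - 1)] <- out[j:(j + length(p) - 1)] + q[j] * p
      out
    }
    m <- m + g
  }
  total <- sum(p)
  M <- sum(outer(tieGroups, tieGroups)[upper.tri(diag(length(tieGroups)))])
  data.frame(s = M - 2 * (seq_along(p) - 1), prob = p / total)
}

# Two-sided p for an observed S given a null table: P(|S'| >= |S|).
.kendallExactP <- function(S, null) sum(null$prob[abs(null$s) >= abs(S) - 1e-9])

# Normal approximation with tie correction and continuity correction
# (variance formula as in the classical tau-b test).
.kendallNormalP <- function(x, y, S) {
  n <- length(x)
  tx <- as.numeric(table(x)); ty <- as.numeric(table(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  v <- (v0 - vt - vu) / 18 + v1 + v2
  if (v <= 0) return(1)
  z <- (abs(S) - 1) / sqrt(v)  # continuity correction
  min(1, 2 * pnorm(z, lower.tail = FALSE))
}

#' JTK_CYCLE nonparametric rhythm detection
#'
#' Tests an expression time course for rhythmicity by rank-correlating the
#' data against cosine reference waveforms over a grid of candidate
#' periods and phase lags (the JTK_CYCLE scheme). For each
#' `(period, lag)` pair the reference is
#' `cos(2*pi*(t - lag)/period)` evaluated at the sampling times; Kendall's
#' S between data and reference is computed and its two-sided p-value is
#' taken from the exact null distribution of S — conditioned on the
#' reference's tie pattern (repeated template values across cycles), see
#' [kendallSNull()] — for `n <= 50`, and from the tie-corrected normal
#' approximation with continuity correction for longer series. The exact
#' null assumes continuously distributed data; ties in the data make the
#' lookup conservative. P-values are Bonferroni-adjusted over the whole
#' period x lag family and capped at 1; the reported result is the pair
#' with the minimal adjusted p.
#'
#' A constant series carries no rank information: the result has
#' `pAdj = 1` and `tau = NA`.
#'
#' @param series An ExpressionSeries data.frame from [ddct()] (columns
#'   `timepoint_h` and `rel`), or a numeric vector with `timepoints`
#'   supplied.
#' @param candidatePeriods Candidate periods in hours (default
#'   `c(20, 24, 28)`, the usual circadian window at 4 h sampling).
#' @param timepoints Sampling times in hours (taken from `series` when it
#'   is a data.frame).
#' @param sampling Lag grid step in hours; default the sampling interval.
#' @return A [JtkResult]; slot `table` holds tau and adjusted p for every
#'   (period, lag) pair.
#' @examples
#' tp <- seq(1, 69, by = 4)
#' rhythmic <- data.frame(timepoint_h = tp,
#'                        rel = 2^cos(2 * pi * (tp - 5) / 24))
#' jtkCycle(rhythmic)
#' @export
jtkCycle <- function(series, candidatePeriods = c(20, 24, 28),
                     timepoints = NULL, sampling = NULL) {
  if (is.data.frame(series)) {
    timepoints <- series$timepoint_h
    y <- series$rel
  } else y <- as.numeric(series)
  if (is.null(timepoints) || length(timepoints) != length(y))
    stop("timepoints must accompany the series values")
  n <- length(y)
  if (n < 4) stop("need at least 4 timepoints")
  if (is.null(sampling)) sampling <- min(diff(sort(timepoints)))

  if (diff(range(y)) == 0) {
    return(new("JtkResult", bestPeriod = NA_real_, bestLag = NA_real_,
               tau = NA_real_, pAdj = 1, method = "degenerate",
               table = data.frame()))
  }

  rows <- list()
  nullCache <- list()
  for (per in candidatePeriods) {
    lags <- seq(0, per - sampling, by = sampling)
    for (lag in lags) {
      ref <- round(cos(2 * pi * (timepoints - lag) / per), 9)
      tau <- kendallTau(ref, y)
      S <- attr(tau, "S")
      if (n <= 50) {
        groups <- sort(as.integer(table(ref)))
        key <- paste(groups, collapse = ",")
        if (is.null(nullCache[[key]]))
          nullCache[[key]] <- kendallSNull(groups)
        p <- .kendallExactP(S, nullCache[[key]])
        method <- "exact"
      } else {
        p <- .kendallNormalP(ref, y, S)
        method <- "normal"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        period = per, lag = lag, tau = as.numeric(tau), p = p,
        method = method)
    }
  }
  tab <- do.call(rbind, rows)
  m <- nrow(tab)
  tab$pAdj <- pmin(1, tab$p * m)
  best <- order(tab$pAdj, -abs(tab$tau), tab$period, tab$lag)[1]
  new("JtkResult", bestPeriod = tab$period[best], bestLag = tab$lag[best],
      tau = tab$tau[best], pAdj = tab$pAdj[best],
      method = tab$method[best], table = tab)
}
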