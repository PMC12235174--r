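#' Preprocessing parameters
#'
#' Parameters of the trace preprocessing chain, applied in the order
#' background subtraction, transient trimming, detrending, smoothing,
#' normalization (see [runPreprocess()]).
#'
#' @param background Plate blank level in raw counts (default 0).
#' @param trimHours Hours removed from the start of the recording to
#'   discard the luciferase-accumulation transient; must lie in
#'   `[12, 24]` (default 24).
#' @param detrendWindow Centered moving-average window for detrending,
#'   hours (default 24: removes the baseline while leaving a 24 h
#'   oscillation intact, since the mean of a cosine over one full period
#'   is zero).
#' @param smoothWindow Moving-average smoothing window, hours (default 2).
#' @param normWindow Window over which the "initial maximum" used for
#'   normalization is taken, hours after trimming (default 24).
#' @return A `PreprocessParams` object.
#' @export PreprocessParams
#' @exportClass PreprocessParams
#' @aliases PreprocessParams-class
PreprocessParams <- setClass("PreprocessParams",
  representation(background = "numeric", trimHours = "numeric",
                 detrendWindow = "numeric", smoothWindow = "numeric",
                 normWindow = "numeric"),
  prototype(background = 0, trimHours = 24, detrendWindow = 24,
            smoothWindow = 2, normWindow = 24),
  validity = function(object) {
    msg <- NULL
    if (object@trimHours < 12 || object@trimHours > 24)
      msg <- c(msg, "trimHours must lie in [12, 24]")
    if (object@detrendWindow <= 0 || object@smoothWindow <= 0 ||
        object@normWindow <= 0)
      msg <- c(msg, "windows must be positive")
    if (object@background < 0) msg <- c(msg, "background must be >= 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' Subtract the plate background level
#'
#' Subtracts a scalar background (luminometer dark counts) from every
#' sample. Negative results are permitted; normalization downstream handles
#' them.
#'
#' @param trace A [TraceSeries].
#' @param background Non-negative counts.
#' @return A [TraceSeries] with `values - background`.
#' @export
subtractBackground <- function(trace, background) {
  if (background < 0) stop("background must be >= 0")
  setValues(trace, traceValues(trace) - background)
}

#' Remove the initial luciferase-accumulation transient
#'
#' Drops all samples earlier than `trimHours` from the start of the
#' recording. Times are kept on the absolute hours-from-start axis so the
#' mapping to zeitgeber time survives trimming.
#'
#' @param trace A [TraceSeries].
#' @param trimHours Hours to remove from the start (the study removed
#'   12-24 h).
#' @return The trimmed [TraceSeries].
#' @details Errors if fewer than two full days of data would remain, since
#'   circadian period estimation then becomes meaningless.
#' @export
trimTransient <- function(trace, trimHours) {
  tt <- traceTimes(trace)
  if (!length(tt)) stop("empty trace")
  if (max(tt) - trimHours < 48)
    stop("trimming ", trimHours,
         " h would leave < 2 full days of data in well ", wellId(trace))
  subsetTrace(trace, t0 = trimHours)
}

#' Detrend a trace by a centered moving average
#'
#' Subtracts the centered moving average over `window` hours from each
#' sample. Windows are defined on the time axis (all available samples
#' within `window/2` hours), so gaps in the recording are tolerated; at the
#' edges the average runs over the available part of the window.
#'
#' @param trace A [TraceSeries].
#' @param window Window width in hours; must be at least twice the sampling
#'   interval and no longer than the trace.
#' @return The detrended [TraceSeries].
#' @export
detrendTrace <- function(trace, window = 24) {
  tt <- traceTimes(trace)
  if (length(tt) < 2) stop("trace too short to detrend")
  dt <- min(diff(tt))
  if (window < 2 * dt)
    stop("detrend window must be at least twice the sampling interval")
  if (window > max(tt) - min(tt)) stop("window longer than trace")
  y <- traceValues(trace)
  setValues(trace, y - movingAverage(tt, y, window))
}

#' Smooth a trace by a centered moving average
#'
#' @param trace A [TraceSeries].
#' @param window Window width in hours (>= sampling interval, <= trace
#'   duration).
#' @return The smoothed [TraceSeries]; same length as the input.
#' @export
smoothTrace <- function(trace, window = 2) {
  tt <- traceTimes(trace)
  if (length(tt) < 2) stop("trace too short to smooth")
  dt <- min(diff(tt))
  if (window < dt)
    stop("smoothing window must be at least the sampling interval")
  if (window > max(tt) - min(tt)) stop("window longer than trace")
  setValues(trace, movingAverage(tt, traceValues(trace), window))
}

#' Normalize a trace to its initial maximum
#'
#' Divides all values by the maximum over the first `normWindow` hours of
#' the (trimmed) trace, so that the maximum over that window becomes exactly
#' 1. A window whose maximum is not positive signals a dead well and raises
#' an error.
#'
#' @param trace A [TraceSeries].
#' @param normWindow Hours after the first retained sample over which the
#'   initial maximum is taken (default 24).
#' @return The normalized [TraceSeries].
#' @export
normalizeInitialMax <- function(trace, normWindow = 24) {
  tt <- traceTimes(trace)
  if (!length(tt)) stop("empty trace")
  y <- traceValues(trace)
  win <- tt < tt[1] + normWindow
  m <- max(y[win])
  if (!is.finite(m) || m <= 0)
    stop("dead well ", wellId(trace),
         ": no positive signal in the normalization window")
  setValues(trace, y / m)
}

#' Run the full preprocessing chain on one trace
#'
#' Applies, in order: background subtraction, transient trimming,
#' moving-average detrending, moving-average smoothing, and normalization
#' to the initial maximum. Errors from any stage (e.g. a dead well at the
#' normalization step) propagate.
#'
#' @param trace A [TraceSeries].
#' @param params A [PreprocessParams].
#' @return The preprocessed [TraceSeries].
#' @examples
#' tr <- generateTrace(GenotypeSpec(), ProtocolSchedule(), seed = 7)
#' pp <- runPreprocess(tr, PreprocessParams(background = 50))
#' max(traceValues(pp)[traceTimes(pp) < traceTimes(pp)[1] + 24])  # exactly 1
#' @export
runPreprocess <- function(trace, params = PreprocessParams()) {
  validObject(params)
  trace |>
    subtractBackground(params@background) |>
    trimTransient(params@trimHours) |>
    detrendTrace(params@detrendWindow) |>
    smoothTrace(params@smoothWindow) |>
    normalizeInitialMax(params@normWindow)
}
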