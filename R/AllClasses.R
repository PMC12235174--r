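#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# Recording protocol and genotype parameter objects
# ---------------------------------------------------------------------------

#' Plate recording protocol
#'
#' Describes the luminometer recording schedule: sampling cadence, number of
#' days under the entraining dual light/temperature cycle, number of days of
#' free run under constant conditions, and the zeitgeber time at which the
#' recording starts. The zeitgeber convention is ZT0 = lights-on / cold-phase
#' onset; recordings conventionally start at ZT12 (lights-off / warm phase).
#'
#' @param samplingInterval Hours between luminescence readings (default 0.5,
#'   i.e. one 10-s integration every 30 min).
#' @param nDaysEntrained Days recorded under the light-dark / cold-warm
#'   (LD/CW) cycle (default 3).
#' @param nDaysFreerun Days recorded under constant dark / constant warm
#'   (DD/WW) free-running conditions (default 3).
#' @param recordStartZt ZT of the first sample, hours (default 12).
#' @param photoperiod Hours of light per 24 h cycle (default 12).
#' @param tempCold,tempWarm Cold- and warm-phase temperatures in deg C
#'   (defaults 15.5 and 17.0; their difference is the 1.5 deg C delta).
#' @return A `ProtocolSchedule` object.
#' @examples
#' proto <- ProtocolSchedule()
#' totalDuration(proto)  # 144 h
#' releaseTime(proto)    # 72 h: transition from entrained to free run
#' @export ProtocolSchedule
#' @exportClass ProtocolSchedule
#' @aliases ProtocolSchedule-class
ProtocolSchedule <- setClass("ProtocolSchedule",
  representation(
    samplingInterval = "numeric",
    nDaysEntrained   = "numeric",
    nDaysFreerun     = "numeric",
    recordStartZt    = "numeric",
    photoperiod      = "numeric",
    tempCold         = "numeric",
    tempWarm         = "numeric"
  ),
  prototype(
    samplingInterval = 0.5, nDaysEntrained = 3, nDaysFreerun = 3,
    recordStartZt = 12, photoperiod = 12, tempCold = 15.5, tempWarm = 17.0
  ),
  validity = function(object) {
    msg <- NULL
    if (object@samplingInterval <= 0)
      msg <- c(msg, "samplingInterval must be > 0")
    if (object@nDaysEntrained < 0 || object@nDaysFreerun < 0)
      msg <- c(msg, "day counts must be >= 0")
    if (object@nDaysEntrained + object@nDaysFreerun <= 0)
      msg <- c(msg, "total recording duration must be positive")
    if (object@tempWarm <= object@tempCold)
      msg <- c(msg, "tempWarm must exceed tempCold")
    if (object@photoperiod <= 0 || object@photoperiod >= 24)
      msg <- c(msg, "photoperiod must lie in (0, 24)")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn ProtocolSchedule Total recording duration in hours,
#'   `24 * (nDaysEntrained + nDaysFreerun)`.
#' @param protocol A `ProtocolSchedule`.
#' @export
totalDuration <- function(protocol) {
  24 * (protocol@nDaysEntrained + protocol@nDaysFreerun)
}

#' @describeIn ProtocolSchedule Hours from recording start at which the plate
#'   is released into free-running conditions.
#' @export
releaseTime <- function(protocol) 24 * protocol@nDaysEntrained

#' Genotype / strain simulation parameters
#'
#' Ground-truth rhythm parameters for one strain on a synthetic plate: the
#' period expressed under entrainment, the endogenous free-running period
#' tau, the entrained acrophase (peak time in ZT hours), oscillation
#' amplitude and MESOR on the raw-count scale, signal damping, the duration
#' of the initial luciferase-accumulation transient, additive noise, and the
#' fraction of wells that are rhythmic at all.
#'
#' Defaults emulate a control-like reporter strain: ~24 h entrained period,
#' free-running tau 24.2 h, night/warm-phase peak at ZT18, and roughly half
#' of wells rhythmic (arrhythmic wells receive amplitude 0 but identical
#' baseline trend and noise).
#'
#' @param label Strain label.
#' @param periodEntrained Period under the entraining cycle, hours
#'   (default 24).
#' @param periodFreerun Endogenous free-running period tau, hours
#'   (default 24.2; a long-period mutant might use 27.1).
#' @param acrophaseZt Entrained peak time, ZT hours in `[0, 24)`
#'   (default 18, mid night/warm phase).
#' @param amplitude Oscillation amplitude, raw luminescence counts
#'   (default 400).
#' @param mesor Baseline level, raw counts (default 1000).
#' @param dampingRate Exponential decay rate of the signal envelope, per
#'   hour (default 0.01).
#' @param transientHours Duration of the initial luciferase-accumulation
#'   ramp, hours (default 24; the preprocessing default trims exactly this).
#' @param noiseSd SD of additive Gaussian noise, raw counts (default 150).
#' @param fractionRhythmic Probability that a well is rhythmic (default 0.5).
#' @param phaseOffsetAtRelease Acrophase jump applied at release into free
#'   run, hours (default 0: phase-continuous transition).
#' @return A `GenotypeSpec` object.
#' @examples
#' ctrl <- GenotypeSpec("control", periodFreerun = 24.2)
#' mut  <- GenotypeSpec("mutant",  periodFreerun = 27.1)
#' @export GenotypeSpec
#' @exportClass GenotypeSpec
#' @aliases GenotypeSpec-class
GenotypeSpec <- setClass("GenotypeSpec",
  representation(
    label = "character",
    periodEntrained = "numeric",
    periodFreerun = "numeric",
    acrophaseZt = "numeric",
    amplitude = "numeric",
    mesor = "numeric",
    dampingRate = "numeric",
    transientHours = "numeric",
    noiseSd = "numeric",
    fractionRhythmic = "numeric",
    phaseOffsetAtRelease = "numeric"
  ),
  prototype(
    label = "control", periodEntrained = 24, periodFreerun = 24.2,
    acrophaseZt = 18, amplitude = 400, mesor = 1000, dampingRate = 0.01,
    transientHours = 24, noiseSd = 150, fractionRhythmic = 0.5,
    phaseOffsetAtRelease = 0
  ),
  validity = function(object) {
    msg <- NULL
    if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@dampingRate < 0) msg <- c(msg, "dampingRate must be >= 0")
    if (object@transientHours < 0) msg <- c(msg, "transientHours must be >= 0")
    if (object@fractionRhythmic < 0 || object@fractionRhythmic > 1)
      msg <- c(msg, "fractionRhythmic must lie in [0, 1]")
    if (object@periodEntrained <= 0 || object@periodFreerun <= 0)
      msg <- c(msg, "periods must be positive")
    if (is.null(msg)) TRUE else msg
  }
)

# convenience for the common constructor style GenotypeSpec("mutant", ...)
setMethod("initialize", "GenotypeSpec", function(.Object, label, ...) {
  if (!missing(label)) .Object@label <- label
  callNextMethod(.Object, ...)
})

# ---------------------------------------------------------------------------
# TraceSeries: one well's luminescence time course
# ---------------------------------------------------------------------------

#' Single-well luminescence time course
#'
#' One well's luminescence trace: strictly increasing times in hours from
#' recording start, one value per time, a per-sample segment label
#' (`"entrained"` or `"freerun"`), and the ZT of the recording start so that
#' internal times can be mapped to zeitgeber / circadian time.
#'
#' @param wellId Well identifier.
#' @param times Numeric, hours from recording start, strictly increasing.
#' @param values Numeric luminescence values, same length as `times`.
#' @param strain Strain label (default `"NA"`).
#' @param segment Character per-sample labels in
#'   `c("entrained", "freerun")`; recycled if length 1. Default: all
#'   `"entrained"`.
#' @param ztOffset ZT of the first recorded hour (default 12).
#' @return A `TraceSeries` object.
#' @examples
#' tr <- TraceSeries("A1", times = seq(0, 47.5, by = 0.5),
#'                   values = 5 + 2 * cos(2 * pi * seq(0, 47.5, by = 0.5) / 24))
#' length(tr)
#' @export TraceSeries
#' @exportClass TraceSeries
#' @aliases TraceSeries-class
TraceSeries <- setClass("TraceSeries",
  representation(
    wellId = "character",
    strain = "character",
    times = "numeric",
    values = "numeric",
    segment = "character",
    ztOffset = "numeric"
  ),
  prototype(wellId = "well", strain = "NA", ztOffset = 12),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) != length(object@values))
      msg <- c(msg, "times and values must have equal length")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(object@segment) != length(object@times))
      msg <- c(msg, "segment must have one label per sample")
    if (length(object@segment) &&
        !all(object@segment %in% c("entrained", "freerun")))
      msg <- c(msg, "segment labels must be 'entrained' or 'freerun'")
    if (length(object@segment) > 1) {
      fr <- object@segment == "freerun"
      if (any(fr) && any(!fr) && min(which(fr)) < max(which(!fr)))
        msg <- c(msg, "entrained samples must precede freerun samples")
    }
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("initialize", "TraceSeries",
  function(.Object, wellId = "well", times = numeric(), values = numeric(),
           strain = "NA", segment = NULL, ztOffset = 12, ...) {
    if (is.null(segment)) segment <- rep("entrained", length(times))
    if (length(segment) == 1L) segment <- rep(segment, length(times))
    callNextMethod(.Object, wellId = wellId, strain = strain,
                   times = as.numeric(times), values = as.numeric(values),
                   segment = segment, ztOffset = ztOffset, ...)
  })

#' @describeIn TraceSeries Number of samples in the trace.
#' @param x A `TraceSeries`.
#' @export
setMethod("length", "TraceSeries", function(x) length(x@times))

#' Accessors for TraceSeries
#'
#' `traceTimes()` and `traceValues()` return the sampling times (hours from
#' recording start) and luminescence values; `wellId()`, `strain()`,
#' `segmentLabels()` and `ztOffset()` return the corresponding metadata.
#'
#' @param x A [TraceSeries] object.
#' @return Numeric or character vectors / scalars as appropriate.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
traceTimes <- function(x) x@times

#' @rdname trace-accessors
#' @export
traceValues <- function(x) x@values

#' @rdname trace-accessors
#' @export
wellId <- function(x) x@wellId

#' @rdname trace-accessors
#' @export
strain <- function(x) x@strain

#' @rdname trace-accessors
#' @export
segmentLabels <- function(x) x@segment

#' @rdname trace-accessors
#' @export
ztOffset <- function(x) x@ztOffset

setMethod("show", "TraceSeries", function(object) {
  cat("TraceSeries '", object@wellId, "' (strain ", object@strain, "): ",
      length(object@times), " samples", sep = "")
  if (length(object@times))
    cat(", t = [", min(object@times), ", ", max(object@times), "] h", sep = "")
  cat(", ZT offset ", object@ztOffset, "\n", sep = "")
})

# replace values, keeping everything else (internal helper used throughout)
setValues <- function(x, values) {
  x@values <- as.numeric(values)
  validObject(x)
  x
}

# restrict a trace to times in [t0, t1)
subsetTrace <- function(x, t0 = -Inf, t1 = Inf) {
  keep <- x@times >= t0 & x@times < t1
  initialize(x, wellId = x@wellId, strain = x@strain,
             times = x@times[keep], values = x@values[keep],
             segment = x@segment[keep], ztOffset = x@ztOffset)
}

# ---------------------------------------------------------------------------
# PlateRecording: a whole plate as a SummarizedExperiment
# ---------------------------------------------------------------------------

#' Plate of luminescence traces
#'
#' A `PlateRecording` is a [SummarizedExperiment::SummarizedExperiment]
#' holding one assay `"lum"` (timepoints x wells), with `rowData` columns
#' `time_h` (hours from recording start) and `segment`
#' (`"entrained"`/`"freerun"`), `colData` columns `well` and `strain`
#' (plus ground-truth columns `truthRhythmic`, `truthPeriod`,
#' `truthAcrophase` for synthetic plates), and metadata entries `ztOffset`,
#' `protocol` and `seed`.
#'
#' @param lum Numeric matrix, timepoints in rows, wells in columns.
#' @param times Hours from recording start, one per row.
#' @param wells,strains Character vectors, one per column.
#' @param segment Per-row segment labels (default from `protocol` if given,
#'   else all `"entrained"`).
#' @param ztOffset ZT of recording start (default 12).
#' @param protocol Optional [ProtocolSchedule].
#' @param truth Optional data.frame of per-well ground truth with columns
#'   `truthRhythmic`, `truthPeriod`, `truthAcrophase`.
#' @param seed Optional integer seed recorded for provenance.
#' @return A `PlateRecording` object.
#' @export PlateRecording
#' @exportClass PlateRecording
#' @aliases PlateRecording-class
PlateRecording <- setClass("PlateRecording", contains = "SummarizedExperiment")

#' @describeIn PlateRecording Constructor.
#' @export
makePlateRecording <- function(lum, times, wells, strains,
                               segment = NULL, ztOffset = 12,
                               protocol = NULL, truth = NULL, seed = NA) {
  lum <- as.matrix(lum)
  if (nrow(lum) != length(times))
    stop("'times' must have one entry per row of 'lum'")
  if (ncol(lum) != length(wells))
    stop("'wells' must have one entry per column of 'lum'")
  if (length(strains) == 1L) strains <- rep(strains, length(wells))
  if (anyDuplicated(wells)) stop("duplicated well ids")
  if (is.null(segment)) {
    segment <- if (!is.null(protocol))
      ifelse(times < releaseTime(protocol), "entrained", "freerun")
    else rep("entrained", length(times))
  }
  rd <- S4Vectors::DataFrame(time_h = as.numeric(times), segment = segment)
  cd <- S4Vectors::DataFrame(well = wells, strain = strains,
                             row.names = wells)
  if (!is.null(truth)) {
    for (cn in colnames(truth)) cd[[cn]] <- truth[[cn]]
  }
  colnames(lum) <- wells
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lum = lum), rowData = rd, colData = cd,
    metadata = list(ztOffset = ztOffset, protocol = protocol, seed = seed))
  new("PlateRecording", se)
}

setValidity("PlateRecording", function(object) {
  msg <- NULL
  if (!"lum" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'lum' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("time_h", "segment") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'time_h' and 'segment'")
  else if (nrow(rd) > 1 && any(diff(rd$time_h) <= 0))
    msg <- c(msg, "time_h must be strictly increasing")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("well", "strain") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'well' and 'strain'")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn PlateRecording Extract one well as a [TraceSeries]
#'   (samples with missing luminescence are dropped).
#' @param plate A `PlateRecording`.
#' @param well Well id or column index.
#' @export
getTrace <- function(plate, well) {
  cd <- SummarizedExperiment::colData(plate)
  j <- if (is.character(well)) match(well, cd$well) else as.integer(well)
  if (is.na(j) || j < 1 || j > ncol(plate)) stop("unknown well: ", well)
  rd <- SummarizedExperiment::rowData(plate)
  y <- SummarizedExperiment::assay(plate, "lum")[, j]
  keep <- !is.na(y)
  TraceSeries(wellId = cd$well[j], strain = cd$strain[j],
              times = rd$time_h[keep], values = y[keep],
              segment = rd$segment[keep],
              ztOffset = S4Vectors::metadata(plate)$ztOffset)
}

#' @describeIn PlateRecording Per-well ground truth (synthetic plates), as a
#'   data.frame, or NULL when absent.
#' @export
plateTruth <- function(plate) {
  cd <- as.data.frame(SummarizedExperiment::colData(plate))
  tc <- intersect(c("truthRhythmic", "truthPeriod", "truthAcrophase"),
                  colnames(cd))
  if (!length(tc)) return(NULL)
  cbind(cd[, c("well", "strain"), drop = FALSE], cd[, tc, drop = FALSE])
}

setMethod("show", "PlateRecording", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("PlateRecording: ", ncol(object), " wells x ", nrow(object),
      " timepoints", sep = "")
  if (nrow(object))
    cat(" (t = [", min(rd$time_h), ", ", max(rd$time_h), "] h)", sep = "")
  cat("\nstrains: ",
      paste(unique(SummarizedExperiment::colData(object)$strain),
            collapse = ", "), "\n", sep = "")
  if (!is.null(plateTruth(object))) cat("ground truth: present\n")
})

# ---------------------------------------------------------------------------
# Analysis result classes
# ---------------------------------------------------------------------------

#' Periodogram search specification
#'
#' Period search window and oversampling for the Lomb-Scargle periodogram.
#' The frequency grid runs from `1/periodMax` to `1/periodMin` in steps of
#' `1 / (oversampling * span)` where `span` is the trace duration; both
#' period bounds are included.
#'
#' @param periodMin,periodMax Period search bounds in hours (defaults 18
#'   and 37).
#' @param oversampling Oversampling factor for the frequency grid
#'   (default 30).
#' @return A `PeriodogramSpec` object.
#' @export PeriodogramSpec
#' @exportClass PeriodogramSpec
#' @aliases PeriodogramSpec-class
PeriodogramSpec <- setClass("PeriodogramSpec",
  representation(periodMin = "numeric", periodMax = "numeric",
                 oversampling = "numeric"),
  prototype(periodMin = 18, periodMax = 37, oversampling = 30),
  validity = function(object) {
    msg <- NULL
    if (object@periodMin <= 0 || object@periodMax <= object@periodMin)
      msg <- c(msg, "need 0 < periodMin < periodMax")
    if (object@oversampling < 1) msg <- c(msg, "oversampling must be >= 1")
    if (is.null(msg)) TRUE else msg
  }
)

#' Lomb-Scargle periodogram result
#'
#' @slot periods Period grid in hours.
#' @slot power Normalized Lomb-Scargle power at each period.
#' @slot peakPeriod Period of maximal power, hours.
#' @slot spec The [PeriodogramSpec] used.
#' @exportClass Periodogram
#' @aliases Periodogram-class
setClass("Periodogram",
  representation(periods = "numeric", power = "numeric",
                 peakPeriod = "numeric", spec = "PeriodogramSpec"),
  validity = function(object) {
    msg <- NULL
    if (length(object@periods) != length(object@power))
      msg <- c(msg, "periods and power must have equal length")
    if (any(object@power < -1e-12)) msg <- c(msg, "power must be >= 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn Periodogram Period of maximal power (hours).
#' @param x A `Periodogram`.
#' @export
peakPeriod <- function(x) x@peakPeriod

setMethod("show", "Periodogram", function(object) {
  cat("Lomb-Scargle periodogram: ", length(object@periods),
      " periods in [", min(object@periods), ", ", max(object@periods),
      "] h; peak at ", round(object@peakPeriod, 3), " h (power ",
      round(max(object@power), 2), ")\n", sep = "")
})

#' Cosinor fit result
#'
#' Parameters of the least-squares cosine fit
#' `y = M + A * cos(2*pi*(t - phi_abs)/tau)`: MESOR `M`, amplitude `A >= 0`,
#' period `tau`, and the acrophase both in internal hours-from-start
#' (`acrophaseAbs`, modulo tau) and mapped to ZT/CT hours modulo 24
#' (`acrophase`).
#'
#' @slot mesor,amplitude,period,acrophase,acrophaseAbs,rSquared,sse Numeric.
#' @slot n Integer number of samples fitted.
#' @slot freePeriod Logical: was tau optimized?
#' @exportClass CosinorFit
#' @aliases CosinorFit-class
setClass("CosinorFit",
  representation(mesor = "numeric", amplitude = "numeric", period = "numeric",
                 acrophase = "numeric", acrophaseAbs = "numeric",
                 rSquared = "numeric", sse = "numeric", n = "integer",
                 freePeriod = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
    if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
      msg <- c(msg, "rSquared must lie in [0, 1]")
    if (object@acrophase < 0 || object@acrophase >= 24)
      msg <- c(msg, "acrophase must lie in [0, 24)")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn CosinorFit Coefficient of determination of the fit.
#' @param x A `CosinorFit`.
#' @export
rSquared <- function(x) x@rSquared

#' @describeIn CosinorFit Fitted period tau in hours.
#' @export
fittedPeriod <- function(x) x@period

#' @describeIn CosinorFit Acrophase in ZT/CT hours, modulo 24.
#' @export
acrophase <- function(x) x@acrophase

#' @describeIn CosinorFit Fitted amplitude (>= 0).
#' @export
amplitude <- function(x) x@amplitude

#' @describeIn CosinorFit Fitted MESOR (rhythm-adjusted mean).
#' @export
mesor <- function(x) x@mesor

setMethod("show", "CosinorFit", function(object) {
  cat(sprintf(
    "CosinorFit: M = %.4g, A = %.4g, tau = %.3f h, acrophase = ZT %.2f, R2 = %.3f (n = %d, %s tau)\n",
    object@mesor, object@amplitude, object@period, object@acrophase,
    object@rSquared, object@n, if (object@freePeriod) "free" else "fixed"))
})

#' Rhythmicity call for one trace
#'
#' Classification of one fitted trace: `"Synchronized"` (entrained
#' condition, ~24 h period, R2 >= 0.5), `"Circadian"` (free run, period in
#' the 18-37 h circadian range, R2 >= 0.5) or `"Arrhythmic"`. The
#' `criteria` slot records the period, R2 and thresholds that produced the
#' label.
#'
#' @slot label One of `"Synchronized"`, `"Circadian"`, `"Arrhythmic"`.
#' @slot condition `"entrained"` or `"freerun"`.
#' @slot criteria Named list of the values and thresholds applied.
#' @exportClass RhythmCall
#' @aliases RhythmCall-class
setClass("RhythmCall",
  representation(label = "character", condition = "character",
                 criteria = "list"),
  validity = function(object) {
    msg <- NULL
    if (!object@label %in% c("Synchronized", "Circadian", "Arrhythmic"))
      msg <- c(msg, "invalid label")
    if (!object@condition %in% c("entrained", "freerun"))
      msg <- c(msg, "invalid condition")
    if (object@label == "Synchronized" && object@condition != "entrained")
      msg <- c(msg, "Synchronized applies only to the entrained condition")
    if (object@label == "Circadian" && object@condition != "freerun")
      msg <- c(msg, "Circadian applies only to the freerun condition")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn RhythmCall The classification label.
#' @param x A `RhythmCall`.
#' @export
rhythmLabel <- function(x) x@label

#' @describeIn RhythmCall TRUE unless the call is `"Arrhythmic"`.
#' @export
isRhythmic <- function(x) x@label != "Arrhythmic"

setMethod("show", "RhythmCall", function(object) {
  cat("RhythmCall: ", object@label, " (", object@condition, "; tau = ",
      round(object@criteria$period, 3), " h, R2 = ",
      round(object@criteria$rSquared, 3), ")\n", sep = "")
})

#' Circular summary of an acrophase sample
#'
#' Circular mean phase (hours mod 24), resultant length `R` in `[0, 1]`,
#' Rayleigh uniformity p-value, circular standard error of the mean phase
#' (hours), and a `dispersed` flag raised when `R < 0.3`.
#'
#' @slot meanPhase,resultantR,rayleighP,semPhase Numeric.
#' @slot n Integer sample size.
#' @slot condition Character condition label.
#' @slot dispersed Logical, TRUE when `R < 0.3`.
#' @exportClass CircularSummary
#' @aliases CircularSummary-class
setClass("CircularSummary",
  representation(meanPhase = "numeric", resultantR = "numeric",
                 n = "integer", rayleighP = "numeric", semPhase = "numeric",
                 condition = "character", dispersed = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@resultantR < -1e-12 || object@resultantR > 1 + 1e-9)
      msg <- c(msg, "resultantR must lie in [0, 1]")
    if (object@n < 1) msg <- c(msg, "n must be >= 1")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn CircularSummary Resultant length R.
#' @param x A `CircularSummary`.
#' @export
resultantR <- function(x) x@resultantR

#' @describeIn CircularSummary Circular mean phase, hours mod 24.
#' @export
meanPhase <- function(x) x@meanPhase

#' @describeIn CircularSummary Rayleigh test p-value.
#' @export
rayleighP <- function(x) x@rayleighP

setMethod("show", "CircularSummary", function(object) {
  cat(sprintf(
    "CircularSummary (%s): mean phase %.2f +/- %.2f h, R = %.3f, n = %d, Rayleigh p = %.3g%s\n",
    object@condition, object@meanPhase,
    ifelse(is.na(object@semPhase), NA, object@semPhase),
    object@resultantR, object@n, object@rayleighP,
    if (object@dispersed) " [dispersed]" else ""))
})

#' JTK_CYCLE result
#'
#' @slot bestPeriod,bestLag,tau,pAdj Numeric: the winning reference period
#'   and phase lag (hours), Kendall tau-b there, and the Bonferroni-adjusted
#'   minimal p over the period x lag family (capped at 1).
#' @slot method `"exact"` or `"normal"` null for the winning pair.
#' @slot table data.frame of per-(period, lag) tau and p values.
#' @exportClass JtkResult
#' @aliases JtkResult-class
setClass("JtkResult",
  representation(bestPeriod = "numeric", bestLag = "numeric",
                 tau = "numeric", pAdj = "numeric", method = "character",
                 table = "data.frame"))

setMethod("show", "JtkResult", function(object) {
  cat(sprintf(
    "JTK_CYCLE: best period %.1f h, lag %.1f h, tau = %.3f, adj. p = %.4g (%s null)\n",
    object@bestPeriod, object@bestLag, object@tau, object@pAdj,
    object@method))
})

#' Two-group period comparison
#'
#' t-test comparison of per-well circadian periods between two groups or two
#' conditions. Both Welch and pooled-variance statistics are computed
#' (Welch is the headline result for unpaired designs); a Shapiro-Wilk
#' normality check is run on the paired differences (paired design) or the
#' group-centered residuals (unpaired design).
#'
#' @slot groups Character length-2 group labels.
#' @slot design `"paired"` or `"unpaired"`.
#' @slot statistic,df,p Welch (unpaired) or paired t-test results.
#' @slot tPooled,dfPooled,pPooled Pooled-variance t-test (unpaired only;
#'   NA for paired).
#' @slot meanDiff Mean of group 1 minus group 2 (or mean paired difference).
#' @slot shapiroP Shapiro-Wilk p-value of the normality check.
#' @slot n Integer per-group sample sizes.
#' @exportClass GroupComparison
#' @aliases GroupComparison-class
setClass("GroupComparison",
  representation(groups = "character", design = "character",
                 statistic = "numeric", df = "numeric", p = "numeric",
                 tPooled = "numeric", dfPooled = "numeric",
                 pPooled = "numeric", meanDiff = "numeric",
                 shapiroP = "numeric", n = "integer"))

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison (%s): %s vs %s; mean diff = %.3f h; t = %.3f (df %.2f), p = %.4g; Shapiro-Wilk p = %.3g\n",
    object@design, object@groups[1], object@groups[2], object@meanDiff,
    object@statistic, object@df, object@p, object@shapiroP))
})
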