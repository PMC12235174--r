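#' Synthetic bioluminescence traces with known ground truth
#'
#' `generateTrace()` simulates one well of a plate-luminometer recording:
#' three days (by default) under a dual light/temperature entraining cycle
#' followed by three days of free run, sampled every 30 min. The signal is
#'
#' \deqn{y(t) = e(t)\,[M + A \cos\theta(t)] + \epsilon_t}
#'
#' where the envelope \eqn{e(t) = (1 - e^{-3t/T})\,e^{-\lambda t}} combines
#' the initial luciferase-accumulation ramp (saturating over
#' `transientHours` \eqn{T}) with exponential damping at rate
#' `dampingRate` \eqn{\lambda}; the oscillation runs at the entrained
#' period until release and at the free-running period afterwards, with a
#' phase-continuous transition (plus any `phaseOffsetAtRelease`); and
#' \eqn{\epsilon_t} is i.i.d. Gaussian noise. A Bernoulli draw with success
#' probability `fractionRhythmic` decides whether the well is rhythmic;
#' arrhythmic wells get amplitude 0 but the identical envelope and noise
#' stream.
#'
#' With `dampingRate = 0` and `transientHours = 0` the envelope is exactly 1
#' and a noiseless rhythmic trace is the pure cosine
#' `mesor + amplitude * cos(2*pi*(zt(t) - acrophaseZt)/period)`.
#'
#' @param genotype A [GenotypeSpec].
#' @param protocol A [ProtocolSchedule].
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   traces.
#' @param wellId,strain Labels for the resulting trace (strain defaults to
#'   the genotype label).
#' @return A [TraceSeries] with attributes accessible via
#'   `attr(x, "truth")`: list with `rhythmic`, `period` (free-running tau)
#'   and `acrophase` (entrained, ZT hours).
#' @examples
#' tr <- generateTrace(GenotypeSpec(), ProtocolSchedule(), seed = 1)
#' attr(tr, "truth")
#' @seealso [generatePlate()] for whole plates, [generateCtTable()] for
#'   synthetic qPCR data.
#' @export
generateTrace <- function(genotype, protocol = ProtocolSchedule(), seed,
                          wellId = "well", strain = genotype@label) {
  validObject(genotype); validObject(protocol)
  if (protocol@samplingInterval <= 0) stop("non-positive sampling interval")
  if (genotype@noiseSd < 0) stop("negative noiseSd")

  dur <- totalDuration(protocol)
  times <- seq(0, dur - protocol@samplingInterval,
               by = protocol@samplingInterval)
  tRel <- releaseTime(protocol)
  segment <- ifelse(times < tRel, "entrained", "freerun")

  withSeed(seed, {
    rhythmic <- runif(1) < genotype@fractionRhythmic
    A <- if (rhythmic) genotype@amplitude else 0
    noise <- if (genotype@noiseSd > 0)
      rnorm(length(times), 0, genotype@noiseSd) else numeric(length(times))

    env <- rep(1, length(times))
    if (genotype@transientHours > 0)
      env <- env * (1 - exp(-3 * times / genotype@transientHours))
    if (genotype@dampingRate > 0)
      env <- env * exp(-genotype@dampingRate * times)

    # oscillation phase: entrained period referenced to ZT so that the peak
    # falls at acrophaseZt; free-running phase continues continuously from
    # the phase reached at release, advancing at the free-running period.
    zt <- protocol@recordStartZt + times
    thetaEnt <- 2 * pi * (zt - genotype@acrophaseZt) /
      genotype@periodEntrained
    thetaRelease <- 2 * pi *
      (protocol@recordStartZt + tRel - genotype@acrophaseZt) /
      genotype@periodEntrained
    thetaFr <- thetaRelease +
      2 * pi * (times - tRel) / genotype@periodFreerun +
      2 * pi * genotype@phaseOffsetAtRelease / 24
    theta <- ifelse(times < tRel, thetaEnt, thetaFr)

    y <- env * (genotype@mesor + A * cos(theta)) + noise

    tr <- TraceSeries(wellId = wellId, strain = strain, times = times,
                      values = y, segment = segment,
                      ztOffset = protocol@recordStartZt)
    attr(tr, "truth") <- list(rhythmic = rhythmic,
                              period = genotype@periodFreerun,
                              acrophase = genotype@acrophaseZt)
    tr
  })
}

#' Generate a synthetic plate of luminescence traces
#'
#' Simulates a whole plate: for each [GenotypeSpec] in `genotypes`, `nWells`
#' wells are generated with [generateTrace()]. Per-well seeds are derived
#' deterministically from the plate seed and well index
#' (`(seed * 10007 + index * 7919) mod (2^31 - 1)`), so wells are mutually
#' independent yet the whole plate is reproducible from one integer. The
#' per-well ground truth (rhythmic flag, free-running period, entrained
#' acrophase) is stored in the plate's `colData`.
#'
#' @param genotypes A list of [GenotypeSpec] objects (or a single one).
#' @param nWells Integer wells per genotype (recycled).
#' @param protocol A [ProtocolSchedule].
#' @param seed Integer plate seed.
#' @return A [PlateRecording] with truth columns in `colData` (see
#'   [plateTruth()]).
#' @examples
#' plate <- generatePlate(list(GenotypeSpec("control"),
#'                             GenotypeSpec("mutant", periodFreerun = 27.1)),
#'                        nWells = 5, seed = 42)
#' head(plateTruth(plate))
#' @export
generatePlate <- function(genotypes, nWells, protocol = ProtocolSchedule(),
                          seed) {
  if (is(genotypes, "GenotypeSpec")) genotypes <- list(genotypes)
  if (!length(genotypes)) stop("empty genotype list")
  nWells <- rep_len(as.integer(nWells), length(genotypes))
  if (sum(nWells) < 1) stop("at least one well must be requested")

  idx <- 0L
  traces <- list()
  truth <- list()
  for (g in seq_along(genotypes)) {
    for (w in seq_len(nWells[g])) {
      idx <- idx + 1L
      id <- sprintf("W%02d", idx)
      tr <- generateTrace(genotypes[[g]], protocol,
                          seed = wellSeed(seed, idx), wellId = id)
      traces[[idx]] <- tr
      tt <- attr(tr, "truth")
      truth[[idx]] <- data.frame(well = id, strain = strain(tr),
                                 truthRhythmic = tt$rhythmic,
                                 truthPeriod = tt$period,
                                 truthAcrophase = tt$acrophase)
    }
  }
  truth <- do.call(rbind, truth)
  lum <- vapply(traces, traceValues, numeric(length(traces[[1]])))
  makePlateRecording(
    lum, times = traceTimes(traces[[1]]),
    wells = truth$well, strains = truth$strain, protocol = protocol,
    ztOffset = protocol@recordStartZt,
    truth = truth[, c("truthRhythmic", "truthPeriod", "truthAcrophase")],
    seed = seed)
}

#' Synthetic qPCR Ct table
#'
#' Generates replicate Ct values for one target gene and one reference
#' (housekeeping) gene over a circadian sampling series (by default every
#' 4 h starting at ZT1, covering one entrained day and two free-running
#' days, mirroring a bulk-RNA time course). Under the perfect-efficiency
#' doubling model, the target Ct at each timepoint is
#' `referenceCt + deltaConst - log2(relative expression) + noise` and the
#' reference Ct is `referenceCt + noise`, so that downstream
#' 2^-ddCt quantification recovers the planted profile exactly when
#' `noiseSd = 0`.
#'
#' @param trueProfile Positive numeric vector of true relative expression,
#'   one per timepoint.
#' @param timepoints ZT/CT hours of sampling, same length as `trueProfile`
#'   (default `seq(1, by = 4, length.out = length(trueProfile))`).
#' @param referenceCt Baseline Ct of the reference gene (default 15).
#' @param deltaConst Constant Ct offset of the target over the reference at
#'   relative expression 1 (default 4).
#' @param replicates Biological replicates per timepoint (default 4).
#' @param noiseSd Gaussian Ct noise SD in cycles (default 0.25).
#' @param seed Integer seed.
#' @param targetGene,referenceGene Gene labels (defaults `"target"` and
#'   `"reference"`).
#' @return A data.frame with columns `sample`, `timepoint_h`, `condition`,
#'   `gene`, `ct` (long Ct-table format; condition is `"entrained"` for the
#'   first 24 h of timepoints and `"freerun"` after).
#' @examples
#' ct <- generateCtTable(rep(1, 6), timepoints = seq(1, 21, 4),
#'                       noiseSd = 0, seed = 1)
#' head(ct)
#' @export
generateCtTable <- function(trueProfile,
                            timepoints = seq(1, by = 4,
                                             length.out = length(trueProfile)),
                            referenceCt = 15, deltaConst = 4,
                            replicates = 4, noiseSd = 0.25, seed,
                            targetGene = "target",
                            referenceGene = "reference") {
  if (any(trueProfile <= 0)) stop("relative expression must be positive")
  if (length(timepoints) != length(trueProfile))
    stop("timepoints and trueProfile must have equal length")
  if (replicates < 1) stop("need at least one replicate")
  if (noiseSd < 0) stop("negative noiseSd")

  nT <- length(timepoints)
  condition <- ifelse(timepoints < timepoints[1] + 24, "entrained", "freerun")
  withSeed(seed, {
    rows <- vector("list", nT * replicates)
    k <- 0L
    for (i in seq_len(nT)) {
      for (r in seq_len(replicates)) {
        k <- k + 1L
        ctTarget <- referenceCt + deltaConst - log2(trueProfile[i]) +
          if (noiseSd > 0) rnorm(1, 0, noiseSd) else 0
        ctRef <- referenceCt + if (noiseSd > 0) rnorm(1, 0, noiseSd) else 0
        rows[[k]] <- data.frame(
          sample = sprintf("T%02d_R%d", i, r),
          timepoint_h = timepoints[i], condition = condition[i],
          gene = c(targetGene, referenceGene), ct = c(ctTarget, ctRef))
      }
    }
    do.call(rbind, rows)
  })
}
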