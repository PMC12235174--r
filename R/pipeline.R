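#' @importFrom stats t.test shapiro.test
NULL

#' Compare per-well circadian periods between two groups
#'
#' Two-sided t-test of per-well period estimates. For unpaired designs both
#' the Welch and the pooled-variance statistics are computed (Welch is the
#' headline result, as the safer default when variances may differ); for
#' paired designs the paired t-test is used and requires matched wells. A
#' Shapiro-Wilk normality check runs on the paired differences (paired) or
#' the group-centered residuals (unpaired).
#'
#' @param a,b Numeric period vectors (hours), each of length >= 2. For
#'   `design = "paired"` they must be equal-length and well-matched in
#'   order.
#' @param design `"unpaired"` (default) or `"paired"`.
#' @param groups Length-2 labels for reporting.
#' @return A [GroupComparison].
#' @examples
#' comparePeriods(c(24.1, 24.3, 24.2, 24.4), c(27.0, 27.2, 27.1, 27.3))
#' @export
comparePeriods <- function(a, b, design = c("unpaired", "paired"),
                           groups = c("group1", "group2")) {
  design <- match.arg(design)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 periods per group")
  if (design == "paired") {
    if (length(a) != length(b))
      stop("paired design requires matched wells (equal lengths)")
    d <- a - b
    if (sd(d) == 0) {
      # all differences identical: the t statistic degenerates; report the
      # 0/1 limit for the exactly-zero case
      tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 parameter = length(d) - 1,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else tt <- t.test(a, b, paired = TRUE)
    sw <- if (length(d) >= 3 && sd(d) > 0) shapiro.test(d)$p.value
          else NA_real_
    new("GroupComparison", groups = groups, design = design,
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, tPooled = NA_real_, dfPooled = NA_real_,
        pPooled = NA_real_, meanDiff = mean(d), shapiroP = sw,
        n = c(length(a), length(b)))
  } else {
    tw <- t.test(a, b, var.equal = FALSE)
    tp <- t.test(a, b, var.equal = TRUE)
    resid <- c(a - mean(a), b - mean(b))
    sw <- if (length(resid) >= 3 && sd(resid) > 0)
      shapiro.test(resid)$p.value else NA_real_
    new("GroupComparison", groups = groups, design = design,
        statistic = unname(tw$statistic), df = unname(tw$parameter),
        p = tw$p.value, tPooled = unname(tp$statistic),
        dfPooled = unname(tp$parameter), pPooled = tp$p.value,
        meanDiff = mean(a) - mean(b), shapiroP = sw,
        n = c(length(a), length(b)))
  }
}

# analyze one preprocessed trace restricted to one condition segment.
# fitLo/fitHi bound the samples used for period fitting: moving-average
# detrending is edge-distorted wherever the window ran off the recording,
# so the fit excludes half a detrend window at the recording's outer ends
# (peak-phase extraction still scans the full segment).
.analyzeSegment <- function(pp, condition, t0, t1, spec, tol24,
                            fitLo = -Inf, fitHi = Inf) {
  seg <- subsetTrace(pp, max(t0, fitLo), min(t1, fitHi))
  pg <- lombScargle(seg, spec)
  fit <- cosinorFit(seg, periodInit = peakPeriod(pg), freePeriod = TRUE,
                    periodRange = c(spec@periodMin, spec@periodMax))
  call <- classifyRhythm(fit, condition = condition, tol24 = tol24,
                         periodRange = c(spec@periodMin, spec@periodMax))
  peaks <- findPeakPhases(pp, window = c(t0, t1),
                          firstOnly = condition == "freerun")
  cs <- circularSummary(peaks, condition = condition)
  list(fit = fit, call = call, lsPeriod = peakPeriod(pg),
       peakPhase = if (condition == "freerun") peaks[1]
                   else meanPhase(cs))
}

#' Run the full analysis pipeline on a plate
#'
#' Per well: preprocess the raw trace ([runPreprocess()]), split it at the
#' release time into the entrained and free-running segments, and for each
#' segment estimate the period (Lomb-Scargle peak refined by a free-period
#' cosinor fit), classify the rhythm (Synchronized / Circadian /
#' Arrhythmic), and extract observed peak phases (per-cycle peaks under
#' entrainment; the first post-release peak under free run). Then
#' summarize: circular statistics of peak phases per strain x condition
#' (restricted to rhythmic wells), percent-rhythmic tallies, and -- when
#' two strains are present -- an unpaired comparison of free-running
#' periods between strains plus a paired entrained-vs-freerun comparison
#' within each strain.
#'
#' A failing well (e.g. dead at normalization, or constant after
#' preprocessing) is logged and skipped; the pipeline continues. Every
#' well ends up in exactly one of the results table, the dead-well log, or
#' the error log. Given identical inputs and parameters the output is
#' deterministic.
#'
#' @param plate A [PlateRecording] or a path to a long-dialect plate CSV.
#' @param params A [PreprocessParams].
#' @param spec A [PeriodogramSpec].
#' @param tol24 Synchronized-rule tolerance around 24 h (default 1).
#' @param edgeExclusion Hours excluded from each outer end of the
#'   (trimmed) recording when fitting periods. Moving-average detrending
#'   is distorted wherever its window runs off the recording, which biases
#'   period estimates; excluding half a detrend window (the default)
#'   restricts the fit to fully supported samples. Peak-phase extraction
#'   is unaffected.
#' @param outputDir Optional directory; when given, `results.csv`,
#'   `circular.csv`, `percent_rhythmic.csv`, `comparisons.csv`,
#'   `dead_wells.csv` and `manifest.json` are written there.
#' @return A list with elements `results` (data.frame, one row per well x
#'   condition), `circular` (data.frame per strain x condition),
#'   `percentRhythmic` (data.frame), `comparisons` (list of
#'   [GroupComparison]), `deadWells` (data.frame of skipped wells with the
#'   stage and message), and `manifest` (parameters, seeds, package
#'   version).
#' @examples
#' plate <- generatePlate(GenotypeSpec(fractionRhythmic = 1), nWells = 3,
#'                        seed = 11)
#' res <- runFullPipeline(plate)
#' res$results[, c("well", "condition", "period", "rSquared", "label")]
#' @export
runFullPipeline <- function(plate, params = PreprocessParams(),
                            spec = PeriodogramSpec(), tol24 = 1,
                            edgeExclusion = params@detrendWindow / 2,
                            outputDir = NULL) {
  if (is.character(plate)) plate <- readPlateCsv(plate)
  validObject(params); validObject(spec)
  cd <- SummarizedExperiment::colData(plate)
  if (!ncol(plate)) stop("empty plate: no wells to analyze")
  proto <- S4Vectors::metadata(plate)$protocol
  rd <- SummarizedExperiment::rowData(plate)
  tEnd <- max(rd$time_h) + 1e-9
  tRel <- if (!is.null(proto)) releaseTime(proto)
          else if (any(rd$segment == "freerun"))
            min(rd$time_h[rd$segment == "freerun"])
          else tEnd

  results <- list()
  dead <- list()
  for (w in cd$well) {
    tr <- getTrace(plate, w)
    stage <- "preprocess"
    out <- tryCatch({
      pp <- runPreprocess(tr, params)
      segs <- list()
      stage <- "rhythmometry"
      fitLo <- params@trimHours + edgeExclusion
      fitHi <- tEnd - edgeExclusion
      if (params@trimHours < tRel)
        segs$entrained <- .analyzeSegment(pp, "entrained",
                                          params@trimHours, tRel, spec,
                                          tol24, fitLo, fitHi)
      if (tRel < tEnd)
        segs$freerun <- .analyzeSegment(pp, "freerun", tRel, tEnd, spec,
                                        tol24, fitLo, fitHi)
      do.call(rbind, lapply(names(segs), function(cond) {
        s <- segs[[cond]]
        data.frame(well = w, strain = strain(tr), condition = cond,
                   period = fittedPeriod(s$fit),
                   lsPeriod = s$lsPeriod,
                   amplitude = amplitude(s$fit), mesor = mesor(s$fit),
                   acrophaseCosinor = acrophase(s$fit),
                   peakPhase = s$peakPhase,
                   rSquared = rSquared(s$fit),
                   label = rhythmLabel(s$call))
      }))
    }, error = function(e) {
      dead[[length(dead) + 1L]] <<- data.frame(
        well = w, stage = stage, message = conditionMessage(e))
      NULL
    })
    if (!is.null(out)) results[[length(results) + 1L]] <- out
  }
  results <- if (length(results)) do.call(rbind, results) else
    stop("no well produced results")
  dead <- if (length(dead)) do.call(rbind, dead) else
    data.frame(well = character(), stage = character(),
               message = character())

  # circular summaries of peak phases per strain x condition (rhythmic wells)
  circ <- list()
  for (st in unique(results$strain)) {
    for (cond in unique(results$condition)) {
      sub <- results[results$strain == st & results$condition == cond &
                       results$label != "Arrhythmic", ]
      if (nrow(sub) < 1) next
      cs <- circularSummary(hoursMod24(sub$peakPhase), condition = cond)
      circ[[length(circ) + 1L]] <- data.frame(
        strain = st, condition = cond, n = cs@n,
        meanPhase = cs@meanPhase, semPhase = cs@semPhase,
        resultantR = cs@resultantR, rayleighP = cs@rayleighP,
        dispersed = cs@dispersed)
    }
  }
  circ <- if (length(circ)) do.call(rbind, circ) else data.frame()

  # percent-rhythmic tallies per strain x condition
  pct <- do.call(rbind, lapply(split(results,
                                     results[, c("strain", "condition")]),
    function(sub) if (!nrow(sub)) NULL else data.frame(
      strain = sub$strain[1], condition = sub$condition[1],
      nRhythmic = sum(sub$label != "Arrhythmic"), nTotal = nrow(sub),
      percent = percentRhythmic(sub$label))))
  rownames(pct) <- NULL

  # group comparisons on free-running periods of rhythmic wells
  comparisons <- list()
  strains <- unique(results$strain)
  frRes <- results[results$condition == "freerun" &
                     results$label == "Circadian", ]
  if (length(strains) == 2) {
    pa <- frRes$period[frRes$strain == strains[1]]
    pb <- frRes$period[frRes$strain == strains[2]]
    if (length(pa) >= 2 && length(pb) >= 2)
      comparisons$freerunBetweenStrains <-
        comparePeriods(pa, pb, design = "unpaired", groups = strains)
  }
  for (st in strains) {
    sub <- results[results$strain == st, ]
    wide <- merge(sub[sub$condition == "entrained",
                      c("well", "period", "label")],
                  sub[sub$condition == "freerun",
                      c("well", "period", "label")], by = "well")
    wide <- wide[wide$label.x != "Arrhythmic" &
                   wide$label.y != "Arrhythmic", ]
    if (nrow(wide) >= 2)
      comparisons[[paste0("entrainedVsFreerun.", st)]] <-
        comparePeriods(wide$period.x, wide$period.y, design = "paired",
                       groups = c("entrained", "freerun"))
  }

  manifest <- list(
    package = "circalum",
    version = as.character(utils::packageVersion("circalum")),
    seed = S4Vectors::metadata(plate)$seed,
    nWells = ncol(plate),
    params = list(background = params@background,
                  trimHours = params@trimHours,
                  detrendWindow = params@detrendWindow,
                  smoothWindow = params@smoothWindow,
                  normWindow = params@normWindow,
                  periodMin = spec@periodMin, periodMax = spec@periodMax,
                  oversampling = spec@oversampling, tol24 = tol24,
                  edgeExclusion = edgeExclusion))

  out <- list(results = results, circular = circ, percentRhythmic = pct,
              comparisons = comparisons, deadWells = dead,
              manifest = manifest)

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(outputDir, "results.csv"),
              row.names = FALSE)
    write.csv(circ, file.path(outputDir, "circular.csv"),
              row.names = FALSE)
    write.csv(pct, file.path(outputDir, "percent_rhythmic.csv"),
              row.names = FALSE)
    write.csv(dead, file.path(outputDir, "dead_wells.csv"),
              row.names = FALSE)
    cmpDf <- do.call(rbind, lapply(names(comparisons), function(nm) {
      g <- comparisons[[nm]]
      data.frame(comparison = nm, group1 = g@groups[1],
                 group2 = g@groups[2], design = g@design,
                 meanDiff = g@meanDiff, t = g@statistic, df = g@df,
                 p = g@p, tPooled = g@tPooled, pPooled = g@pPooled,
                 shapiroP = g@shapiroP)
    }))
    if (is.null(cmpDf)) cmpDf <- data.frame()
    write.csv(cmpDf, file.path(outputDir, "comparisons.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
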