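#' Relative expression by the 2^-ddCt method
#'
#' Computes relative expression from a long-format qPCR Ct table. Replicate
#' Ct values are averaged per (timepoint, gene); for each timepoint
#' `dCt = Ct_target - Ct_reference`, then `ddCt = dCt - dCt_calibrator`
#' and relative expression `2^-ddCt`, so the calibrator timepoint is 1 by
#' construction. When target and reference measurements can be paired by
#' sample id, a per-replicate spread (SEM of replicate fold changes) is
#' also reported.
#'
#' @param table data.frame with columns `sample`, `timepoint_h`, `gene`,
#'   `ct` (and optionally `condition`), one row per well reaction — the
#'   format written by [generateCtTable()].
#' @param target Target gene name.
#' @param reference Reference (housekeeping) gene name, e.g. the
#'   `Y45F10D.4`-style invariant control.
#' @param calibrator Timepoint (hours) used as calibrator; default the
#'   earliest timepoint.
#' @return data.frame ("ExpressionSeries") with columns `timepoint_h`,
#'   `condition` (if present), `rel` (fold change, > 0), `sem`, `n`; the
#'   calibrator is stored in `attr(x, "calibrator")`.
#' @examples
#' ct <- generateCtTable(c(1, 2, 4, 2, 1, 0.5), noiseSd = 0, seed = 1)
#' ddct(ct, "target", "reference")
#' @export
ddct <- function(table, target, reference, calibrator = NULL) {
  need <- c("sample", "timepoint_h", "gene", "ct")
  if (!all(need %in% colnames(table)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  tps <- sort(unique(table$timepoint_h))
  if (is.null(calibrator)) calibrator <- tps[1]
  if (!calibrator %in% tps) stop("calibrator timepoint not present")

  meanCt <- function(tp, gene) {
    v <- table$ct[table$timepoint_h == tp & table$gene == gene]
    if (!length(v)) NA_real_ else mean(v)
  }
  ctT <- vapply(tps, meanCt, numeric(1), gene = target)
  ctR <- vapply(tps, meanCt, numeric(1), gene = reference)
  if (anyNA(ctR))
    stop("reference gene '", reference, "' missing at timepoint(s) ",
         paste(tps[is.na(ctR)], collapse = ", "))
  if (anyNA(ctT))
    stop("target gene '", target, "' missing at timepoint(s) ",
         paste(tps[is.na(ctT)], collapse = ", "))

  dCt <- ctT - ctR
  ddCt <- dCt - dCt[match(calibrator, tps)]
  rel <- 2^(-ddCt)

  # per-replicate fold changes (sample-paired dCt) for an SEM
  sem <- rep(NA_real_, length(tps))
  nrep <- integer(length(tps))
  for (i in seq_along(tps)) {
    sub <- table[table$timepoint_h == tps[i], ]
    tv <- sub[sub$gene == target, c("sample", "ct")]
    rv <- sub[sub$gene == reference, c("sample", "ct")]
    m <- merge(tv, rv, by = "sample")
    nrep[i] <- nrow(m)
    if (nrow(m) > 1) {
      relRep <- 2^(-((m$ct.x - m$ct.y) - dCt[match(calibrator, tps)]))
      sem[i] <- sd(relRep) / sqrt(length(relRep))
    }
  }

  out <- data.frame(timepoint_h = tps, rel = rel, sem = sem, n = nrep)
  if ("condition" %in% colnames(table))
    out$condition <- vapply(tps, function(tp)
      table$condition[table$timepoint_h == tp][1], character(1))
  attr(out, "calibrator") <- calibrator
  class(out) <- c("ExpressionSeries", "data.frame")
  out
}

#' Day/night block means of an expression series
#'
#' Descriptive per-block summary of an expression time course: timepoints
#' are assigned to the diurnal or nocturnal block by their ZT hour mod 24,
#' and the block mean and SEM of the relative expression are reported. No
#' test is implied. Blocks holding a single timepoint get an `NA` SEM and
#' are flagged.
#'
#' @param series An ExpressionSeries data.frame from [ddct()] (columns
#'   `timepoint_h`, `rel`).
#' @param dayWindow ZT interval `[from, to)` counted as the diurnal block
#'   (default `c(0, 12)`, lights-on hours).
#' @return data.frame with columns `block`, `mean`, `sem`, `n`,
#'   `singleton`.
#' @export
dailyPatternSummary <- function(series, dayWindow = c(0, 12)) {
  zt <- hoursMod24(series$timepoint_h)
  day <- zt >= dayWindow[1] & zt < dayWindow[2]
  blk <- ifelse(day, "diurnal", "nocturnal")
  out <- do.call(rbind, lapply(c("diurnal", "nocturnal"), function(b) {
    v <- series$rel[blk == b]
    data.frame(block = b, mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v), singleton = length(v) == 1)
  }))
  rownames(out) <- NULL
  out
}
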