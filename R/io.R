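#' @importFrom utils read.csv write.csv
NULL

#' Read a plate of luminescence traces from CSV
#'
#' Two dialects are supported. `"long"`: columns `well`, `strain`,
#' `time_h`, `lum`, one row per reading. `"wide"`: first header row names
#' the columns (`time_h` followed by well ids), a second header row gives
#' the strain of each well (first field `strain`), and each subsequent row
#' holds one timepoint. Gaps (missing readings) are tolerated and stored
#' as `NA`; duplicated (well, time) pairs, non-increasing times and
#' unparseable numeric fields are each rejected with a distinct error.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @param ztOffset ZT of recording start (default 12).
#' @param protocol Optional [ProtocolSchedule] used to label
#'   entrained/free-run segments; if absent, release is assumed at 72 h.
#' @return A [PlateRecording].
#' @seealso [writePlateCsv()]
#' @export
readPlateCsv <- function(path, dialect = c("long", "wide"), ztOffset = 12,
                         protocol = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    d <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("well", "strain", "time_h", "lum")
    if (!all(need %in% colnames(d)))
      stop("long dialect needs columns: ", paste(need, collapse = ", "))
    for (cn in c("time_h", "lum")) {
      v <- suppressWarnings(as.numeric(d[[cn]]))
      if (anyNA(v) && !all(is.na(d[[cn]][is.na(v)])))
        stop("unparseable numeric values in column '", cn, "'")
      d[[cn]] <- v
    }
    if (anyDuplicated(d[, c("well", "time_h")]))
      stop("duplicated (well, time) sample(s)")
    times <- sort(unique(d$time_h))
    wells <- unique(d$well)
    strains <- unname(vapply(wells, function(w) d$strain[d$well == w][1],
                             character(1)))
    lum <- matrix(NA_real_, length(times), length(wells))
    for (j in seq_along(wells)) {
      sub <- d[d$well == wells[j], ]
      if (is.unsorted(sub$time_h, strictly = TRUE))
        stop("non-monotone times for well ", wells[j])
      lum[match(sub$time_h, times), j] <- sub$lum
    }
  } else {
    hdr <- read.csv(path, header = FALSE, nrows = 2,
                    stringsAsFactors = FALSE)
    if (tolower(hdr[2, 1]) != "strain")
      stop("wide dialect: second header row must start with 'strain'")
    wells <- as.character(unlist(hdr[1, -1]))
    strains <- as.character(unlist(hdr[2, -1]))
    d <- read.csv(path, header = FALSE, skip = 2, stringsAsFactors = FALSE)
    times <- suppressWarnings(as.numeric(d[[1]]))
    if (anyNA(times)) stop("unparseable numeric values in time column")
    lum <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(lum) <- "double"
    if (anyDuplicated(times)) stop("duplicated (well, time) sample(s)")
  }
  if (any(diff(times) <= 0)) stop("non-monotone times")
  makePlateRecording(lum, times = times, wells = wells, strains = strains,
                     ztOffset = ztOffset, protocol = protocol,
                     segment = if (is.null(protocol))
                       ifelse(times < 72, "entrained", "freerun") else NULL)
}

#' Write a plate of luminescence traces to CSV
#'
#' Inverse of [readPlateCsv()]; both dialects round-trip losslessly.
#'
#' @param plate A [PlateRecording].
#' @param path Output CSV path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
writePlateCsv <- function(plate, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  rd <- SummarizedExperiment::rowData(plate)
  cd <- SummarizedExperiment::colData(plate)
  lum <- SummarizedExperiment::assay(plate, "lum")
  if (dialect == "long") {
    d <- data.frame(
      well = rep(cd$well, each = nrow(lum)),
      strain = rep(cd$strain, each = nrow(lum)),
      time_h = rep(rd$time_h, ncol(lum)),
      lum = as.vector(lum))
    d <- d[!is.na(d$lum), ]
    write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("time_h", cd$well), collapse = ","), con)
    writeLines(paste(c("strain", cd$strain), collapse = ","), con)
    body <- apply(cbind(rd$time_h, lum), 1,
                  function(r) paste(r, collapse = ","))
    writeLines(body, con)
  }
  invisible(path)
}

#' Write the ground-truth sidecar of a synthetic plate
#'
#' @param plate A synthetic [PlateRecording] from [generatePlate()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTruthCsv <- function(plate, path) {
  tr <- plateTruth(plate)
  if (is.null(tr)) stop("plate carries no ground truth")
  write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table from CSV
#'
#' Expects the long Ct format with columns `sample`, `timepoint_h`,
#' `condition`, `gene`, `ct` (as produced by [generateCtTable()]).
#'
#' @param path CSV file path.
#' @return A data.frame suitable for [ddct()].
#' @export
readCtCsv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "timepoint_h", "gene", "ct")
  if (!all(need %in% colnames(d)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  d$timepoint_h <- as.numeric(d$timepoint_h)
  d$ct <- as.numeric(d$ct)
  if (any(d$ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  d
}
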