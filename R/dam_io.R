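#' Read a DAM-style activity monitor file
#'
#' Parses a Trikinetics-style tab-separated monitor file: one row per
#' timestamp with a row index, date, time, a block of status columns, and 32
#' integer channel counts.  The common 42-column dialect (7 status columns)
#' is the default; the column map is configurable for other layouts.  The
#' acquisition bin width is inferred from consecutive timestamps.
#'
#' Channels that never registered a single beam cross are flagged in the
#' \code{"allZero"} attribute of the returned list (and a warning is raised)
#' but are never dropped: whether an empty channel is an empty tube or a
#' dead fly is for \code{\link{detectDeath}} and the caller to decide.
#'
#' @param path monitor file path.
#' @param schedule a \linkS4class{LightSchedule} (kept with the series'
#'   metadata; timestamp-to-ZT mapping is done by \code{\link{toZeitgeber}}).
#' @param genotype genotype label stamped on every channel.
#' @param countColumns indices of the 32 channel-count columns.
#' @param dateColumn,timeColumn indices of the date and time columns.
#' @return a named list of \linkS4class{ActivitySeries}, one per channel,
#'   with attribute \code{allZero} (logical per channel).
#' @seealso \code{\link{writeDamMonitor}}, \code{\link{readFlyCsv}}
#' @export
readDamMonitor <- function(path, schedule, genotype = "unknown",
                           countColumns = 11:42, dateColumn = 2L,
                           timeColumn = 3L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty monitor file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  need <- max(countColumns, dateColumn, timeColumn)
  bad <- which(ncols < need)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected at least %d columns, got %d",
                 bad[1L], need, ncols[bad[1L]]))
  mat <- do.call(rbind, fields)
  stamps <- parseDamTimestamp(mat[, dateColumn], mat[, timeColumn])
  if (anyNA(stamps))
    stop(sprintf("parse error at line %d: unreadable timestamp '%s %s'",
                 which(is.na(stamps))[1L],
                 mat[which(is.na(stamps))[1L], dateColumn],
                 mat[which(is.na(stamps))[1L], timeColumn]))
  raw <- mat[, countColumns, drop = FALSE]
  suppressWarnings(counts <- matrix(as.integer(raw), nrow = nrow(raw)))
  if (anyNA(counts)) {
    badCell <- which(is.na(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error at line %d: non-integer count '%s'",
                 badCell[1L], raw[badCell[1L], badCell[2L]]))
  }
  if (nrow(counts) > 1L) {
    steps <- diff(as.numeric(stamps)) / 60
    if (any(abs(steps - steps[1L]) > 1e-6))
      stop(sprintf("format error: non-constant time step at line %d",
                   which(abs(steps - steps[1L]) > 1e-6)[1L] + 1L))
    binMin <- as.integer(round(steps[1L]))
    if (binMin < 1L) stop("format error: time step below one minute")
  } else {
    binMin <- 5L
  }
  monitor <- sub("\\.[^.]*$", "", basename(path))
  out <- lapply(seq_along(countColumns), function(ch) {
    ActivitySeries(counts[, ch], binMinutes = binMin, startTime = stamps[1L],
                   flyId = sprintf("%s_ch%02d", monitor, ch),
                   genotype = genotype)
  })
  names(out) <- vapply(out, flyId, character(1L))
  allZero <- colSums(counts) == 0L
  names(allZero) <- names(out)
  if (any(allZero))
    warning(sprintf("%d channel(s) with no activity at all: %s",
                    sum(allZero),
                    paste(names(out)[allZero], collapse = ", ")))
  attr(out, "allZero") <- allZero
  out
}

parseDamTimestamp <- function(date, time) {
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%d %b %y %H:%M:%S")) {
    parsed <- as.POSIXct(paste(date, time), format = fmt, tz = "UTC")
    if (!anyNA(parsed)) return(parsed)
  }
  # mixed or partially bad rows: best effort with the ISO format so the
  # caller can point at the offending line
  as.POSIXct(paste(date, time), format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
}

#' Write activity series as a DAM-style monitor file
#'
#' Inverse of \code{\link{readDamMonitor}} for up to 32 series sharing one
#' time grid; unused channels are zero-filled so the 42-column layout is
#' preserved.
#'
#' @param seriesList list of \linkS4class{ActivitySeries} on a common grid.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDamMonitor <- function(seriesList, path) {
  if (!length(seriesList)) stop("nothing to write")
  n <- length(activityCounts(seriesList[[1L]]))
  bm <- binMinutes(seriesList[[1L]])
  t0 <- startTime(seriesList[[1L]])
  same <- vapply(seriesList, function(s)
    length(activityCounts(s)) == n && binMinutes(s) == bm &&
      identical(as.numeric(startTime(s)), as.numeric(t0)), logical(1L))
  if (!all(same)) stop("all series must share the same time grid")
  if (length(seriesList) > 32L) stop("a monitor holds at most 32 channels")
  stamps <- t0 + (seq_len(n) - 1L) * bm * 60
  counts <- matrix(0L, nrow = n, ncol = 32L)
  for (ch in seq_along(seriesList))
    counts[, ch] <- activityCounts(seriesList[[ch]])
  status <- matrix(rep(c("1", rep("0", 6L)), each = n), nrow = n)
  rows <- cbind(seq_len(n), format(stamps, "%Y-%m-%d"),
                format(stamps, "%H:%M:%S"), status, counts)
  writeLines(apply(rows, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read/write per-fly CSV activity data
#'
#' Long-format alternative to the monitor layout, one row per fly and bin:
#' \code{fly_id,genotype,timestamp,count}.
#'
#' @param path CSV path.
#' @return \code{readFlyCsv}: a named list of \linkS4class{ActivitySeries}.
#' @export
readFlyCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("fly_id", "genotype", "timestamp", "count")
  if (!all(need %in% names(df)))
    stop("per-fly CSV must have columns ", paste(need, collapse = ","))
  out <- lapply(split(df, df$fly_id), function(d) {
    stamps <- as.POSIXct(d$timestamp, tz = "UTC")
    o <- order(stamps)
    d <- d[o, ]; stamps <- stamps[o]
    steps <- diff(as.numeric(stamps)) / 60
    if (length(steps) && any(abs(steps - steps[1L]) > 1e-6))
      stop("non-constant time step for fly ", d$fly_id[1L])
    ActivitySeries(d$count,
                   binMinutes = if (length(steps)) round(steps[1L]) else 5L,
                   startTime = stamps[1L], flyId = d$fly_id[1L],
                   genotype = d$genotype[1L])
  })
  out[order(names(out))]
}

#' @param seriesList list of \linkS4class{ActivitySeries}.
#' @rdname readFlyCsv
#' @export
writeFlyCsv <- function(seriesList, path) {
  rows <- lapply(seriesList, function(s) {
    n <- length(activityCounts(s))
    data.frame(
      fly_id = flyId(s), genotype = genotype(s),
      timestamp = format(startTime(s) + (seq_len(n) - 1L) *
                           binMinutes(s) * 60, "%Y-%m-%d %H:%M:%S"),
      count = activityCounts(s))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a light schedule from a YAML config
#'
#' Expects keys \code{lights_on} ("HH:MM"), \code{photoperiod_hours},
#' \code{n_ld_days}, \code{n_dd_days} (at the top level or under
#' \code{schedule:}).
#'
#' @param path YAML file path.
#' @return a \linkS4class{LightSchedule}.
#' @export
readLightSchedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$schedule)) cfg <- cfg$schedule
  need <- c("lights_on", "photoperiod_hours", "n_ld_days", "n_dd_days")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("light schedule config is missing keys: ",
         paste(miss, collapse = ", "))
  LightSchedule(cfg$lights_on, cfg$photoperiod_hours,
                cfg$n_ld_days, cfg$n_dd_days)
}

#' @rdname rebin
#' @export
setMethod("rebin", "ActivitySeries", function(object, targetBinMinutes) {
  targetBinMinutes <- as.integer(targetBinMinutes)
  src <- binMinutes(object)
  if (targetBinMinutes < src || targetBinMinutes %% src != 0L)
    stop("targetBinMinutes must be a positive multiple of the source bin (",
         src, " min)")
  ratio <- targetBinMinutes %/% src
  if (ratio == 1L) return(object)
  x <- activityCounts(object)
  nOut <- length(x) %/% ratio
  dropped <- length(x) - nOut * ratio
  if (dropped > 0L)
    warning(sprintf("truncating %d trailing bin(s) (partial %d-min bin)",
                    dropped, targetBinMinutes))
  if (nOut == 0L) stop("series shorter than one target bin")
  summed <- colSums(matrix(x[seq_len(nOut * ratio)], nrow = ratio))
  new("ActivitySeries", flyId = object@flyId, genotype = object@genotype,
      startTime = object@startTime, binMinutes = targetBinMinutes,
      counts = as.integer(summed))
})

#' Map a timestamp to Zeitgeber time
#'
#' ZT0 is lights-on; ZT is the clock time elapsed since the most recent
#' lights-on, in [0, 24).  During constant darkness the same projection is
#' carried forward at a strict 24-h cycle from the last entrained lights-on
#' and read as circadian time (CT); no correction for the fly's own period
#' is applied.
#'
#' @param timestamp \code{POSIXct} (vectorized).
#' @param schedule a \linkS4class{LightSchedule}.
#' @return ZT/CT hours in [0, 24).
#' @examples
#' sch <- LightSchedule("08:00", 12, 3, 7)
#' toZeitgeber(as.POSIXct("2016-01-04 09:30:00", tz = "UTC"), sch)  # 1.5
#' @export
toZeitgeber <- function(timestamp, schedule) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  clockHours <- lt$hour + lt$min / 60 + lt$sec / 3600
  (clockHours - parseClockHours(schedule@lightsOn)) %% 24
}

#' Flag flies that died during the recording
#'
#' A fly is scored dead when its terminal run of all-zero bins spans at
#' least \code{minTerminalZeroHours} and reaches the end of the recording;
#' the time of death is taken as the end of the last bin with any activity
#' (the start of the recording if the fly never moved).  Standard DAM
#' practice; the threshold is exposed because the call is a heuristic, not a
#' measurement.
#'
#' @param series an \linkS4class{ActivitySeries}.
#' @param minTerminalZeroHours hours of terminal immobility scored as death.
#' @return a \linkS4class{VitalStatus}.
#' @export
detectDeath <- function(series, minTerminalZeroHours = 24) {
  x <- activityCounts(series)
  binH <- binHoursOf(series)
  if (length(x) * binH < minTerminalZeroHours)
    stop("recording shorter than minTerminalZeroHours; cannot assess death")
  lastActive <- if (any(x > 0L)) max(which(x > 0L)) else 0L
  terminalZeroH <- (length(x) - lastActive) * binH
  if (terminalZeroH >= minTerminalZeroHours) {
    new("VitalStatus", alive = FALSE,
        deathTime = startTime(series) + lastActive * binMinutes(series) * 60)
  } else {
    new("VitalStatus", alive = TRUE,
        deathTime = as.POSIXct(character(0L), tz = "UTC"))
  }
}
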