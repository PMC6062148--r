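# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so that simulations are
# pure functions of their seed.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (tables round 30.555... up to 30.56, which
# base round()'s banker's rounding does not guarantee at .5 boundaries).
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

parseClockHours <- function(hhmm) {
  parts <- as.numeric(strsplit(hhmm, ":", fixed = TRUE)[[1L]])
  parts[1L] + parts[2L] / 60
}

binHoursOf <- function(series) binMinutes(series) / 60

# Hours elapsed since the lights-on event at or before the start of the
# recording, for each bin start.  Day 1 begins at that lights-on.
elapsedZtHours <- function(series, schedule) {
  zt0 <- toZeitgeber(startTime(series), schedule)
  zt0 + (seq_along(activityCounts(series)) - 1L) * binHoursOf(series)
}

# 1-based day index of every bin (ZT days counted from the first lights-on).
dayIndexOf <- function(series, schedule) {
  floor(elapsedZtHours(series, schedule) / 24) + 1L
}

# ZT (or CT, during DD) of every bin start, in [0, 24).
ztOf <- function(series, schedule) {
  elapsedZtHours(series, schedule) %% 24
}

# Subset an ActivitySeries to whole recording days (ZT days).
sliceDays <- function(series, schedule, days) {
  idx <- dayIndexOf(series, schedule) %in% days
  if (!any(idx)) stop("requested days are outside the recording")
  keep <- which(idx)
  new("ActivitySeries", flyId = series@flyId, genotype = series@genotype,
      startTime = series@startTime +
        (keep[1L] - 1L) * binMinutes(series) * 60,
      binMinutes = series@binMinutes, counts = series@counts[keep])
}

# 3-point parabolic interpolation of a peak on a uniform grid; ties and
# edge peaks fall back to the grid point.  `prefer` breaks exact ties
# toward a reference abscissa (24 h for circadian peaks).
refinePeak <- function(x, y, prefer = 24) {
  best <- which(y == max(y))
  if (length(best) > 1L) best <- best[which.min(abs(x[best] - prefer))]
  if (best == 1L || best == length(y)) return(x[best])
  y0 <- y[best - 1L]; y1 <- y[best]; y2 <- y[best + 1L]
  denom <- y0 - 2 * y1 + y2
  if (denom >= 0) return(x[best])   # not a strict local maximum
  shift <- 0.5 * (y0 - y2) / denom
  shift <- max(-0.5, min(0.5, shift))
  x[best] + shift * (x[2L] - x[1L])
}

pkgVersionString <- function() {
  as.character(utils::packageVersion("circafly"))
}

# Provenance header written at the top of every output file.
provenanceHeader <- function(seed = NA, configHash = NA) {
  sprintf("# circafly %s | seed: %s | config: %s | written: %s",
          pkgVersionString(),
          if (is.na(seed)) "none" else as.character(seed),
          if (is.na(configHash)) "none" else configHash,
          format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
}
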