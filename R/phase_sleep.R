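#' Average-day activity profile
#'
#' Folds the requested recording days onto a single Zeitgeber day: value at
#' ZT bin \eqn{b} is the mean, across days, of the count in that bin.  Three
#' entrained LD days are the conventional input for the phase metrics.
#'
#' @param series an \linkS4class{ActivitySeries}; rebinned internally to
#'   30-min bins.
#' @param days 1-based recording-day indices to average (ZT days counted
#'   from the first lights-on).
#' @param schedule a \linkS4class{LightSchedule}.
#' @return a \linkS4class{DayProfile}.
#' @examples
#' sch <- LightSchedule("08:00", 12, 3, 7)
#' fly <- simulateFly(FlyParams(seed = 1L), sch)
#' averageDayProfile(fly, days = 1:3, sch)
#' @export
averageDayProfile <- function(series, days = 1:3, schedule) {
  if (binMinutes(series) != 30L) series <- rebin(series, 30L)
  dayIdx <- dayIndexOf(series, schedule)
  if (!all(days %in% dayIdx))
    stop("requested day(s) outside the recording: ",
         paste(setdiff(days, dayIdx), collapse = ", "))
  keep <- dayIdx %in% days
  ztBin <- floor(ztOf(series, schedule)[keep] / 0.5)   # 0..47
  perDay <- table(factor(ztBin, levels = 0:47))
  if (any(perDay < length(days)))
    stop("requested day(s) not fully covered by the recording")
  vals <- tapply(as.numeric(activityCounts(series))[keep],
                 factor(ztBin, levels = 0:47), mean)
  new("DayProfile", values = as.numeric(vals), binHours = 0.5,
      nDaysAveraged = length(unique(dayIdx[keep])))
}

# Mean profile value over a ZT window [from, to), hours.
profileWindowMean <- function(profile, from, to) {
  zt <- (seq_len(48L) - 1L) * 0.5
  mean(profile@values[zt >= from & zt < to])
}

#' Morning index
#'
#' Bounded contrast of pre-dawn activity build-up:
#' \deqn{MI = (A_{late} - A_{early}) / (A_{late} + A_{early})}
#' with \eqn{A_{late}} the mean activity over the 3 h directly before
#' lights-on (ZT 21--24) and \eqn{A_{early}} the mean over the 3 h before
#' that (ZT 18--21).  A clock-driven anticipatory ramp makes the late block
#' exceed the early one, pushing MI towards 1; a flat night gives MI near
#' 0 (defined as exactly 0 when both blocks are empty).
#'
#' @param profile an LD \linkS4class{DayProfile}.
#' @param earlyWindow,lateWindow ZT windows (hours) of the two blocks.
#' @return MI in [-1, 1].
#' @export
morningIndex <- function(profile, earlyWindow = c(18, 21),
                         lateWindow = c(21, 24)) {
  aEarly <- profileWindowMean(profile, earlyWindow[1L], earlyWindow[2L])
  aLate <- profileWindowMean(profile, lateWindow[1L], lateWindow[2L])
  if (aEarly + aLate == 0) return(0)
  (aLate - aEarly) / (aLate + aEarly)
}

#' Detect anticipation of a light transition
#'
#' Scores, fly by fly, whether activity builds up over the 3 h preceding
#' lights-on (morning anticipation) or lights-off (evening anticipation).
#' The window is split into three 1-h thirds with means \eqn{a_1, a_2, a_3}
#' (\eqn{a_3} adjacent to the transition); anticipation requires
#' \eqn{a_3 > a_2 \ge a_1}, \eqn{a_3 > 0}, and a non-trivial rise
#' \eqn{a_3 \ge} \code{minRiseRatio}\eqn{\cdot a_1}.  The rise requirement
#' keeps chance orderings of a flat noisy profile (which alone would pass
#' about one time in six) from being scored as anticipation.
#'
#' @param profile an LD \linkS4class{DayProfile}.
#' @param transition \code{"lights-on"} or \code{"lights-off"}.
#' @param photoperiodHours lights-off time (ZT) for the evening window.
#' @param minRiseRatio minimum ratio of the third adjacent to the
#'   transition over the farthest third.
#' @return logical.
#' @export
detectAnticipation <- function(profile,
                               transition = c("lights-on", "lights-off"),
                               photoperiodHours = 12,
                               minRiseRatio = 1.5) {
  transition <- match.arg(transition)
  endZt <- if (transition == "lights-on") 24 else photoperiodHours
  a <- vapply(1:3, function(i)
    profileWindowMean(profile, (endZt - 4 + i) %% 24,
                      if (endZt - 3 + i == 24) 24 else (endZt - 3 + i) %% 24),
    numeric(1L))
  a[3L] > a[2L] && a[2L] >= a[1L] && a[3L] > 0 &&
    a[3L] >= minRiseRatio * a[1L]
}

#' Evening activity onset
#'
#' Locates the ZT at which the evening bout begins after the midday rest
#' (siesta), mirroring the manual scoring rule: (1) the evening peak is the
#' profile maximum in \code{peakWindow} (ties to the latest bin); (2) a
#' rest is a run of at least \code{restMinBins} consecutive bins below
#' \code{restThreshold} times the profile maximum, inside
#' [\code{restSearchFrom}, peak); (3) walking backward from the peak, the
#' onset run extends while each earlier bin does not exceed its successor,
#' tolerating at most one zero-activity bin inside the run (leading zeros
#' are trimmed so the run starts on movement); (4) the onset is the ZT of
#' the run's first bin, accepted only when a rest precedes it.  Flies with
#' no qualifying rest or rise have no onset (and are excluded from cohort
#' onset averages).
#'
#' @param profile an LD \linkS4class{DayProfile}.
#' @param peakWindow ZT window searched for the evening peak, hours.
#' @param restThreshold rest level as a fraction of the profile maximum.
#' @param restMinBins minimum rest length, bins.
#' @param restSearchFrom earliest ZT a rest may start, hours.
#' @return onset ZT in hours, or \code{NA} when undefined.
#' @export
eveningOnset <- function(profile, peakWindow = c(6, 13),
                         restThreshold = 0.25, restMinBins = 2L,
                         restSearchFrom = 2) {
  v <- profile@values
  zt <- (seq_len(48L) - 1L) * 0.5
  inPeakWin <- which(zt >= peakWindow[1L] & zt <= peakWindow[2L])
  peakIdx <- inPeakWin[v[inPeakWin] == max(v[inPeakWin])]
  peakIdx <- peakIdx[length(peakIdx)]            # ties -> latest
  if (v[peakIdx] == 0) return(NA_real_)

  # backward walk: non-decreasing towards the peak, at most one zero inside;
  # a tolerated zero is skipped over, so the bin before it compares against
  # the last nonzero bin of the run
  runStart <- peakIdx
  zerosUsed <- 0L
  refVal <- v[peakIdx]
  i <- peakIdx
  repeat {
    if (i == 1L) break
    nxt <- v[i - 1L]
    if (nxt == 0) {
      if (zerosUsed >= 1L) break
      zerosUsed <- zerosUsed + 1L
    } else if (nxt <= refVal) {
      refVal <- nxt
    } else break
    i <- i - 1L
    runStart <- i
  }
  while (runStart < peakIdx && v[runStart] == 0)  # trim leading zeros
    runStart <- runStart + 1L
  if (runStart == peakIdx) return(NA_real_)       # no rise at all

  # a rest must precede the onset run, inside [restSearchFrom, peak)
  thr <- restThreshold * max(v)
  restWin <- which(zt >= restSearchFrom & seq_len(48L) < runStart)
  if (length(restWin) < restMinBins) return(NA_real_)
  below <- v[restWin] < thr
  r <- rle(below)
  if (!any(r$values & r$lengths >= restMinBins)) return(NA_real_)
  zt[runStart]
}

#' Free-running activity phase in DD
#'
#' CT of the highest bout of activity on one DD day (the fourth by
#' convention), read off data smoothed with a centred moving average.
#' Window edges are truncated (partial-window means), ties resolve to the
#' earliest bin, and an all-zero day has no phase.
#'
#' @param series an \linkS4class{ActivitySeries}; rebinned internally to
#'   30-min bins.
#' @param schedule a \linkS4class{LightSchedule}.
#' @param ddDayIndex which DD day to use (1-based within the DD block).
#' @param smoothBins odd width of the centred moving average.
#' @return CT in hours, or \code{NA} for an all-zero day.
#' @export
ddPhase <- function(series, schedule, ddDayIndex = 4L, smoothBins = 3L) {
  if (smoothBins %% 2L != 1L) stop("smoothBins must be odd")
  if (ddDayIndex < 1L || ddDayIndex > schedule@nDdDays)
    stop("ddDayIndex outside the DD span")
  if (binMinutes(series) != 30L) series <- rebin(series, 30L)
  day <- sliceDays(series, schedule, schedule@nLdDays + ddDayIndex)
  v <- as.numeric(activityCounts(day))
  if (length(v) != 48L) stop("selected DD day not fully covered")
  if (all(v == 0)) return(NA_real_)
  half <- (smoothBins - 1L) %/% 2L
  sm <- vapply(seq_along(v), function(i)
    mean(v[max(1L, i - half):min(length(v), i + half)]), numeric(1L))
  ztOf(day, schedule)[which.max(sm)]              # ties -> earliest
}

#' Sleep per the 5-minute inactivity rule
#'
#' Fly sleep is operationally 5 min of consecutive inactivity, so on a
#' 5-min acquisition grid every zero-count bin contributes 5 min of sleep.
#' Minutes are attributed to the light or dark phase by the ZT of the bin
#' start.  The rule is undefined on coarser grids, so the series must still
#' be at 5-min resolution.
#'
#' @param series an \linkS4class{ActivitySeries} at 5-min bins.
#' @param schedule a \linkS4class{LightSchedule}.
#' @param day 1-based recording-day index to score.
#' @return named numeric: \code{total}, \code{day}, \code{night} minutes.
#' @export
sleepSummary <- function(series, schedule, day = 1L) {
  if (binMinutes(series) != 5L)
    stop("sleep must be scored on the raw 5-min bins, not analysis bins")
  d <- sliceDays(series, schedule, day)
  if (length(activityCounts(d)) != 288L)
    stop("selected day not fully covered by the recording")
  zero <- activityCounts(d) == 0L
  isDay <- ztOf(d, schedule) < schedule@photoperiodHours
  c(total = 5 * sum(zero),
    day = 5 * sum(zero & isDay),
    night = 5 * sum(zero & !isDay))
}

#' All phase and sleep metrics for one fly
#'
#' Convenience wrapper bundling the per-fly phase metrics (morning index,
#' morning/evening anticipation, evening onset, DD phase) and sleep
#' (averaged over the LD days) into one row.
#'
#' @param series an \linkS4class{ActivitySeries} at 5-min bins.
#' @param schedule a \linkS4class{LightSchedule}.
#' @param ldDays LD days used for the average-day profile.
#' @return one-row data.frame.
#' @export
phaseSleepMetrics <- function(series, schedule,
                              ldDays = seq_len(schedule@nLdDays)) {
  profile <- averageDayProfile(series, days = ldDays, schedule)
  sleep <- rowMeans(vapply(ldDays, function(d)
    sleepSummary(series, schedule, day = d), numeric(3L)))
  ddp <- if (schedule@nDdDays >= 4L) ddPhase(series, schedule) else NA_real_
  data.frame(
    fly_id = flyId(series),
    mi = morningIndex(profile),
    ma = detectAnticipation(profile, "lights-on",
                            photoperiodHours = schedule@photoperiodHours),
    ea = detectAnticipation(profile, "lights-off",
                            photoperiodHours = schedule@photoperiodHours),
    e_onset_zt = eveningOnset(profile),
    dd_phase_ct = ddp,
    sleep_total_min = sleep[["total"]],
    sleep_day_min = sleep[["day"]],
    sleep_night_min = sleep[["night"]])
}
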