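#' Autocorrelogram of an activity series
#'
#' Mean-detrended sample autocorrelation,
#' \eqn{r_k = \sum (x_t-\bar x)(x_{t+k}-\bar x) / \sum (x_t-\bar x)^2},
#' with \eqn{r_0 = 1}.  Intended for 30-min analysis bins over several days
#' of recording.
#'
#' @param series an \linkS4class{ActivitySeries} (30-min bins expected).
#' @param maxLagHours largest lag evaluated, hours.
#' @return data.frame with columns \code{lag_hours} and \code{coefficient}.
#' @export
autocorrelogram <- function(series, maxLagHours = 36) {
  x <- as.numeric(activityCounts(series))
  if (sd(x) == 0)
    stop("degenerate input: constant series has no autocorrelation")
  binH <- binHoursOf(series)
  maxLag <- min(length(x) - 1L, floor(maxLagHours / binH))
  a <- acf(x, lag.max = maxLag, plot = FALSE, demean = TRUE)
  data.frame(lag_hours = as.numeric(a$lag) * binH,
             coefficient = as.numeric(a$acf))
}

#' Autocorrelation rhythmicity statistic
#'
#' The peak autocorrelation coefficient inside the circadian search window,
#' scaled by the white-noise band \code{2/sqrt(nBins)}: RS >= 1 means the
#' peak clears the approximate 95\% band expected for an unstructured
#' series.  The peak lag is refined by 3-point parabolic interpolation,
#' exact grid ties broken toward 24 h.
#'
#' @param acfDf output of \code{\link{autocorrelogram}}.
#' @param nBins number of bins the autocorrelogram was computed from.
#' @param searchWindowHours circadian lag window, hours.
#' @return list with \code{rs} and \code{peakLag} (hours).
#' @export
rhythmicityStatistic <- function(acfDf, nBins,
                                 searchWindowHours = c(18, 30)) {
  inWin <- acfDf$lag_hours >= searchWindowHours[1L] &
    acfDf$lag_hours <= searchWindowHours[2L]
  if (!any(inWin))
    stop("search window lies outside the computed lags")
  lag <- acfDf$lag_hours[inWin]
  coefs <- acfDf$coefficient[inWin]
  peak <- max(coefs)
  list(rs = peak / (2 / sqrt(nBins)),
       peakLag = refinePeak(lag, coefs, prefer = 24))
}

#' Chi-square periodogram
#'
#' Enright/Sokolove--Bushell periodogram on binned counts.  For each
#' candidate period \eqn{P} (in bins) the first \eqn{K} complete cycles are
#' folded into a cycle-by-phase block; phases are whole bins, so
#' non-integer \eqn{P} drops the fractional tail of each cycle.  The
#' statistic is the between-phase sum of squares over the pooled variance,
#' \eqn{Q_P = n \sum_h n_h (M_h - \bar M)^2 / \sum_i (x_i - \bar M)^2},
#' with \eqn{M_h} the phase-column means, \eqn{n_h} their fold counts and
#' \eqn{n} the folded bins; under the null \eqn{Q_P \sim \chi^2} with
#' (columns - 1) degrees of freedom.  The best period maximizes the clearance of \eqn{Q_P} over
#' its significance line and is refined by parabolic interpolation.
#'
#' @param series an \linkS4class{ActivitySeries} (30-min bins expected).
#' @param periods candidate periods, hours.
#' @param alpha significance level for the chi-square line.
#' @param alphaAdjust \code{"bonferroni"} (default) divides \code{alpha} by
#'   the number of evaluated candidates before drawing the line, keeping the
#'   family-wise false-positive rate of the peak test near \code{alpha};
#'   \code{"none"} uses the per-candidate level.
#' @return list with \code{bestPeriod} (h), \code{stat}, \code{pvalue},
#'   \code{significant}, and the full \code{curve} data.frame
#'   (period, stat, df, pvalue, sigLine).
#' @export
chiSquarePeriodogram <- function(series, periods = seq(18, 30, by = 0.1),
                                 alpha = 0.01,
                                 alphaAdjust = c("bonferroni", "none")) {
  alphaAdjust <- match.arg(alphaAdjust)
  x <- as.numeric(activityCounts(series))
  binH <- binHoursOf(series)
  n <- length(x)
  rows <- lapply(periods, function(P) {
    pBins <- P / binH
    K <- floor(n / pBins)
    if (K < 2L) return(NULL)
    nCycleBins <- floor(K * pBins)
    phase <- floor((seq_len(nCycleBins) - 1L) %% pBins)
    keep <- phase < floor(pBins)          # drop the fractional tail bin
    xi <- x[seq_len(nCycleBins)][keep]
    ph <- phase[keep]
    mh <- tapply(xi, ph, mean)
    nh <- tapply(xi, ph, length)
    mbar <- mean(xi)
    denom <- sum((xi - mbar)^2)
    if (denom == 0) return(NULL)
    # one-way decomposition: between-phase sum of squares over the pooled
    # variance estimate; chi-square with (columns - 1) df under the null
    stat <- length(xi) * sum(nh * (mh - mbar)^2) / denom
    data.frame(period = P, stat = stat, df = length(mh) - 1L)
  })
  skipped <- sum(vapply(rows, is.null, logical(1L)))
  if (skipped > 0L)
    warning(sprintf("%d candidate period(s) skipped (fewer than 2 complete %s",
                    skipped, "cycles or zero variance)"))
  curve <- do.call(rbind, rows)
  if (is.null(curve) || !nrow(curve))
    stop("degenerate input: no candidate period could be evaluated")
  alphaEff <- if (alphaAdjust == "bonferroni") alpha / nrow(curve) else alpha
  curve$pvalue <- pchisq(curve$stat, curve$df, lower.tail = FALSE)
  curve$sigLine <- qchisq(1 - alphaEff, curve$df)
  clearance <- curve$stat - curve$sigLine
  bestIdx <- which(clearance == max(clearance))
  if (length(bestIdx) > 1L)
    bestIdx <- bestIdx[which.min(abs(curve$period[bestIdx] - 24))]
  bestPeriod <- refinePeak(curve$period, clearance, prefer = 24)
  list(bestPeriod = bestPeriod,
       stat = curve$stat[bestIdx],
       pvalue = curve$pvalue[bestIdx],
       significant = clearance[bestIdx] > 0,
       curve = curve)
}

#' Classify a fly as rhythmic or arrhythmic in DD
#'
#' Dual-method call on the free-running days: a fly is rhythmic when its
#' chi-square periodogram peak is significant at \code{alpha} (family-wise,
#' see \code{\link{chiSquarePeriodogram}}) \emph{and} its autocorrelation
#' rhythmicity statistic reaches \code{rsThreshold}.  The first DD day is
#' excluded by default as an entrainment transient.  The period estimate
#' \eqn{\tau} is the refined periodogram peak; arrhythmic flies carry none.
#'
#' @param series an \linkS4class{ActivitySeries} at acquisition resolution
#'   (rebinned internally to \code{analysisBinMinutes}).
#' @param schedule a \linkS4class{LightSchedule} with at least 5 DD days.
#' @param ddDays DD day indices used (default 2--7, i.e. skipping DD day 1).
#' @param alpha periodogram significance level.
#' @param rsThreshold autocorrelation statistic threshold.
#' @param alphaAdjust passed to \code{\link{chiSquarePeriodogram}}.
#' @param periods candidate period grid, hours.
#' @param analysisBinMinutes analysis bin width.
#' @param vital optional \linkS4class{VitalStatus}; dead flies are refused
#'   (computed from the series when not supplied).
#' @return a \linkS4class{RhythmResult}.
#' @export
classifyRhythmicity <- function(series, schedule, ddDays = 2:7,
                                alpha = 0.01, rsThreshold = 1,
                                alphaAdjust = c("bonferroni", "none"),
                                periods = seq(18, 30, by = 0.1),
                                analysisBinMinutes = 30L, vital = NULL) {
  alphaAdjust <- match.arg(alphaAdjust)
  if (schedule@nDdDays < 5L)
    stop("classification needs at least 5 DD days")
  if (is.null(vital)) vital <- detectDeath(series)
  if (!vital@alive)
    stop("fly '", flyId(series),
         "' died during recording; exclude it before classification")
  ddDays <- ddDays[ddDays <= schedule@nDdDays]
  dd <- sliceDays(series, schedule, schedule@nLdDays + ddDays)
  dd <- rebin(dd, analysisBinMinutes)
  x <- activityCounts(dd)

  arrhythmicResult <- function(rs = 0, acfLag = NA_real_,
                               pg = NA_real_, stat = NA_real_,
                               pv = NA_real_) {
    new("RhythmResult", isRhythmic = FALSE, tauHours = NA_real_, rs = rs,
        acfPeakLagHours = acfLag, periodogramPeakPeriodHours = pg,
        periodogramStat = stat, periodogramPvalue = pv)
  }
  if (sd(as.numeric(x)) == 0) return(arrhythmicResult())

  acfDf <- autocorrelogram(dd)
  rsRes <- rhythmicityStatistic(acfDf, nBins = length(x))
  pg <- chiSquarePeriodogram(dd, periods = periods, alpha = alpha,
                             alphaAdjust = alphaAdjust)
  rhythmic <- pg$significant && rsRes$rs >= rsThreshold
  tau <- if (rhythmic) min(30, max(18, pg$bestPeriod)) else NA_real_
  new("RhythmResult", isRhythmic = rhythmic, tauHours = tau,
      rs = rsRes$rs, acfPeakLagHours = rsRes$peakLag,
      periodogramPeakPeriodHours = pg$bestPeriod,
      periodogramStat = pg$stat, periodogramPvalue = pg$pvalue)
}
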