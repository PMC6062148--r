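#' @rdname ActivitySeries-class
#' @param object an \linkS4class{ActivitySeries}.
#' @export
setGeneric("activityCounts", function(object) standardGeneric("activityCounts"))

#' @rdname ActivitySeries-class
#' @export
setMethod("activityCounts", "ActivitySeries", function(object) object@counts)

#' @rdname ActivitySeries-class
#' @export
setGeneric("binMinutes", function(object) standardGeneric("binMinutes"))

#' @rdname ActivitySeries-class
#' @export
setMethod("binMinutes", "ActivitySeries", function(object) object@binMinutes)

#' @rdname ActivitySeries-class
#' @export
setGeneric("flyId", function(object) standardGeneric("flyId"))

#' @rdname ActivitySeries-class
#' @export
setMethod("flyId", "ActivitySeries", function(object) object@flyId)

#' @rdname ActivitySeries-class
#' @export
setGeneric("genotype", function(object) standardGeneric("genotype"))

#' @rdname ActivitySeries-class
#' @export
setMethod("genotype", "ActivitySeries", function(object) object@genotype)

#' @rdname ActivitySeries-class
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))

#' @rdname ActivitySeries-class
#' @export
setMethod("startTime", "ActivitySeries", function(object) object@startTime)

setMethod("length", "ActivitySeries", function(x) length(x@counts))

setMethod("show", "ActivitySeries", function(object) {
  cat(sprintf(
    "ActivitySeries '%s' (%s): %d bins of %d min from %s (%.1f days)\n",
    object@flyId, object@genotype, length(object@counts), object@binMinutes,
    format(object@startTime, "%Y-%m-%d %H:%M"),
    length(object@counts) * object@binMinutes / 1440))
})

setMethod("show", "LightSchedule", function(object) {
  cat(sprintf(
    "LightSchedule: lights on %s, %g h photoperiod, %d LD + %d DD days\n",
    object@lightsOn, object@photoperiodHours, object@nLdDays, object@nDdDays))
})

setMethod("show", "VitalStatus", function(object) {
  if (object@alive) cat("VitalStatus: alive\n")
  else cat(sprintf("VitalStatus: dead (last activity %s)\n",
                   format(object@deathTime, "%Y-%m-%d %H:%M")))
})

setMethod("show", "RhythmResult", function(object) {
  cat(sprintf(
    "RhythmResult: %s | tau = %s h | RS = %.2f | periodogram %.2f h (p = %.3g)\n",
    if (object@isRhythmic) "rhythmic" else "arrhythmic",
    if (is.na(object@tauHours)) "NA" else sprintf("%.2f", object@tauHours),
    object@rs, object@periodogramPeakPeriodHours, object@periodogramPvalue))
})

setMethod("show", "DayProfile", function(object) {
  cat(sprintf(
    "DayProfile: 48 x %g h bins, mean of %d day(s); peak %.2f at ZT %.1f\n",
    object@binHours, object@nDaysAveraged, max(object@values),
    (which.max(object@values) - 1) * object@binHours))
})

setMethod("show", "SamResult", function(object) {
  cat(sprintf(
    paste0("SamResult: %d probes | s0 = %.4g | delta = %.3g | ",
           "%d up / %d down | FDR = %.3g (pi0 = %.2f)\n"),
    length(object@dScores), object@s0, object@delta,
    length(object@significantUp), length(object@significantDown),
    object@fdrEstimate, object@pi0))
})

#' @rdname SamResult-class
#' @param object a \linkS4class{SamResult}.
#' @export
setGeneric("dScores", function(object) standardGeneric("dScores"))

#' @rdname SamResult-class
#' @export
setMethod("dScores", "SamResult", function(object) object@dScores)

#' @rdname SamResult-class
#' @export
setGeneric("significantProbes", function(object)
  standardGeneric("significantProbes"))

#' Called probe sets of a SAM fit
#'
#' @return a list with elements \code{up} and \code{down}.
#' @rdname SamResult-class
#' @export
setMethod("significantProbes", "SamResult", function(object)
  list(up = object@significantUp, down = object@significantDown))

#' @rdname DayProfile-class
#' @param object a \linkS4class{DayProfile}.
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))

#' @rdname DayProfile-class
#' @export
setMethod("profileValues", "DayProfile", function(object) object@values)

#' @rdname ExpressionMatrix-class
#' @param object an \linkS4class{ExpressionMatrix}.
#' @export
setGeneric("exprsValues", function(object) standardGeneric("exprsValues"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprsValues", "ExpressionMatrix", function(object)
  SummarizedExperiment::assay(object, "exprs"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("sampleGroups", "ExpressionMatrix", function(object)
  as.character(SummarizedExperiment::colData(object)$group))

#' Rebin an activity series to a coarser grid
#'
#' Sums consecutive bins into wider bins (e.g. 5-min acquisition bins into
#' the 30-min analysis bins).  The target width must be a positive multiple
#' of the source width; a trailing partial bin is truncated with a warning.
#' Total counts are conserved up to the truncated tail.
#'
#' @param object an \linkS4class{ActivitySeries}.
#' @param targetBinMinutes new bin width in minutes.
#' @return an \linkS4class{ActivitySeries} on the coarser grid.
#' @examples
#' s <- ActivitySeries(c(1L, 0L, 2L, 0L, 0L, 3L))
#' activityCounts(rebin(s, 30))   # 6
#' @export
setGeneric("rebin", function(object, targetBinMinutes) standardGeneric("rebin"))
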