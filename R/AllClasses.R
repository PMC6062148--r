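#' @import methods
#' @importFrom stats acf approx coef lm mad median pchisq phyper qchisq
#'   qnorm quantile rnorm rpois sd setNames
#' @importFrom utils head read.csv read.delim read.table tail write.csv
#'   write.table combn packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
NULL

#' Lighting regime of a recording
#'
#' Describes the light schedule a cohort experienced: a block of
#' light--dark (LD) days with lights-on at a fixed clock time, followed by a
#' block of constant-darkness (DD) days.  Zeitgeber time (ZT) 0 is defined by
#' \code{lightsOn}; during DD the same projection continues at a strict 24-h
#' cycle and is reported as circadian time (CT).
#'
#' @slot lightsOn character, clock time of lights-on as \code{"HH:MM"}.
#' @slot photoperiodHours numeric, hours of light per LD day (12 for LD 12:12).
#' @slot nLdDays integer, number of entrained LD days.
#' @slot nDdDays integer, number of free-running DD days.
#'
#' @export
setClass("LightSchedule",
  representation(
    lightsOn = "character",
    photoperiodHours = "numeric",
    nLdDays = "integer",
    nDdDays = "integer"
  )
)

setValidity("LightSchedule", function(object) {
  msg <- character()
  if (length(object@lightsOn) != 1L ||
      !grepl("^[0-9]{1,2}:[0-9]{2}$", object@lightsOn))
    msg <- c(msg, "lightsOn must be a single \"HH:MM\" string")
  if (length(object@photoperiodHours) != 1L ||
      object@photoperiodHours <= 0 || object@photoperiodHours >= 24)
    msg <- c(msg, "photoperiodHours must lie strictly between 0 and 24")
  if (object@nLdDays < 0L || object@nDdDays < 0L)
    msg <- c(msg, "day counts must be non-negative")
  if (object@nLdDays + object@nDdDays < 1L)
    msg <- c(msg, "schedule must cover at least one day")
  if (length(msg)) msg else TRUE
})

#' @param lightsOn clock time of lights-on, \code{"HH:MM"}.
#' @param photoperiodHours hours of light per LD day.
#' @param nLdDays number of LD days.
#' @param nDdDays number of DD days.
#' @rdname LightSchedule-class
#' @examples
#' LightSchedule("08:00", 12, nLdDays = 3, nDdDays = 7)
#' @export
LightSchedule <- function(lightsOn = "08:00", photoperiodHours = 12,
                          nLdDays = 3L, nDdDays = 7L) {
  new("LightSchedule", lightsOn = lightsOn,
      photoperiodHours = as.numeric(photoperiodHours),
      nLdDays = as.integer(nLdDays), nDdDays = as.integer(nDdDays))
}

#' One fly's activity record
#'
#' Beam-cross counts for a single fly on a uniform time grid.  Bins are
#' half-open intervals labelled by their start time; the first bin starts at
#' \code{startTime}.
#'
#' @slot flyId character identifier (monitor/channel or simulation id).
#' @slot genotype character genotype label.
#' @slot startTime \code{POSIXct} start of the first bin.
#' @slot binMinutes integer bin width in minutes; must divide 60 or be a
#'   multiple of 60 so the grid aligns to whole hours over a day.
#' @slot counts integer vector of non-negative beam crossings per bin.
#'
#' @export
setClass("ActivitySeries",
  representation(
    flyId = "character",
    genotype = "character",
    startTime = "POSIXct",
    binMinutes = "integer",
    counts = "integer"
  )
)

setValidity("ActivitySeries", function(object) {
  msg <- character()
  if (length(object@counts) < 1L)
    msg <- c(msg, "counts must contain at least one bin")
  if (anyNA(object@counts) || any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative and non-missing")
  bm <- object@binMinutes
  if (length(bm) != 1L || bm < 1L || !(60L %% bm == 0L || bm %% 60L == 0L))
    msg <- c(msg, "binMinutes must divide 60 or be a multiple of 60")
  if (length(msg)) msg else TRUE
})

#' @param counts non-negative integer vector of beam crossings per bin.
#' @param binMinutes bin width in minutes.
#' @param startTime POSIXct start of the recording.
#' @param flyId,genotype metadata strings.
#' @rdname ActivitySeries-class
#' @export
ActivitySeries <- function(counts, binMinutes = 5L,
                           startTime = as.POSIXct("2016-01-04 08:00:00",
                                                  tz = "UTC"),
                           flyId = "fly1", genotype = "unknown") {
  new("ActivitySeries", flyId = as.character(flyId),
      genotype = as.character(genotype), startTime = startTime,
      binMinutes = as.integer(binMinutes), counts = as.integer(counts))
}

#' Survival call for a recorded fly
#'
#' @slot alive logical.
#' @slot deathTime \code{POSIXct}; empty when \code{alive} is \code{TRUE},
#'   otherwise the end of the last bin with any activity (start of the
#'   recording when the fly never moved).
#'
#' @export
setClass("VitalStatus",
  representation(alive = "logical", deathTime = "POSIXct"))

setValidity("VitalStatus", function(object) {
  if (object@alive && length(object@deathTime) != 0L)
    return("deathTime must be absent for a living fly")
  if (!object@alive && length(object@deathTime) != 1L)
    return("deathTime required for a dead fly")
  TRUE
})

#' Per-fly rhythmicity call
#'
#' @slot isRhythmic logical call from the conjunction rule (significant
#'   periodogram peak and autocorrelation rhythmicity statistic RS >= 1).
#' @slot tauHours free-running period estimate in hours (\code{NA} when
#'   arrhythmic).
#' @slot rs autocorrelation rhythmicity statistic (peak coefficient relative
#'   to the white-noise band \code{2/sqrt(n)}).
#' @slot acfPeakLagHours lag of the autocorrelation peak, hours.
#' @slot periodogramPeakPeriodHours best chi-square periodogram period, hours.
#' @slot periodogramStat periodogram statistic at the best period.
#' @slot periodogramPvalue chi-square upper-tail p-value at the best period.
#'
#' @export
setClass("RhythmResult",
  representation(
    isRhythmic = "logical",
    tauHours = "numeric",
    rs = "numeric",
    acfPeakLagHours = "numeric",
    periodogramPeakPeriodHours = "numeric",
    periodogramStat = "numeric",
    periodogramPvalue = "numeric"
  )
)

setValidity("RhythmResult", function(object) {
  msg <- character()
  if (object@isRhythmic && is.na(object@tauHours))
    msg <- c(msg, "rhythmic flies must carry a period estimate")
  if (!object@isRhythmic && !is.na(object@tauHours))
    msg <- c(msg, "arrhythmic flies carry no period estimate")
  if (!is.na(object@tauHours) &&
      (object@tauHours < 18 || object@tauHours > 30))
    msg <- c(msg, "tauHours must lie in [18, 30]")
  if (!is.na(object@rs) && object@rs < 0)
    msg <- c(msg, "rs must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Average-day activity profile
#'
#' Mean activity per 30-min Zeitgeber-time bin across a set of recording
#' days, the per-fly object from which morning index, anticipation and
#' evening onset are scored.
#'
#' @slot values numeric of length 48, mean counts per ZT bin (bin b covers
#'   ZT [(b-1)/2, b/2)).
#' @slot binHours bin width in hours, fixed at 0.5.
#' @slot nDaysAveraged how many days went into the mean.
#'
#' @export
setClass("DayProfile",
  representation(values = "numeric", binHours = "numeric",
                 nDaysAveraged = "integer"))

setValidity("DayProfile", function(object) {
  msg <- character()
  if (length(object@values) != 48L)
    msg <- c(msg, "profile must have exactly 48 half-hour bins")
  if (anyNA(object@values) || any(object@values < 0))
    msg <- c(msg, "profile values must be non-negative")
  if (!identical(object@binHours, 0.5))
    msg <- c(msg, "binHours is fixed at 0.5")
  if (length(msg)) msg else TRUE
})

#' Probes-by-samples expression matrix
#'
#' A thin \linkS4class{SummarizedExperiment} wrapper: one assay
#' (\code{"exprs"}, log2-scale values, \code{NA} for unreliable spots) and a
#' \code{group} column in \code{colData} carrying the two-class labels.
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay \"exprs\" is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry a \"group\" column")
  if (length(msg)) msg else TRUE
})

#' @param values numeric matrix, probes x samples (log2 scale, NAs allowed).
#' @param groups group label per column (length \code{ncol(values)}).
#' @param probeIds optional probe identifiers (defaults to rownames).
#' @rdname ExpressionMatrix-class
#' @examples
#' m <- matrix(rnorm(40), nrow = 10,
#'             dimnames = list(paste0("p", 1:10), NULL))
#' em <- ExpressionMatrix(m, groups = rep(c("oe", "ctrl"), each = 2))
#' @export
ExpressionMatrix <- function(values, groups, probeIds = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(probeIds))
    probeIds <- paste0("probe_", seq_len(nrow(values)))
  if (length(probeIds) != nrow(values))
    stop("probeIds must match the number of rows")
  if (length(groups) != ncol(values))
    stop("groups must supply one label per column")
  rownames(values) <- probeIds
  if (is.null(colnames(values)))
    colnames(values) <- make.unique(as.character(groups), sep = "_")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(values)))
  new("ExpressionMatrix", se)
}

#' Two-class SAM result
#'
#' @slot dScores named numeric, moderated d statistic per probe (\code{NA}
#'   for probes with fewer than two usable values in a group).
#' @slot s0 exchangeability (fudge) factor added to every denominator.
#' @slot delta calling threshold on |d - expected order statistic|.
#' @slot fdrEstimate pi0-adjusted median-based FDR at \code{delta}.
#' @slot pi0 estimated proportion of null probes.
#' @slot significantUp,significantDown called probe ids.
#' @slot cutUp,cutLow d-score cutpoints implied by \code{delta}.
#' @slot flagged probes excluded from calling (insufficient data or zero
#'   spread with \code{s0 = 0}).
#' @slot nPermutations number of label permutations used.
#' @slot seed RNG seed used when permutations were sampled.
#'
#' @export
setClass("SamResult",
  representation(
    dScores = "numeric",
    s0 = "numeric",
    delta = "numeric",
    fdrEstimate = "numeric",
    pi0 = "numeric",
    significantUp = "character",
    significantDown = "character",
    cutUp = "numeric",
    cutLow = "numeric",
    flagged = "character",
    nPermutations = "integer",
    seed = "integer"
  )
)

setValidity("SamResult", function(object) {
  msg <- character()
  if (length(intersect(object@significantUp, object@significantDown)))
    msg <- c(msg, "up and down sets must be disjoint")
  if (!is.na(object@fdrEstimate) && object@fdrEstimate < 0)
    msg <- c(msg, "fdrEstimate must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Ground-truth parameters of one simulated fly
#'
#' Defaults are the cohort conditions used throughout the test-bench: a
#' crepuscular fly entrained to LD 12:12 with morning and evening peaks of
#' four times the baseline rate, a 3-h anticipation ramp and a 24-h
#' free-running period.
#'
#' @slot tauHours free-running period, hours (16--32).
#' @slot phaseOffsetHours evening-peak offset from lights-off, hours
#'   (positive = delayed).
#' @slot morningAmplitude,eveningAmplitude expected extra counts per 5-min
#'   bin at the peak of each bout.
#' @slot baselineRate expected counts per 5-min bin away from the bouts.
#' @slot anticipationRampHours duration of the linear pre-transition ramp,
#'   hours (0--6).
#' @slot arrhythmic when \code{TRUE} the time-varying rate is replaced by its
#'   time average (the fly stays alive, just unstructured).
#' @slot deathDay integer day on which the fly dies (activity zero from that
#'   day's start); \code{NA} for survivors.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("FlyParams",
  representation(
    tauHours = "numeric",
    phaseOffsetHours = "numeric",
    morningAmplitude = "numeric",
    eveningAmplitude = "numeric",
    baselineRate = "numeric",
    anticipationRampHours = "numeric",
    arrhythmic = "logical",
    deathDay = "integer",
    seed = "integer"
  )
)

setValidity("FlyParams", function(object) {
  msg <- character()
  if (object@tauHours < 16 || object@tauHours > 32)
    msg <- c(msg, "tauHours must lie in [16, 32]")
  if (object@morningAmplitude < 0 || object@eveningAmplitude < 0 ||
      object@baselineRate < 0)
    msg <- c(msg, "rates must be non-negative")
  if (object@anticipationRampHours < 0 || object@anticipationRampHours > 6)
    msg <- c(msg, "anticipationRampHours must lie in [0, 6]")
  if (length(msg)) msg else TRUE
})

#' @param tauHours free-running period in hours.
#' @param phaseOffsetHours evening-peak offset from lights-off.
#' @param morningAmplitude,eveningAmplitude peak extra counts per 5-min bin.
#' @param baselineRate baseline counts per 5-min bin.
#' @param anticipationRampHours pre-transition ramp duration, hours.
#' @param arrhythmic logical; flatten the rate to its time average.
#' @param deathDay day of death or \code{NA}.
#' @param seed integer RNG seed.
#' @rdname FlyParams-class
#' @examples
#' FlyParams(tauHours = 24.85, seed = 7L)
#' @export
FlyParams <- function(tauHours = 24, phaseOffsetHours = 0,
                      morningAmplitude = 8, eveningAmplitude = 8,
                      baselineRate = 2, anticipationRampHours = 3,
                      arrhythmic = FALSE, deathDay = NA_integer_,
                      seed = 1L) {
  new("FlyParams", tauHours = tauHours, phaseOffsetHours = phaseOffsetHours,
      morningAmplitude = morningAmplitude, eveningAmplitude = eveningAmplitude,
      baselineRate = baselineRate,
      anticipationRampHours = anticipationRampHours,
      arrhythmic = arrhythmic, deathDay = as.integer(deathDay),
      seed = as.integer(seed))
}
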