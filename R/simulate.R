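#' Parameters of a simulated two-group expression experiment
#'
#' Defaults emulate the microarray design the behaviour cohorts are paired
#' with: two genotypes, four biological replicates each, log2-scale
#' intensities with a known differentially expressed subset and
#' missing-at-random entries.
#'
#' @slot nProbes number of probes.
#' @slot nPerGroup replicates per group (>= 2).
#' @slot deFraction proportion of probes differentially expressed.
#' @slot log2Effect log2 fold change of the DE subset (half up, half down).
#' @slot noiseSd within-group standard deviation, log2 scale.
#' @slot naFraction proportion of entries missing at random.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("ExpressionSimParams",
  representation(
    nProbes = "integer", nPerGroup = "integer", deFraction = "numeric",
    log2Effect = "numeric", noiseSd = "numeric", naFraction = "numeric",
    seed = "integer"
  )
)

setValidity("ExpressionSimParams", function(object) {
  msg <- character()
  if (object@deFraction < 0 || object@deFraction > 1)
    msg <- c(msg, "deFraction must lie in [0, 1]")
  if (object@naFraction < 0 || object@naFraction >= 1)
    msg <- c(msg, "naFraction must lie in [0, 1)")
  if (object@nPerGroup < 2L)
    msg <- c(msg, "nPerGroup must be at least 2")
  if (length(msg)) msg else TRUE
})

#' @param nProbes,nPerGroup,deFraction,log2Effect,noiseSd,naFraction,seed
#'   see the slot documentation.
#' @rdname ExpressionSimParams-class
#' @export
ExpressionSimParams <- function(nProbes = 2000L, nPerGroup = 4L,
                                deFraction = 0.05, log2Effect = 2,
                                noiseSd = 0.5, naFraction = 0, seed = 1L) {
  new("ExpressionSimParams", nProbes = as.integer(nProbes),
      nPerGroup = as.integer(nPerGroup), deFraction = deFraction,
      log2Effect = log2Effect, noiseSd = noiseSd, naFraction = naFraction,
      seed = as.integer(seed))
}

# Expected counts per 5-min bin for one fly, evaluated at bin midpoints.
# The crepuscular template places an activity bout at each light transition:
# a linear anticipation ramp rising over `rampH` hours to a peak at the
# transition, then a raised-cosine decay over 1.5 h.  The pre-transition
# mass is therefore entirely the (clock-driven) anticipation ramp; a fly
# simulated with rampH = 0 shows no anticipation, which is what the
# morning-index and anticipation detectors are validated against.
flyRate <- function(params, schedule) {
  nLd <- schedule@nLdDays
  nDd <- schedule@nDdDays
  totalH <- (nLd + nDd) * 24
  nBins <- (nLd + nDd) * 288L
  tMid <- (seq_len(nBins) - 0.5) * (5 / 60)

  tau <- params@tauHours
  halfWidth <- 1.5
  rampH <- params@anticipationRampHours

  eventTimes <- function(anchor) {
    ld <- if (nLd >= 1L) anchor + (seq_len(nLd) - 1L) * 24 else numeric(0L)
    base <- if (nLd >= 1L) anchor + (nLd - 1L) * 24 else anchor - tau
    kMax <- ceiling((totalH - base) / tau) + 1L
    dd <- base + seq_len(kMax) * tau
    c(ld, dd[dd > max(ld, -Inf)])
  }

  bump <- function(t, centres) {
    g <- numeric(length(t))
    for (c0 in centres) {
      d <- t - c0
      inRamp <- rampH > 0 & d >= -rampH & d < 0
      if (rampH > 0)
        g[inRamp] <- pmax(g[inRamp], (d[inRamp] + rampH) / rampH)
      inDecay <- d >= 0 & d <= halfWidth
      g[inDecay] <- pmax(g[inDecay],
                         0.5 * (1 + cos(pi * d[inDecay] / halfWidth)))
    }
    g
  }

  lam <- params@baselineRate +
    params@morningAmplitude * bump(tMid, eventTimes(0)) +
    params@eveningAmplitude *
      bump(tMid, eventTimes(schedule@photoperiodHours +
                              params@phaseOffsetHours))
  if (params@arrhythmic) lam <- rep(mean(lam), length(lam))
  if (!is.na(params@deathDay)) {
    day <- floor((seq_len(nBins) - 1L) / 288L) + 1L
    lam[day >= params@deathDay] <- 0
  }
  lam
}

#' Simulate one fly's activity recording
#'
#' Draws 5-min beam-cross counts from independent Poisson laws whose rate
#' follows a crepuscular template: morning and evening bouts peaking at
#' lights-on and at lights-off plus \code{phaseOffsetHours}, each a linear
#' anticipation ramp followed by a 1.5-h raised-cosine decay.  Under DD the
#' bout centres recur every \code{tauHours} from the last entrained cycle,
#' so a fly with \eqn{\tau \ne 24} drifts by \eqn{\tau - 24} hours per day.
#' Arrhythmic flies keep the same mean rate but lose all temporal structure;
#' \code{deathDay} zeroes activity from that day's start.  Identical seeds
#' give identical series.
#'
#' @param params a \linkS4class{FlyParams}.
#' @param schedule a \linkS4class{LightSchedule}.
#' @param flyId,genotype metadata stamped on the series.
#' @return an \linkS4class{ActivitySeries} at 5-min bins covering the whole
#'   schedule, starting at lights-on of day 1.
#' @examples
#' sch <- LightSchedule("08:00", 12, 3, 7)
#' fly <- simulateFly(FlyParams(seed = 42L), sch)
#' @export
simulateFly <- function(params, schedule, flyId = paste0("sim", params@seed),
                        genotype = "sim") {
  lam <- flyRate(params, schedule)
  counts <- withSeed(params@seed, rpois(length(lam), lam))
  start <- as.POSIXct(paste("2016-01-04", schedule@lightsOn),
                      format = "%Y-%m-%d %H:%M", tz = "UTC")
  ActivitySeries(counts, binMinutes = 5L, startTime = start,
                 flyId = flyId, genotype = genotype)
}

#' Simulate a cohort with a known arrhythmic fraction
#'
#' Generates \code{n} flies from a shared parameter template; exactly
#' \code{round(n * arrhythmicFraction)} of them (chosen by a seeded draw)
#' are arrhythmic.  Fly \code{i} uses seed \code{seed + i}, so a cohort can
#' be extended without changing existing flies.
#'
#' @param n cohort size.
#' @param paramsTemplate a \linkS4class{FlyParams} supplying every per-fly
#'   parameter except \code{arrhythmic} and \code{seed}.
#' @param arrhythmicFraction proportion of arrhythmic flies in [0, 1].
#' @param schedule a \linkS4class{LightSchedule}.
#' @param seed cohort-level seed.
#' @param genotype genotype label.
#' @return list with \code{series} (named list of
#'   \linkS4class{ActivitySeries}) and \code{truth} (data.frame of per-fly
#'   ground truth: fly_id, arrhythmic, tau_hours, death_day).
#' @export
simulateCohort <- function(n, paramsTemplate = FlyParams(),
                           arrhythmicFraction = 0, schedule = LightSchedule(),
                           seed = 1L, genotype = "sim") {
  stopifnot(arrhythmicFraction >= 0, arrhythmicFraction <= 1)
  n <- as.integer(n)
  if (n == 0L)
    return(list(series = list(),
                truth = data.frame(fly_id = character(0L),
                                   arrhythmic = logical(0L),
                                   tau_hours = numeric(0L),
                                   death_day = integer(0L))))
  k <- round(n * arrhythmicFraction)
  arrIdx <- withSeed(seed, sample.int(n, k))
  arrhythmic <- seq_len(n) %in% arrIdx
  ids <- sprintf("%s_f%03d", genotype, seq_len(n))
  series <- lapply(seq_len(n), function(i) {
    p <- paramsTemplate
    p@arrhythmic <- arrhythmic[i]
    p@seed <- as.integer(seed + i)
    simulateFly(p, schedule, flyId = ids[i], genotype = genotype)
  })
  names(series) <- ids
  list(series = series,
       truth = data.frame(fly_id = ids, arrhythmic = arrhythmic,
                          tau_hours = paramsTemplate@tauHours,
                          death_day = paramsTemplate@deathDay))
}

#' Simulate a two-group expression matrix with known truth
#'
#' Per-probe log2 baselines (Normal, mean 8, sd 1.5) plus a group effect of
#' \code{log2Effect} for the DE subset (first half shifted up in the first
#' group, second half down) plus Gaussian noise; a \code{naFraction} of
#' entries is then masked missing completely at random.
#'
#' @param params an \linkS4class{ExpressionSimParams}.
#' @param groupLabels labels for (treated, control) columns.
#' @return list with \code{matrix} (an \linkS4class{ExpressionMatrix}) and
#'   \code{truth} (data.frame: probe_id, de, direction).
#' @export
simulateExpressionMatrix <- function(params = ExpressionSimParams(),
                                     groupLabels = c("oe", "ctrl")) {
  p <- params@nProbes
  nG <- params@nPerGroup
  nDe <- round(p * params@deFraction)
  nUp <- nDe %/% 2L + nDe %% 2L
  direction <- rep("none", p)
  if (nDe > 0L) {
    direction[seq_len(nUp)] <- "up"
    if (nDe > nUp) direction[(nUp + 1L):nDe] <- "down"
  }
  effect <- ifelse(direction == "up", params@log2Effect,
                   ifelse(direction == "down", -params@log2Effect, 0))
  groups <- rep(groupLabels, each = nG)
  vals <- withSeed(params@seed, {
    baseline <- rnorm(p, mean = 8, sd = 1.5)
    m <- baseline +
      outer(effect, as.numeric(groups == groupLabels[1L])) +
      matrix(rnorm(p * 2L * nG, sd = params@noiseSd), nrow = p)
    if (params@naFraction > 0) {
      nMask <- round(length(m) * params@naFraction)
      m[sample.int(length(m), nMask)] <- NA_real_
    }
    m
  })
  probeIds <- sprintf("probe_%05d", seq_len(p))
  rownames(vals) <- probeIds
  colnames(vals) <- paste0(groups, "_", rep(seq_len(nG), times = 2L))
  list(matrix = ExpressionMatrix(vals, groups = groups),
       truth = data.frame(probe_id = probeIds, de = direction != "none",
                          direction = direction))
}

#' Simulate a qRT-PCR Ct table with a known fold change
#'
#' Produces replicate cycle-threshold values for a target and a reference
#' assay in a sample and a calibrator condition.  With zero noise the
#' table's ddCt equals \code{-log2(trueFoldChange)} exactly, so
#' \code{\link{deltaDeltaCt}} recovers the fold change; Gaussian noise of
#' \code{ctNoiseSd} cycles is added independently per well.
#'
#' @param trueFoldChange expression of the target in the sample relative to
#'   the calibrator (> 0).
#' @param nReplicates technical replicates per well.
#' @param ctNoiseSd per-well Gaussian noise, cycles.
#' @param seed integer RNG seed.
#' @return data.frame with columns assay (target/reference), condition
#'   (sample/calibrator), replicate, ct.
#' @export
simulateQpcrCt <- function(trueFoldChange, nReplicates = 3L, ctNoiseSd = 0,
                           seed = 1L) {
  stopifnot(trueFoldChange > 0)
  base <- expand.grid(assay = c("target", "reference"),
                      condition = c("sample", "calibrator"),
                      replicate = seq_len(nReplicates),
                      stringsAsFactors = FALSE)
  ctClean <- with(base, ifelse(assay == "reference", 20,
                        ifelse(condition == "calibrator", 24,
                               24 - log2(trueFoldChange))))
  noise <- withSeed(seed, rnorm(nrow(base), sd = ctNoiseSd))
  base$ct <- ctClean + noise
  base
}
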