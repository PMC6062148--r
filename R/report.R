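#' Per-fly analysis of a cohort
#'
#' Runs the full behavioural chain on every fly: death detection,
#' rhythmicity classification on the free-running days (skipped when the
#' schedule has fewer than 5 DD days), and the LD phase and sleep metrics.
#' Dead flies keep a row (alive = FALSE) with missing metrics so that
#' cohort counts remain auditable, but contribute to no statistic.
#'
#' @param seriesList list of \linkS4class{ActivitySeries} at 5-min bins.
#' @param schedule a \linkS4class{LightSchedule}.
#' @param minTerminalZeroHours death-call threshold, hours.
#' @param alpha,rsThreshold rhythmicity thresholds
#'   (see \code{\link{classifyRhythmicity}}).
#' @param ddDays DD days used for period estimation.
#' @return data.frame, one row per fly.
#' @export
analyzeCohort <- function(seriesList, schedule, minTerminalZeroHours = 24,
                          alpha = 0.01, rsThreshold = 1, ddDays = 2:7) {
  doRhythm <- schedule@nDdDays >= 5L
  rows <- lapply(seriesList, function(s) {
    vital <- detectDeath(s, minTerminalZeroHours)
    base <- data.frame(fly_id = flyId(s), genotype = genotype(s),
                       alive = vital@alive, is_rhythmic = NA,
                       tau_hours = NA_real_, rs = NA_real_,
                       periodogram_pvalue = NA_real_)
    if (!vital@alive) {
      metrics <- data.frame(mi = NA_real_, ma = NA, ea = NA,
                            e_onset_zt = NA_real_, dd_phase_ct = NA_real_,
                            sleep_total_min = NA_real_,
                            sleep_day_min = NA_real_,
                            sleep_night_min = NA_real_)
      return(cbind(base, metrics))
    }
    if (doRhythm) {
      rr <- classifyRhythmicity(s, schedule, ddDays = ddDays, alpha = alpha,
                                rsThreshold = rsThreshold, vital = vital)
      base$is_rhythmic <- rr@isRhythmic
      base$tau_hours <- rr@tauHours
      base$rs <- rr@rs
      base$periodogram_pvalue <- rr@periodogramPvalue
    }
    metrics <- phaseSleepMetrics(s, schedule)
    cbind(base, metrics[, setdiff(names(metrics), "fly_id")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary in the conventional table layout
#'
#' Collapses per-fly results into the one-row-per-genotype summary used for
#' circadian cohorts: counts, percentage rhythmic, free-running period
#' (mean +/- SEM over rhythmic flies only), percentage showing
#' morning/evening anticipation, morning index, evening onset (over flies
#' with a defined onset) and DD phase.  Percentages are over living flies
#' and rounded half-up to 2 decimals; SEM uses the n-1 sample standard
#' deviation.
#'
#' @param perFly data.frame from \code{\link{analyzeCohort}} (or any frame
#'   with the same columns).
#' @param genotype label for the summary row (defaults to the first
#'   genotype present).
#' @return one-row data.frame (a cohort-summary record).
#' @examples
#' flies <- data.frame(alive = rep(TRUE, 108), is_rhythmic = rep(c(TRUE,
#'   FALSE), c(33, 75)))
#' summarizeCohort(flies, genotype = "oe")$pct_rhythmic   # 30.56
#' @export
summarizeCohort <- function(perFly, genotype = NULL) {
  if (is.null(genotype))
    genotype <- if ("genotype" %in% names(perFly) && nrow(perFly))
      perFly$genotype[1L] else "cohort"
  col <- function(nm) if (nm %in% names(perFly)) perFly[[nm]] else
    rep(NA, nrow(perFly))
  alive <- col("alive")
  a <- perFly[!is.na(alive) & alive, , drop = FALSE]
  nTotal <- nrow(perFly)
  nAlive <- nrow(a)
  rhythmic <- !is.na(col("is_rhythmic")[!is.na(alive) & alive]) &
    col("is_rhythmic")[!is.na(alive) & alive]
  nRhythmic <- sum(rhythmic)
  pct <- function(k) if (nAlive == 0L) NA_real_ else
    roundHalfUp(100 * k / nAlive, 2L)
  aCol <- function(nm) if (nm %in% names(a)) a[[nm]] else
    rep(NA_real_, nrow(a))
  tau <- aCol("tau_hours")[rhythmic]
  onset <- aCol("e_onset_zt")
  ddp <- aCol("dd_phase_ct")
  data.frame(
    genotype = genotype,
    n_total = nTotal, n_alive = nAlive, n_rhythmic = nRhythmic,
    pct_rhythmic = pct(nRhythmic),
    tau_mean = if (nRhythmic) mean(tau, na.rm = TRUE) else NA_real_,
    tau_sem = if (nRhythmic) sem(tau) else NA_real_,
    pct_ma = pct(sum(aCol("ma"), na.rm = TRUE)),
    pct_ea = pct(sum(aCol("ea"), na.rm = TRUE)),
    mi_mean = mean(aCol("mi"), na.rm = TRUE),
    mi_sem = sem(aCol("mi")),
    e_onset_mean = mean(onset, na.rm = TRUE),
    e_onset_sem = sem(onset),
    n_onset = sum(!is.na(onset)),
    dd_phase_mean = mean(ddp, na.rm = TRUE),
    dd_phase_sem = sem(ddp))
}

# --- pipeline plumbing -----------------------------------------------------

openRunLog <- function(outDir, name, verbose) {
  path <- file.path(outDir, name)
  con <- file(path, open = "wt")
  list(log = function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    writeLines(line, con)
    if (verbose) message(line)
  }, close = function() close(con), path = path)
}

writeWithHeader <- function(df, path, seed, configHash) {
  writeLines(provenanceHeader(seed, configHash), path)
  suppressWarnings(write.table(df, path, sep = ",", row.names = FALSE,
                               quote = FALSE, append = TRUE,
                               col.names = TRUE))
  invisible(path)
}

loadConfig <- function(config) {
  if (is.character(config)) {
    list(cfg = yaml::read_yaml(config),
         hash = unname(tools::md5sum(config)))
  } else {
    list(cfg = config,
         hash = substr(paste(unlist(config), collapse = "|"), 1L, 0L))
  }
}

# YAML 1.1 parses a bare `n:` key as a boolean, so accept `n_flies`
# (documented), `n`, and the mangled boolean name alike.
normalizeSimKeys <- function(sim) {
  if (is.null(sim$n_flies)) {
    alt <- c(which(names(sim) == "n"), which(names(sim) == "FALSE"))
    if (length(alt)) {
      sim$n_flies <- sim[[alt[1L]]]
      sim[[alt[1L]]] <- NULL
    }
  }
  sim
}

requireKeys <- function(cfg, keys, where) {
  miss <- setdiff(keys, names(cfg))
  if (length(miss))
    stop(sprintf("config validation failed (%s): missing key(s) %s", where,
                 paste(miss, collapse = ", ")))
}

scheduleFromConfig <- function(cfg) {
  requireKeys(cfg, "schedule", "top level")
  s <- cfg$schedule
  requireKeys(s, c("lights_on", "photoperiod_hours", "n_ld_days",
                   "n_dd_days"), "schedule")
  LightSchedule(s$lights_on, s$photoperiod_hours, s$n_ld_days, s$n_dd_days)
}

flyParamsFromConfig <- function(p, seed) {
  getOr <- function(nm, dflt) if (!is.null(p[[nm]])) p[[nm]] else dflt
  FlyParams(tauHours = getOr("tau_hours", 24),
            phaseOffsetHours = getOr("phase_offset_hours", 0),
            morningAmplitude = getOr("morning_amplitude", 8),
            eveningAmplitude = getOr("evening_amplitude", 8),
            baselineRate = getOr("baseline_rate", 2),
            anticipationRampHours = getOr("anticipation_ramp_hours", 3),
            seed = seed)
}

#' Run the behavioural pipeline from a config
#'
#' Orchestrates simulate-or-read, per-fly analysis and cohort summary.  The
#' YAML config names either a \code{simulate} scenario (n, genotype,
#' arrhythmic_fraction, params) or \code{inputs} (monitor files with
#' genotypes, or a per-fly CSV), plus a \code{schedule} block and optional
#' \code{thresholds}.  Outputs (per-fly CSV, cohort-summary CSV, run log)
#' land in \code{outDir}; every file carries a provenance header with
#' package version, seed and config hash, every threshold used is echoed
#' into the log, and an unreadable monitor file is skipped with a logged
#' warning rather than aborting the run.  Deterministic given config and
#' seed.
#'
#' @param config path to a YAML config, or an equivalent list.
#' @param outDir output directory (created if needed).
#' @param seed integer seed for the simulation scenario.
#' @param verbose echo log lines to the console.
#' @return invisibly, a list with \code{perFly}, \code{summary} and the
#'   output paths.
#' @export
runBehaviorPipeline <- function(config, outDir = ".", seed = 1L,
                                verbose = FALSE) {
  cc <- loadConfig(config)
  cfg <- cc$cfg
  schedule <- scheduleFromConfig(cfg)
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config validation failed (top level): missing key(s) ",
         "simulate or inputs")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  lg <- openRunLog(outDir, "behavior_run.log", verbose)
  on.exit(lg$close())
  th <- cfg$thresholds
  getTh <- function(nm, dflt) if (!is.null(th[[nm]])) th[[nm]] else dflt
  alpha <- getTh("alpha", 0.01)
  rsThreshold <- getTh("rs_threshold", 1)
  deathHours <- getTh("death_hours", 24)
  lg$log(sprintf(
    "thresholds: alpha=%g rs_threshold=%g death_hours=%g", alpha,
    rsThreshold, deathHours))
  lg$log(sprintf("schedule: lights_on=%s photoperiod=%gh LD=%d DD=%d",
                 schedule@lightsOn, schedule@photoperiodHours,
                 schedule@nLdDays, schedule@nDdDays))

  series <- list()
  if (!is.null(cfg$simulate)) {
    sim <- normalizeSimKeys(cfg$simulate)
    requireKeys(sim, "n_flies", "simulate")
    tmpl <- flyParamsFromConfig(sim$params, seed = seed)
    genotype <- if (!is.null(sim$genotype)) sim$genotype else "sim"
    frac <- if (!is.null(sim$arrhythmic_fraction))
      sim$arrhythmic_fraction else 0
    lg$log(sprintf("simulating %d flies (%s), arrhythmic fraction %g, seed %d",
                   sim$n_flies, genotype, frac, seed))
    series <- simulateCohort(sim$n_flies, tmpl, frac, schedule, seed = seed,
                             genotype = genotype)$series
  } else {
    for (inp in cfg$inputs) {
      got <- tryCatch({
        if (!is.null(inp$monitor))
          readDamMonitor(inp$monitor, schedule,
                         genotype = if (!is.null(inp$genotype))
                           inp$genotype else "unknown")
        else if (!is.null(inp$fly_csv)) readFlyCsv(inp$fly_csv)
        else stop("input entry needs 'monitor' or 'fly_csv'")
      }, error = function(e) {
        lg$log(paste("WARNING: skipping input:", conditionMessage(e)))
        NULL
      })
      if (!is.null(got)) series <- c(series, got)
    }
  }
  if (!length(series)) stop("no readable input series")
  lg$log(sprintf("analyzing %d flies", length(series)))
  perFly <- analyzeCohort(series, schedule,
                          minTerminalZeroHours = deathHours,
                          alpha = alpha, rsThreshold = rsThreshold)
  summaries <- do.call(rbind, lapply(split(perFly, perFly$genotype),
                                     summarizeCohort))
  perFlyPath <- writeWithHeader(perFly, file.path(outDir, "per_fly.csv"),
                                seed, cc$hash)
  summaryPath <- writeWithHeader(summaries,
                                 file.path(outDir, "cohort_summary.csv"),
                                 seed, cc$hash)
  lg$log(sprintf("wrote %s and %s", perFlyPath, summaryPath))
  invisible(list(perFly = perFly, summary = summaries,
                 paths = c(perFlyPath, summaryPath, lg$path)))
}

#' Run the expression pipeline from a config
#'
#' Fixed stage order: probe filter, quantile normalization, two-class SAM,
#' overlap with a predicted-target list, hypergeometric enrichment.  The
#' config names a tab-delimited \code{matrix} file or a \code{simulate}
#' block, optional \code{targets} list, and \code{sam} settings
#' (\code{target_fdr} or \code{delta}, \code{n_permutations}).  Enrichment
#' is skipped (and logged) when SAM calls no probes or no target list is
#' given.
#'
#' @inheritParams runBehaviorPipeline
#' @return invisibly, a list with the \linkS4class{SamResult}, the SAM
#'   table, the enrichment report (or NULL) and output paths.
#' @export
runExpressionPipeline <- function(config, outDir = ".", seed = 1L,
                                  verbose = FALSE) {
  cc <- loadConfig(config)
  cfg <- cc$cfg
  if (is.null(cfg$matrix) && is.null(cfg$simulate))
    stop("config validation failed (top level): missing key(s) ",
         "matrix or simulate")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  lg <- openRunLog(outDir, "expression_run.log", verbose)
  on.exit(lg$close())

  truth <- NULL
  if (!is.null(cfg$matrix)) {
    em <- readExpressionMatrix(cfg$matrix, groups = unlist(cfg$groups))
    lg$log(sprintf("read %d probes x %d samples from %s", nrow(em),
                   ncol(em), cfg$matrix))
  } else {
    sim <- cfg$simulate
    getOr <- function(nm, dflt) if (!is.null(sim[[nm]])) sim[[nm]] else dflt
    params <- ExpressionSimParams(
      nProbes = getOr("n_probes", 2000L),
      nPerGroup = getOr("n_per_group", 4L),
      deFraction = getOr("de_fraction", 0.05),
      log2Effect = getOr("log2_effect", 2),
      noiseSd = getOr("noise_sd", 0.5),
      naFraction = getOr("na_fraction", 0), seed = seed)
    simOut <- simulateExpressionMatrix(params)
    em <- simOut$matrix
    truth <- simOut$truth
    lg$log(sprintf("simulated %d probes x %d samples (seed %d)",
                   nrow(em), ncol(em), seed))
  }
  samCfg <- cfg$sam
  getSam <- function(nm, dflt) if (!is.null(samCfg[[nm]])) samCfg[[nm]] else
    dflt
  targetFdr <- getSam("target_fdr", 0.07)
  nPerm <- getSam("n_permutations", 1000L)
  delta <- getSam("delta", NULL)
  lg$log(sprintf("sam: target_fdr=%g n_permutations=%d delta=%s",
                 targetFdr, nPerm,
                 if (is.null(delta)) "auto" else format(delta)))

  em <- filterProbes(em)
  lg$log(sprintf("%d probes survive the 50%% NA filter", nrow(em)))
  em <- quantileNormalize(em)
  sam <- samTwoClass(em, nPermutations = nPerm, delta = delta,
                     targetFdr = targetFdr, seed = seed)
  called <- significantProbes(sam)
  lg$log(sprintf("SAM: s0=%.4g delta=%.3g, %d up / %d down, FDR=%.3g",
                 sam@s0, sam@delta, length(called$up), length(called$down),
                 sam@fdrEstimate))
  samTable <- data.frame(
    probe_id = names(dScores(sam)), d = unname(dScores(sam)),
    called = names(dScores(sam)) %in% c(called$up, called$down),
    direction = ifelse(names(dScores(sam)) %in% called$up, "up",
                ifelse(names(dScores(sam)) %in% called$down, "down",
                       "none")))
  samPath <- writeWithHeader(samTable, file.path(outDir, "sam_results.csv"),
                             seed, cc$hash)

  enrichment <- NULL
  allCalled <- c(called$up, called$down)
  if (!is.null(cfg$targets) && length(allCalled)) {
    targets <- readTargetList(cfg$targets)
    overlap <- intersect(allCalled, targets)
    enrichment <- list(
      universe = nrow(em), annotated = length(intersect(targets,
                                                        rownames(em))),
      drawn = length(allCalled), overlap = length(overlap),
      p_value = hypergeometricEnrichment(
        N = nrow(em), K = length(intersect(targets, rownames(em))),
        n = length(allCalled), k = length(overlap)),
      overlap_genes = overlap)
    lg$log(sprintf("enrichment: overlap %d, p = %.4g", length(overlap),
                   enrichment$p_value))
    jsonlite::write_json(enrichment,
                         file.path(outDir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    lg$log("enrichment skipped (no target list or zero probes called)")
  }
  invisible(list(sam = sam, samTable = samTable, enrichment = enrichment,
                 truth = truth, paths = samPath))
}
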