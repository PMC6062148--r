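test_that("cohort percentages recompute from integer counts", {
  mkFlies <- function(nAlive, nRhythmic, nDead = 0L)
    data.frame(alive = rep(c(TRUE, FALSE), c(nAlive, nDead)),
               is_rhythmic = c(rep(c(TRUE, FALSE),
                                   c(nRhythmic, nAlive - nRhythmic)),
                               rep(NA, nDead)))
  expect_equal(summarizeCohort(mkFlies(108L, 33L, 29L))$pct_rhythmic, 30.56)
  expect_equal(summarizeCohort(mkFlies(91L, 62L, 4L))$pct_rhythmic, 68.13)
  zero <- summarizeCohort(mkFlies(10L, 0L))
  expect_equal(zero$pct_rhythmic, 0)
  expect_true(is.na(zero$tau_mean))
  allDead <- summarizeCohort(data.frame(alive = rep(FALSE, 3L),
                                        is_rhythmic = NA))
  expect_true(is.na(allDead$pct_rhythmic))
  # tau statistics run over rhythmic flies only
  flies <- data.frame(alive = TRUE, is_rhythmic = c(TRUE, TRUE, FALSE),
                      tau_hours = c(24, 25, NA))
  s <- summarizeCohort(flies)
  expect_equal(s$tau_mean, 24.5)
  expect_equal(s$tau_sem, sd(c(24, 25)) / sqrt(2))
})

test_that("the behaviour pipeline is deterministic and complete", {
  cfgFile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "schedule:", "  lights_on: '08:00'", "  photoperiod_hours: 12",
    "  n_ld_days: 3", "  n_dd_days: 7",
    "simulate:", "  n_flies: 6", "  genotype: simA",
    "  arrhythmic_fraction: 0.5"), cfgFile)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  r1 <- runBehaviorPipeline(cfgFile, out1, seed = 9L)
  r2 <- runBehaviorPipeline(cfgFile, out2, seed = 9L)
  expect_identical(r1$perFly, r2$perFly)
  expect_identical(r1$summary, r2$summary)
  expect_true(file.exists(file.path(out1, "per_fly.csv")))
  expect_true(file.exists(file.path(out1, "cohort_summary.csv")))
  expect_true(file.exists(file.path(out1, "behavior_run.log")))
  # provenance header carries version + seed; thresholds echoed in the log
  expect_match(readLines(file.path(out1, "per_fly.csv"))[1L],
               "circafly.*seed: 9")
  expect_match(paste(readLines(file.path(out1, "behavior_run.log")),
                     collapse = "\n"), "alpha=0.01")
  expect_equal(nrow(r1$summary), 1L)
  expect_equal(r1$summary$n_total, 6L)
  # arrhythmic fraction 0.5 -> about half classified rhythmic
  expect_equal(r1$summary$n_rhythmic, 3L)
})

test_that("an LD-only config yields LD metrics and no DD metrics", {
  cfg <- list(schedule = list(lights_on = "08:00", photoperiod_hours = 12,
                              n_ld_days = 3L, n_dd_days = 0L),
              simulate = list(n = 3L, genotype = "ldonly"))
  out <- withr::local_tempdir()
  r <- runBehaviorPipeline(cfg, out, seed = 4L)
  expect_true(all(is.na(r$perFly$is_rhythmic)))
  expect_true(all(is.na(r$perFly$dd_phase_ct)))
  expect_false(anyNA(r$perFly$mi))
  expect_false(anyNA(r$perFly$sleep_total_min))
})

test_that("config validation reports all missing keys at once", {
  cfg <- list(schedule = list(lights_on = "08:00"))
  expect_error(runBehaviorPipeline(cfg, withr::local_tempdir()),
               "photoperiod_hours.*n_ld_days.*n_dd_days")
  expect_error(runBehaviorPipeline(list(schedule = list(
    lights_on = "08:00", photoperiod_hours = 12, n_ld_days = 3L,
    n_dd_days = 7L)), withr::local_tempdir()), "simulate or inputs")
})

test_that("unreadable monitors are skipped with a logged warning", {
  sch <- stdSchedule()
  goodFile <- withr::local_tempfile(fileext = ".txt")
  coh <- simulateCohort(2L, FlyParams(), 0, sch, seed = 8L)
  writeDamMonitor(coh$series, goodFile)
  cfg <- list(schedule = list(lights_on = "08:00", photoperiod_hours = 12,
                              n_ld_days = 3L, n_dd_days = 7L),
              inputs = list(list(monitor = goodFile),
                            list(monitor = "/nonexistent/monitor.txt")))
  out <- withr::local_tempdir()
  r <- suppressWarnings(runBehaviorPipeline(cfg, out, seed = 1L))
  expect_match(paste(readLines(file.path(out, "behavior_run.log")),
                     collapse = "\n"), "WARNING: skipping input")
  expect_equal(sum(r$perFly$alive), 2L)
})

test_that("the expression pipeline runs filter-normalize-SAM-enrichment", {
  targetsFile <- withr::local_tempfile(fileext = ".txt")
  sim <- simulateExpressionMatrix(ExpressionSimParams(seed = 5L))
  writeLines(sim$truth$probe_id[sim$truth$de], targetsFile)
  cfg <- list(simulate = list(n_probes = 2000L, de_fraction = 0.05,
                              log2_effect = 2, noise_sd = 0.5),
              targets = targetsFile,
              sam = list(target_fdr = 0.10))
  out <- withr::local_tempdir()
  r <- runExpressionPipeline(cfg, out, seed = 5L)
  called <- r$samTable$probe_id[r$samTable$called]
  trueDe <- sim$truth$probe_id[sim$truth$de]
  # overlap k equals the number of called true positives
  expect_equal(r$enrichment$overlap, length(intersect(called, trueDe)))
  expect_lt(r$enrichment$p_value, 1e-10)
  expect_true(file.exists(file.path(out, "sam_results.csv")))
  expect_true(file.exists(file.path(out, "enrichment.json")))
  # deterministic rerun
  r2 <- runExpressionPipeline(cfg, withr::local_tempdir(), seed = 5L)
  expect_identical(r$samTable, r2$samTable)

  # null matrix: nothing called at a tight delta -> enrichment skipped
  cfgNull <- list(simulate = list(n_probes = 300L, de_fraction = 0),
                  targets = targetsFile, sam = list(delta = 2))
  outN <- withr::local_tempdir()
  rN <- runExpressionPipeline(cfgNull, outN, seed = 6L)
  expect_null(rN$enrichment)
  expect_match(paste(readLines(file.path(outN, "expression_run.log")),
                     collapse = "\n"), "enrichment skipped")
})

test_that("the CLI writes simulated cohorts in monitor format", {
  cfgFile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "schedule:", "  lights_on: '08:00'", "  photoperiod_hours: 12",
    "  n_ld_days: 1", "  n_dd_days: 1",
    "simulate:", "  n_flies: 3", "  genotype: cliA"), cfgFile)
  out <- withr::local_tempdir()
  circaflyCli(c("simulate", "--config", cfgFile, "--seed", "2",
                "--out", out))
  expect_true(file.exists(file.path(out, "Monitor01.txt")))
  expect_true(file.exists(file.path(out, "truth.csv")))
  sch <- stdSchedule(1L, 1L)
  back <- suppressWarnings(readDamMonitor(file.path(out, "Monitor01.txt"),
                                          sch))
  direct <- simulateCohort(3L, FlyParams(), 0, sch, seed = 2L)
  expect_identical(activityCounts(back[[1L]]),
                   activityCounts(direct$series[[1L]]))
})
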