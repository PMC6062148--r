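test_that("monitor files parse into one series per channel", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  stamps <- stdStart() + (0:11) * 300
  rows <- sapply(seq_along(stamps), function(i) {
    counts <- rep(0L, 32L)
    counts[1L] <- i          # channel 1 active
    counts[2L] <- 2L * i     # channel 2 active
    paste(c(i, format(stamps[i], "%Y-%m-%d"), format(stamps[i], "%H:%M:%S"),
            rep("0", 7L), counts), collapse = "\t")
  })
  writeLines(rows, tmp)
  expect_warning(series <- readDamMonitor(tmp, stdSchedule()),
                 "no activity")
  expect_length(series, 32L)
  expect_equal(binMinutes(series[[1L]]), 5L)
  expect_equal(activityCounts(series[[1L]]), 1:12)
  expect_equal(activityCounts(series[[2L]]), 2L * (1:12))
  flagged <- attr(series, "allZero")
  expect_false(any(flagged[1:2]))
  expect_true(all(flagged[3:32]))
})

test_that("malformed monitor rows raise parse errors naming the line", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  stamps <- stdStart() + (0:2) * 300
  mkRow <- function(i, c1) paste(c(i, format(stamps[i], "%Y-%m-%d"),
                                   format(stamps[i], "%H:%M:%S"),
                                   rep("0", 7L), c1, rep(0L, 31L)),
                                 collapse = "\t")
  writeLines(c(mkRow(1L, "3"), mkRow(2L, "NA"), mkRow(3L, "1")), tmp)
  expect_error(readDamMonitor(tmp, stdSchedule()), "line 2.*NA")

  # non-constant time step
  tmp2 <- withr::local_tempfile(fileext = ".txt")
  bad <- stdStart() + c(0, 300, 900)
  writeLines(sapply(1:3, function(i) paste(
    c(i, format(bad[i], "%Y-%m-%d"), format(bad[i], "%H:%M:%S"),
      rep("0", 7L), rep(1L, 32L)), collapse = "\t")), tmp2)
  expect_error(readDamMonitor(tmp2, stdSchedule()), "non-constant time step")
})

test_that("write/read round trips preserve counts exactly", {
  sch <- stdSchedule(nLd = 1L, nDd = 0L)
  coh <- simulateCohort(3L, FlyParams(), 0, sch, seed = 42L)
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeDamMonitor(coh$series, tmp)
  back <- suppressWarnings(readDamMonitor(tmp, sch))
  for (i in 1:3)
    expect_identical(activityCounts(back[[i]]),
                     activityCounts(coh$series[[i]]))
  # per-fly CSV round trip keeps counts and metadata
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeFlyCsv(coh$series, tmp2)
  back2 <- readFlyCsv(tmp2)
  ids <- sort(names(coh$series))
  for (id in ids) {
    expect_identical(activityCounts(back2[[id]]),
                     activityCounts(coh$series[[id]]))
    expect_identical(genotype(back2[[id]]), genotype(coh$series[[id]]))
  }
})

test_that("rebin sums constituent bins and conserves totals", {
  s <- series5(c(1L, 0L, 2L, 0L, 0L, 3L))
  expect_equal(activityCounts(rebin(s, 30)), 6L)
  expect_identical(rebin(s, 5), s)
  expect_error(rebin(s, 7), "multiple")
  expect_warning(out <- rebin(series5(rep(1L, 8L)), 30),
                 "truncating")
  expect_equal(activityCounts(out), 6L)
  # conservation over random simulated flies with even lengths
  for (seed in 1:5) {
    fly <- simulateFly(FlyParams(seed = seed), stdSchedule(1L, 1L))
    expect_equal(sum(activityCounts(rebin(fly, 30))),
                 sum(activityCounts(fly)))
  }
})

test_that("Zeitgeber mapping anchors ZT0 at lights-on and is 24h-periodic", {
  sch <- stdSchedule()
  at <- function(s) as.POSIXct(s, tz = "UTC")
  expect_equal(toZeitgeber(at("2016-01-04 09:30:00"), sch), 1.5)
  expect_equal(toZeitgeber(at("2016-01-04 07:00:00"), sch), 23.0)
  expect_equal(toZeitgeber(at("2016-01-05 08:00:00"), sch), 0.0)
  stamps <- at("2016-01-04 00:00:00") + seq(0, 3600 * 50, by = 1800)
  zt <- toZeitgeber(stamps, sch)
  expect_true(all(zt >= 0 & zt < 24))
  expect_equal(toZeitgeber(stamps + 86400, sch), zt)
})

test_that("death detection flags terminal immobility only", {
  sch <- stdSchedule()
  nDay <- 288L
  active <- series5(rep(c(1L, 0L), 5L * nDay / 2L))
  expect_true(detectDeath(active)@alive)
  # final 30 h of zeros -> dead, death at end of last active bin
  x <- c(rep(1L, 2L * nDay), rep(0L, 360L))
  dead <- series5(x)
  vs <- detectDeath(dead)
  expect_false(vs@alive)
  expect_equal(vs@deathTime, stdStart() + 2L * nDay * 300)
  # a 30-h zero run mid-recording followed by activity -> alive
  revived <- series5(c(rep(1L, nDay), rep(0L, 360L), rep(1L, nDay)))
  expect_true(detectDeath(revived)@alive)
  # never active at all -> death at recording start
  silent <- series5(rep(0L, 2L * nDay))
  expect_equal(detectDeath(silent)@deathTime, stdStart())
})

test_that("light schedules load from YAML configs", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("schedule:", "  lights_on: '09:00'", "  photoperiod_hours: 12",
               "  n_ld_days: 3", "  n_dd_days: 7"), tmp)
  sch <- readLightSchedule(tmp)
  expect_s4_class(sch, "LightSchedule")
  expect_equal(sch@lightsOn, "09:00")
  expect_equal(sch@nDdDays, 7L)
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("lights_on: '08:00'", tmp2)
  expect_error(readLightSchedule(tmp2),
               "photoperiod_hours.*n_ld_days.*n_dd_days")
})
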