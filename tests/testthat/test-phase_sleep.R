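test_that("average day profiles fold days onto the Zeitgeber grid", {
  sch <- stdSchedule()
  const <- series30(rep(5L, 10L * 48L))
  p <- averageDayProfile(const, 1:3, sch)
  expect_equal(profileValues(p), rep(5, 48L))
  twoDays <- series30(c(rep(2L, 48L), rep(4L, 48L)),
                      schedule = stdSchedule(2L, 0L))
  p2 <- averageDayProfile(twoDays, 1:2, sch)
  expect_equal(profileValues(p2), rep(3, 48L))
  p1 <- averageDayProfile(twoDays, 2L, sch)
  expect_equal(profileValues(p1), rep(4, 48L))
  expect_error(averageDayProfile(twoDays, 5L, sch), "outside the recording")
})

test_that("morning index contrasts the two pre-dawn blocks", {
  p <- profileWith(1, list(18, 21, 10), list(21, 24, 20))
  expect_equal(morningIndex(p), 10 / 30)
  expect_equal(morningIndex(mkProfile(rep(7, 48L))), 0)
  expect_equal(morningIndex(profileWith(0, list(21, 24, 5))), 1)
  expect_equal(morningIndex(mkProfile(rep(0, 48L))), 0)
  # antisymmetry: swapping the ZT18-21 and ZT21-24 blocks negates MI
  q <- profileWith(1, list(18, 21, 20), list(21, 24, 10))
  expect_equal(morningIndex(q), -morningIndex(p))
})

test_that("anticipation requires a rising pre-transition bout", {
  expect_true(detectAnticipation(
    profileWith(0, list(21, 22, 2), list(22, 23, 5), list(23, 24, 9)),
    "lights-on"))
  expect_false(detectAnticipation(
    profileWith(0, list(21, 24, 5)), "lights-on"))
  expect_false(detectAnticipation(
    profileWith(0, list(21, 22, 9), list(22, 23, 5), list(23, 24, 2)),
    "lights-on"))
  # evening window sits before lights-off
  expect_true(detectAnticipation(
    profileWith(0, list(9, 10, 2), list(10, 11, 5), list(11, 12, 9)),
    "lights-off"))
})

test_that("anticipation detection separates ramped from flat cohorts", {
  sch <- stdSchedule()
  prof <- function(p) averageDayProfile(simulateFly(p, sch), 1:3, sch)
  ramped <- sapply(1:15, function(i)
    detectAnticipation(prof(FlyParams(seed = 1000L + i)), "lights-on"))
  flat <- sapply(1:15, function(i)
    detectAnticipation(prof(FlyParams(anticipationRampHours = 0,
                                      seed = 2000L + i)), "lights-on"))
  expect_gte(mean(ramped), 0.9)       # recall on 3-h ramps
  expect_gte(mean(!flat), 0.9)        # specificity on ramp-free flies
})

test_that("evening onset follows the manual rest-then-rise rule", {
  # rest at ZT5-7.5, rise 1,3,6,10 to a peak of 12 at ZT9.5
  v <- rep(0, 48L); zt <- (0:47) * 0.5
  v[zt < 1.5] <- 8           # morning bout
  v[zt >= 1.5 & zt < 5] <- 4 # midday, above the rest threshold
  v[zt >= 5 & zt < 7.5] <- 0 # siesta
  v[zt == 7.5] <- 1; v[zt == 8] <- 3; v[zt == 8.5] <- 6; v[zt == 9] <- 10
  v[zt == 9.5] <- 12
  v[zt >= 10 & zt < 12] <- 5
  expect_equal(eveningOnset(mkProfile(v)), 7.5)

  # one interior zero bin is tolerated: run 1,0,4,9 starts at the '1'
  w <- v; w[zt == 8] <- 0; w[zt == 8.5] <- 4; w[zt == 9] <- 9
  w[zt == 9.5] <- 12
  expect_equal(eveningOnset(mkProfile(w)), 7.5)

  # monotone flat profile: no rest, no rise, no onset
  expect_true(is.na(eveningOnset(mkProfile(rep(6, 48L)))))
  # no rest before the rise: onset rejected
  u <- v; u[zt >= 5 & zt < 7.5] <- 4
  expect_true(is.na(eveningOnset(mkProfile(u))))
})

test_that("cohorts with shifted evening templates separate in onset", {
  sch <- stdSchedule()
  prof <- function(p) averageDayProfile(simulateFly(p, sch), 1:3, sch)
  onA <- sapply(1:12, function(i)
    eveningOnset(prof(FlyParams(phaseOffsetHours = -1.5, seed = 3000L + i))))
  onB <- sapply(1:12, function(i)
    eveningOnset(prof(FlyParams(phaseOffsetHours = 0, seed = 4000L + i))))
  sep <- mean(onB, na.rm = TRUE) - mean(onA, na.rm = TRUE)
  expect_lt(abs(sep - 1.5), 0.5)
})

test_that("DD phase reads the smoothed fourth-day activity peak", {
  sch <- stdSchedule()
  x <- rep(0L, 10L * 48L)
  day4 <- (3L + 3L) * 48L          # start of DD day 4 (recording day 7)
  x[day4 + 30:32] <- c(5L, 10L, 5L)  # burst centred at CT15 (bin 31)
  s <- series30(x)
  expect_equal(ddPhase(s, sch), 15.0)
  expect_true(is.na(ddPhase(series30(rep(0L, 10L * 48L)), sch)))
  # width-1 smoothing equals the raw argmax
  y <- x; y[day4 + 10] <- 20L
  expect_equal(ddPhase(series30(y), sch, smoothBins = 1L),
               (10 - 1) * 0.5)
})

test_that("sleep is five minutes per zero bin, split by light phase", {
  sch <- stdSchedule()
  allZero <- series5(rep(0L, 5L * 288L))
  expect_equal(sleepSummary(allZero, sch, day = 1L),
               c(total = 1440, day = 720, night = 720))
  alt <- series5(rep(c(1L, 0L), 288L))
  expect_equal(sleepSummary(alt, sch, day = 1L)[["total"]], 720)
  oneNap <- series5(c(rep(1L, 100L), rep(0L, 6L), rep(1L, 288L - 106L),
                      rep(1L, 288L)))
  expect_equal(sleepSummary(oneNap, sch, day = 1L)[["total"]], 30)
  expect_error(sleepSummary(series30(rep(0L, 480L)), sch, 1L), "5-min")
  # sleep and active bins partition the day, for any simulated fly
  for (seed in 1:4) {
    fly <- simulateFly(FlyParams(seed = seed), sch)
    sl <- sleepSummary(fly, sch, day = 2L)
    dayBins <- activityCounts(circafly:::sliceDays(fly, sch, 2L))
    expect_equal(sl[["total"]] + 5 * sum(dayBins > 0L), 1440)
    expect_equal(sl[["total"]], sl[["day"]] + sl[["night"]])
  }
})
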