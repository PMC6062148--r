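# Shared fixtures, built in code at test time.

stdSchedule <- function(nLd = 3L, nDd = 7L)
  LightSchedule("08:00", 12, nLdDays = nLd, nDdDays = nDd)

stdStart <- function(lightsOn = "08:00")
  as.POSIXct(paste("2016-01-04", lightsOn), format = "%Y-%m-%d %H:%M",
             tz = "UTC")

# DayProfile from 48 half-hour values (ZT 0, 0.5, ..., 23.5).
mkProfile <- function(values, nDays = 3L)
  new("DayProfile", values = as.numeric(values), binHours = 0.5,
      nDaysAveraged = as.integer(nDays))

# DayProfile with a default level, overridden on ZT windows:
# ... are lists list(from, to, value) with [from, to) in ZT hours.
profileWith <- function(default = 0, ...) {
  v <- rep(default, 48L)
  zt <- (0:47) * 0.5
  for (blk in list(...))
    v[zt >= blk[[1L]] & zt < blk[[2L]]] <- blk[[3L]]
  mkProfile(v)
}

# A 30-min-bin series covering the full schedule, from explicit counts.
series30 <- function(counts, schedule = stdSchedule())
  ActivitySeries(counts, binMinutes = 30L, startTime = stdStart())

# A 5-min-bin series covering `days` days, from explicit counts.
series5 <- function(counts)
  ActivitySeries(counts, binMinutes = 5L, startTime = stdStart())

# Independent enumeration oracle for the hypergeometric upper tail:
# exact combinatorial sum, deliberately not phyper().
enumHyperTail <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
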