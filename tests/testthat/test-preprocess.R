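cfg <- study_config()

counts_stream <- function(counts, start = "2013-12-03 08:00:00") {
  list(ts = as.POSIXct(start, tz = "UTC") + 15 * (seq_along(counts) - 1),
       counts = counts)
}

test_that("the 60-min zero rule is boundary-inclusive", {
  s59 <- counts_stream(c(100, rep(0, 59 * 4), 100))
  expect_equal(nrow(detect_non_wear(s59$ts, s59$counts, cfg)), 0)

  s60 <- counts_stream(c(100, rep(0, 60 * 4), 100))
  nw <- detect_non_wear(s60$ts, s60$counts, cfg)
  expect_equal(nrow(nw), 1)
  expect_equal(nw$minutes, 60)

  s90 <- counts_stream(c(rep(0, 90 * 4), 100))
  expect_equal(detect_non_wear(s90$ts, s90$counts, cfg)$minutes, 90)
})

test_that("non-wear intervals are disjoint, maximal, and cover with wear", {
  for (seed in 1:15) {
    set.seed(seed)
    counts <- sample(c(0L, 0L, 0L, 50L), 2000, TRUE)
    # splice in guaranteed long zero-runs
    at <- sample(1:1500, 2)
    counts[at[1]:(at[1] + 300)] <- 0L
    s <- counts_stream(counts)
    nw <- detect_non_wear(s$ts, s$counts, cfg)
    if (nrow(nw) > 1) {
      expect_true(all(diff(as.numeric(nw$start)) > 0))
      expect_true(all(utils::head(nw$end, -1) < utils::tail(nw$start, -1)))
    }
    # maximality: epochs adjacent to an interval are non-zero
    for (i in seq_len(nrow(nw))) {
      before <- s$counts[match(as.numeric(nw$start[i]) - 15, as.numeric(s$ts))]
      after <- s$counts[match(as.numeric(nw$end[i]) + 15, as.numeric(s$ts))]
      expect_true(is.na(before) || before > 0)
      expect_true(is.na(after) || after > 0)
    }
    wear <- wear_indicator(s$ts, s$counts, cfg)
    in_nw <- rep(FALSE, length(counts))
    for (i in seq_len(nrow(nw))) {
      in_nw[s$ts >= nw$start[i] & s$ts <= nw$end[i]] <- TRUE
    }
    expect_equal(wear, !in_nw)              # union covers all count epochs
  }
})

test_that("non-wear equals the running-window oracle on random streams", {
  for (seed in 1:200) {
    set.seed(seed)
    n <- sample(300:800, 1)
    counts <- sample(c(0L, 1L), n, TRUE, prob = c(0.85, 0.15))
    eidx <- cumsum(1 + (runif(n) < 0.005) * sample(1:50, n, TRUE))
    ts <- as.POSIXct("2013-12-03", tz = "UTC") + eidx * 15
    nw <- detect_non_wear(ts, counts, cfg)
    impl <- rep(FALSE, n)
    for (i in seq_len(nrow(nw))) impl[ts >= nw$start[i] & ts <= nw$end[i]] <- TRUE
    expect_equal(impl, oracle_nonwear_indicator(eidx, counts, cfg))
  }
})

test_that("valid days require 9 h of simultaneous wear and fix, not day 1", {
  base <- as.POSIXct("2013-12-02 07:00:00", tz = "UTC")   # a Monday
  mk_day <- function(day, n_ep, with_fix = n_ep) {
    ts <- base + 86400 * day + 15 * (0:(n_ep - 1))
    data.frame(participant_id = "P1", timestamp = ts,
               lat = c(rep(51, with_fix), rep(NA, n_ep - with_fix)),
               lon = c(rep(3.7, with_fix), rep(NA, n_ep - with_fix)),
               speed_kmh = c(rep(0, with_fix), rep(NA, n_ep - with_fix)),
               counts = 100L)
  }
  ep <- rbind(mk_day(0, 12 * 240),          # day 1: 12 h -> excluded anyway
              mk_day(1, 9 * 240),           # exactly 9 h -> valid
              mk_day(2, 8 * 240),           # 8 h -> invalid
              mk_day(3, 10 * 240, with_fix = 6 * 240))  # 10 h wear, 6 h fix
  wd <- flag_valid_days(ep, cfg)
  expect_equal(wd$is_valid, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(wd$is_first_day[1])
  expect_equal(wd$combined_wear_minutes[4], 360)
})

test_that("inclusion needs four valid days with at least one weekend day", {
  mk_wd <- function(id, dates, valid) {
    d <- as.Date(dates)
    data.frame(participant_id = id, date = d, combined_wear_minutes = 600,
               is_weekend = format(d, "%u") %in% c("6", "7"),
               is_first_day = FALSE, is_valid = valid)
  }
  wd <- rbind(
    mk_wd("A", c("2013-12-03", "2013-12-04", "2013-12-05", "2013-12-06"), TRUE),
    mk_wd("B", c("2013-12-03", "2013-12-04", "2013-12-05", "2013-12-07"), TRUE))
  inc <- include_participants(wd, cfg)
  expect_equal(inc$included[inc$participant_id == "A"], FALSE)  # no weekend day
  expect_equal(inc$included[inc$participant_id == "B"], TRUE)   # 3 week + 1 weekend
})

test_that("wear monotonicity: turning zero counts into activity never lowers combined wear", {
  set.seed(9)
  n <- 5000
  ts <- as.POSIXct("2013-12-03 07:00:00", tz = "UTC") + 15 * (0:(n - 1))
  counts <- sample(c(0L, 0L, 60L), n, TRUE)
  ep <- data.frame(participant_id = "P1", timestamp = ts, lat = 51, lon = 3.7,
                   speed_kmh = 0, counts = counts)
  before <- flag_valid_days(ep, cfg)$combined_wear_minutes
  flip <- sample(which(counts == 0), 200)
  ep$counts[flip] <- 80L
  after <- flag_valid_days(ep, cfg)$combined_wear_minutes
  expect_true(all(after >= before))
})

test_that("cohort inclusion equals the manifest prediction", {
  sim <- sim_noisy()
  ep <- sim_epochs(sim)
  wd <- flag_valid_days(ep, sim$study_config)
  inc <- include_participants(wd, sim$study_config)
  m <- sim$manifest$inclusion
  expect_equal(inc$included, m$included[match(inc$participant_id, m$participant_id)])
  mwd <- sim$manifest$weardays
  j <- merge(wd, mwd, by = c("participant_id", "date"))
  expect_equal(j$is_valid.x, j$is_valid.y)
  expect_lt(max(abs(j$combined_wear_minutes.x - j$combined_wear_minutes.y)), 3)
})
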