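cfg1 <- study_config(smooth_window = 1)

make_epochs <- function(speeds, id = "P1") {
  stream_to_epochs(seq_along(speeds), speeds, id = id)
}

test_that("epoch speeds classify into the documented bands", {
  expect_equal(classify_epoch_speed(c(0.5, 0.99, 1, 5, 9.99), cfg1),
               c("stationary", "stationary", "walk_band", "walk_band", "walk_band"))
  expect_equal(classify_epoch_speed(c(10, 24.99, 25, 60), cfg1),
               c("cycle_band", "cycle_band", "passive_band", "passive_band"))
  expect_equal(classify_epoch_speed(NA_real_, cfg1), "stationary")
  expect_error(classify_epoch_speed(-1, cfg1), "negative")
})

test_that("running-median smoothing removes isolated spikes and preserves constants", {
  x <- rep(5, 41)
  expect_identical(smooth_speeds(x, 1), x)
  expect_equal(smooth_speeds(x, 5), x)
  x[21] <- 80
  expect_equal(smooth_speeds(x, 5), rep(5, 41))
  y <- c(rep(2, 10), NA, rep(2, 10))
  expect_true(is.na(smooth_speeds(y, 5)[11]))
  expect_error(smooth_speeds(x, 4), "odd")
})

test_that("pauses within the 5-min allowance merge, longer pauses split", {
  sp <- c(rep(5, 40), rep(0, 16), rep(5, 40))          # 10 min, 4-min pause, 10 min
  tr <- detect_trips(make_epochs(sp), cfg1)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$mode, "walk")
  expect_equal(tr$duration_min, 24)

  sp2 <- c(rep(5, 40), rep(0, 24), rep(5, 40))         # 6-min pause
  tr2 <- detect_trips(make_epochs(sp2), cfg1)
  expect_equal(nrow(tr2), 2)
  expect_equal(tr2$duration_min, c(10, 10))
  expect_equal(tr2$mode, c("walk", "walk"))

  sp3 <- c(rep(0, 40), rep(20, 10), rep(0, 40))        # 2.5 min moving only
  expect_equal(nrow(detect_trips(make_epochs(sp3), cfg1)), 0)

  # exactly 5 min of pause still merges (allowance is inclusive)
  sp4 <- c(rep(5, 40), rep(0, 20), rep(5, 40))
  expect_equal(nrow(detect_trips(make_epochs(sp4), cfg1)), 1)
})

test_that("sustained band changes split trips, flicker does not", {
  sp <- c(rep(5, 40), rep(16, 40))                     # 10 min walk, 10 min cycle
  tr <- detect_trips(make_epochs(sp), cfg1)
  expect_equal(tr$mode, c("walk", "cycle"))
  expect_equal(tr$duration_min, c(10, 10))

  spf <- rep(16, 80); spf[30:31] <- 5                  # 30-s dip below the band
  trf <- detect_trips(make_epochs(spf), cfg1)
  expect_equal(nrow(trf), 1)
  expect_equal(trf$mode, "cycle")
})

test_that("detected trips satisfy the trip-type invariants", {
  for (seed in 1:25) {
    st <- random_epoch_stream(400, seed)
    tr <- detect_trips(stream_to_epochs(st$eidx, st$speed), cfg1)
    if (nrow(tr) == 0) next
    expect_true(all(tr$duration_min >= cfg1$min_trip_min))
    expect_true(all(tr$end >= tr$start))
    expect_equal(unname(band_mode <- vapply(tr$median_speed_kmh, function(m)
      c(walk_band = "walk", cycle_band = "cycle", passive_band = "passive")[
        classify_epoch_speed(m, cfg1)], character(1))), tr$mode)
    # trips never span a stationary gap exceeding the allowance
    ep <- stream_to_epochs(st$eidx, st$speed)
    band <- classify_epoch_speed(ep$speed_kmh, cfg1)
    for (i in seq_len(nrow(tr))) {
      in_trip <- ep$timestamp >= tr$start[i] & ep$timestamp <= tr$end[i]
      mv <- st$eidx[in_trip & band != "stationary"]
      expect_true(max(diff(mv)) - 1 <= 20)
    }
  }
})

test_that("segmentation is idempotent on a detected trip", {
  for (seed in 1:10) {
    st <- random_epoch_stream(500, seed + 100)
    ep <- stream_to_epochs(st$eidx, st$speed)
    tr <- detect_trips(ep, cfg1)
    for (i in seq_len(min(nrow(tr), 3))) {
      sub <- ep[ep$timestamp >= tr$start[i] & ep$timestamp <= tr$end[i], ]
      re <- detect_trips(sub, cfg1)
      expect_equal(nrow(re), 1)
      expect_equal(re$start, tr$start[i])
      expect_equal(re$end, tr$end[i])
      expect_equal(re$mode, tr$mode[i])
    }
  }
})

test_that("trip detection matches the explicit state-machine oracle", {
  for (seed in 1:60) {
    n <- sample(c(100, 300, 800), 1)
    st <- random_epoch_stream(n, seed + 500)
    ep <- stream_to_epochs(st$eidx, st$speed)
    got <- detect_trips(ep, cfg1)
    want <- oracle_trips(st$eidx, st$speed, cfg1)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(as.numeric(got$start), as.numeric(ep$timestamp[want$i0]))
      expect_equal(as.numeric(got$end), as.numeric(ep$timestamp[want$i1]))
      expect_equal(got$mode, want$mode)
      expect_equal(got$duration_min, want$span * 0.25)
    }
  }
})
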