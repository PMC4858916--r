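sch <- school_table("S1", start = "08:30", end = "15:30", wed_end = "12:00")

test_that("leisure windows follow the school schedule, Wednesdays end early", {
  sat <- leisure_window(as.Date("2013-12-07"), sch)
  expect_equal(sat, data.frame(from_min = 0, to_min = 1440))
  mon <- leisure_window(as.Date("2013-12-02"), sch)
  expect_equal(mon$from_min, c(0, 15.5 * 60))
  expect_equal(mon$to_min, c(8.5 * 60, 1440))
  wed <- leisure_window(as.Date("2013-12-04"), sch)
  expect_equal(wed$from_min[2], 12 * 60)    # afternoon fully leisure
})

mk_cfg <- function() {
  anchors <- data.frame(participant_id = "P1", home_lat = 51.06,
                        home_lon = 3.72, school_id = "S1")
  study_config(schools = sch, anchors = anchors)
}

mk_trip <- function(start, end, s_lat, s_lon, e_lat, e_lon, mode = "walk") {
  data.frame(participant_id = "P1",
             start = as.POSIXct(start, tz = "UTC"),
             end = as.POSIXct(end, tz = "UTC"), mode = mode,
             duration_min = as.numeric(as.POSIXct(end, tz = "UTC") -
                                         as.POSIXct(start, tz = "UTC"),
                                       units = "mins"),
             median_speed_kmh = 5, start_lat = s_lat, start_lon = s_lon,
             end_lat = e_lat, end_lon = e_lon, stringsAsFactors = FALSE)
}

test_that("home-school geofencing identifies commutes in both directions", {
  cfg <- mk_cfg()
  home <- c(51.06, 3.72); school <- c(sch$lat, sch$lon)
  t1 <- mk_trip("2013-12-02 08:05:00", "2013-12-02 08:20:00",
                home[1], home[2], school[1], school[2])
  t2 <- mk_trip("2013-12-07 10:00:00", "2013-12-07 10:15:00",
                school[1], school[2], home[1], home[2])
  t3 <- mk_trip("2013-12-02 17:00:00", "2013-12-02 17:15:00",
                home[1], home[2], 51.06, 3.75)        # home -> shop
  expect_equal(is_school_trip(rbind(t1, t2, t3), cfg), c(TRUE, TRUE, FALSE))
  cfg_no <- cfg; cfg_no$anchors <- NULL
  expect_error(is_school_trip(t1, cfg_no), "anchors")
})

test_that("leisure filtering keeps midpoint-in-window non-commute trips on valid days", {
  cfg <- mk_cfg()
  wd <- data.frame(participant_id = "P1",
                   date = as.Date(c("2013-12-02", "2013-12-04", "2013-12-07")),
                   combined_wear_minutes = 700,
                   is_weekend = c(FALSE, FALSE, TRUE),
                   is_first_day = FALSE, is_valid = TRUE)
  home <- c(51.06, 3.72); school <- c(sch$lat, sch$lon)
  trips <- rbind(
    # Wednesday 12:10-12:20, school ends 12:00 -> kept
    mk_trip("2013-12-04 12:10:00", "2013-12-04 12:20:00", home[1], home[2], 51.07, 3.73),
    # Monday commute at 08:00 -> dropped (in window, but a school trip)
    mk_trip("2013-12-02 08:00:00", "2013-12-02 08:15:00", home[1], home[2], school[1], school[2]),
    # Monday 10:00, inside school hours -> dropped
    mk_trip("2013-12-02 10:00:00", "2013-12-02 10:10:00", 51.07, 3.73, 51.08, 3.74),
    # weekend school->home -> dropped (school-trip exclusion is unconditional)
    mk_trip("2013-12-07 10:00:00", "2013-12-07 10:15:00", school[1], school[2], home[1], home[2]),
    # Tuesday: not a valid day -> dropped
    mk_trip("2013-12-03 17:00:00", "2013-12-03 17:10:00", home[1], home[2], 51.07, 3.73))
  kept <- filter_leisure_trips(trips, wd, cfg)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$date, as.Date("2013-12-04"))
  expect_equal(kept$stratum, "week")
})

test_that("every valid-day trip lands in exactly one leisure/commute/school bucket", {
  sim <- sim_clean()
  ep <- sim_epochs(sim)
  cfgS <- sim$study_config
  wd <- flag_valid_days(ep, cfgS)
  trips <- detect_trips(ep, cfgS)
  mid <- trips$start + (as.numeric(trips$end) - as.numeric(trips$start)) / 2
  date <- as.Date(mid, tz = "UTC")
  onval <- paste(trips$participant_id, date) %in%
    paste(wd$participant_id, wd$date)[wd$is_valid]
  tv <- trips[onval, ]
  kept <- filter_leisure_trips(trips, wd, cfgS)
  is_sch <- is_school_trip(tv, cfgS)
  # non-school trips on valid days either kept (leisure) or in school hours
  expect_equal(sum(!is_sch) , nrow(kept) + sum(!is_sch & !trip_in_leisure(tv, cfgS)))
  expect_equal(nrow(tv), sum(is_sch) + sum(!is_sch))
})

test_that("outcomes average over valid days and flag non-engagement", {
  wd <- data.frame(participant_id = "P1",
                   date = as.Date("2013-12-02") + 1:5,
                   combined_wear_minutes = 700,
                   is_weekend = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                   is_first_day = FALSE,
                   is_valid = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  inc <- data.frame(participant_id = "P1", n_valid_days = 4,
                    n_valid_weekend_days = 1, included = TRUE)
  lt <- data.frame(participant_id = "P1",
                   duration_min = rep(6, 6), mode = "walk",
                   date = as.Date("2013-12-02") + c(1, 1, 2, 2, 3, 3),
                   stratum = "week")
  out <- compute_outcomes(lt, wd, inc)
  ww <- out[out$stratum == "week" & out$mode == "walk", ]
  expect_equal(ww$trips_per_day, 2)         # 6 trips over 3 valid weekdays
  expect_equal(ww$minutes_per_day, 12)
  expect_equal(ww$minutes_per_trip, 6)
  wc <- out[out$stratum == "weekend" & out$mode == "cycle", ]
  expect_false(wc$engaged)
  expect_equal(wc$trips_per_day, 0)
  # minutes >= 3 x trips whenever trips > 0
  expect_true(all(out$minutes[out$trips > 0] >= 3 * out$trips[out$trips > 0]))
})

test_that("noise-free leisure trips and outcomes equal the manifest", {
  sim <- sim_clean()
  ep <- sim_epochs(sim)
  cfgS <- sim$study_config
  wd <- flag_valid_days(ep, cfgS)
  inc <- include_participants(wd, cfgS)
  kept <- filter_leisure_trips(detect_trips(ep, cfgS), wd, cfgS)
  mf <- sim$manifest
  vkey <- paste(mf$weardays$participant_id, mf$weardays$date)[mf$weardays$is_valid]
  want <- mf$trips[!mf$trips$is_school_trip &
                     paste(mf$trips$participant_id, mf$trips$date) %in% vkey, ]
  expect_equal(nrow(kept), nrow(want))
  ka <- kept[order(kept$participant_id, kept$start), ]
  wa <- want[order(want$participant_id, want$start), ]
  expect_equal(ka$start, wa$start)
  expect_equal(ka$mode, wa$mode)
  expect_equal(ka$duration_min, wa$duration_min)

  out <- compute_outcomes(kept, wd, inc)
  # recompute directly from the manifest
  ids <- inc$participant_id[inc$included]
  for (st in c("week", "weekend")) for (mo in c("walk", "cycle", "passive")) {
    for (id in ids[1:3]) {
      vd <- mf$weardays[mf$weardays$participant_id == id & mf$weardays$is_valid, ]
      vd <- vd[if (st == "weekend") vd$is_weekend else !vd$is_weekend, ]
      tm <- wa[wa$participant_id == id & wa$mode == mo &
                 wa$date %in% vd$date, ]
      row <- out[out$participant_id == id & out$stratum == st & out$mode == mo, ]
      if (nrow(vd) == 0) { expect_true(is.na(row$trips_per_day)); next }
      expect_equal(row$trips_per_day, nrow(tm) / nrow(vd))
      expect_equal(row$minutes_per_day, sum(tm$duration_min) / nrow(vd))
    }
  }
  # per-stratum minutes never exceed the day
  tot <- stats::aggregate(minutes_per_day ~ participant_id + stratum,
                          out, sum)
  expect_true(all(tot$minutes_per_day <= 1440))
})
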