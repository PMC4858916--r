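#' Leisure-time window for a calendar date
#'
#' Leisure time is the whole day on weekend days, and the time before school
#' start plus after school end on school weekdays (Wednesdays end early in
#' Belgian primary schools, so Wednesday afternoons are fully leisure).
#'
#' @param date a `Date`.
#' @param school one row of the school table ([school_table()]) for the
#'   participant's school.
#' @return data frame `from_min, to_min` of half-open intervals
#'   `[from, to)` in minutes from midnight.
#' @export
leisure_window <- function(date, school) {
  wd <- as.integer(format(date, "%u"))       # 1 = Monday ... 7 = Sunday
  if (wd >= 6) return(data.frame(from_min = 0, to_min = 1440))
  day <- c("mon", "tue", "wed", "thu", "fri")[wd]
  s <- school[[paste0("start_", day)]]
  e <- school[[paste0("end_", day)]]
  data.frame(from_min = c(0, e), to_min = c(s, 1440))
}

in_leisure <- function(time, date, school) {
  w <- leisure_window(date, school)
  mins <- as.numeric(time - as.POSIXct(paste0(format(date), "T00:00:00"),
                                       format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                     units = "mins")
  any(mins >= w$from_min & mins < w$to_min)
}

#' Is a trip a home-school commute?
#'
#' TRUE when one trip endpoint lies within the home geofence and the other
#' within the school geofence, in either direction. School commutes are
#' excluded from leisure outcomes unconditionally, weekends included.
#'
#' @param trips trip table from [detect_trips()].
#' @param config a [study_config()] with `anchors` and `schools` defined.
#' @return logical vector along the rows of `trips`.
#' @export
is_school_trip <- function(trips, config) {
  if (is.null(config$anchors)) stop("config$anchors must be defined")
  a <- config$anchors
  sc <- config$schools
  a$school_lat <- sc$lat[match(a$school_id, sc$school_id)]
  a$school_lon <- sc$lon[match(a$school_id, sc$school_id)]
  i <- match(trips$participant_id, a$participant_id)
  if (any(is.na(i))) stop("missing anchors for participant(s): ",
                          paste(unique(trips$participant_id[is.na(i)]), collapse = ", "))
  r <- config$geofence_m
  dist_ok <- function(lat1, lon1, lat2, lon2) {
    d <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
    !is.na(d) & d <= r
  }
  s_home <- dist_ok(trips$start_lat, trips$start_lon, a$home_lat[i], a$home_lon[i])
  e_home <- dist_ok(trips$end_lat, trips$end_lon, a$home_lat[i], a$home_lon[i])
  s_sch <- dist_ok(trips$start_lat, trips$start_lon, a$school_lat[i], a$school_lon[i])
  e_sch <- dist_ok(trips$end_lat, trips$end_lon, a$school_lat[i], a$school_lon[i])
  (s_home & e_sch) | (s_sch & e_home)
}

#' Restrict trips to leisure time on valid days
#'
#' Keeps trips that (1) fall on a valid measurement day, (2) have their
#' temporal midpoint inside the leisure window of that day, and (3) are not
#' home-school commutes. Midpoint assignment avoids double counting trips
#' that straddle a window boundary.
#'
#' @param trips trip table from [detect_trips()].
#' @param weardays valid-day table from [flag_valid_days()].
#' @param config a [study_config()] with anchors and schools.
#' @return the kept subset of `trips` with added columns `date` (of the
#'   midpoint) and `stratum` (`"week"`/`"weekend"`).
#' @export
filter_leisure_trips <- function(trips, weardays, config) {
  if (nrow(trips) == 0) {
    out <- trips; out$date <- as.Date(character()); out$stratum <- character()
    return(out)
  }
  mid <- trips$start + (as.numeric(trips$end) - as.numeric(trips$start)) / 2
  date <- as.Date(mid, tz = "UTC")
  valid_key <- paste(weardays$participant_id, weardays$date)[weardays$is_valid]
  on_valid <- paste(trips$participant_id, date) %in% valid_key

  a <- config$anchors
  sid <- a$school_id[match(trips$participant_id, a$participant_id)]
  leis <- vapply(seq_len(nrow(trips)), function(k) {
    sch <- config$schools[config$schools$school_id == sid[k], , drop = FALSE]
    in_leisure(mid[k], date[k], sch)
  }, logical(1))
  keep <- on_valid & leis & !is_school_trip(trips, config)
  out <- trips[keep, , drop = FALSE]
  out$date <- date[keep]
  out$stratum <- ifelse(format(out$date, "%u") %in% c("6", "7"), "weekend", "week")
  rownames(out) <- NULL
  out
}

#' Per-participant leisure-transport outcomes
#'
#' Averages leisure trips over valid days, stratified into week and weekend
#' days: trips/day and minutes/day are per-valid-day means within the stratum;
#' minutes/trip is total minutes over total trips (undefined without trips);
#' `engaged` flags any trip in the stratum. Participants with zero valid days
#' in a stratum get `NA` outcomes for it.
#'
#' @param leisure_trips output of [filter_leisure_trips()].
#' @param weardays output of [flag_valid_days()].
#' @param inclusion output of [include_participants()]; only included
#'   participants are tabulated.
#' @return data frame `participant_id, stratum, mode, trips, minutes,
#'   valid_days, trips_per_day, minutes_per_day, minutes_per_trip, engaged`.
#' @export
compute_outcomes <- function(leisure_trips, weardays, inclusion) {
  ids <- inclusion$participant_id[inclusion$included]
  modes <- c("walk", "cycle", "passive")
  grid <- expand.grid(participant_id = ids, stratum = c("week", "weekend"),
                      mode = modes, stringsAsFactors = FALSE)
  wd <- weardays[weardays$is_valid, ]
  wd$stratum <- ifelse(wd$is_weekend, "weekend", "week")
  vd <- stats::aggregate(list(valid_days = wd$date),
                         by = list(participant_id = wd$participant_id,
                                   stratum = wd$stratum), FUN = length)
  lt <- leisure_trips[leisure_trips$participant_id %in% ids, , drop = FALSE]
  agg <- if (nrow(lt) > 0) {
    stats::aggregate(list(trips = rep(1, nrow(lt)), minutes = lt$duration_min),
                     by = list(participant_id = lt$participant_id,
                               stratum = lt$stratum, mode = lt$mode), FUN = sum)
  } else {
    data.frame(participant_id = character(), stratum = character(),
               mode = character(), trips = numeric(), minutes = numeric())
  }
  out <- merge(grid, vd, by = c("participant_id", "stratum"), all.x = TRUE)
  out <- merge(out, agg, by = c("participant_id", "stratum", "mode"), all.x = TRUE)
  has_days <- !is.na(out$valid_days) & out$valid_days > 0
  out$trips[is.na(out$trips) & has_days] <- 0
  out$minutes[is.na(out$minutes) & has_days] <- 0
  out$trips_per_day <- ifelse(has_days, out$trips / out$valid_days, NA_real_)
  out$minutes_per_day <- ifelse(has_days, out$minutes / out$valid_days, NA_real_)
  out$minutes_per_trip <- ifelse(!is.na(out$trips) & out$trips > 0,
                                 out$minutes / out$trips, NA_real_)
  out$engaged <- ifelse(has_days, out$trips > 0, NA)
  out <- out[order(out$participant_id, out$stratum, out$mode), ]
  rownames(out) <- NULL
  out
}

#' Diary outcomes on the same denominators
#'
#' Self-reported trips/day per mode and stratum, averaged over the same valid
#' days as the GPS outcomes so the two instruments are comparable. Diary
#' school trips are excluded, and reported trips on non-valid days are
#' dropped.
#'
#' @param diary data frame from [read_diary()].
#' @inheritParams compute_outcomes
#' @return data frame `participant_id, stratum, mode, trips, valid_days,
#'   trips_per_day, engaged`.
#' @export
compute_diary_outcomes <- function(diary, weardays, inclusion) {
  ids <- inclusion$participant_id[inclusion$included]
  d <- diary[!diary$is_school_trip & diary$participant_id %in% ids, , drop = FALSE]
  valid_key <- paste(weardays$participant_id, weardays$date)[weardays$is_valid]
  d <- d[paste(d$participant_id, d$date) %in% valid_key, , drop = FALSE]
  d$stratum <- ifelse(format(d$date, "%u") %in% c("6", "7"), "weekend", "week")
  fake <- d[, c("participant_id", "stratum", "mode")]
  fake$duration_min <- 0
  fake$date <- d$date
  out <- compute_outcomes(fake, weardays, inclusion)
  out[, c("participant_id", "stratum", "mode", "trips", "valid_days",
          "trips_per_day", "engaged")]
}
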