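#' Study configuration
#'
#' Bundles every numeric constant of the processing chain together with the
#' school schedules and per-participant home/school anchor points. All
#' downstream functions take a `study_config` so that each threshold is
#' reviewable and overridable in one place.
#'
#' @param epoch_s epoch length in seconds (devices record every 15 s).
#' @param movement_kmh minimum speed counted as movement, km/h.
#' @param walk_band,cycle_band two-element numeric vectors `c(lo, hi)` in km/h;
#'   an epoch with speed in `[lo, hi)` falls in the band.
#' @param passive_min lower speed bound of passive (vehicle) transport, km/h.
#' @param min_trip_min minimum total trip duration in minutes (pauses included).
#' @param max_pause_min longest stationary period tolerated inside a trip, minutes.
#' @param sustain_epochs number of consecutive moving epochs in a new speed band
#'   required to split a movement run into a new trip (band-change hysteresis).
#' @param smooth_window running-median window (epochs, odd) applied to speed
#'   before segmentation; 1 disables smoothing.
#' @param nonwear_min minimum run of zero accelerometer counts classed as
#'   non-wear, minutes.
#' @param min_wear_h minimum hours per day of simultaneous accelerometer-wear
#'   and GPS-fix coverage for a valid day.
#' @param min_valid_days,min_weekend_days inclusion rule: a participant needs at
#'   least this many valid days, of which at least this many weekend days.
#' @param geofence_m radius in metres of the home and school geofences used to
#'   identify school commutes.
#' @param schools data frame of school schedules, see [school_table()].
#' @param anchors data frame with one row per participant:
#'   `participant_id, home_lat, home_lon, school_id`.
#'
#' @return A list of class `study_config`.
#' @export
study_config <- function(epoch_s = 15,
                         movement_kmh = 1,
                         walk_band = c(1, 10),
                         cycle_band = c(10, 25),
                         passive_min = 25,
                         min_trip_min = 3,
                         max_pause_min = 5,
                         sustain_epochs = 4,
                         smooth_window = 5,
                         nonwear_min = 60,
                         min_wear_h = 9,
                         min_valid_days = 4,
                         min_weekend_days = 1,
                         geofence_m = 100,
                         schools = school_table(),
                         anchors = NULL) {
  cfg <- list(
    epoch_s = epoch_s, movement_kmh = movement_kmh,
    walk_band = walk_band, cycle_band = cycle_band, passive_min = passive_min,
    min_trip_min = min_trip_min, max_pause_min = max_pause_min,
    sustain_epochs = sustain_epochs, smooth_window = smooth_window,
    nonwear_min = nonwear_min, min_wear_h = min_wear_h,
    min_valid_days = min_valid_days, min_weekend_days = min_weekend_days,
    geofence_m = geofence_m, schools = schools, anchors = anchors
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  stopifnot(
    cfg$epoch_s > 0,
    cfg$movement_kmh > 0,
    length(cfg$walk_band) == 2, length(cfg$cycle_band) == 2,
    cfg$min_trip_min > 0, cfg$max_pause_min > 0,
    cfg$sustain_epochs >= 1,
    cfg$smooth_window >= 1, cfg$smooth_window %% 2 == 1,
    cfg$nonwear_min > 0, cfg$min_wear_h > 0,
    cfg$min_valid_days >= 1, cfg$min_weekend_days >= 0,
    cfg$geofence_m > 0
  )
  edges <- c(cfg$movement_kmh, cfg$walk_band[2], cfg$cycle_band[2])
  if (cfg$walk_band[1] != cfg$movement_kmh ||
      cfg$cycle_band[1] != cfg$walk_band[2] ||
      cfg$passive_min != cfg$cycle_band[2]) {
    stop("mode bands must be contiguous: walk starts at movement threshold, ",
         "cycle at walk's upper edge, passive at cycle's upper edge")
  }
  if (any(diff(edges) <= 0)) stop("mode band edges must be strictly increasing")
  if (!is.null(cfg$schools)) {
    s <- cfg$schools
    startm <- as.matrix(s[, grep("^start_", names(s))])
    endm <- as.matrix(s[, grep("^end_", names(s))])
    if (any(startm >= endm)) stop("school start must precede end on every school day")
  }
  invisible(cfg)
}

#' School schedule table
#'
#' One row per school with clock times (minutes from midnight) for each school
#' weekday. Belgian primary schools typically start 08:15-08:30 and end
#' 15:30-16:00, except Wednesdays which end at noon; the defaults reflect that.
#'
#' @param school_id character vector of school identifiers.
#' @param lat,lon school coordinates (WGS84 decimal degrees).
#' @param start,end default start/end clock times `"HH:MM"` for Mon/Tue/Thu/Fri.
#' @param wed_end Wednesday end time `"HH:MM"`.
#'
#' @return data frame with columns `school_id, lat, lon,
#'   start_mon..start_fri, end_mon..end_fri` (minutes from midnight).
#' @export
school_table <- function(school_id = "S1", lat = 51.05, lon = 3.72,
                         start = "08:30", end = "15:30", wed_end = "12:00") {
  n <- length(school_id)
  sm <- rep(hhmm_to_min(start), length.out = n)
  em <- rep(hhmm_to_min(end), length.out = n)
  wm <- rep(hhmm_to_min(wed_end), length.out = n)
  data.frame(
    school_id = school_id, lat = rep(lat, length.out = n), lon = rep(lon, length.out = n),
    start_mon = sm, start_tue = sm, start_wed = sm, start_thu = sm, start_fri = sm,
    end_mon = em, end_tue = em, end_wed = wm, end_thu = em, end_fri = em,
    stringsAsFactors = FALSE
  )
}

hhmm_to_min <- function(x) {
  if (is.numeric(x)) return(x)
  p <- strsplit(x, ":", fixed = TRUE)
  vapply(p, function(v) as.numeric(v[1]) * 60 + as.numeric(v[2]), numeric(1))
}

min_to_hhmm <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)

#' Read / write a study configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_study_config` returns a `study_config`;
#'   `write_study_config` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  schools <- if (!is.null(y$schools)) do.call(rbind, lapply(y$schools, function(s) {
    as.data.frame(s, stringsAsFactors = FALSE)
  })) else school_table()
  anchors <- if (!is.null(y$anchors)) do.call(rbind, lapply(y$anchors, function(a) {
    as.data.frame(a, stringsAsFactors = FALSE)
  })) else NULL
  args <- y[setdiff(names(y), c("schools", "anchors"))]
  args$walk_band <- as.numeric(args$walk_band)
  args$cycle_band <- as.numeric(args$cycle_band)
  do.call(study_config, c(args, list(schools = schools, anchors = anchors)))
}

#' @rdname read_study_config
#' @param cfg a `study_config`.
#' @export
write_study_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$schools <- lapply(seq_len(nrow(cfg$schools)), function(i) as.list(cfg$schools[i, ]))
  y$anchors <- if (is.null(cfg$anchors)) NULL else
    lapply(seq_len(nrow(cfg$anchors)), function(i) as.list(cfg$anchors[i, ]))
  yaml::write_yaml(y, path)
  invisible(path)
}
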