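#' Classify a 15-s epoch speed into a movement band
#'
#' Speed bands follow the standard GPS travel-mode convention for children:
#' below the movement threshold (1 km/h) an epoch is stationary; walking is
#' 1 to <10 km/h; cycling 10 to <25 km/h; passive (vehicle) transport
#' >= 25 km/h. A missing speed (no GPS fix) is treated as stationary.
#'
#' @param speed_kmh numeric vector of epoch speeds in km/h (NA allowed).
#' @param config a [study_config()].
#' @return character vector in
#'   `c("stationary", "walk_band", "cycle_band", "passive_band")`.
#' @export
classify_epoch_speed <- function(speed_kmh, config = study_config()) {
  if (any(speed_kmh < 0, na.rm = TRUE)) stop("negative speed")
  out <- rep("stationary", length(speed_kmh))
  ok <- !is.na(speed_kmh)
  s <- speed_kmh[ok]
  b <- ifelse(s < config$walk_band[1], "stationary",
       ifelse(s < config$walk_band[2], "walk_band",
       ifelse(s < config$cycle_band[2], "cycle_band", "passive_band")))
  out[ok] <- b
  out
}

band_to_mode <- function(band) {
  c(walk_band = "walk", cycle_band = "cycle", passive_band = "passive")[band]
}

#' Running-median speed smoothing
#'
#' Suppresses single-epoch GPS speed spikes (a consequence of the device's
#' few-metre positional error) before segmentation. Epochs without a fix stay
#' missing; for the purpose of the median they count as zero speed, matching
#' their stationary role in segmentation.
#'
#' @param speed_kmh numeric vector (NA = no fix).
#' @param window odd integer window in epochs; 1 is the identity.
#' @return smoothed numeric vector, NA preserved where input was NA.
#' @export
smooth_speeds <- function(speed_kmh, window = 5) {
  if (window %% 2 == 0) stop("smoothing window must be odd")
  if (window == 1 || length(speed_kmh) < 2) return(speed_kmh)
  na <- is.na(speed_kmh)
  x <- speed_kmh
  x[na] <- 0
  k <- min(window, if (length(x) %% 2 == 0) length(x) - 1 else length(x))
  sm <- as.numeric(stats::runmed(x, k, endrule = "median"))
  sm[na] <- NA_real_
  sm
}

max_pause_epochs <- function(config) round(config$max_pause_min * 60 / config$epoch_s)
min_trip_epochs <- function(config) ceiling(config$min_trip_min * 60 / config$epoch_s)

#' Detect trips from an aligned epoch stream
#'
#' A trip is a continuous period of movement in one transport mode lasting at
#' least 3 min, tolerating internal stationary periods of at most 5 min.
#' Detection proceeds per participant:
#'
#' 1. speeds are smoothed by a running median (`config$smooth_window`);
#' 2. epochs are banded by [classify_epoch_speed()]; missing fixes count as
#'    stationary, so GPS dropouts up to the pause allowance are bridged and
#'    longer dropouts terminate the movement run;
#' 3. moving epochs are chained into movement runs, joining across stationary
#'    gaps of at most `max_pause_min`;
#' 4. a run is split where a different speed band sustains for at least
#'    `sustain_epochs` consecutive moving epochs (band-change hysteresis, so
#'    momentary flicker such as a cyclist slowing does not fragment a trip);
#' 5. segments whose total span (pauses included) is shorter than
#'    `min_trip_min` are discarded;
#' 6. each surviving segment becomes a trip whose mode is the band of the
#'    median smoothed speed over its moving epochs.
#'
#' Trips start and end on moving epochs and never span a stationary gap longer
#' than the pause allowance.
#'
#' @param epochs data frame with columns
#'   `participant_id, timestamp, lat, lon, speed_kmh` (see [read_epochs()]).
#' @param config a [study_config()].
#' @return data frame with one row per trip: `participant_id, start, end, mode,
#'   duration_min, median_speed_kmh, start_lat, start_lon, end_lat, end_lon`.
#' @export
detect_trips <- function(epochs, config = study_config()) {
  parts <- split(epochs, epochs$participant_id)
  res <- lapply(parts, detect_trips_one, config = config)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (is.null(out)) out <- empty_trip_table()
  out
}

empty_trip_table <- function() {
  data.frame(participant_id = character(), start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"), mode = character(),
             duration_min = numeric(), median_speed_kmh = numeric(),
             start_lat = numeric(), start_lon = numeric(),
             end_lat = numeric(), end_lon = numeric(), stringsAsFactors = FALSE)
}

detect_trips_one <- function(ep, config) {
  ep <- ep[order(ep$timestamp), ]
  if (nrow(ep) == 0) return(NULL)
  eidx <- round(as.numeric(ep$timestamp) / config$epoch_s)
  sm <- smooth_speeds(ep$speed_kmh, config$smooth_window)
  band <- classify_epoch_speed(sm, config)
  moving <- which(band != "stationary")
  if (length(moving) == 0) return(NULL)

  gap_ok <- max_pause_epochs(config)
  midx <- eidx[moving]                      # grid indices of moving epochs
  # chain moving epochs: break where stationary/missing gap exceeds allowance
  newrun <- c(TRUE, diff(midx) - 1 > gap_ok)
  run_id <- cumsum(newrun)

  segs <- list()
  for (r in unique(run_id)) {
    rows <- moving[run_id == r]
    b <- band[rows]
    rl <- rle(b)
    nblk <- length(rl$lengths)
    blk_end <- cumsum(rl$lengths)
    blk_start <- blk_end - rl$lengths + 1
    cur_band <- rl$values[1]
    seg_from <- 1                           # index into rows
    if (nblk > 1) {
      for (bi in 2:nblk) {
        if (rl$values[bi] != cur_band && rl$lengths[bi] >= config$sustain_epochs) {
          segs[[length(segs) + 1]] <- rows[seg_from:(blk_start[bi] - 1)]
          seg_from <- blk_start[bi]
          cur_band <- rl$values[bi]
        }
      }
    }
    segs[[length(segs) + 1]] <- rows[seg_from:length(b)]
  }

  trips <- lapply(segs, function(rows) {
    i0 <- rows[1]; i1 <- rows[length(rows)]
    span <- eidx[i1] - eidx[i0] + 1
    if (span < min_trip_epochs(config)) return(NULL)
    med <- stats::median(sm[rows])
    data.frame(
      participant_id = ep$participant_id[1],
      start = ep$timestamp[i0], end = ep$timestamp[i1],
      mode = unname(band_to_mode(classify_epoch_speed(med, config))),
      duration_min = span * config$epoch_s / 60,
      median_speed_kmh = med,
      start_lat = ep$lat[i0], start_lon = ep$lon[i0],
      end_lat = ep$lat[i1], end_lon = ep$lon[i1],
      stringsAsFactors = FALSE
    )
  })
  trips <- trips[!vapply(trips, is.null, logical(1))]
  if (length(trips) == 0) return(NULL)
  do.call(rbind, trips)
}
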