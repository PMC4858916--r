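# Input formats:
#   GPS CSV:   participant_id,timestamp,lat,lon,speed_kmh   (ISO-8601 timestamps)
#   accel CSV: participant_id,timestamp,counts
#   diary CSV: participant_id,date,mode,is_school_trip
# GPX 1.1 is accepted for GPS input (trkpt lat/lon/time; <speed> in m/s if present).

fmt_ts <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

floor_to_grid <- function(t, epoch_s) {
  as.POSIXct(floor(as.numeric(t) / epoch_s) * epoch_s,
             origin = "1970-01-01", tz = "UTC")
}

#' Read GPS fixes from CSV or GPX
#'
#' @param path file path; `.gpx` files are parsed as GPX 1.1 tracks, anything
#'   else as CSV with header `participant_id,timestamp,lat,lon,speed_kmh`.
#' @param participant_id used for GPX files, which carry no participant column.
#' @return data frame `participant_id, timestamp, lat, lon, speed_kmh`.
#' @export
read_gps <- function(path, participant_id = NULL) {
  if (grepl("\\.gpx$", path, ignore.case = TRUE)) {
    return(read_gpx(path, participant_id %||% tools::file_path_sans_ext(basename(path))))
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "timestamp", "lat", "lon", "speed_kmh")
  if (!all(need %in% names(d))) stop("GPS CSV ", path, " must have columns ",
                                     paste(need, collapse = ","))
  d$participant_id <- as.character(d$participant_id)
  d$timestamp <- parse_ts(d$timestamp)
  bad <- !is.na(d$lat) & !is.na(d$lon) & (abs(d$lat) > 90 | abs(d$lon) > 180)
  if (any(bad)) {
    warning(sum(bad), " GPS record(s) with out-of-range coordinates rejected in ", path)
    d <- d[!bad, ]
  }
  d[, need]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_gpx <- function(path, participant_id) {
  x <- xml2::read_xml(path)
  xml2::xml_ns_strip(x)
  pts <- xml2::xml_find_all(x, ".//trkpt")
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tim <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  tim <- as.POSIXct(tim, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  spd <- suppressWarnings(as.numeric(xml2::xml_text(
    xml2::xml_find_first(pts, ".//speed"))))
  data.frame(participant_id = participant_id, timestamp = tim,
             lat = lat, lon = lon,
             speed_kmh = spd * 3.6,      # GPX speed is m/s
             stringsAsFactors = FALSE)
}

#' Read accelerometer counts from CSV
#' @param path CSV with header `participant_id,timestamp,counts`.
#' @return data frame `participant_id, timestamp, counts`.
#' @export
read_accel <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "timestamp", "counts")
  if (!all(need %in% names(d))) stop("accelerometer CSV ", path,
                                     " must have columns ", paste(need, collapse = ","))
  d$participant_id <- as.character(d$participant_id)
  d$timestamp <- parse_ts(d$timestamp)
  if (any(d$counts < 0, na.rm = TRUE)) stop("negative accelerometer counts in ", path)
  d[, need]
}

drop_grid_duplicates <- function(d, what) {
  key <- paste(d$participant_id, as.numeric(d$timestamp))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate ", what,
            " record(s) after flooring to the epoch grid rejected (first kept)")
    d <- d[!dup, ]
  }
  d
}

#' Align GPS and accelerometer streams to a common 15-s epoch grid
#'
#' Timestamps are floored to the epoch grid (epoch-start convention); the two
#' streams are joined over the union of grid points, so every epoch covered by
#' either stream yields a record and the unmatched side carries missing
#' fields. Where a fix exists but the device speed is missing, speed is
#' recomputed from consecutive fixes as great-circle distance over elapsed
#' time. Alignment is idempotent: aligned input passes through unchanged.
#'
#' @param gps data frame from [read_gps()].
#' @param accel data frame from [read_accel()].
#' @param config a [study_config()].
#' @return data frame `participant_id, timestamp, lat, lon, speed_kmh, counts`
#'   ordered by participant and time.
#' @export
align_epochs <- function(gps, accel, config = study_config()) {
  gps$timestamp <- floor_to_grid(gps$timestamp, config$epoch_s)
  accel$timestamp <- floor_to_grid(accel$timestamp, config$epoch_s)
  gps <- drop_grid_duplicates(gps, "GPS")
  accel <- drop_grid_duplicates(accel, "accelerometer")
  m <- merge(gps, accel, by = c("participant_id", "timestamp"), all = TRUE)
  m <- m[order(m$participant_id, m$timestamp), ]
  m$speed_kmh[is.na(m$lat) | is.na(m$lon)] <- NA_real_
  m <- do.call(rbind, lapply(split(m, m$participant_id), fill_speed_from_fixes))
  rownames(m) <- NULL
  m[, c("participant_id", "timestamp", "lat", "lon", "speed_kmh", "counts")]
}

fill_speed_from_fixes <- function(ep) {
  fix <- which(!is.na(ep$lat) & !is.na(ep$lon))
  need <- fix[is.na(ep$speed_kmh[fix])]
  if (length(need) == 0 || length(fix) < 2) return(ep)
  pos <- match(need, fix)
  prev <- fix[pos - 1]
  ok <- !is.na(prev)
  if (!any(ok)) return(ep)
  i <- need[ok]; p <- prev[ok]
  dist_m <- geosphere::distHaversine(cbind(ep$lon[p], ep$lat[p]),
                                     cbind(ep$lon[i], ep$lat[i]))
  dt_s <- as.numeric(ep$timestamp[i]) - as.numeric(ep$timestamp[p])
  ep$speed_kmh[i] <- dist_m / dt_s * 3.6
  ep
}

#' Read and align a participant's GPS and accelerometer files
#'
#' @param gps_path GPS CSV or GPX file.
#' @param accel_path accelerometer CSV file.
#' @param config a [study_config()].
#' @return aligned epoch data frame, see [align_epochs()].
#' @export
read_epochs <- function(gps_path, accel_path, config = study_config()) {
  align_epochs(read_gps(gps_path), read_accel(accel_path), config)
}

#' Read a travel diary
#'
#' Diary modes `walking`/`walk`, `cycling`/`cycle`/`bike` map to the active
#' modes; `car`, `public transport`, `public_transport` and `bus` all map to
#' `passive`. Rows with unknown codes are rejected with a warning. School
#' trips are retained but flagged so they can be excluded downstream.
#'
#' @param path CSV with header `participant_id,date,mode,is_school_trip`.
#' @return data frame `participant_id, date, mode, is_school_trip` with
#'   `mode` in `c("walk","cycle","passive")`.
#' @export
read_diary <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) {
    warning("empty diary file ", path)
    return(data.frame(participant_id = character(), date = as.Date(character()),
                      mode = character(), is_school_trip = logical()))
  }
  need <- c("participant_id", "date", "mode", "is_school_trip")
  if (!all(need %in% names(d))) stop("diary CSV ", path, " must have columns ",
                                     paste(need, collapse = ","))
  map <- c(walking = "walk", walk = "walk",
           cycling = "cycle", cycle = "cycle", bike = "cycle",
           car = "passive", `public transport` = "passive",
           public_transport = "passive", bus = "passive", passive = "passive")
  mode <- unname(map[tolower(trimws(d$mode))])
  if (any(is.na(mode))) {
    warning(sum(is.na(mode)), " diary row(s) with unknown mode code rejected")
    d <- d[!is.na(mode), ]; mode <- mode[!is.na(mode)]
  }
  data.frame(participant_id = d$participant_id, date = as.Date(d$date),
             mode = mode, is_school_trip = as.logical(d$is_school_trip),
             stringsAsFactors = FALSE)
}

#' Write / read tabular outputs
#'
#' CSV writers for the pipeline's tables; timestamps are serialized as
#' ISO-8601 so that write followed by read round-trips exactly.
#'
#' @param x table to write.
#' @param path CSV path.
#' @return the path, invisibly (writers); the table (readers).
#' @export
write_epoch_table <- function(x, path) {
  x$timestamp <- fmt_ts(x$timestamp)
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_epoch_table
#' @export
read_epoch_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(participant_id = "character"))
  d$timestamp <- parse_ts(d$timestamp)
  for (cc in c("lat", "lon", "speed_kmh", "counts"))
    if (cc %in% names(d)) d[[cc]] <- as.numeric(d[[cc]])
  d
}

#' @rdname write_epoch_table
#' @export
write_trip_table <- function(x, path) {
  x$start <- fmt_ts(x$start); x$end <- fmt_ts(x$end)
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_epoch_table
#' @export
read_trip_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(participant_id = "character"))
  d$start <- parse_ts(d$start); d$end <- parse_ts(d$end)
  d
}
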