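#' Detect accelerometer non-wear intervals
#'
#' Non-wear time is any run of 60 min or more of consecutive zero counts; the
#' boundary is inclusive (exactly 60 min of zeros is non-wear). Runs are
#' maximal: they are bounded by non-zero counts, missing epochs, or the ends
#' of the record. Epochs without counts (device returned no data) are neither
#' wear nor non-wear.
#'
#' @param timestamps POSIXct vector on the epoch grid, strictly increasing.
#' @param counts non-negative integer vector, NA where the device has no data.
#' @param config a [study_config()].
#' @return data frame `start, end, n_epochs, minutes` with one row per
#'   non-wear interval (`start`/`end` are the first/last epoch of the run).
#' @export
detect_non_wear <- function(timestamps, counts, config = study_config()) {
  stopifnot(length(timestamps) == length(counts))
  empty <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      n_epochs = integer(), minutes = numeric())
  if (length(counts) == 0) return(empty)
  o <- order(timestamps)
  timestamps <- timestamps[o]; counts <- counts[o]
  eidx <- round(as.numeric(timestamps) / config$epoch_s)
  # a zero run is broken by non-zero counts, missing counts, or grid gaps
  zero <- !is.na(counts) & counts == 0
  brk <- c(TRUE, diff(eidx) != 1) | !zero
  grp <- cumsum(brk)
  need <- ceiling(config$nonwear_min * 60 / config$epoch_s)
  runs <- split(seq_along(counts)[zero], grp[zero])
  runs <- Filter(function(ix) length(ix) >= need, runs)
  if (length(runs) == 0) return(empty)
  do.call(rbind, lapply(runs, function(ix) {
    data.frame(start = timestamps[ix[1]], end = timestamps[ix[length(ix)]],
               n_epochs = length(ix),
               minutes = length(ix) * config$epoch_s / 60)
  })) -> out
  rownames(out) <- NULL
  out[order(out$start), ]
}

#' Epoch-level wear indicator
#'
#' TRUE for epochs with accelerometer data that do not fall in a non-wear run.
#' @inheritParams detect_non_wear
#' @return logical vector aligned with `timestamps`.
#' @export
wear_indicator <- function(timestamps, counts, config = study_config()) {
  nw <- detect_non_wear(timestamps, counts, config)
  wear <- !is.na(counts)
  if (nrow(nw) > 0) {
    for (i in seq_len(nrow(nw))) {
      wear[timestamps >= nw$start[i] & timestamps <= nw$end[i]] <- FALSE
    }
  }
  wear
}

#' Flag valid measurement days
#'
#' A day is valid when it provides at least `min_wear_h` hours of simultaneous
#' accelerometer wear and GPS fixes, and it is not the participant's first
#' recorded calendar day (instruments are handed out during day 1, so that day
#' is always incomplete and excluded).
#'
#' @param epochs aligned epoch data frame (see [read_epochs()]) with columns
#'   `participant_id, timestamp, lat, lon, speed_kmh, counts`.
#' @param config a [study_config()].
#' @return data frame `participant_id, date, combined_wear_minutes, is_weekend,
#'   is_first_day, is_valid`.
#' @export
flag_valid_days <- function(epochs, config = study_config()) {
  parts <- split(epochs, epochs$participant_id)
  out <- do.call(rbind, lapply(parts, function(ep) {
    ep <- ep[order(ep$timestamp), ]
    wear <- wear_indicator(ep$timestamp, ep$counts, config)
    fix <- !is.na(ep$lat) & !is.na(ep$lon)
    date <- as.Date(ep$timestamp, tz = "UTC")
    comb <- tapply(wear & fix, date, sum) * config$epoch_s / 60
    d <- as.Date(names(comb))
    data.frame(
      participant_id = ep$participant_id[1],
      date = d,
      combined_wear_minutes = as.numeric(comb),
      is_weekend = format(d, "%u") %in% c("6", "7"),
      is_first_day = d == min(d),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out$is_valid <- !out$is_first_day &
    out$combined_wear_minutes >= config$min_wear_h * 60
  out
}

#' Participant inclusion table
#'
#' A participant is included when they have at least `min_valid_days` valid
#' days of which at least `min_weekend_days` are weekend days.
#'
#' @param weardays output of [flag_valid_days()].
#' @param config a [study_config()].
#' @return data frame `participant_id, n_valid_days, n_valid_weekend_days,
#'   included`.
#' @export
include_participants <- function(weardays, config = study_config()) {
  sp <- split(weardays, weardays$participant_id)
  out <- do.call(rbind, lapply(sp, function(w) {
    nv <- sum(w$is_valid)
    nw <- sum(w$is_valid & w$is_weekend)
    data.frame(participant_id = w$participant_id[1],
               n_valid_days = nv, n_valid_weekend_days = nw,
               included = nv >= config$min_valid_days &
                 nw >= config$min_weekend_days,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
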