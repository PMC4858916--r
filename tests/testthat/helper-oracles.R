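# Independent reference implementations used as oracles. These are written
# as explicit scans, deliberately different in structure from the package's
# vectorized implementations.

# Trip segmentation oracle: explicit state machine over epochs.
# eidx: integer epoch grid indices (strictly increasing); speed: km/h (NA =
# no fix). Returns data frame first/last epoch index (into the input
# vectors), mode, span_epochs.
oracle_trips <- function(eidx, speed, config) {
  band <- classify_epoch_speed(speed, config)
  moving <- which(band != "stationary")
  out <- list()
  if (length(moving) == 0) {
    return(data.frame(i0 = integer(), i1 = integer(), mode = character(),
                      span = integer()))
  }
  gap_ok <- round(config$max_pause_min * 60 / config$epoch_s)
  min_ep <- ceiling(config$min_trip_min * 60 / config$epoch_s)

  # split moving epochs into runs by walking pairwise
  runs <- list(moving[1])
  for (k in seq_along(moving)[-1]) {
    prev <- runs[[length(runs)]]
    if (eidx[moving[k]] - eidx[prev[length(prev)]] - 1 <= gap_ok) {
      runs[[length(runs)]] <- c(prev, moving[k])
    } else {
      runs[[length(runs) + 1]] <- moving[k]
    }
  }

  for (run in runs) {
    b <- band[run]
    K <- length(b)
    seg_start <- 1
    cur <- b[1]
    k <- 2
    segs <- list()
    while (k <= K) {
      if (b[k] != cur && b[k] != b[k - 1]) {
        j <- k
        while (j + 1 <= K && b[j + 1] == b[k]) j <- j + 1
        if (j - k + 1 >= config$sustain_epochs) {
          segs[[length(segs) + 1]] <- c(seg_start, k - 1)
          seg_start <- k
          cur <- b[k]
        }
        k <- j + 1
      } else {
        k <- k + 1
      }
    }
    segs[[length(segs) + 1]] <- c(seg_start, K)
    for (s in segs) {
      rows <- run[s[1]:s[2]]
      span <- eidx[rows[length(rows)]] - eidx[rows[1]] + 1
      if (span < min_ep) next
      med <- stats::median(speed[rows])
      out[[length(out) + 1]] <- data.frame(
        i0 = rows[1], i1 = rows[length(rows)],
        mode = unname(c(walk_band = "walk", cycle_band = "cycle",
                        passive_band = "passive")[
                          classify_epoch_speed(med, config)]),
        span = span)
    }
  }
  if (length(out) == 0) {
    return(data.frame(i0 = integer(), i1 = integer(), mode = character(),
                      span = integer()))
  }
  do.call(rbind, out)
}

# Non-wear oracle: an epoch is non-wear iff it lies inside some window of
# >= `need` consecutive grid epochs that all carry zero counts. Computed by
# a running-sum window scan (the implementation uses maximal-run extraction
# instead). Returns the logical per-epoch indicator.
oracle_nonwear_indicator <- function(eidx, counts, config) {
  n <- length(counts)
  need <- ceiling(config$nonwear_min * 60 / config$epoch_s)
  zero <- !is.na(counts) & counts == 0
  contiguous <- c(TRUE, diff(eidx) == 1)
  nonwear <- rep(FALSE, n)
  if (n < need) return(nonwear)
  # running count of qualifying epochs ending at each position
  runlen <- integer(n)
  runlen[1] <- as.integer(zero[1])
  for (k in 2:n) {
    runlen[k] <- if (zero[k] && contiguous[k]) runlen[k - 1] + 1L else
      as.integer(zero[k])
  }
  ends <- which(runlen >= need)
  for (e in ends) nonwear[(e - need + 1):e] <- TRUE
  # windows extend left through any epoch already in a qualifying window:
  # covered by marking every window of length `need`; positions in longer
  # runs are covered because every suffix window of the run qualifies
  nonwear
}

# random epoch stream on a (possibly gappy) grid for the oracle tests
random_epoch_stream <- function(n, seed, p_move = 0.35, p_gap = 0.01) {
  set.seed(seed)
  gaps <- sample(0:30, n, TRUE, prob = c(1 - p_gap, rep(p_gap / 30, 30)))
  eidx <- cumsum(1 + gaps)
  state <- sample(c("stat", "walk", "cycle", "passive"), n, TRUE,
                  prob = c(1 - p_move, p_move * c(0.5, 0.3, 0.2)))
  speed <- ifelse(state == "stat", runif(n, 0, 0.99),
           ifelse(state == "walk", runif(n, 1, 9.99),
           ifelse(state == "cycle", runif(n, 10, 24.99), runif(n, 25, 80))))
  speed[runif(n) < 0.03] <- NA            # dropouts
  # make band runs persist so instances carry realistic trips
  keep <- runif(n) < 0.8
  for (k in 2:n) if (keep[k] && !is.na(speed[k - 1]) && !is.na(speed[k])) {
    speed[k] <- speed[k - 1]
  }
  list(eidx = eidx, speed = speed)
}

# convert an epoch-index stream to the epochs table detect_trips expects
stream_to_epochs <- function(eidx, speed, id = "P1",
                             origin = as.POSIXct("2013-12-03 00:00:00", tz = "UTC")) {
  data.frame(participant_id = id,
             timestamp = origin + eidx * 15,
             lat = 51, lon = 3.7, speed_kmh = speed,
             counts = 100L, stringsAsFactors = FALSE)
}

# is each trip's midpoint inside the leisure window of its day?
trip_in_leisure <- function(trips, cfg) {
  mid <- trips$start + (as.numeric(trips$end) - as.numeric(trips$start)) / 2
  date <- as.Date(mid, tz = "UTC")
  a <- cfg$anchors
  sid <- a$school_id[match(trips$participant_id, a$participant_id)]
  vapply(seq_len(nrow(trips)), function(k) {
    sch <- cfg$schools[cfg$schools$school_id == sid[k], , drop = FALSE]
    w <- leisure_window(date[k], sch)
    mins <- as.numeric(mid[k] - as.POSIXct(paste(format(date[k]), "00:00:00"),
                                           tz = "UTC"), units = "mins")
    any(mins >= w$from_min & mins < w$to_min)
  }, logical(1))
}

# greedy overlap matching of detected against true trips; returns counts
# and mode accuracy among matches
match_trips <- function(truth, detected, min_overlap_frac = 0.5) {
  used <- rep(FALSE, nrow(detected))
  tp <- 0L; mode_ok <- 0L
  for (i in seq_len(nrow(truth))) {
    cand <- which(!used &
                    detected$participant_id == truth$participant_id[i] &
                    detected$start <= truth$end[i] &
                    detected$end >= truth$start[i])
    if (length(cand) == 0) next
    ov <- vapply(cand, function(j) {
      as.numeric(min(detected$end[j], truth$end[i]) -
                   max(detected$start[j], truth$start[i]), units = "secs")
    }, numeric(1))
    j <- cand[which.max(ov)]
    if (max(ov) >= min_overlap_frac *
        as.numeric(truth$end[i] - truth$start[i], units = "secs")) {
      used[j] <- TRUE
      tp <- tp + 1L
      if (detected$mode[j] == truth$mode[i]) mode_ok <- mode_ok + 1L
    }
  }
  list(tp = tp, fp = nrow(detected) - tp, fn = nrow(truth) - tp,
       f1 = 2 * tp / (2 * tp + (nrow(detected) - tp) + (nrow(truth) - tp)),
       mode_acc = if (tp > 0) mode_ok / tp else NA_real_)
}
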