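# Synthetic-study generator. Emulates a one-week combined GPS +
# accelerometer protocol in 10-12 year olds: 15-s epoch streams with
# walking/cycling/vehicle trips and stationary pauses, GPS dropouts and
# positional noise, accelerometer wear/non-wear blocks, school commutes on a
# Belgian primary-school schedule, under-reported travel diaries, and
# parental neighbourhood-environment questionnaires optionally linked to the
# transport outcomes. Everything is returned together with a ground-truth
# manifest so each downstream stage can be verified.

#' Synthetic-study configuration
#'
#' Defaults reproduce the study conditions the pipeline targets: 126
#' children in 8 classes at 4 schools wearing the devices for 7 consecutive
#' days (Monday through Sunday, so two weekend days), device epoch 15 s,
#' median positional error 2.9 m, trip rates and durations per mode and
#' stratum at the levels observed by GPS in this population, and a diary
#' that heavily under-reports active trips (report probability 0.2 for
#' walking and cycling) while reporting passive transport quite accurately
#' (0.9, plus a small over-report rate that keeps the passive diary unbiased
#' on average).
#'
#' @param n_participants,n_schools,n_classes cohort structure (classes are
#'   nested in schools).
#' @param days number of consecutive days starting on `start_date` (a
#'   Monday by default, so 7 days include one weekend).
#' @param start_date first calendar day (instruments handed out during it).
#' @param day1_handout_hour hour wear starts on day 1 (handed out at school).
#' @param trip_rate mean leisure trips/day by mode and stratum (matrix-like
#'   list `week`/`weekend`, each named by mode).
#' @param trip_minutes mean minutes/trip by mode and stratum.
#' @param engage_prob probability a participant engages in a mode at all
#'   within a stratum (zero-part of the generator).
#' @param speed_mean,speed_sd,speed_clip per-mode epoch speed distribution
#'   (km/h), clipped to `speed_clip` within the mode's band.
#' @param pause_prob probability a trip contains a stationary pause.
#' @param pause_min_range pause duration range in minutes (within the 5-min
#'   stationary allowance).
#' @param dropout_prob per-epoch probability a GPS fix is missing.
#' @param noise_sd_m isotropic positional noise SD in metres (device-grade
#'   2.9 m).
#' @param speed_noise_sd_kmh SD of device (Doppler) speed noise in km/h.
#' @param nonwear_per_week mean number of injected non-wear blocks per
#'   participant-week; `nonwear_min_range` their duration range (minutes).
#' @param low_compliance_frac fraction of children who wear the devices too
#'   little to be included.
#' @param report_prob diary report probability per mode.
#' @param phantom_passive_per_day rate of diary passive trips without a
#'   matching GPS trip (over-report model).
#' @param commute_mode_probs probability a child walks vs cycles to school.
#' @param env_beta_count,env_beta_zero named coefficients (per subscale)
#'   linking environment scores to log trip rates and to the logit of
#'   engaging; defaults are zero (no association).
#' @param class_sd_count,class_sd_zero SDs of class-level random intercepts
#'   on the two links.
#' @param sd_subscale SD of the latent subscale values across parents.
#' @param seed RNG seed; the whole simulation is deterministic given it.
#'
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 126, n_schools = 4, n_classes = 8,
                         days = 7, start_date = as.Date("2013-12-01") + 1,
                         day1_handout_hour = 13,
                         trip_rate = list(
                           week = c(walk = 3.96, cycle = 1.17, passive = 1.87),
                           weekend = c(walk = 1.59, cycle = 0.87, passive = 2.12)),
                         trip_minutes = list(
                           week = c(walk = 6.83, cycle = 6.23, passive = 8.37),
                           weekend = c(walk = 7.89, cycle = 6.67, passive = 15.90)),
                         engage_prob = list(
                           week = c(walk = 1.00, cycle = 0.90, passive = 0.85),
                           weekend = c(walk = 0.75, cycle = 0.67, passive = 0.79)),
                         speed_mean = c(walk = 5, cycle = 16, passive = 40),
                         speed_sd = c(walk = 1.5, cycle = 3, passive = 8),
                         speed_clip = list(walk = c(1.5, 9.5),
                                           cycle = c(10.5, 24.5),
                                           passive = c(25.5, 70)),
                         pause_prob = 0.3, pause_min_range = c(1, 4),
                         dropout_prob = 0.05, noise_sd_m = 2.9,
                         speed_noise_sd_kmh = 0.5,
                         nonwear_per_week = 2, nonwear_min_range = c(60, 110),
                         low_compliance_frac = 0.15,
                         report_prob = c(walk = 0.2, cycle = 0.2, passive = 0.9),
                         phantom_passive_per_day = 0.2,
                         commute_mode_probs = c(walk = 0.55, cycle = 0.45),
                         env_beta_count = NULL, env_beta_zero = NULL,
                         class_sd_count = 0.1, class_sd_zero = 0.25,
                         sd_subscale = 0.5,
                         seed = 1) {
  zero_env <- stats::setNames(numeric(7), c("residential_density", env_subscales()))
  cfg <- list(
    n_participants = n_participants, n_schools = n_schools,
    n_classes = n_classes, days = days, start_date = start_date,
    day1_handout_hour = day1_handout_hour,
    trip_rate = trip_rate, trip_minutes = trip_minutes,
    engage_prob = engage_prob,
    speed_mean = speed_mean, speed_sd = speed_sd, speed_clip = speed_clip,
    pause_prob = pause_prob, pause_min_range = pause_min_range,
    dropout_prob = dropout_prob, noise_sd_m = noise_sd_m,
    speed_noise_sd_kmh = speed_noise_sd_kmh,
    nonwear_per_week = nonwear_per_week, nonwear_min_range = nonwear_min_range,
    low_compliance_frac = low_compliance_frac,
    report_prob = report_prob,
    phantom_passive_per_day = phantom_passive_per_day,
    commute_mode_probs = commute_mode_probs,
    env_beta_count = if (is.null(env_beta_count)) zero_env else env_beta_count,
    env_beta_zero = if (is.null(env_beta_zero)) zero_env else env_beta_zero,
    class_sd_count = class_sd_count, class_sd_zero = class_sd_zero,
    sd_subscale = sd_subscale,
    seed = seed
  )
  stopifnot(all(unlist(cfg$report_prob) >= 0), all(unlist(cfg$report_prob) <= 1),
            cfg$dropout_prob >= 0, cfg$dropout_prob <= 1,
            cfg$days >= 1, cfg$n_participants >= 1)
  class(cfg) <- "synth_config"
  cfg
}

# reject configurations whose expected excursion time cannot fit the
# leisure time of a typical (full-wear) day
check_feasible <- function(cfg) {
  for (st in c("week", "weekend")) {
    block_min <- 2 * (cfg$trip_minutes[[st]] + cfg$pause_min_range[2] + 6) + 19
    need <- sum(cfg$trip_rate[[st]] / 2 * block_min)
    avail <- if (st == "week") 6.5 * 60 else 14 * 60
    if (need > 0.85 * avail) {
      stop("infeasible synthetic configuration: expected ", round(need),
           " min/day of ", st, " excursions exceeds the ~", round(avail),
           " min of leisure time available")
    }
  }
  invisible(cfg)
}

EP_DAY <- 5760L                 # 15-s epochs per day
EP_MIN <- 4L                    # epochs per minute

# local metric frame around a reference point
local_to_wgs <- function(x_m, y_m, lat0, lon0) {
  list(lat = lat0 + y_m / 111320,
       lon = lon0 + x_m / (111320 * cos(lat0 * pi / 180)))
}

clip_speed <- function(v, clip) pmin(pmax(v, clip[1]), clip[2])

# draw per-epoch speeds for one trip of m moving epochs
draw_speeds <- function(m, mode, cfg) {
  clip_speed(stats::rnorm(m, cfg$speed_mean[mode], cfg$speed_sd[mode]),
             cfg$speed_clip[[mode]])
}

# subtract occupied intervals (with margin) from windows; all in epoch units,
# half-open [from, to)
free_intervals <- function(windows, occupied, margin) {
  if (nrow(windows) == 0) return(windows)
  if (nrow(occupied) > 0) {
    occ <- occupied
    occ$from <- occ$from - margin
    occ$to <- occ$to + margin
    occ <- occ[order(occ$from), , drop = FALSE]
  } else occ <- occupied
  out <- list()
  for (i in seq_len(nrow(windows))) {
    a <- windows$from[i]; b <- windows$to[i]
    if (nrow(occ) > 0) {
      for (j in seq_len(nrow(occ))) {
        oa <- occ$from[j]; ob <- occ$to[j]
        if (ob <= a || oa >= b) next
        if (oa > a) out[[length(out) + 1]] <- c(a, oa)
        a <- max(a, ob)
        if (a >= b) break
      }
    }
    if (a < b) out[[length(out) + 1]] <- c(a, b)
  }
  if (length(out) == 0) return(data.frame(from = numeric(), to = numeric()))
  m <- do.call(rbind, out)
  data.frame(from = m[, 1], to = m[, 2])
}

# sample a start epoch for a block of length L from free intervals
sample_slot <- function(free, L) {
  cap <- pmax(0, floor(free$to - free$from - L + 1))
  if (sum(cap) <= 0) return(NA_integer_)
  i <- sample.int(nrow(free), 1, prob = cap)
  free$from[i] + sample.int(cap[i], 1) - 1
}

#' Simulate a complete synthetic study
#'
#' Generates GPS and accelerometer epoch streams, travel diaries,
#' parental questionnaires, the matching [study_config()] (schools,
#' schedules, home/school anchors), and a ground-truth manifest. School
#' commutes are injected on every school day covered by wear time (see
#' [inject_school_commutes()]); all other trips are home-based leisure
#' excursions placed inside leisure windows, so the manifest's leisure
#' trips are exactly its non-school trips.
#'
#' @param cfg a [synth_config()].
#' @param include_commutes add home-school commutes (default TRUE).
#' @return list with elements `gps`, `accel` (epoch data frames), `diary`,
#'   `questionnaire`, `study_config`, and `manifest` (list of `participants`,
#'   `trips`, `weardays`, `inclusion`, `nonwear`, `epoch_counts`,
#'   `env_effects`).
#' @export
simulate_study <- function(cfg = synth_config(), include_commutes = TRUE) {
  check_feasible(cfg)
  set.seed(cfg$seed)
  schools <- school_table(
    school_id = paste0("S", seq_len(cfg$n_schools)),
    lat = 51.0 + seq_len(cfg$n_schools) * 0.03,
    lon = 3.7 + seq_len(cfg$n_schools) * 0.04)
  urban <- rep(c(TRUE, FALSE), length.out = cfg$n_schools)

  n <- cfg$n_participants
  pid <- sprintf("P%03d", seq_len(n))
  school_of_class <- rep(seq_len(cfg$n_schools), length.out = cfg$n_classes)
  class_id <- paste0("C", rep(seq_len(cfg$n_classes), length.out = n))
  school_ix <- school_of_class[rep(seq_len(cfg$n_classes), length.out = n)]
  school_id <- schools$school_id[school_ix]

  # homes 700-1800 m from the child's school, random bearing
  hb <- stats::runif(n, 0, 2 * pi)
  hd <- stats::runif(n, 700, 1800)
  home <- local_to_wgs(hd * cos(hb), hd * sin(hb),
                       schools$lat[school_ix], schools$lon[school_ix])
  commute_mode <- sample(names(cfg$commute_mode_probs), n, TRUE,
                         prob = cfg$commute_mode_probs)
  commute_speed <- ifelse(commute_mode == "walk", 4.8, 12)
  commute_ep <- pmax(ceiling(hd / (commute_speed / 3.6 * 15)),
                     12 + 1)   # always above the minimum trip duration

  age <- round(stats::runif(n, 10, 12), 1)
  sex <- sample(c("girl", "boy"), n, TRUE, prob = c(0.64, 0.36))
  ses <- sample(c("high", "low"), n, TRUE, prob = c(0.75, 0.25))
  low_comp <- stats::runif(n) < cfg$low_compliance_frac

  # ---- questionnaire + environment link ------------------------------------
  subs <- c("residential_density", env_subscales())
  q <- questionnaire_draw(n, pid, class_id, school_id, urban[school_ix],
                          age, sex, ses, cfg)
  scores <- score_questionnaire(q)
  zmat <- scale(as.matrix(scores[, subs]))
  zmat[is.na(zmat)] <- 0
  b_cl_count <- stats::setNames(stats::rnorm(cfg$n_classes, 0, cfg$class_sd_count),
                                paste0("C", seq_len(cfg$n_classes)))
  b_cl_zero <- stats::setNames(stats::rnorm(cfg$n_classes, 0, cfg$class_sd_zero),
                               paste0("C", seq_len(cfg$n_classes)))
  rate_mult <- exp(drop(zmat %*% cfg$env_beta_count[subs]) + b_cl_count[class_id])
  zero_shift <- drop(zmat %*% cfg$env_beta_zero[subs]) + b_cl_zero[class_id]

  dates <- cfg$start_date + seq_len(cfg$days) - 1
  wd <- as.integer(format(dates, "%u"))
  is_weekend <- wd >= 6
  modes <- c("walk", "cycle", "passive")

  # per participant x stratum x mode engagement (zero part of the generator)
  engage <- array(FALSE, c(n, 2, 3),
                  dimnames = list(pid, c("week", "weekend"), modes))
  for (st in c("week", "weekend")) for (mo in modes) {
    p0 <- cfg$engage_prob[[st]][mo]
    pe <- if (p0 >= 1) rep(1, n) else stats::plogis(stats::qlogis(p0) + zero_shift)
    engage[, st, mo] <- stats::runif(n) < pe
  }

  gps_l <- list(); acc_l <- list(); trips_l <- list(); nonwear_l <- list()
  diary_l <- list()

  for (i in seq_len(n)) {
    sim_p <- simulate_participant(
      i, pid[i], dates, wd, is_weekend, cfg,
      home_lat = home$lat[i], home_lon = home$lon[i],
      school = schools[school_ix[i], ],
      commute_mode = commute_mode[i], commute_ep = commute_ep[i],
      engage_i = engage[i, , ], rate_mult = rate_mult[i],
      low_comp = low_comp[i], include_commutes = include_commutes)
    gps_l[[i]] <- sim_p$gps; acc_l[[i]] <- sim_p$accel
    trips_l[[i]] <- sim_p$trips; nonwear_l[[i]] <- sim_p$nonwear
  }
  gps <- do.call(rbind, gps_l)
  accel <- do.call(rbind, acc_l)
  trips <- do.call(rbind, trips_l)
  nonwear <- do.call(rbind, nonwear_l)
  rownames(gps) <- rownames(accel) <- rownames(trips) <- NULL

  diary <- diary_draw(trips, pid, dates, is_weekend, cfg)

  anchors <- data.frame(participant_id = pid, home_lat = home$lat,
                        home_lon = home$lon, school_id = school_id,
                        stringsAsFactors = FALSE)
  study_cfg <- study_config(schools = schools, anchors = anchors)

  manifest <- build_manifest(pid, class_id, school_id, age, sex, ses,
                             low_comp, commute_mode, home, gps, accel, trips,
                             nonwear, dates, is_weekend, cfg, study_cfg)
  list(gps = gps, accel = accel, diary = diary, questionnaire = q,
       study_config = study_cfg, manifest = manifest, config = cfg)
}

questionnaire_draw <- function(n, pid, class_id, school_id, urban,
                               age, sex, ses, cfg) {
  q <- data.frame(participant_id = pid, class_id = class_id,
                  school_id = school_id, age = age, sex = sex, ses = ses,
                  stringsAsFactors = FALSE)
  # density items: urban neighbourhoods have more row houses / apartments
  q$res_density_a <- pmin(4, pmax(0, round(stats::rnorm(n, ifelse(urban, 2, 3.2), 0.8))))
  q$res_density_b <- pmin(4, pmax(0, round(stats::rnorm(n, ifelse(urban, 2.5, 1.2), 0.9))))
  q$res_density_c <- pmin(4, pmax(0, round(stats::rnorm(n, ifelse(urban, 1.8, 0.5), 0.9))))
  n_items <- c(land_use_mix_access = 6, street_connectivity = 3,
               walk_cycle_facilities = 5, aesthetics = 4,
               traffic_safety = 5, crime_safety = 4)
  for (s in names(n_items)) {
    latent <- stats::rnorm(n, 2.5, cfg$sd_subscale)
    for (k in seq_len(n_items[s])) {
      q[[paste0(s, "_", k)]] <-
        pmin(4, pmax(1, round(latent + stats::rnorm(n, 0, 0.6))))
    }
  }
  q
}

simulate_participant <- function(i, id, dates, wd, is_weekend, cfg,
                                 home_lat, home_lon, school,
                                 commute_mode, commute_ep,
                                 engage_i, rate_mult, low_comp,
                                 include_commutes) {
  margin <- 24L                       # 6-min separation between events
  modes <- c("walk", "cycle", "passive")
  gps_days <- list(); acc_days <- list(); trip_days <- list(); nw_l <- list()
  fail <- 0L; tried <- 0L

  for (d in seq_along(dates)) {
    date <- dates[d]
    day0 <- as.numeric(as.POSIXct(paste0(format(date), "T00:00:00"),
                                  format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    # wear window in epochs from midnight
    ws <- round((7 + stats::runif(1, 0, 0.5)) * 240)
    we <- round((21 + stats::runif(1, 0, 0.75)) * 240)
    if (d == 1) ws <- max(ws, round(cfg$day1_handout_hour * 240))
    if (low_comp && d > 1 && stats::runif(1) < 0.7) {
      we <- ws + round(stats::runif(1, 4, 7) * 240)   # short wear day
    }

    # leisure windows (epochs) intersected with wear
    if (is_weekend[d]) {
      lw <- data.frame(from = ws, to = we)
      commutes <- NULL
    } else {
      day <- c("mon", "tue", "wed", "thu", "fri")[wd[d]]
      s_ep <- school[[paste0("start_", day)]] * EP_MIN
      e_ep <- school[[paste0("end_", day)]] * EP_MIN
      commutes <- data.frame(
        leg = c("morning", "afternoon"),
        from = c(s_ep - 20 - commute_ep, e_ep + 20),
        to = c(s_ep - 20, e_ep + 20 + commute_ep))
      keep <- commutes$from >= ws & commutes$to <= we
      lw <- data.frame(from = c(ws, e_ep), to = c(s_ep, we))
      lw <- lw[lw$to - lw$from > 0, , drop = FALSE]
      # reserve commute windows inside leisure regardless of rendering
      lw <- free_intervals(lw, commutes[, c("from", "to")], margin)
      commutes <- commutes[keep, , drop = FALSE]
      if (!include_commutes) commutes <- NULL
      lw <- lw[lw$to - lw$from >= 12, , drop = FALSE]
    }

    st <- if (is_weekend[d]) "weekend" else "week"
    occupied <- data.frame(from = numeric(), to = numeric())
    events <- list()

    # leisure excursions (out + back, home-based)
    for (mo in modes) {
      if (!engage_i[st, mo]) next
      lam <- cfg$trip_rate[[st]][mo] / max(cfg$engage_prob[[st]][mo], 1e-9) *
        rate_mult / 2
      n_exc <- stats::rpois(1, lam)
      if (n_exc == 0) next
      for (e in seq_len(n_exc)) {
        dur_min <- max(3.25, 3 + stats::rexp(1, 1 / max(cfg$trip_minutes[[st]][mo] - 3, 0.5)))
        m_ep <- round(dur_min * EP_MIN)
        dwell <- round(stats::runif(1, 8, 30) * EP_MIN)
        pmax_ep <- round(cfg$pause_min_range[2] * EP_MIN)
        L <- 2 * (m_ep + pmax_ep) + dwell   # budget for a pause on each leg
        tried <- tried + 1L
        slot <- sample_slot(free_intervals(lw, occupied, margin), L)
        if (is.na(slot)) { fail <- fail + 1L; next }
        occupied <- rbind(occupied, data.frame(from = slot, to = slot + L))
        events[[length(events) + 1]] <- list(kind = "excursion", mode = mo,
                                             from = slot, m_ep = m_ep,
                                             dwell = dwell)
      }
    }
    # failed placements on short days thin the realized rate; configs whose
    # rates cannot fit a normal day are rejected up front in simulate_study

    # non-wear blocks in free wear time
    nw_day <- data.frame(from = integer(), to = integer())
    n_nw <- stats::rpois(1, cfg$nonwear_per_week / length(dates))
    if (n_nw > 0) {
      all_w <- data.frame(from = ws, to = we)
      occ_all <- rbind(occupied,
                       if (!is.null(commutes)) commutes[, c("from", "to")])
      for (b in seq_len(n_nw)) {
        len <- round(stats::runif(1, cfg$nonwear_min_range[1],
                                  cfg$nonwear_min_range[2]) * EP_MIN)
        slot <- sample_slot(free_intervals(all_w, rbind(occ_all, nw_day), margin), len)
        if (is.na(slot)) next
        nw_day <- rbind(nw_day, data.frame(from = slot, to = slot + len))
      }
    }

    r <- render_day(id, date, day0, ws, we, events, commutes, nw_day,
                    home_lat, home_lon, school, commute_mode, commute_ep,
                    cfg, st)
    gps_days[[d]] <- r$gps; acc_days[[d]] <- r$accel; trip_days[[d]] <- r$trips
    if (nrow(nw_day) > 0) {
      nw_l[[d]] <- data.frame(
        participant_id = id, date = date,
        start = as.POSIXct(day0 + nw_day$from * 15, origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(day0 + (nw_day$to - 1) * 15, origin = "1970-01-01", tz = "UTC"),
        minutes = (nw_day$to - nw_day$from) / EP_MIN)
    }
  }
  list(gps = do.call(rbind, gps_days), accel = do.call(rbind, acc_days),
       trips = do.call(rbind, trip_days),
       nonwear = if (length(nw_l)) do.call(rbind, nw_l) else NULL)
}

# render one participant-day into GPS/accel epoch rows plus true trips
render_day <- function(id, date, day0, ws, we, events, commutes, nw_day,
                       home_lat, home_lon, school, commute_mode, commute_ep,
                       cfg, stratum) {
  n_ep <- we - ws
  if (n_ep <= 0) {
    return(list(gps = NULL, accel = NULL, trips = NULL))
  }
  ep <- ws:(we - 1)                       # epoch index within day
  speed <- numeric(n_ep)                  # true speed, km/h
  x <- numeric(n_ep); y <- numeric(n_ep)  # local metres relative to school
  lat0 <- school$lat; lon0 <- school$lon
  hx <- (home_lon - lon0) * 111320 * cos(lat0 * pi / 180)
  hy <- (home_lat - lat0) * 111320
  x[] <- hx; y[] <- hy                    # default: at home
  counts <- stats::rpois(n_ep, 60) * stats::rbinom(n_ep, 1, 0.8)
  trips <- list()

  put_trip <- function(from_ep, speeds, x0, y0, bearing, mode, is_school,
                       start_anchor, end_anchor, retrace = NULL) {
    m <- length(speeds)
    ix <- match(from_ep:(from_ep + m - 1), ep)
    step <- speeds * 15 / 3.6
    if (is.null(retrace)) {
      xs <- x0 + cos(bearing) * cumsum(step)
      ys <- y0 + sin(bearing) * cumsum(step)
    } else {
      xs <- retrace$x; ys <- retrace$y
    }
    speed[ix] <<- speeds
    x[ix] <<- xs; y[ix] <<- ys
    act <- c(walk = 350, cycle = 250, passive = 30)[mode]
    counts[ix] <<- stats::rpois(m, act) * stats::rbinom(m, 1, 0.9)
    trips[[length(trips) + 1]] <<- data.frame(
      participant_id = id, date = date,
      start = as.POSIXct(day0 + (from_ep) * 15, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(day0 + (from_ep + m - 1) * 15, origin = "1970-01-01", tz = "UTC"),
      mode = mode, duration_min = m / EP_MIN,
      is_school_trip = is_school, stratum = stratum,
      start_anchor = start_anchor, end_anchor = end_anchor,
      stringsAsFactors = FALSE)
    list(x = xs, y = ys)
  }

  insert_pause <- function(speeds) {
    # stationary run strictly inside the trip, within the 5-min allowance
    if (stats::runif(1) > cfg$pause_prob || length(speeds) < 6 * EP_MIN)
      return(speeds)
    plen <- round(stats::runif(1, cfg$pause_min_range[1],
                               cfg$pause_min_range[2]) * EP_MIN)
    at <- sample(seq(EP_MIN + 1, length(speeds) - EP_MIN), 1)
    c(speeds[1:at], rep(0, plen), speeds[(at + 1):length(speeds)])
  }

  # school commutes along the exact home-school line
  if (!is.null(commutes) && nrow(commutes) > 0) {
    d_hs <- sqrt(hx^2 + hy^2)
    for (ci in seq_len(nrow(commutes))) {
      m <- commutes$to[ci] - commutes$from[ci]
      v <- draw_speeds(m, commute_mode, cfg)
      v <- v * d_hs / sum(v * 15 / 3.6)   # land exactly at the far anchor
      v <- clip_speed(v, cfg$speed_clip[[commute_mode]])
      frac <- cumsum(v * 15 / 3.6) / sum(v * 15 / 3.6)
      if (commutes$leg[ci] == "morning") {
        xs <- hx + (0 - hx) * frac; ys <- hy + (0 - hy) * frac
        put_trip(commutes$from[ci], v, hx, hy, 0, commute_mode, TRUE,
                 "home", "school", retrace = list(x = xs, y = ys))
        # at school until the afternoon leg
        ix <- which(ep >= commutes$to[ci] &
                      ep < (if (nrow(commutes) > 1) commutes$from[2] else we))
        x[ix] <- 0; y[ix] <- 0
      } else {
        xs <- 0 + (hx - 0) * frac; ys <- 0 + (hy - 0) * frac
        put_trip(commutes$from[ci], v, 0, 0, 0, commute_mode, TRUE,
                 "school", "home", retrace = list(x = xs, y = ys))
      }
    }
  }

  for (ev in events) {
    out_speeds <- draw_speeds(ev$m_ep, ev$mode, cfg)
    # keep the destination clear of the school geofence so leisure trips are
    # never mistaken for commutes
    dist <- sum(out_speeds * 15 / 3.6)
    repeat {
      bearing <- stats::runif(1, 0, 2 * pi)
      dest0 <- c(hx + dist * cos(bearing), hy + dist * sin(bearing))
      if (sqrt(sum(dest0^2)) > 200) break
    }
    out_full <- insert_pause(out_speeds)
    tr <- put_trip(ev$from, out_full, hx, hy, bearing, ev$mode, FALSE,
                   "home", "away")
    moving <- out_full > 0
    dest_x <- tr$x[length(tr$x)]; dest_y <- tr$y[length(tr$y)]
    # dwell at the destination
    ix <- match((ev$from + length(out_full)):(ev$from + length(out_full) + ev$dwell - 1), ep)
    ix <- ix[!is.na(ix)]
    x[ix] <- dest_x; y[ix] <- dest_y
    # return leg retraces the outbound moving positions in reverse
    back_speeds <- rev(out_speeds)
    back_full <- insert_pause(back_speeds)
    mv <- which(out_full > 0)
    path_x <- c(rev(tr$x[mv][-length(mv)]), hx)
    path_y <- c(rev(tr$y[mv][-length(mv)]), hy)
    bx <- numeric(length(back_full)); by <- numeric(length(back_full))
    pos <- 0
    cur_x <- dest_x; cur_y <- dest_y
    for (k in seq_along(back_full)) {
      if (back_full[k] > 0) { pos <- pos + 1; cur_x <- path_x[pos]; cur_y <- path_y[pos] }
      bx[k] <- cur_x; by[k] <- cur_y
    }
    back_from <- ev$from + length(out_full) + ev$dwell
    put_trip(back_from, back_full, dest_x, dest_y, 0, ev$mode, FALSE,
             "away", "home", retrace = list(x = bx, y = by))
  }

  # accelerometer: zero counts inside injected non-wear blocks
  if (nrow(nw_day) > 0) {
    for (b in seq_len(nrow(nw_day))) {
      counts[ep >= nw_day$from[b] & ep < nw_day$to[b]] <- 0L
    }
  }
  ts <- as.POSIXct(day0 + ep * 15, origin = "1970-01-01", tz = "UTC")
  accel <- data.frame(participant_id = id, timestamp = ts, counts = counts,
                      stringsAsFactors = FALSE)

  # GPS: absent during non-wear, random dropout, positional + speed noise
  has_fix <- rep(TRUE, n_ep)
  if (nrow(nw_day) > 0) {
    for (b in seq_len(nrow(nw_day))) {
      has_fix[ep >= nw_day$from[b] & ep < nw_day$to[b]] <- FALSE
    }
  }
  if (cfg$dropout_prob > 0) {
    has_fix <- has_fix & stats::runif(n_ep) >= cfg$dropout_prob
  }
  xn <- x + stats::rnorm(n_ep, 0, cfg$noise_sd_m)
  yn <- y + stats::rnorm(n_ep, 0, cfg$noise_sd_m)
  sp <- pmax(0, speed + stats::rnorm(n_ep, 0, cfg$speed_noise_sd_kmh))
  ll <- local_to_wgs(xn, yn, lat0, lon0)
  gps <- data.frame(participant_id = id, timestamp = ts[has_fix],
                    lat = ll$lat[has_fix], lon = ll$lon[has_fix],
                    speed_kmh = sp[has_fix], stringsAsFactors = FALSE)
  list(gps = gps, accel = accel,
       trips = if (length(trips)) do.call(rbind, trips) else NULL)
}

diary_draw <- function(trips, pid, dates, is_weekend, cfg) {
  rows <- list()
  if (!is.null(trips) && nrow(trips) > 0) {
    p_rep <- ifelse(trips$is_school_trip, 0.95, cfg$report_prob[trips$mode])
    rep_flag <- stats::runif(nrow(trips)) < p_rep
    if (any(rep_flag)) {
      rows[[1]] <- data.frame(
        participant_id = trips$participant_id[rep_flag],
        date = trips$date[rep_flag],
        mode = trips$mode[rep_flag],
        is_school_trip = trips$is_school_trip[rep_flag],
        stringsAsFactors = FALSE)
    }
  }
  # over-report: diary passive trips with no matching GPS trip
  if (cfg$phantom_passive_per_day > 0) {
    grid <- expand.grid(participant_id = pid, date = dates,
                        stringsAsFactors = FALSE)
    k <- stats::rpois(nrow(grid), cfg$phantom_passive_per_day)
    if (sum(k) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = rep(grid$participant_id, k),
        date = rep(grid$date, k),
        mode = "passive", is_school_trip = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(participant_id = character(), date = as.Date(character()),
                      mode = character(), is_school_trip = logical()))
  }
  d <- do.call(rbind, rows)
  d[order(d$participant_id, d$date), ]
}

build_manifest <- function(pid, class_id, school_id, age, sex, ses, low_comp,
                           commute_mode, home, gps, accel, trips, nonwear,
                           dates, is_weekend, cfg, study_cfg) {
  participants <- data.frame(
    participant_id = pid, class_id = class_id, school_id = school_id,
    age = age, sex = sex, ses = ses, low_compliance = low_comp,
    commute_mode = commute_mode, home_lat = home$lat, home_lon = home$lon,
    stringsAsFactors = FALSE)

  # combined wear recomputed from the generator's own bookkeeping:
  # accel epochs outside injected non-wear blocks that also carry a fix
  acc_key <- paste(accel$participant_id, as.numeric(accel$timestamp))
  gps_key <- paste(gps$participant_id, as.numeric(gps$timestamp))
  worn <- rep(TRUE, nrow(accel))
  if (!is.null(nonwear) && nrow(nonwear) > 0) {
    for (b in seq_len(nrow(nonwear))) {
      worn[accel$participant_id == nonwear$participant_id[b] &
             accel$timestamp >= nonwear$start[b] &
             accel$timestamp <= nonwear$end[b]] <- FALSE
    }
  }
  comb <- accel[worn & acc_key %in% gps_key, c("participant_id", "timestamp")]
  comb$date <- as.Date(comb$timestamp, tz = "UTC")
  wdtab <- expand.grid(participant_id = pid, date = dates,
                       stringsAsFactors = FALSE)
  cnt <- stats::aggregate(list(n = rep(1, nrow(comb))),
                          by = comb[, c("participant_id", "date")], FUN = sum)
  wdtab <- merge(wdtab, cnt, all.x = TRUE)
  wdtab$n[is.na(wdtab$n)] <- 0
  wdtab$combined_wear_minutes <- wdtab$n / EP_MIN
  wdtab$is_weekend <- format(wdtab$date, "%u") %in% c("6", "7")
  wdtab$is_first_day <- wdtab$date == min(dates)
  wdtab$is_valid <- !wdtab$is_first_day &
    wdtab$combined_wear_minutes >= study_cfg$min_wear_h * 60
  wdtab <- wdtab[order(wdtab$participant_id, wdtab$date),
                 c("participant_id", "date", "combined_wear_minutes",
                   "is_weekend", "is_first_day", "is_valid")]
  rownames(wdtab) <- NULL

  incl <- do.call(rbind, lapply(split(wdtab, wdtab$participant_id), function(w) {
    data.frame(participant_id = w$participant_id[1],
               n_valid_days = sum(w$is_valid),
               n_valid_weekend_days = sum(w$is_valid & w$is_weekend),
               included = sum(w$is_valid) >= study_cfg$min_valid_days &
                 sum(w$is_valid & w$is_weekend) >= study_cfg$min_weekend_days,
               stringsAsFactors = FALSE)
  }))
  rownames(incl) <- NULL

  ec <- merge(
    stats::aggregate(list(n_gps = rep(1, nrow(gps))),
                     by = list(participant_id = gps$participant_id), FUN = sum),
    stats::aggregate(list(n_accel = rep(1, nrow(accel))),
                     by = list(participant_id = accel$participant_id), FUN = sum),
    all = TRUE)
  ec$n_union <- vapply(ec$participant_id, function(p) {
    length(union(as.numeric(gps$timestamp[gps$participant_id == p]),
                 as.numeric(accel$timestamp[accel$participant_id == p])))
  }, numeric(1))

  list(participants = participants, trips = trips, weardays = wdtab,
       inclusion = incl, nonwear = nonwear, epoch_counts = ec,
       env_effects = list(count = cfg$env_beta_count, zero = cfg$env_beta_zero,
                          class_sd_count = cfg$class_sd_count,
                          class_sd_zero = cfg$class_sd_zero))
}

#' Add home-school commutes to a commute-free simulation
#'
#' Re-renders the simulation with morning home-to-school and afternoon
#' school-to-home trips on every school day whose wear window covers them
#' (Wednesday's afternoon commute happens at the early Wednesday end time).
#' The leisure excursions keep their reserved windows, so commute injection
#' never overlaps them.
#'
#' @param sim result of `simulate_study(cfg, include_commutes = FALSE)`.
#' @return a new simulation list with commutes present in the streams and
#'   flagged `is_school_trip = TRUE` in the manifest.
#' @export
inject_school_commutes <- function(sim) {
  simulate_study(sim$config, include_commutes = TRUE)
}

#' Simulate hurdle-model data with known coefficients
#'
#' Direct generator for two-part model recovery studies: engagement follows
#' a mixed logistic model and the positive amount a mixed Gamma-log model,
#' both with class-level random intercepts.
#'
#' @param n_classes,n_per_class cluster structure.
#' @param or_x true odds ratio of the single predictor in the logit part.
#' @param expb_x true exp(b) of the predictor in the Gamma part.
#' @param b0_zero,b0_pos true intercepts (link scale).
#' @param sigma_zero,sigma_pos random-intercept SDs of the two parts.
#' @param shape Gamma shape.
#' @return data frame `y, x, class_id` plus the latent `engaged` indicator.
#' @export
simulate_hurdle_data <- function(n_classes = 25, n_per_class = 20,
                                 or_x = 1.8, expb_x = 1.3,
                                 b0_zero = 0.3, b0_pos = 0.7,
                                 sigma_zero = 0.5, sigma_pos = 0.4,
                                 shape = 2) {
  n <- n_classes * n_per_class
  cl <- rep(seq_len(n_classes), each = n_per_class)
  x <- stats::rnorm(n)
  u <- stats::rnorm(n_classes, 0, sigma_zero)
  v <- stats::rnorm(n_classes, 0, sigma_pos)
  engaged <- stats::rbinom(n, 1, stats::plogis(b0_zero + log(or_x) * x + u[cl]))
  mu <- exp(b0_pos + log(expb_x) * x + v[cl])
  amount <- stats::rgamma(n, shape = shape, rate = shape / mu)
  data.frame(y = engaged * amount, x = x,
             class_id = paste0("C", cl), engaged = engaged,
             stringsAsFactors = FALSE)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- sim$gps; g$timestamp <- fmt_ts(g$timestamp)
  utils::write.csv(g, file.path(dir, "gps.csv"), row.names = FALSE, na = "")
  a <- sim$accel; a$timestamp <- fmt_ts(a$timestamp)
  utils::write.csv(a, file.path(dir, "accel.csv"), row.names = FALSE, na = "")
  utils::write.csv(sim$diary, file.path(dir, "diary.csv"), row.names = FALSE)
  utils::write.csv(sim$questionnaire, file.path(dir, "questionnaire.csv"),
                   row.names = FALSE)
  write_study_config(sim$study_config, file.path(dir, "study_config.yaml"))
  tr <- sim$manifest$trips
  tr$start <- fmt_ts(tr$start); tr$end <- fmt_ts(tr$end)
  utils::write.csv(tr, file.path(dir, "manifest_trips.csv"), row.names = FALSE)
  utils::write.csv(sim$manifest$weardays, file.path(dir, "manifest_weardays.csv"),
                   row.names = FALSE)
  yaml::write_yaml(sim$manifest$env_effects, file.path(dir, "manifest_env.yaml"))
  invisible(dir)
}
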