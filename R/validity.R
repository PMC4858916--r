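#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform
#' `t = r * sqrt((n-2)/(1-r^2))` with `n-2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3), pairwise-complete pairs
#'   are used.
#' @return list `r, n, p`; `r` is `NA` (flagged) when either vector has zero
#'   variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(r = NA_real_, n = n, p = NA_real_))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = n, p = NA_real_))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), n = n, p = ct$p.value)
}

#' Classify a correlation as low / moderate / high
#'
#' Conventional cutoffs: low when `|r|` <= 0.30, moderate 0.31-0.50, high
#' above 0.50. Boundaries are inclusive downwards (0.30 is low, 0.50
#' moderate).
#'
#' @param r numeric vector of correlations.
#' @return character vector in `c("low","moderate","high")`.
#' @export
classify_r <- function(r) {
  a <- abs(r)
  ifelse(a <= 0.30, "low", ifelse(a <= 0.50, "moderate", "high"))
}

#' Paired t-test from raw paired data
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the differences, `df = n - 1`,
#' two-sided p.
#'
#' @param x,y paired numeric vectors; pairwise-complete pairs are used.
#' @return list `t, df, p, n, mean_diff`; infinite `t` (zero-variance
#'   differences with nonzero mean) is flagged via `p = 0`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                         n = n, mean_diff = mean(d)))
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    return(list(t = t, df = n - 1, p = if (is.finite(t)) 1 else 0,
                n = n, mean_diff = mean(d)))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       n = n, mean_diff = mean(d))
}

#' Paired t-statistic from summary statistics
#'
#' Algebraically identical to [paired_t()] but computed from the two means,
#' the two SDs, their correlation, and n:
#' `t = (m1 - m2) / sqrt((sd1^2 + sd2^2 - 2 r sd1 sd2) / n)`.
#' Useful to reconstruct published t-values from printed tables.
#'
#' @param m1,sd1 mean and SD of the first measure.
#' @param m2,sd2 mean and SD of the second measure.
#' @param r Pearson correlation between the paired measures.
#' @param n number of pairs.
#' @return list `t, df, p`.
#' @export
paired_t_summary <- function(m1, sd1, m2, sd2, r, n) {
  se <- sqrt((sd1^2 + sd2^2 - 2 * r * sd1 * sd2) / n)
  t <- (m1 - m2) / se
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

wide_by_mode_stratum <- function(out, value) {
  d <- out[, c("participant_id", "stratum", "mode", value)]
  stats::reshape(d, idvar = "participant_id",
                 timevar = "stratum", direction = "wide",
                 v.names = value)
}

#' GPS versus diary concurrent-validity table
#'
#' One row per mode and stratum comparing GPS-determined with self-reported
#' trips/day (means, SDs, Pearson r with its class, paired t), plus GPS
#' week-versus-weekend comparisons for trips/day, minutes/day and
#' minutes/trip, plus the percentage of included participants not engaging in
#' each mode per instrument. Participants missing one side of a comparison
#' are dropped pairwise for that row.
#'
#' @param outcomes GPS outcome table from [compute_outcomes()].
#' @param diary_outcomes diary outcome table from [compute_diary_outcomes()].
#' @return data frame with columns `comparison, mode, stratum, measure, n,
#'   mean_1, sd_1, mean_2, sd_2, pearson_r, r_class, t, df, p`.
#' @export
compare_table <- function(outcomes, diary_outcomes) {
  rows <- list()
  modes <- c("walk", "cycle", "passive")
  grab <- function(tab, mode, stratum, col) {
    t2 <- tab[tab$mode == mode & tab$stratum == stratum,
              c("participant_id", col)]
    names(t2)[2] <- "v"
    t2
  }
  add_row <- function(comparison, mode, stratum, measure, a, b) {
    m <- merge(a, b, by = "participant_id")
    x <- m$v.x; y <- m$v.y
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    pr <- pearson_r(x, y)
    tt <- paired_t(x, y)
    rows[[length(rows) + 1]] <<- data.frame(
      comparison = comparison, mode = mode, stratum = stratum,
      measure = measure, n = length(x),
      mean_1 = mean(x), sd_1 = stats::sd(x),
      mean_2 = mean(y), sd_2 = stats::sd(y),
      pearson_r = pr$r,
      r_class = if (is.na(pr$r)) NA_character_ else classify_r(pr$r),
      t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  }
  for (mode in modes) {
    for (st in c("week", "weekend")) {
      add_row("gps_vs_self", mode, st, "trips_per_day",
              grab(outcomes, mode, st, "trips_per_day"),
              grab(diary_outcomes, mode, st, "trips_per_day"))
    }
    for (meas in c("trips_per_day", "minutes_per_day", "minutes_per_trip")) {
      add_row("gps_week_vs_weekend", mode, "week_vs_weekend", meas,
              grab(outcomes, mode, "week", meas),
              grab(outcomes, mode, "weekend", meas))
    }
  }
  tab <- do.call(rbind, rows)

  eng <- list()
  for (mode in modes) for (st in c("week", "weekend")) {
    g <- outcomes[outcomes$mode == mode & outcomes$stratum == st, "engaged"]
    s <- diary_outcomes[diary_outcomes$mode == mode &
                          diary_outcomes$stratum == st, "engaged"]
    eng[[length(eng) + 1]] <- data.frame(
      mode = mode, stratum = st,
      pct_not_engaging_gps = 100 * mean(!g, na.rm = TRUE),
      pct_not_engaging_self = 100 * mean(!s, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  list(comparisons = tab, not_engaging = do.call(rbind, eng))
}
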