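#' Weighted residential-density score
#'
#' The three dwelling-type frequency items (single-family homes, row houses,
#' apartments) are answered on a 5-point none-to-all scale coded 0-4. Denser
#' dwelling types are up-weighted relative to single-family homes:
#' `score = q1a + 12 * q1b + 25 * q1c`.
#'
#' @param q1a,q1b,q1c numeric responses coded 0-4 (vectors allowed).
#' @return numeric score vector.
#' @export
score_residential_density <- function(q1a, q1b, q1c) {
  for (q in list(q1a, q1b, q1c)) {
    if (any(!is.na(q) & (q < 0 | q > 4 | q != round(q))))
      stop("residential-density responses must be integers coded 0-4")
  }
  q1a + 12 * q1b + 25 * q1c
}

#' Mean-of-items subscale score
#'
#' Agreement subscales (1-4 scale) are the arithmetic mean of their items.
#' Missing items are tolerated as long as at least half the items are
#' answered; otherwise the score is missing.
#'
#' @param items numeric matrix or data frame, one row per respondent, one
#'   column per item (1-4 scale).
#' @return numeric vector of subscale means.
#' @export
score_mean_subscale <- function(items) {
  items <- as.matrix(items)
  if (any(!is.na(items) & (items < 1 | items > 4)))
    stop("subscale items must lie on the 1-4 agreement scale")
  n_ok <- rowSums(!is.na(items))
  m <- rowMeans(items, na.rm = TRUE)
  m[n_ok < ncol(items) / 2 | n_ok == 0] <- NA_real_
  m
}

#' Cronbach's alpha
#'
#' Internal consistency of a subscale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`.
#'
#' @param items numeric matrix, >= 2 columns (items), >= 2 rows (respondents);
#'   rows with missing values are dropped.
#' @return alpha, or `NA` when the total score has zero variance.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2 || nrow(items) < 2) stop("need >= 2 items and >= 2 respondents")
  tot_var <- stats::var(rowSums(items))
  if (tot_var == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / tot_var)
}

env_subscales <- function() {
  c("land_use_mix_access", "street_connectivity", "walk_cycle_facilities",
    "aesthetics", "traffic_safety", "crime_safety")
}

#' Score a parental neighbourhood-environment questionnaire table
#'
#' Expects one row per parent with the three density items
#' `res_density_a/b/c` (0-4), mean-subscale items named
#' `<subscale>_<index>` on the 1-4 scale (item counts are configurable --
#' any number of items per subscale is accepted), and the covariates
#' `participant_id, age, sex, ses, school_id, class_id`.
#'
#' @param q questionnaire data frame (see [read_questionnaire()]).
#' @return data frame with `participant_id`, the seven subscale scores, and
#'   the covariates.
#' @export
score_questionnaire <- function(q) {
  out <- data.frame(participant_id = q$participant_id, stringsAsFactors = FALSE)
  out$residential_density <- score_residential_density(
    q$res_density_a, q$res_density_b, q$res_density_c)
  for (s in env_subscales()) {
    cols <- grep(paste0("^", s, "_[0-9]+$"), names(q), value = TRUE)
    if (length(cols) == 0) stop("no items found for subscale ", s)
    out[[s]] <- score_mean_subscale(q[, cols, drop = FALSE])
  }
  for (cv in c("age", "sex", "ses", "school_id", "class_id"))
    if (cv %in% names(q)) out[[cv]] <- q[[cv]]
  out
}

#' Read a questionnaire CSV
#' @param path CSV path with the columns described in [score_questionnaire()].
#' @return data frame.
#' @export
read_questionnaire <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
}
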