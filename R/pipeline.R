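# End-to-end orchestration: inputs -> aligned epochs -> wear/valid days ->
# trips -> leisure outcomes -> validity table -> environment scores ->
# association models, with a run manifest recording attrition at each stage.

#' Run the full processing pipeline
#'
#' Reads the input files, applies every processing stage, and writes the
#' wear-day, trip, outcome, comparison and model tables plus a run manifest
#' to `out_dir`. Deterministic given the inputs and `seed`.
#'
#' Family choice per outcome follows the distributional situation: an
#' outcome with more than 5% zeros is fitted as a two-part hurdle model;
#' otherwise Gaussian-identity and Gamma-log candidates are both fitted and
#' the AIC decides.
#'
#' @param gps_path,accel_path,diary_path,questionnaire_path input files
#'   (CSV; GPX accepted for GPS).
#' @param study_config_path YAML study configuration
#'   ([write_study_config()]), or a `study_config` object.
#' @param out_dir output directory.
#' @param seed integer seed (model restarts draw jitter from it).
#' @param fit_models fit the association models (the slowest stage).
#' @param nAGQ quadrature points for the mixed models.
#' @return invisibly, a list with all intermediate tables and the run
#'   manifest.
#' @export
run_pipeline <- function(gps_path, accel_path, diary_path, questionnaire_path,
                         study_config_path, out_dir, seed = 1,
                         fit_models = TRUE, nAGQ = 25) {
  for (p in c(gps_path, accel_path, diary_path, questionnaire_path)) {
    if (!file.exists(p)) stop("missing input: ", p)
  }
  cfg <- if (inherits(study_config_path, "study_config")) study_config_path
         else read_study_config(study_config_path)
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  epochs <- read_epochs(gps_path, accel_path, cfg)
  diary <- read_diary(diary_path)
  quest <- read_questionnaire(questionnaire_path)

  weardays <- flag_valid_days(epochs, cfg)
  inclusion <- include_participants(weardays, cfg)
  trips <- detect_trips(epochs, cfg)
  leisure <- filter_leisure_trips(trips, weardays, cfg)
  outcomes <- compute_outcomes(leisure, weardays, inclusion)
  diary_out <- compute_diary_outcomes(diary, weardays, inclusion)
  comparison <- compare_table(outcomes, diary_out)
  scores <- score_questionnaire(quest)

  utils::write.csv(weardays, file.path(out_dir, "weardays.csv"), row.names = FALSE)
  utils::write.csv(inclusion, file.path(out_dir, "inclusion.csv"), row.names = FALSE)
  write_trip_table(trips, file.path(out_dir, "trips.csv"))
  write_trip_table(leisure, file.path(out_dir, "leisure_trips.csv"))
  utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"), row.names = FALSE)
  utils::write.csv(comparison$comparisons, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(comparison$not_engaging, file.path(out_dir, "not_engaging.csv"),
                   row.names = FALSE)
  utils::write.csv(scores, file.path(out_dir, "env_scores.csv"), row.names = FALSE)

  models <- NULL
  if (fit_models) {
    model_data <- build_model_data(outcomes, weardays, scores)
    models <- fit_all_models(model_data, nAGQ = nAGQ)
    utils::write.csv(models, file.path(out_dir, "model_results.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    software_version = as.character(utils::packageVersion("leisuretrips")),
    seed = seed,
    inputs = list(gps = gps_path, accel = accel_path, diary = diary_path,
                  questionnaire = questionnaire_path),
    stages = list(
      epochs_read = nrow(epochs),
      participants_in = length(unique(epochs$participant_id)),
      nonwear_minutes = nonwear_total_minutes(epochs, cfg),
      valid_days = sum(weardays$is_valid),
      participants_included = sum(inclusion$included),
      participants_excluded = sum(!inclusion$included),
      trips_detected = nrow(trips),
      leisure_trips = nrow(leisure)
    )
  )
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  invisible(list(epochs = epochs, weardays = weardays, inclusion = inclusion,
                 trips = trips, leisure = leisure, outcomes = outcomes,
                 diary_outcomes = diary_out, comparison = comparison,
                 env_scores = scores, models = models, manifest = manifest))
}

nonwear_total_minutes <- function(epochs, cfg) {
  sum(vapply(split(epochs, epochs$participant_id), function(ep) {
    ep <- ep[order(ep$timestamp), ]
    sum(detect_non_wear(ep$timestamp, ep$counts, cfg)$minutes)
  }, numeric(1)))
}

#' Assemble the modelling data set
#'
#' One row per included participant and stratum-mode-measure outcome column,
#' joined with the environment scores and the mean combined wear minutes per
#' valid day (the wear-time adjuster).
#'
#' @param outcomes from [compute_outcomes()].
#' @param weardays from [flag_valid_days()].
#' @param scores from [score_questionnaire()].
#' @return wide data frame, one row per participant, with columns
#'   `<mode>_<stratum>_trips` and `<mode>_<stratum>_min`.
#' @export
build_model_data <- function(outcomes, weardays, scores) {
  w <- outcomes
  w$key <- paste(w$mode, w$stratum, sep = "_")
  wide <- stats::reshape(
    w[, c("participant_id", "key", "trips_per_day", "minutes_per_day")],
    idvar = "participant_id", timevar = "key", direction = "wide")
  names(wide) <- sub("^trips_per_day\\.(.*)$", "\\1_trips", names(wide))
  names(wide) <- sub("^minutes_per_day\\.(.*)$", "\\1_min", names(wide))
  wv <- weardays[weardays$is_valid, ]
  wear <- stats::aggregate(list(wear_min = wv$combined_wear_minutes),
                           by = list(participant_id = wv$participant_id),
                           FUN = mean)
  d <- merge(wide, wear, by = "participant_id")
  merge(d, scores, by = "participant_id")
}

#' Fit the association models for every outcome
#'
#' @param model_data from [build_model_data()].
#' @param nAGQ quadrature points.
#' @param zero_frac_hurdle zero fraction above which the hurdle model is
#'   used instead of a single-family fit.
#' @return result table in the Tables-2/3 layout (see
#'   [model_result_table()]).
#' @export
fit_all_models <- function(model_data, nAGQ = 25, zero_frac_hurdle = 0.05) {
  out <- list()
  for (mode in c("walk", "cycle", "passive")) {
    for (st in c("week", "weekend")) {
      for (meas in c("trips", "min")) {
        oc <- paste0(mode, "_", st, "_", meas)
        if (!oc %in% names(model_data)) next
        d <- model_data[!is.na(model_data[[oc]]), , drop = FALSE]
        if (nrow(d) < 20) next
        f <- env_model_formula(oc)
        y <- d[[oc]]
        fit <- if (mean(y == 0) > zero_frac_hurdle) {
          fit_hurdle(f, d, nAGQ = nAGQ)
        } else {
          cands <- list(gaussian = fit_gaussian(f, d))
          if (all(y > 0)) cands$gamma <- fit_gamma_log(f, d, nAGQ = nAGQ)
          select_family_by_aic(cands)
        }
        out[[oc]] <- model_result_table(fit, outcome = oc)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
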