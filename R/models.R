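# Association models between neighbourhood-environment scores and
# leisure-transport outcomes, with a class-level random intercept:
#   * Gaussian identity (normally distributed outcomes, e.g. weekday walking),
#   * Gamma log (positive skewed outcomes),
#   * two-part hurdle (zero-heavy outcomes, e.g. weekend strata):
#     logit part for any-vs-no engagement over everyone, Gamma-log part for
#     the amount among engagers.
# Every model adjusts for age, sex, SES, school and wear time.

env_adjusters <- function() c("age", "sex", "ses", "school_id", "wear_min")

#' Standard model formula: seven environment scores plus adjusters
#'
#' @param outcome name of the outcome column.
#' @return a formula `outcome ~ 7 subscales + age + sex + ses + school_id +
#'   wear_min`.
#' @export
env_model_formula <- function(outcome) {
  stats::as.formula(paste(
    outcome, "~",
    paste(c("residential_density", env_subscales(), env_adjusters()),
          collapse = " + ")))
}

wald_table <- function(est, se, exponentiate, scale_label, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- est - z * se; hi <- est + z * se
  if (exponentiate) { est <- exp(est); lo <- exp(lo); hi <- exp(hi) }
  data.frame(predictor = names(est), estimate = unname(est),
             ci_low = unname(lo), ci_high = unname(hi),
             scale = scale_label, stringsAsFactors = FALSE)
}

#' Gaussian identity mixed model (class random intercept)
#'
#' Linear mixed model fitted by maximum likelihood through [lme4::lmer()];
#' reports beta with Wald 95% CIs. If the random-intercept variance is
#' estimated as singular (zero), the fit falls back to an ordinary linear
#' model with a warning.
#'
#' @param formula fixed-effects formula (see [env_model_formula()]).
#' @param data data frame.
#' @param cluster grouping column name (default `"class_id"`).
#' @return object of class `envassoc_fit`.
#' @export
fit_gaussian <- function(formula, data, cluster = "class_id") {
  ff <- stats::as.formula(paste(deparse1(formula), "+ (1 |", cluster, ")"))
  fit <- lme4::lmer(ff, data = data, REML = FALSE)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("singular random-intercept variance; falling back to a fixed-effects model")
    fit <- stats::lm(formula, data = data)
    est <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  } else {
    est <- lme4::fixef(fit); se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  }
  structure(list(
    family = "gaussian_identity", part = "single",
    estimates = wald_table(est, se, exponentiate = FALSE, scale_label = "beta"),
    logLik = as.numeric(stats::logLik(fit)), AIC = stats::AIC(fit),
    n = stats::nobs(fit), converged = TRUE, singular = singular, fit = fit
  ), class = "envassoc_fit")
}

#' Gamma log-link mixed model (class random intercept)
#'
#' Gamma GLMM with log link fitted by adaptive Gauss-Hermite quadrature
#' ([agq_glmm()]); reports exp(b) with 95% CIs, interpretable as the
#' proportional change in the outcome per one-unit increase of the
#' predictor. Requires a strictly positive outcome; outcomes with zeros
#' belong to [fit_hurdle()].
#'
#' @inheritParams fit_gaussian
#' @param nAGQ quadrature points.
#' @return object of class `envassoc_fit`.
#' @export
fit_gamma_log <- function(formula, data, cluster = "class_id", nAGQ = 25) {
  fit <- agq_glmm(formula, data, cluster, family = "gamma", nAGQ = nAGQ)
  structure(list(
    family = "gamma_log", part = "single",
    estimates = wald_table(stats::coef(fit), fit$se, TRUE, "exp_b"),
    logLik = fit$logLik, AIC = fit$AIC, n = fit$n,
    converged = fit$converged, singular = FALSE, fit = fit
  ), class = "envassoc_fit")
}

#' Two-part hurdle mixed model
#'
#' For non-negative outcomes with excess zeros. Part 1 is a mixed logistic
#' regression on the engagement indicator (>= 1 trip, i.e. outcome > 0) over
#' all participants, reported as odds ratios; part 2 is a mixed Gamma-log
#' model on the positive subset, reported as exp(b). Both parts carry the
#' class random intercept and are fitted by adaptive Gauss-Hermite
#' quadrature with `nAGQ` points. A degenerate part (all-zero or
#' all-positive outcome) is skipped and flagged.
#'
#' @inheritParams fit_gamma_log
#' @return object of class `hurdle_fit` with components `logit` and
#'   `positive` (each an `envassoc_fit` or `NULL` when skipped).
#' @export
fit_hurdle <- function(formula, data, cluster = "class_id", nAGQ = 25) {
  out_name <- all.vars(formula)[1]
  y <- data[[out_name]]
  if (any(y < 0, na.rm = TRUE)) stop("hurdle outcome must be non-negative")
  pos <- !is.na(y) & y > 0

  logit_part <- NULL
  if (any(pos) && any(!pos & !is.na(y))) {
    d1 <- data
    d1$.engaged <- as.integer(pos)
    f1 <- stats::as.formula(paste(".engaged ~",
                                  paste(attr(stats::terms(formula), "term.labels"),
                                        collapse = " + ")))
    bfit <- agq_glmm(f1, d1, cluster, family = "binomial", nAGQ = nAGQ)
    logit_part <- structure(list(
      family = "binomial_logit", part = "logit",
      estimates = wald_table(stats::coef(bfit), bfit$se, TRUE, "OR"),
      logLik = bfit$logLik, AIC = bfit$AIC, n = bfit$n,
      converged = bfit$converged, singular = FALSE, fit = bfit
    ), class = "envassoc_fit")
  }
  positive_part <- NULL
  if (sum(pos) > 0) {
    positive_part <- fit_gamma_log(formula, data[pos, , drop = FALSE],
                                   cluster, nAGQ)
    positive_part$part <- "positive"
  }
  structure(list(logit = logit_part, positive = positive_part,
                 skipped = c(logit = is.null(logit_part),
                             positive = is.null(positive_part)),
                 outcome = out_name),
            class = "hurdle_fit")
}

#' Choose among candidate fits by AIC
#'
#' Returns the converged fit with the smallest AIC (`AIC = 2k - 2 logLik`);
#' ties go to the earliest candidate. Non-converged candidates are excluded
#' with a message.
#'
#' @param fits named list of `envassoc_fit` objects on identical data.
#' @return the chosen fit, with attribute `aic_table`.
#' @export
select_family_by_aic <- function(fits) {
  stopifnot(length(fits) >= 1)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv)) message("excluding ", sum(!conv), " non-converged candidate(s)")
  cand <- fits[conv]
  if (length(cand) == 0) stop("no converged candidate fits")
  aic <- vapply(cand, function(f) f$AIC, numeric(1))
  best <- cand[[which.min(aic)]]
  attr(best, "aic_table") <- data.frame(
    family = vapply(cand, function(f) f$family, character(1)),
    AIC = aic, row.names = NULL)
  best
}

#' @export
print.envassoc_fit <- function(x, ...) {
  cat("Environment-association fit:", x$family, "(", x$part, ")",
      if (!x$converged) "[NOT CONVERGED]", "\n")
  cat("  n =", x$n, "| logLik =", format(x$logLik, digits = 6),
      "| AIC =", format(x$AIC, digits = 6), "\n")
  print(x$estimates, digits = 3)
  invisible(x)
}

#' @export
coef.envassoc_fit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$predictor)
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat("Two-part hurdle model for", x$outcome, "\n")
  if (!is.null(x$logit)) { cat("\n-- Logit part (odds of engaging) --\n"); print(x$logit) }
  else cat("\n-- Logit part skipped (degenerate outcome) --\n")
  if (!is.null(x$positive)) { cat("\n-- Positive part (amount among engagers) --\n"); print(x$positive) }
  else cat("\n-- Positive part skipped (no positive outcomes) --\n")
  invisible(x)
}

#' Tidy one or several fits into the result-table layout
#'
#' @param fit an `envassoc_fit` or `hurdle_fit`.
#' @param outcome label for the outcome column.
#' @return data frame `outcome, part, predictor, estimate, ci_low, ci_high,
#'   scale, n, converged`.
#' @export
model_result_table <- function(fit, outcome = "") {
  one <- function(f) {
    cbind(data.frame(outcome = outcome, part = f$part, stringsAsFactors = FALSE),
          f$estimates, n = f$n, converged = f$converged)
  }
  if (inherits(fit, "hurdle_fit")) {
    do.call(rbind, lapply(Filter(Negate(is.null),
                                 list(fit$logit, fit$positive)), one))
  } else one(fit)
}
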