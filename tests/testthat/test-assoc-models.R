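# The AGQ engine is the package's own implementation; lme4::glmer (nAGQ=25)
# and brute-force numerical integration serve as independent cross-checks.

sim_binom <- function(seed, n_classes = 25, n_per = 20, beta = c(-0.3, 0.6),
                      sigma = 0.7) {
  set.seed(seed)
  cl <- rep(seq_len(n_classes), each = n_per)
  x <- rnorm(n_classes * n_per)
  u <- rnorm(n_classes, 0, sigma)
  y <- rbinom(length(x), 1, plogis(beta[1] + beta[2] * x + u[cl]))
  data.frame(y = y, x = x, class_id = paste0("C", cl))
}

sim_gamma <- function(seed, n_classes = 25, n_per = 20, beta = c(0.5, 0.26),
                      sigma = 0.4, shape = 2) {
  set.seed(seed)
  cl <- rep(seq_len(n_classes), each = n_per)
  x <- rnorm(n_classes * n_per)
  u <- rnorm(n_classes, 0, sigma)
  mu <- exp(beta[1] + beta[2] * x + u[cl])
  data.frame(y = rgamma(length(x), shape, rate = shape / mu), x = x,
             class_id = paste0("C", cl))
}

test_that("the AGQ logistic fit matches glmer at 25 quadrature points", {
  d <- sim_binom(1)
  f <- agq_glmm(y ~ x, d, "class_id", "binomial", nAGQ = 25)
  g <- lme4::glmer(y ~ x + (1 | class_id), d, family = binomial, nAGQ = 25)
  expect_equal(unname(coef(f)), unname(lme4::fixef(g)), tolerance = 1e-4)
  expect_equal(f$sigma, sqrt(unlist(lme4::VarCorr(g))[[1]]), tolerance = 1e-3)
  expect_equal(f$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("the AGQ marginal likelihood matches brute-force integration", {
  d <- sim_gamma(2, n_classes = 4, n_per = 6)
  beta <- c(0.4, 0.2); sigma <- 0.5; shape <- 1.8
  ll_agq <- leisuretrips:::agq_loglik(
    beta, sigma, shape, X = cbind(1, d$x), y = d$y,
    cl = as.integer(factor(d$class_id)), nc = 4,
    rule = leisuretrips:::gh_rule(25), family = "gamma")
  ll_int <- sum(vapply(split(seq_len(nrow(d)), d$class_id), function(ix) {
    eta <- beta[1] + beta[2] * d$x[ix]
    f <- function(u) vapply(u, function(ui) {
      prod(dgamma(d$y[ix], shape, rate = shape / exp(eta + ui))) *
        dnorm(ui, 0, sigma)
    }, numeric(1))
    log(integrate(f, -10 * sigma, 10 * sigma, rel.tol = 1e-12)$value)
  }, numeric(1)))
  expect_equal(ll_agq, ll_int, tolerance = 1e-8)

  db <- sim_binom(3, n_classes = 4, n_per = 6)
  bb <- c(-0.2, 0.5); sb <- 0.8
  ll_agq_b <- leisuretrips:::agq_loglik(
    bb, sb, NA, X = cbind(1, db$x), y = db$y,
    cl = as.integer(factor(db$class_id)), nc = 4,
    rule = leisuretrips:::gh_rule(25), family = "binomial")
  ll_int_b <- sum(vapply(split(seq_len(nrow(db)), db$class_id), function(ix) {
    eta <- bb[1] + bb[2] * db$x[ix]
    f <- function(u) vapply(u, function(ui) {
      p <- plogis(eta + ui)
      prod(ifelse(db$y[ix] == 1, p, 1 - p)) * dnorm(ui, 0, sb)
    }, numeric(1))
    log(integrate(f, -10 * sb, 10 * sb, rel.tol = 1e-12)$value)
  }, numeric(1)))
  expect_equal(ll_agq_b, ll_int_b, tolerance = 1e-8)
})

test_that("fixing the random-effect variance at zero reproduces the GLM", {
  d <- sim_binom(4, sigma = 0)
  f <- agq_glmm(y ~ x, d, "class_id", "binomial", fix_sigma = 0)
  g <- glm(y ~ x, data = d, family = binomial)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)

  dg <- sim_gamma(5, sigma = 0)
  fg <- agq_glmm(y ~ x, dg, "class_id", "gamma", fix_sigma = 0)
  gg <- glm(y ~ x, data = dg, family = Gamma(link = "log"))
  expect_equal(unname(coef(fg)), unname(coef(gg)), tolerance = 1e-5)
})

test_that("likelihood at the optimum is stable under quadrature refinement", {
  d <- sim_gamma(6)
  f <- agq_glmm(y ~ x, d, "class_id", "gamma", nAGQ = 25)
  cl <- as.integer(factor(d$class_id))
  ll <- vapply(c(5, 15, 25, 51, 101), function(k) {
    leisuretrips:::agq_loglik(coef(f), f$sigma, f$shape, cbind(1, d$x), d$y,
                              cl, 25, leisuretrips:::gh_rule(k), "gamma")
  }, numeric(1))
  expect_true(all(diff(ll) >= -1e-8))       # refinement never loses likelihood
  expect_lt(abs(ll[5] - ll[3]), 1e-6)
  # refitting with 101 points moves the estimates by a negligible amount
  f101 <- agq_glmm(y ~ x, d, "class_id", "gamma", nAGQ = 101)
  expect_lt(max(abs(coef(f) - coef(f101))), 1e-4)
  expect_lt(abs(f$sigma - f101$sigma), 1e-4)
})

test_that("Gaussian mixed fit recovers a simulated effect and handles degeneracy", {
  set.seed(7)
  n <- 500
  cl <- rep(1:25, each = 20)
  d <- data.frame(aesthetics = rnorm(n), other = rnorm(n),
                  class_id = paste0("C", cl))
  d$y <- 2 + 4 * d$aesthetics + rnorm(25, 0, 1)[cl] + rnorm(n, 0, 2)
  f <- fit_gaussian(y ~ aesthetics + other, d)
  est <- f$estimates[f$estimates$predictor == "aesthetics", ]
  expect_gt(4, est$ci_low); expect_lt(4, est$ci_high)
  expect_equal(est$estimate, 4, tolerance = 0.1)

  # all-zero predictor must not crash; its row is dropped or unbounded
  d$null_x <- 0
  expect_no_error(suppressWarnings(f0 <- fit_gaussian(y ~ aesthetics + null_x, d)))

  # no between-class variance in truth: estimates collapse onto OLS
  d$y2 <- 1 + 0.5 * d$aesthetics + rnorm(n)
  f2 <- suppressWarnings(fit_gaussian(y2 ~ aesthetics, d))
  ols <- lm(y2 ~ aesthetics, d)
  expect_equal(coef(f2)[["aesthetics"]], unname(coef(ols)[2]), tolerance = 1e-4)
})

test_that("Gamma fits report exp(b), refuse zeros, and cover null effects", {
  d <- sim_gamma(8, beta = c(0.5, log(1.5)))
  f <- fit_gamma_log(y ~ x, d)
  est <- f$estimates[f$estimates$predictor == "x", ]
  expect_gt(1.5, est$ci_low); expect_lt(1.5, est$ci_high)

  d$null_x <- rnorm(nrow(d))
  fn <- fit_gamma_log(y ~ x + null_x, d)
  en <- fn$estimates[fn$estimates$predictor == "null_x", ]
  expect_true(en$ci_low <= 1 && en$ci_high >= 1)

  d0 <- d; d0$y[1] <- 0
  expect_error(fit_gamma_log(y ~ x, d0), "hurdle")

  # intercept-only fit on a constant outcome returns that constant
  dc <- data.frame(y = rep(2.5, 60), class_id = rep(paste0("C", 1:6), 10))
  fc <- suppressWarnings(agq_glmm(y ~ 1, dc, "class_id", "gamma", fix_sigma = 0))
  expect_equal(exp(unname(coef(fc))), 2.5, tolerance = 1e-4)
})

test_that("hurdle fits split into logit and positive parts consistently", {
  set.seed(9)
  d <- simulate_hurdle_data()
  f <- fit_hurdle(y ~ x, d)
  expect_s3_class(f, "hurdle_fit")
  expect_equal(f$logit$estimates$scale[1], "OR")
  expect_equal(f$positive$estimates$scale[1], "exp_b")
  expect_equal(f$positive$n, sum(d$y > 0))
  # CIs bracket their point estimates, all positive after exponentiation
  for (part in list(f$logit, f$positive)) {
    expect_true(all(part$estimates$ci_low <= part$estimates$estimate))
    expect_true(all(part$estimates$ci_high >= part$estimates$estimate))
    expect_true(all(part$estimates$estimate > 0))
  }

  # without zeros the logit part is skipped and the Gamma part is identical
  dp <- d[d$y > 0, ]
  fp <- fit_hurdle(y ~ x, dp)
  expect_true(fp$skipped["logit"])
  fg <- fit_gamma_log(y ~ x, dp)
  expect_equal(fp$positive$estimates$estimate, fg$estimates$estimate,
               tolerance = 1e-8)
  expect_error(fit_hurdle(y ~ x, transform(d, y = -y)), "non-negative")
})

test_that("AIC selection prefers the generating family and breaks ties stably", {
  set.seed(10)
  n <- 400
  d <- data.frame(x = rnorm(n), class_id = paste0("C", rep(1:20, each = 20)))
  d$y <- 10 + 0.5 * d$x + rnorm(20, 0, 0.5)[rep(1:20, each = 20)] + rnorm(n)
  fits <- list(gaussian = fit_gaussian(y ~ x, d),
               gamma = fit_gamma_log(y ~ x, d))
  best <- select_family_by_aic(fits)
  expect_equal(best$family, "gaussian_identity")
  expect_equal(nrow(attr(best, "aic_table")), 2)

  tie <- select_family_by_aic(list(a = fits$gaussian, b = fits$gaussian))
  expect_identical(tie$family, "gaussian_identity")
  single <- select_family_by_aic(list(only = fits$gamma))
  expect_equal(single$family, "gamma_log")
  bad <- fits$gamma; bad$converged <- FALSE
  expect_message(sel <- select_family_by_aic(list(g = fits$gaussian, b = bad)),
                 "non-converged")
  expect_equal(sel$family, "gaussian_identity")
})
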