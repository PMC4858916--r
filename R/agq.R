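# Random-intercept GLMMs fitted by adaptive Gauss-Hermite quadrature.
#
# Model: y_ij ~ family(mean = g^{-1}(x_ij' beta + u_i)), u_i ~ N(0, sigma^2),
# with logit link for binomial outcomes and log link for Gamma outcomes.
# The marginal likelihood integrates each cluster's random intercept out
# numerically: quadrature nodes are re-centered at the cluster's posterior
# mode and re-scaled by the curvature there (the "adaptive" part), so a
# modest number of points (25 by default) is accurate even for small
# clusters.

# Gauss-Hermite rule for weight exp(-z^2) via the Golub-Welsch eigenvalue
# construction; exact for polynomials of degree 2n-1.
gh_rule <- function(n) {
  if (n == 1) return(list(z = 0, logw = 0.5 * log(pi)))
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- J[cbind(k + 1, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(z = e$values[ord],
       logw = 0.5 * log(pi) + 2 * log(abs(e$vectors[1, ord])))
}

# pointwise log-likelihood and its first two derivatives in eta
fam_loglik <- function(eta, y, family, shape) {
  if (family == "binomial") {
    l <- y * eta - ifelse(eta > 30, eta, log1p(exp(eta)))
    p <- stats::plogis(eta)
    list(l = l, dl = y - p, d2l = -p * (1 - p))
  } else {                                 # gamma, log link
    a <- shape
    ye <- y * exp(-eta)
    list(l = a * (log(a) - eta) + (a - 1) * log(y) - a * ye - lgamma(a),
         dl = a * (ye - 1), d2l = -a * ye)
  }
}

# posterior mode of each cluster's random intercept (concave => plain Newton)
find_modes <- function(eta, y, cl, nc, s2, family, shape, u0) {
  u <- u0
  for (it in 1:100) {
    eta_u <- eta + u[cl]
    fl <- fam_loglik(eta_u, y, family, shape)
    g <- rowsum(fl$dl, cl, reorder = TRUE)[, 1] - u / s2
    H <- rowsum(fl$d2l, cl, reorder = TRUE)[, 1] - 1 / s2
    step <- g / H
    step <- pmin(pmax(step, -5), 5)
    u <- u - step
    if (max(abs(step)) < 1e-10) break
  }
  list(u = u, tau = 1 / sqrt(-(rowsum(fam_loglik(eta + u[cl], y, family, shape)$d2l,
                                      cl, reorder = TRUE)[, 1] - 1 / s2)))
}

# marginal log-likelihood by adaptive GH quadrature
agq_loglik <- function(beta, sigma, shape, X, y, cl, nc, rule, family,
                       mode_env = NULL) {
  eta <- drop(X %*% beta)
  if (sigma == 0) {
    return(sum(fam_loglik(eta, y, family, shape)$l))
  }
  s2 <- sigma^2
  u0 <- if (!is.null(mode_env) && !is.null(mode_env$u)) mode_env$u else rep(0, nc)
  md <- find_modes(eta, y, cl, nc, s2, family, shape, u0)
  if (!is.null(mode_env)) mode_env$u <- md$u
  K <- length(rule$z)
  # u_{ik} = uhat_i + sqrt(2) tau_i z_k
  uk <- outer(md$tau * sqrt(2), rule$z) + md$u          # nc x K
  etam <- matrix(eta, length(eta), K) + uk[cl, , drop = FALSE]
  lm_ <- fam_loglik(etam, rep(y, K), family, shape)$l
  dim(lm_) <- dim(etam)
  hik <- rowsum(lm_, cl, reorder = TRUE) +
    stats::dnorm(uk, 0, sigma, log = TRUE)              # nc x K
  lsum <- hik + matrix(rule$logw + rule$z^2, nc, K, byrow = TRUE)
  m <- apply(lsum, 1, max)
  sum(m + log(rowSums(exp(lsum - m))) + log(sqrt(2) * md$tau))
}

#' Fit a random-intercept GLMM by adaptive Gauss-Hermite quadrature
#'
#' Maximum-likelihood fit of a generalized linear mixed model with one
#' scalar (cluster-level) random intercept, for binomial (logit link) or
#' Gamma (log link) responses. The marginal likelihood is evaluated by
#' adaptive Gauss-Hermite quadrature with `nAGQ` points (1 = Laplace
#' approximation) and maximised over the fixed effects, the random-intercept
#' SD, and (for Gamma) the shape parameter jointly. On non-convergence the
#' optimiser restarts from jittered initial values.
#'
#' @param formula fixed-effects formula, e.g. `y ~ x1 + x2`.
#' @param data data frame.
#' @param cluster name of the grouping column (the random-intercept factor).
#' @param family `"binomial"` (0/1 outcome, logit link) or `"gamma"`
#'   (strictly positive outcome, log link).
#' @param nAGQ number of quadrature points (>= 1).
#' @param fix_sigma optionally fix the random-intercept SD (0 reduces the
#'   fit to an ordinary GLM).
#' @param n_restarts jittered restarts on non-convergence.
#' @return object of class `agq_glmm` with coefficients, Wald
#'   variance-covariance, `sigma`, `shape`, `logLik`, `AIC` and convergence
#'   information.
#' @export
agq_glmm <- function(formula, data, cluster, family = c("binomial", "gamma"),
                     nAGQ = 25, fix_sigma = NULL, n_restarts = 5) {
  family <- match.arg(family)
  ff <- stats::update(formula, paste0("~ . + ", cluster))
  mf <- stats::model.frame(ff, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  clf <- factor(mf[[cluster]])
  cl <- as.integer(clf)
  nc <- nlevels(clf)
  if (family == "binomial") stopifnot(all(y %in% 0:1))
  if (family == "gamma") {
    if (any(y <= 0)) stop("Gamma-log outcome must be strictly positive; ",
                          "use fit_hurdle() for outcomes with zeros")
  }
  rule <- gh_rule(nAGQ)
  p <- ncol(X)
  est_sigma <- is.null(fix_sigma)

  # standardize predictor columns internally so the optimiser and the
  # numeric Hessian work on O(1) parameters; estimates are mapped back below
  Xraw <- X
  j_int <- which(colnames(X) == "(Intercept)")
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  if (length(j_int)) { ctr[j_int] <- 0; scl[j_int] <- 1 } else ctr[] <- 0
  X <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")

  # starting values from the fixed-effects GLM
  g0 <- if (family == "binomial") {
    stats::glm.fit(X, y, family = stats::binomial())
  } else {
    stats::glm.fit(X, y, family = stats::Gamma(link = "log"))
  }
  beta0 <- g0$coefficients
  beta0[is.na(beta0)] <- 0
  shape0 <- if (family == "gamma") {
    disp <- sum(g0$weights * g0$residuals^2) / g0$df.residual
    max(1 / disp, 0.1)
  } else NA
  start <- c(beta0,
             if (est_sigma) log(0.5),
             if (family == "gamma") log(shape0))

  mode_env <- new.env()
  unpack <- function(par) {
    beta <- par[1:p]
    i <- p
    sigma <- if (est_sigma) exp(par[(i <- i + 1)]) else fix_sigma
    shape <- if (family == "gamma") exp(par[i + 1]) else NA
    list(beta = beta, sigma = unname(sigma), shape = unname(shape))
  }
  nll <- function(par) {
    q <- unpack(par)
    if (!all(is.finite(par)) || q$sigma > 50) return(1e10)
    ll <- tryCatch(agq_loglik(q$beta, q$sigma, q$shape, X, y, cl, nc, rule,
                              family, mode_env),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }

  best <- NULL
  par_try <- start
  for (r in 0:n_restarts) {
    opt <- stats::optim(par_try, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0 && opt$value < 1e9) break
    par_try <- if (opt$convergence == 1 && opt$value < 1e9) {
      opt$par                                  # ran out of iterations: continue
    } else {
      start + stats::rnorm(length(start), 0, 0.3)
    }
  }
  opt <- best
  conv <- opt$convergence == 0 && opt$value < 1e9

  # boundary fit: random-intercept SD estimated at (numerically) zero makes
  # log(sigma) unidentified; refit as the fixed-effects model, like the
  # singular-fit fallback of mixed-model practice
  if (est_sigma && exp(opt$par[p + 1]) < 1e-3) {
    out <- agq_glmm(formula, data, cluster, family = family, nAGQ = nAGQ,
                    fix_sigma = 0, n_restarts = n_restarts)
    out$singular <- TRUE
    return(out)
  }

  hess <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
  vc <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL) else NULL
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) < 0)) {
    vc <- matrix(NA_real_, length(opt$par), length(opt$par))
    conv <- FALSE
  }
  q <- unpack(opt$par)
  # map the standardized-scale estimates back to the raw predictor scale
  A <- diag(1 / scl, p, p)
  if (length(j_int)) A[j_int, -j_int] <- -ctr[-j_int] / scl[-j_int]
  q$beta <- drop(A %*% q$beta)
  vc[1:p, 1:p] <- A %*% vc[1:p, 1:p, drop = FALSE] %*% t(A)
  X <- Xraw
  names(q$beta) <- colnames(X)
  npar <- length(opt$par)
  out <- list(
    coefficients = q$beta,
    vcov = vc[1:p, 1:p, drop = FALSE],
    se = sqrt(diag(vc)[1:p]),
    sigma = q$sigma, shape = q$shape,
    logLik = -opt$value, AIC = 2 * npar + 2 * opt$value,
    npar = npar, nAGQ = nAGQ, family = family, formula = formula,
    cluster = cluster, n = nrow(X), n_clusters = nc,
    converged = conv, singular = FALSE, X = X
  )
  dimnames(out$vcov) <- list(names(q$beta), names(q$beta))
  names(out$se) <- names(q$beta)
  class(out) <- "agq_glmm"
  out
}

#' @export
coef.agq_glmm <- function(object, ...) object$coefficients

#' @export
vcov.agq_glmm <- function(object, ...) object$vcov

#' @export
logLik.agq_glmm <- function(object, ...) {
  structure(object$logLik, df = object$npar, class = "logLik")
}

#' @export
confint.agq_glmm <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.agq_glmm <- function(object, newdata = NULL,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else
    stats::model.matrix(stats::delete.response(stats::terms(object$formula)), newdata)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") return(eta)
  if (object$family == "binomial") stats::plogis(eta) else exp(eta)
}

#' @export
print.agq_glmm <- function(x, ...) {
  cat("Random-intercept GLMM (", x$family,
      if (x$family == "binomial") ", logit link" else ", log link",
      "), adaptive Gauss-Hermite quadrature with ", x$nAGQ, " points\n", sep = "")
  cat("  n =", x$n, "in", x$n_clusters, "clusters of", x$cluster,
      "| logLik =", format(x$logLik, digits = 6), "| AIC =",
      format(x$AIC, digits = 6), "\n")
  cat("  random-intercept SD =", format(x$sigma, digits = 4))
  if (x$family == "gamma") cat(" | shape =", format(x$shape, digits = 4))
  cat(if (x$converged) "" else "  [NOT CONVERGED]", "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.agq_glmm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab), class = "summary.agq_glmm")
}

#' @export
print.summary.agq_glmm <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}
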