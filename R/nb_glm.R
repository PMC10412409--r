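# Weighted negative binomial regression with log link: Fisher scoring for
# the coefficients alternating with maximum-likelihood estimation of the
# dispersion. This is the M-step workhorse of the mixture EM, where the
# weights are fractional responsibilities.

#' Negative binomial probability mass function
#'
#' Mean/size parameterization: variance = mu + mu^2 / nu, so nu -> Inf
#' recovers the Poisson distribution. Evaluated in log space internally.
#'
#' @param y Non-negative integer count(s).
#' @param mu Positive mean.
#' @param nu Positive dispersion (size).
#' @param log Return the log pmf?
#' @return Probability (or log probability) of each `y`.
#' @examples
#' nb_pmf(0, 5, 2)  # (2/7)^2
#' @export
nb_pmf <- function(y, mu, nu, log = FALSE) {
  if (anyNA(y) || any(y < 0) || any(y != floor(y)))
    stop("y must be non-negative integers")
  if (any(mu <= 0) || any(nu <= 0)) stop("mu and nu must be positive")
  stats::dnbinom(y, size = nu, mu = mu, log = log)
}

# Weighted NB log-likelihood for linear predictor eta = alpha + beta*log(x).
nb_wll <- function(y, lx, w, alpha, beta, nu) {
  mu <- exp(pmin(pmax(alpha + beta * lx, -30), 30))
  sum(w * stats::dnbinom(y, size = nu, mu = mu, log = TRUE))
}

# One IRLS (Fisher scoring) pass for (alpha, beta) at fixed nu.
# Working weights for the log link: w * mu * nu / (mu + nu).
nb_irls <- function(y, lx, w, alpha, beta, nu, fix_beta_zero,
                    tol = 1e-10, max_iter = 25L) {
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(alpha + beta * lx, -30), 30)
    mu <- exp(eta)
    W <- w * mu * nu / (mu + nu)
    z <- eta + (y - mu) / mu
    if (fix_beta_zero) {
      alpha_new <- sum(W * z) / sum(W)
      beta_new <- 0
    } else {
      sw <- sum(W); swx <- sum(W * lx); swxx <- sum(W * lx * lx)
      swz <- sum(W * z); swxz <- sum(W * lx * z)
      det <- sw * swxx - swx * swx
      if (!is.finite(det) || abs(det) < 1e-12 * max(sw * swxx, 1))
        stop("singular design: detected-gene covariate has no usable variation")
      beta_new <- (sw * swxz - swx * swz) / det
      alpha_new <- (swz - beta_new * swx) / sw
    }
    delta <- max(abs(alpha_new - alpha), abs(beta_new - beta))
    alpha <- alpha_new; beta <- beta_new
    if (delta < tol) break
  }
  list(alpha = alpha, beta = beta)
}

#' Fit a weighted negative binomial regression (or intercept-only) model
#'
#' Maximizes the weighted NB log-likelihood with mean
#' `mu_i = exp(alpha + beta * log(x_i))` by alternating (a) Fisher-scoring
#' IRLS for the coefficients at fixed dispersion with (b) a univariate
#' maximum-likelihood update of the dispersion `nu` on the log scale, until
#' the weighted log-likelihood stabilizes.
#'
#' @param y Count vector.
#' @param x Positive covariate vector (detected genes per droplet).
#' @param weights Weights in `[0, 1]` (EM responsibilities); unit weights
#'   give the ordinary ML fit. Rescaling all weights by a constant does not
#'   change the estimates.
#' @param fix_beta_zero If `TRUE`, fit the intercept-only model (`beta = 0`),
#'   i.e. the component mean does not depend on the detected genes.
#' @param tol Convergence tolerance on the weighted log-likelihood.
#' @param max_outer Maximum number of coefficient/dispersion alternations.
#' @param nu_cap Upper bound for the dispersion; data that are effectively
#'   Poisson drive `nu` to the cap, which is flagged, not an error.
#' @param min_ess Minimum effective sample size `sum(weights)`.
#' @param init Optional warm start: list with `alpha`, `beta`, `nu`.
#' @return List of class `nb_component`: `alpha`, `beta`, `nu`, `loglik`
#'   (weighted), `converged`, `nu_capped`, `n_iter`.
#' @export
fit_weighted_nb <- function(y, x, weights = rep(1, length(y)),
                            fix_beta_zero = FALSE, tol = 1e-8,
                            max_outer = 50L, nu_cap = 1e6,
                            min_ess = 10, init = NULL) {
  stopifnot(length(y) == length(x), length(weights) == length(y))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(x <= 0)) stop("covariate x must be positive")
  ess <- sum(weights)
  if (ess < min_ess)
    stop("effective sample size ", signif(ess, 3), " below floor ", min_ess)
  lx <- log(x)
  w <- weights

  if (!is.null(init)) {
    alpha <- init$alpha; beta <- if (fix_beta_zero) 0 else init$beta
    nu <- min(max(init$nu, 1e-4), nu_cap)
  } else {
    mu0 <- max(sum(w * y) / ess, 1e-3)
    alpha <- log(mu0)
    beta <- 0
    v0 <- sum(w * (y - mu0)^2) / ess
    nu <- if (v0 > mu0) mu0^2 / (v0 - mu0) else nu_cap
    nu <- min(max(nu, 1e-4), nu_cap)
  }

  ll_old <- -Inf
  converged <- FALSE
  nu_capped <- FALSE
  it <- 0L
  for (it in seq_len(max_outer)) {
    co <- nb_irls(y, lx, w, alpha, beta, nu, fix_beta_zero)
    alpha <- co$alpha; beta <- co$beta
    opt <- stats::optimize(function(lnu) nb_wll(y, lx, w, alpha, beta, exp(lnu)),
                           interval = c(log(1e-4), log(nu_cap)),
                           maximum = TRUE, tol = 1e-10)
    nu <- exp(opt$maximum)
    ll <- opt$objective
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (nu > 0.99 * nu_cap) {
    nu <- nu_cap
    nu_capped <- TRUE
    warning("dispersion at cap (data near-Poisson); nu clamped at ", nu_cap)
  }
  structure(list(alpha = alpha, beta = beta, nu = nu,
                 loglik = nb_wll(y, lx, w, alpha, beta, nu),
                 converged = converged, nu_capped = nu_capped, n_iter = it),
            class = "nb_component")
}

#' Component mean at given detected-gene counts
#'
#' @param comp An `nb_component`.
#' @param x Detected-gene count(s).
#' @return `exp(alpha + beta * log(x))`.
#' @export
component_mean <- function(comp, x) {
  exp(pmin(pmax(comp$alpha + comp$beta * log(x), -30), 30))
}

#' @export
print.nb_component <- function(x, ...) {
  cat(sprintf("NB component: alpha=%.4f beta=%.4f nu=%.3f (loglik %.3f%s)\n",
              x$alpha, x$beta, x$nu, x$loglik,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
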