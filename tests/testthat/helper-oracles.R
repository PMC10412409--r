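# Independent oracles used by the suite. These deliberately avoid the
# package's own code paths: the NB pmf is written out via lgamma, and the
# reference fits use a generic numerical optimizer on the explicit
# weighted log-likelihood.

oracle_nb_logpmf <- function(y, mu, nu) {
  lgamma(y + nu) - lgamma(nu) - lfactorial(y) +
    nu * (log(nu) - log(nu + mu)) + y * (log(mu) - log(nu + mu))
}

oracle_nb_pmf <- function(y, mu, nu) exp(oracle_nb_logpmf(y, mu, nu))

# Posterior of the positive component by direct arithmetic on the pmf.
oracle_posterior <- function(pi2, mu1, nu1, mu2, nu2, y) {
  h1 <- oracle_nb_pmf(y, mu1, nu1)
  h2 <- oracle_nb_pmf(y, mu2, nu2)
  pi2 * h2 / ((1 - pi2) * h1 + pi2 * h2)
}

oracle_wll <- function(y, x, w, alpha, beta, nu) {
  sum(w * oracle_nb_logpmf(y, exp(alpha + beta * log(x)), nu))
}

# Generic numerical maximizer of the weighted NB regression likelihood.
oracle_fit_nb <- function(y, x, w, fix_beta_zero = FALSE, start = NULL) {
  if (is.null(start)) {
    mu0 <- max(weighted.mean(y, w), 0.1)
    start <- if (fix_beta_zero) c(log(mu0), log(1)) else c(log(mu0), 0, log(1))
  }
  neg <- function(par) {
    if (fix_beta_zero) {
      -oracle_wll(y, x, w, par[1], 0, exp(par[2]))
    } else {
      -oracle_wll(y, x, w, par[1], par[2], exp(par[3]))
    }
  }
  o <- stats::optim(start, neg, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-12))
  o <- stats::optim(o$par, neg, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-12))
  list(par = o$par, loglik = -o$value)
}

# Minimal hand-built naive mixture model object.
make_naive_model <- function(mu1, nu1, mu2, nu2, pi2) {
  comp <- function(mu, nu)
    structure(list(alpha = log(mu), beta = 0, nu = nu,
                   converged = TRUE, nu_capped = FALSE),
              class = "nb_component")
  structure(list(pi = c(1 - pi2, pi2), comp_neg = comp(mu1, nu1),
                 comp_pos = comp(mu2, nu2), variant = "naive"),
            class = "hto_mixture")
}

# Two-component naive NB sample with the generating component recorded.
sample_naive_mixture <- function(m, mu1, nu1, mu2, nu2, pi2, seed) {
  set.seed(seed)
  z <- stats::rbinom(m, 1, pi2)
  y <- ifelse(z == 1, stats::rnbinom(m, size = nu2, mu = mu2),
              stats::rnbinom(m, size = nu1, mu = mu1))
  list(y = y, z = z)
}

expect_nondecreasing <- function(trace, slack = 1e-8) {
  expect_true(all(diff(trace) >= -slack * (abs(trace[-length(trace)]) + 1)))
}
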