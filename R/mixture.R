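# Two-component NB (regression) mixture per HTO, fitted by EM.
#
# Component k = 1 models negative droplets (background HTO reads only),
# component k = 2 positive droplets (cell tagged with this HTO). Variants:
#   full     - regression on log(detected genes) in both components
#   pos_only - regression in the positive component only (beta_neg = 0)
#   naive    - no regression in either component (both beta = 0)

MODEL_VARIANTS <- c("full", "pos_only", "naive")

variant_fix <- function(variant) {
  switch(variant,
         full = c(neg = FALSE, pos = FALSE),
         pos_only = c(neg = TRUE, pos = FALSE),
         naive = c(neg = TRUE, pos = TRUE),
         stop("unknown model variant: ", variant))
}

# log component densities for all droplets: m x 2 matrix.
mix_logdens <- function(model, y, x) {
  cbind(log(model$pi[1]) +
          stats::dnbinom(y, size = model$comp_neg$nu,
                         mu = component_mean(model$comp_neg, x), log = TRUE),
        log(model$pi[2]) +
          stats::dnbinom(y, size = model$comp_pos$nu,
                         mu = component_mean(model$comp_pos, x), log = TRUE))
}

#' Posterior probability that a droplet is positive for an HTO
#'
#' Bayes' rule over the two fitted components, evaluated with log-sum-exp
#' stabilization: `pi_2 h(y | theta_2, x) / sum_k pi_k h(y | theta_k, x)`.
#'
#' @param model A fitted `hto_mixture` model.
#' @param y HTO count(s).
#' @param x Detected-gene count(s), recycled against `y`.
#' @return Posterior probability vector in `[0, 1]`.
#' @export
posterior_positive <- function(model, y, x) {
  ld <- mix_logdens(model, y, x)
  if (any(!is.finite(ld[, 1]) & !is.finite(ld[, 2])))
    stop("both component densities underflowed in log space")
  # 1 / (1 + exp(l1 - l2)), with the degenerate-prior limits handled exactly
  d <- ld[, 1] - ld[, 2]
  p <- ifelse(is.infinite(d) & d > 0, 0,
              ifelse(is.infinite(d) & d < 0, 1, 1 / (1 + exp(d))))
  as.numeric(p)
}

#' Maximum a posteriori class for one posterior probability
#'
#' Positive iff the posterior exceeds 0.5; a tie at exactly 0.5 is called
#' negative (conservative: keeps ambiguous droplets out of singlet calls).
#'
#' @param posterior Posterior probability vector.
#' @return Integer vector of 0 (negative) / 1 (positive).
#' @export
hard_class <- function(posterior) as.integer(posterior > 0.5)

#' Expected number of classification errors of a fitted mixture
#'
#' Under the MAP rule the per-droplet error probability is
#' `min(p, 1 - p)`; the criterion is its sum, used to select among the
#' model variants.
#'
#' @param posterior Posterior probability vector (typically over the
#'   non-outlier droplets).
#' @return Non-negative real.
#' @export
expected_errors <- function(posterior) sum(pmin(posterior, 1 - posterior))

#' Fit one two-component NB mixture by EM
#'
#' E-step: responsibilities from the current components; M-step: mixing
#' proportions as mean responsibilities and weighted NB (regression) fits
#' per component via [fit_weighted_nb()]. Initialized from the k-means
#' clustering (`init_positive`), so component 2 starts as, and represents,
#' the positive droplets; if label switching occurs the components are
#' re-ordered at the end by their fitted mean at the average detected-gene
#' count. The model is fitted on `fit_mask` droplets only (outliers
#' excluded) but posteriors are returned for all droplets.
#'
#' @param y_j Count vector for one HTO.
#' @param x Detected-gene vector.
#' @param init_positive Logical initialization mask from [initial_clusters()].
#' @param fit_mask Logical mask of droplets used for fitting (default: all).
#' @param variant `"full"`, `"pos_only"` or `"naive"`.
#' @param tol Relative EM convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param hto HTO name used in error messages.
#' @param pi_floor Mixing-proportion floor below which the fit is declared
#'   collapsed.
#' @return An `hto_mixture`: `pi`, `comp_neg`, `comp_pos`, `variant`,
#'   `converged`, `loglik`, `loglik_trace`, `n_iter`, `posterior` (all
#'   droplets), `fit_mask`.
#' @export
fit_em <- function(y_j, x, init_positive, fit_mask = NULL,
                   variant = "full", tol = 1e-6, max_iter = 100L,
                   hto = "HTO", pi_floor = 1e-4) {
  m <- length(y_j)
  stopifnot(length(x) == m, length(init_positive) == m)
  if (is.null(fit_mask)) fit_mask <- rep(TRUE, m)
  fix <- variant_fix(variant)
  yf <- y_j[fit_mask]
  xf <- x[fit_mask]
  pos0 <- init_positive[fit_mask]
  if (!any(pos0) || all(pos0))
    stop("initialization for ", hto, " leaves a class empty")

  resp <- as.numeric(pos0)  # responsibility of the positive component
  model <- NULL
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  comp_neg <- comp_pos <- NULL
  for (iter in seq_len(max_iter)) {
    pi2 <- mean(resp)
    if (min(pi2, 1 - pi2) < pi_floor)
      stop("component collapse for ", hto, ": mixing proportion below ",
           pi_floor)
    fit_comp <- function(w, fixb, init) {
      tryCatch(fit_weighted_nb(yf, xf, weights = w, fix_beta_zero = fixb,
                               init = init),
               error = function(e)
                 stop("component collapse for ", hto, ": ",
                      conditionMessage(e), call. = FALSE))
    }
    comp_neg <- fit_comp(1 - resp, fix[["neg"]], comp_neg)
    comp_pos <- fit_comp(resp, fix[["pos"]], comp_pos)
    model <- structure(list(pi = c(1 - pi2, pi2), comp_neg = comp_neg,
                            comp_pos = comp_pos, variant = variant),
                       class = "hto_mixture")
    ld <- mix_logdens(model, yf, xf)
    mx <- pmax(ld[, 1], ld[, 2])
    ll <- sum(mx + log(exp(ld[, 1] - mx) + exp(ld[, 2] - mx)))
    ll_trace <- c(ll_trace, ll)
    resp <- posterior_positive(model, yf, xf)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  # re-order on label switch: component 2 must be the high-count component
  xbar <- mean(xf)
  if (component_mean(model$comp_pos, xbar) <
      component_mean(model$comp_neg, xbar)) {
    model <- structure(list(pi = rev(model$pi), comp_neg = model$comp_pos,
                            comp_pos = model$comp_neg, variant = variant),
                       class = "hto_mixture")
  }
  # Degeneracy: the mixture must beat a single NB component by the BIC
  # penalty for its extra parameters, else the data support one component
  # only (e.g. an HTO whose counts are a single background population).
  single <- tryCatch(
    suppressWarnings(fit_weighted_nb(yf, xf, fix_beta_zero = fix[["pos"]])),
    error = function(e) NULL)
  if (!is.null(single)) {
    ll_mix <- ll_trace[length(ll_trace)]
    extra <- 1L + if (fix[["neg"]]) 2L else 3L  # pi plus negative component
    if (ll_mix - single$loglik < 0.5 * extra * log(length(yf)))
      stop("component collapse for ", hto,
           ": two components do not improve on a single NB fit")
  }

  model$converged <- converged
  model$loglik <- ll_trace[length(ll_trace)]
  model$loglik_trace <- ll_trace
  model$n_iter <- length(ll_trace)
  model$posterior <- posterior_positive(model, y_j, x)
  model$fit_mask <- fit_mask
  model$hto <- hto
  model
}

#' Fit all model variants for one HTO and select the best
#'
#' Fits the full, positive-only and naive variants and returns the one
#' minimizing the expected classification errors, evaluated over the
#' non-outlier droplets. Variants that fail (collapse, empty class,
#' singular design) or do not converge are excluded from selection; at
#' least one variant must succeed.
#'
#' @inheritParams fit_em
#' @param variants Variants to try (default all three).
#' @return The selected `hto_mixture` with an extra `selection` element:
#'   a data.frame of variant, expected-error criterion, convergence flag
#'   and failure message for every attempted variant.
#' @export
fit_best_model <- function(y_j, x, init_positive, fit_mask = NULL,
                           variants = MODEL_VARIANTS, tol = 1e-6,
                           max_iter = 100L, hto = "HTO") {
  if (is.null(fit_mask)) fit_mask <- rep(TRUE, length(y_j))
  fits <- list()
  crit <- rep(NA_real_, length(variants))
  conv <- rep(NA, length(variants))
  msg <- rep(NA_character_, length(variants))
  for (i in seq_along(variants)) {
    v <- variants[i]
    fit <- tryCatch(
      fit_em(y_j, x, init_positive, fit_mask = fit_mask, variant = v,
             tol = tol, max_iter = max_iter, hto = hto),
      error = function(e) e)
    if (inherits(fit, "error")) {
      msg[i] <- conditionMessage(fit)
      next
    }
    fits[[v]] <- fit
    conv[i] <- fit$converged
    crit[i] <- expected_errors(fit$posterior[fit_mask])
  }
  usable <- !is.na(crit) & conv %in% TRUE
  if (!any(usable))
    stop("all model variants failed for ", hto, ": ",
         paste(stats::na.omit(msg), collapse = " | "))
  best <- variants[usable][which.min(crit[usable])]
  model <- fits[[best]]
  model$selection <- data.frame(variant = variants,
                                expected_errors = crit,
                                converged = conv,
                                error = msg,
                                stringsAsFactors = FALSE)
  model
}

#' @export
print.hto_mixture <- function(x, ...) {
  cat(sprintf("NB mixture [%s] for %s: pi2=%.3f%s\n", x$variant,
              if (is.null(x$hto)) "HTO" else x$hto, x$pi[2],
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  cat("  negative: "); print(x$comp_neg)
  cat("  positive: "); print(x$comp_pos)
  invisible(x)
}

#' Serialize a fitted mixture model to JSON
#'
#' @param model An `hto_mixture`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
mixture_to_json <- function(model, path = NULL) {
  comp <- function(cc) list(alpha = cc$alpha, beta = cc$beta, nu = cc$nu,
                            nu_capped = cc$nu_capped)
  obj <- list(hto = model$hto, variant = model$variant,
              pi = as.numeric(model$pi),
              comp_neg = comp(model$comp_neg),
              comp_pos = comp(model$comp_pos),
              converged = model$converged,
              loglik = model$loglik, n_iter = model$n_iter)
  if (!is.null(model$selection))
    obj$selection <- model$selection[, c("variant", "expected_errors",
                                         "converged")]
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
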