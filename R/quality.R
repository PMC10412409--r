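# Overlap score: shared probability mass of the negative and positive
# components, a per-HTO quality metric in (0, 1]. 1 means the components
# are indistinguishable; values near 0 mean clean separation.

# Shared mass of two NB pmfs, truncated where both tails are < tail_tol.
nb_overlap <- function(mu1, nu1, mu2, nu2, tail_tol = 1e-9) {
  zmax <- max(stats::qnbinom(tail_tol / 10, size = nu1, mu = mu1,
                             lower.tail = FALSE),
              stats::qnbinom(tail_tol / 10, size = nu2, mu = mu2,
                             lower.tail = FALSE)) + 1L
  z <- 0:zmax
  ovs <- sum(pmin(stats::dnbinom(z, size = nu1, mu = mu1),
                  stats::dnbinom(z, size = nu2, mu = mu2)))
  trunc_mass <- max(stats::pnbinom(zmax, size = nu1, mu = mu1,
                                   lower.tail = FALSE),
                    stats::pnbinom(zmax, size = nu2, mu = mu2,
                                   lower.tail = FALSE))
  list(ovs = min(max(ovs, 1e-300), 1), truncation_mass = trunc_mass,
       z_max = zmax)
}

#' Posterior-weighted mean detected genes of the two components
#'
#' The positive mean weights each droplet's detected-gene count by its
#' posterior probability of being positive, the negative mean by the
#' complement; outliers are removed before averaging.
#'
#' @param x Detected-gene vector.
#' @param posteriors Posterior probability vector (same length).
#' @param outlier_mask Logical mask of droplets excluded from the averages
#'   (default: none).
#' @return List with `xbar_neg` and `xbar_pos`.
#' @export
weighted_mean_genes <- function(x, posteriors,
                                outlier_mask = rep(FALSE, length(x))) {
  stopifnot(length(posteriors) == length(x),
            length(outlier_mask) == length(x))
  keep <- !outlier_mask
  p <- posteriors[keep]
  xs <- x[keep]
  wpos <- sum(p)
  wneg <- sum(1 - p)
  if (wpos < .Machine$double.eps * length(p))
    stop("positive component has no posterior weight; mean undefined")
  if (wneg < .Machine$double.eps * length(p))
    stop("negative component has no posterior weight; mean undefined")
  list(xbar_neg = sum((1 - p) * xs) / wneg, xbar_pos = sum(p * xs) / wpos)
}

#' Overlap score of a fitted HTO mixture model
#'
#' Sums `min(h(z | theta_neg, xbar_neg), h(z | theta_pos, xbar_pos))` over
#' the count support, truncated where both component tails hold less than
#' `1e-9` mass (residual reported). Each component is evaluated at its own
#' posterior-weighted mean detected-gene count; for the naive variant the
#' means do not enter. The score does not depend on the mixing proportions.
#'
#' @param model An `hto_mixture`.
#' @param xbar_neg,xbar_pos Weighted mean detected genes from
#'   [weighted_mean_genes()]; ignored for the naive variant.
#' @return List with `ovs`, `truncation_mass`, `z_max`.
#' @export
overlap_score <- function(model, xbar_neg = NULL, xbar_pos = NULL) {
  if (model$variant == "naive") {
    mu1 <- exp(model$comp_neg$alpha)
    mu2 <- exp(model$comp_pos$alpha)
  } else {
    if (is.null(xbar_neg) || is.null(xbar_pos))
      stop("xbar_neg/xbar_pos required for regression variants")
    mu1 <- component_mean(model$comp_neg, xbar_neg)
    mu2 <- component_mean(model$comp_pos, xbar_pos)
  }
  nb_overlap(mu1, model$comp_neg$nu, mu2, model$comp_pos$nu)
}

#' Per-HTO quality report
#'
#' @param models List of fitted `hto_mixture` models, one per HTO.
#' @param x Detected-gene vector.
#' @param outlier_masks List of logical outlier masks, one per HTO.
#' @return data.frame: hto, variant, ovs, xbar_neg, xbar_pos, pi_pos,
#'   converged, truncation_mass.
#' @export
quality_report <- function(models, x, outlier_masks) {
  rows <- lapply(seq_along(models), function(j) {
    mod <- models[[j]]
    wm <- weighted_mean_genes(x, mod$posterior, outlier_masks[[j]])
    ov <- overlap_score(mod, wm$xbar_neg, wm$xbar_pos)
    data.frame(hto = if (is.null(mod$hto)) paste0("HTO", j) else mod$hto,
               variant = mod$variant, ovs = ov$ovs,
               xbar_neg = wm$xbar_neg, xbar_pos = wm$xbar_pos,
               pi_pos = mod$pi[2], converged = mod$converged,
               truncation_mass = ov$truncation_mass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
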