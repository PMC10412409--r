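# End-to-end demultiplexing: preprocessing, per-HTO mixture fitting,
# joint classification, quality report.

#' Demultiplex a hashing experiment
#'
#' For every HTO: k-means initialization on log counts, outlier flagging,
#' EM fitting of the two-component NB mixture (all three variants with
#' expected-error model selection, unless a variant is forced), then joint
#' probabilistic classification of the droplets and a per-HTO quality
#' report.
#'
#' @param hx A [HashingExperiment].
#' @param p_acpt Acceptance threshold; default `0.9^n` for `n` HTOs.
#' @param variant `"auto"` (model selection) or one of `"full"`,
#'   `"pos_only"`, `"naive"` to force a variant for every HTO.
#' @param seed Seed for the k-means initialization.
#' @param tol,max_iter EM convergence controls.
#' @param verbose Log the per-HTO selected variant and overlap score to
#'   stderr.
#' @return List of class `demux_result`: `assignments`
#'   ([classify_droplets()] output), `posterior` (droplets x HTOs),
#'   `models` (per-HTO `hto_mixture`), `quality` ([quality_report()]
#'   data.frame), `preprocess` (per-HTO masks), `p_acpt`.
#' @examples
#' sim <- generate_dataset(m = 600, n = 2, seed = 7)
#' res <- demux(sim$experiment, seed = 7)
#' table(res$assignments$class)
#' @export
demux <- function(hx, p_acpt = NULL, variant = c("auto", "full", "pos_only",
                                                 "naive"),
                  seed = 1L, tol = 1e-6, max_iter = 100L, verbose = FALSE) {
  stopifnot(inherits(hx, "HashingExperiment"))
  variant <- match.arg(variant)
  n <- ncol(hx$counts)
  x <- hx$detected_genes

  prep <- vector("list", n)
  models <- vector("list", n)
  post <- matrix(NA_real_, nrow(hx$counts), n,
                 dimnames = dimnames(hx$counts))
  for (j in seq_len(n)) {
    nm <- hx$hto_names[j]
    y_j <- hx$counts[, j]
    prep[[j]] <- preprocess_hto(y_j, x, seed = seed)
    fit_mask <- !prep[[j]]$outlier_mask
    models[[j]] <- if (variant == "auto") {
      fit_best_model(y_j, x, prep[[j]]$positive_mask, fit_mask = fit_mask,
                     tol = tol, max_iter = max_iter, hto = nm)
    } else {
      fit_em(y_j, x, prep[[j]]$positive_mask, fit_mask = fit_mask,
             variant = variant, tol = tol, max_iter = max_iter, hto = nm)
    }
    post[, j] <- models[[j]]$posterior
  }
  quality <- quality_report(models, x,
                            lapply(prep, `[[`, "outlier_mask"))
  if (verbose) {
    for (j in seq_len(n))
      message(sprintf("%s: variant=%s ovs=%.4g pi_pos=%.3f",
                      hx$hto_names[j], models[[j]]$variant,
                      quality$ovs[j], models[[j]]$pi[2]))
  }
  assignments <- classify_droplets(post, p_acpt = p_acpt,
                                   hto_names = hx$hto_names,
                                   droplet_ids = hx$droplet_ids)
  structure(list(assignments = assignments, posterior = post,
                 models = models, quality = quality, preprocess = prep,
                 p_acpt = attr(assignments, "p_acpt")),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("demux_result: %d droplets, %d HTOs, p_acpt = %.4g\n",
              nrow(x$posterior), ncol(x$posterior), x$p_acpt))
  print(table(x$assignments$class))
  cat("\nper-HTO quality:\n")
  print(x$quality[, c("hto", "variant", "ovs", "pi_pos", "converged")],
        row.names = FALSE)
  invisible(x)
}

#' Write quality report TSV
#'
#' @param result A `demux_result` (or the `quality` data.frame itself).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quality <- function(result, path) {
  q <- if (inherits(result, "demux_result")) result$quality else result
  data.table::fwrite(q, path, sep = "\t")
  invisible(path)
}
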