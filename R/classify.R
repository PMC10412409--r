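# Joint classification: combine the per-HTO posterior probabilities into a
# droplet-level call (single-sample droplet, multi-sample multiplet,
# negative) with an error probability, and reject uncertain droplets.

#' Default acceptance threshold
#'
#' `0.9^n` for `n` HTOs: the joint probability a droplet must reach to be
#' classified rather than labelled uncertain. Override per call for
#' stricter or looser error control.
#'
#' @param n Number of HTOs.
#' @return `0.9^n`.
#' @export
default_acceptance <- function(n) 0.9^n

#' Joint probability of a droplet's estimated class vector
#'
#' Under independence across HTOs the probability that the MAP class vector
#' is correct is the product of `p_j` for the HTOs called positive and
#' `1 - p_j` for those called negative. Computed in log space.
#'
#' @param posteriors_row Per-HTO posterior probability vector.
#' @param c_hat Binary class vector of the same length.
#' @return Probability in `[0, 1]`.
#' @export
joint_probability <- function(posteriors_row, c_hat) {
  stopifnot(length(posteriors_row) == length(c_hat))
  p <- ifelse(c_hat == 1, posteriors_row, 1 - posteriors_row)
  if (any(p == 0)) return(0)
  exp(sum(log(p)))
}

#' Classify droplets from the per-HTO posterior matrix
#'
#' Each droplet's per-HTO class is the MAP call (positive iff posterior
#' > 0.5); the joint probability of the class vector (product across HTOs)
#' is compared against `p_acpt`. Droplets below the threshold are
#' `uncertain`; otherwise exactly one positive HTO gives `SSD`, two or
#' more give `MSM`, none gives `negative`. The classifier is defined for a
#' single HTO (`n = 1`), supporting designs where untagged cells are
#' pooled with one tagged sample.
#'
#' @param post Posterior matrix, droplets x HTOs.
#' @param p_acpt Acceptance threshold in `(0, 1]`; default `0.9^n`.
#' @param hto_names HTO names; default from `colnames(post)`.
#' @param droplet_ids Droplet ids; default from `rownames(post)`.
#' @return data.frame of class `droplet_assignment`: `droplet_id`, `class`
#'   (`SSD`/`MSM`/`negative`/`uncertain`), `assignment` (HTO name, comma
#'   joined for MSMs, `NA` otherwise), `joint_prob`, plus one
#'   `posterior.<hto>` column per HTO. The binary MAP matrix is attached as
#'   attribute `c_hat` and the threshold as `p_acpt`.
#' @export
classify_droplets <- function(post, p_acpt = NULL, hto_names = NULL,
                              droplet_ids = NULL) {
  post <- as.matrix(post)
  m <- nrow(post)
  n <- ncol(post)
  if (is.null(hto_names))
    hto_names <- if (!is.null(colnames(post))) colnames(post)
                 else paste0("HTO", seq_len(n))
  if (is.null(droplet_ids))
    droplet_ids <- if (!is.null(rownames(post))) rownames(post)
                   else sprintf("droplet_%04d", seq_len(m))
  if (is.null(p_acpt)) p_acpt <- default_acceptance(n)
  if (!is.numeric(p_acpt) || length(p_acpt) != 1L || p_acpt <= 0 ||
      p_acpt > 1)
    stop("p_acpt must lie in (0, 1]")
  if (anyNA(post) || any(post < 0) || any(post > 1))
    stop("posterior matrix must lie in [0, 1]")

  c_hat <- matrix(hard_class(post), nrow = m, ncol = n,
                  dimnames = list(droplet_ids, hto_names))
  # log-space product over HTOs of p (called positive) or 1-p (negative)
  pj <- ifelse(c_hat == 1L, post, 1 - post)
  lp <- rowSums(log(pj))
  joint <- exp(lp)
  joint[is.nan(joint)] <- 0

  npos <- rowSums(c_hat)
  cls <- ifelse(joint < p_acpt, "uncertain",
                ifelse(npos == 0, "negative",
                       ifelse(npos == 1, "SSD", "MSM")))
  assignment <- rep(NA_character_, m)
  idx <- which(cls %in% c("SSD", "MSM"))
  if (length(idx))
    assignment[idx] <- vapply(idx, function(i)
      paste(hto_names[c_hat[i, ] == 1L], collapse = ","), character(1))

  out <- data.frame(droplet_id = droplet_ids, class = cls,
                    assignment = assignment, joint_prob = joint,
                    stringsAsFactors = FALSE)
  pc <- as.data.frame(post)
  names(pc) <- paste0("posterior.", hto_names)
  out <- cbind(out, pc)
  rownames(out) <- NULL
  attr(out, "c_hat") <- c_hat
  attr(out, "p_acpt") <- p_acpt
  class(out) <- c("droplet_assignment", "data.frame")
  out
}

#' Write droplet assignments to TSV
#'
#' Columns: `droplet_id`, `class`, `assignment`, `joint_prob`, then one
#' `posterior.<hto>` column per HTO.
#'
#' @param assignments A `droplet_assignment` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  data.table::fwrite(as.data.frame(assignments), path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}
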