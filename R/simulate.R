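# Synthetic hashing experiments with known ground truth, the benchmark
# transforms (signal attenuation, doublet injection), and the
# precision/sensitivity metrics used to score demultiplexing runs.

#' Generate a synthetic hashing experiment with ground truth
#'
#' Detected genes are drawn from a log-normal law (default median ~1800
#' genes, typical of filtered 10x droplets). Each droplet's true class is
#' a singlet of one of the `n` samples, a two-sample multiplet, or a
#' negative (untagged) droplet. HTO counts are negative binomial with mean
#' `exp(alpha + beta * log(x_i))`, using the signal parameters where the
#' truth is positive and the background parameters elsewhere. Default
#' signal parameters give a median tagged count of ~1450 reads and a
#' median background of ~25 reads, the scale of a high-quality antibody
#' hashing run; `beta` defaults reflect the strong (signal) and weak
#' (background) positive association between HTO counts and detected
#' genes.
#'
#' @param m Number of droplets.
#' @param n Number of HTOs (samples).
#' @param gene_count_law List with `meanlog` and `sdlog` of the log-normal
#'   detected-gene law (default `log(1800)`, `0.45`).
#' @param signal_params List with `alpha`, `beta`, `nu` for tagged counts;
#'   each element is recycled across HTOs. Default
#'   `alpha = log(1450) - 0.6 * log(1800)`, `beta = 0.6`, `nu = 10`.
#' @param background_params Same shape for background counts. Default
#'   `alpha = log(25) - 0.1 * log(1800)`, `beta = 0.1`, `nu = 5`.
#' @param class_probs List with `msm` (two-sample multiplet probability,
#'   default 0.05) and `negative` (default 0.05); singlets split the rest
#'   equally across samples.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return List of class `simulated_hashing`: `experiment`
#'   ([HashingExperiment]), `truth` (binary droplets x HTOs matrix),
#'   `params` (the complete generating parameter set including the seed).
#' @export
generate_dataset <- function(m = 2000L, n = 4L,
                             gene_count_law = list(meanlog = log(1800),
                                                   sdlog = 0.45),
                             signal_params = list(alpha = log(1450) -
                                                    0.6 * log(1800),
                                                  beta = 0.6, nu = 10),
                             background_params = list(alpha = log(25) -
                                                        0.1 * log(1800),
                                                      beta = 0.1, nu = 5),
                             class_probs = list(msm = 0.05,
                                                negative = 0.05),
                             seed = 1L) {
  p_msm <- class_probs$msm %||% 0
  p_neg <- class_probs$negative %||% 0
  if (p_msm < 0 || p_neg < 0 || p_msm + p_neg >= 1)
    stop("invalid class probabilities")
  if (p_msm > 0 && n < 2L)
    stop("multiplets require at least 2 HTOs")
  rec <- function(p, what) {
    p <- lapply(p, rep_len, n)
    if (any(p$nu <= 0)) stop("non-positive dispersion in ", what)
    p
  }
  sig <- rec(signal_params, "signal_params")
  bg <- rec(background_params, "background_params")

  with_seed(seed, {
    x <- pmax(1L, as.integer(round(stats::rlnorm(m, gene_count_law$meanlog,
                                                 gene_count_law$sdlog))))
    cls <- sample(c("singlet", "msm", "negative"), m, replace = TRUE,
                  prob = c(1 - p_msm - p_neg, p_msm, p_neg))
    truth <- matrix(0L, m, n)
    for (i in seq_len(m)) {
      if (cls[i] == "singlet") {
        truth[i, sample.int(n, 1L)] <- 1L
      } else if (cls[i] == "msm") {
        truth[i, sample.int(n, 2L)] <- 1L
      }
    }
    counts <- matrix(0L, m, n)
    for (j in seq_len(n)) {
      pos <- truth[, j] == 1L
      mu_sig <- exp(sig$alpha[j] + sig$beta[j] * log(x))
      mu_bg <- exp(bg$alpha[j] + bg$beta[j] * log(x))
      counts[pos, j] <- stats::rnbinom(sum(pos), size = sig$nu[j],
                                       mu = mu_sig[pos])
      counts[!pos, j] <- stats::rnbinom(sum(!pos), size = bg$nu[j],
                                        mu = mu_bg[!pos])
    }
    hto_names <- paste0("HTO", seq_len(n))
    dimnames(truth) <- list(sprintf("droplet_%04d", seq_len(m)), hto_names)
    hx <- HashingExperiment(counts, x, hto_names = hto_names)
    structure(list(experiment = hx, truth = truth,
                   params = list(m = m, n = n,
                                 gene_count_law = gene_count_law,
                                 signal_params = sig,
                                 background_params = bg,
                                 class_probs = list(msm = p_msm,
                                                    negative = p_neg),
                                 seed = seed)),
              class = "simulated_hashing")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.simulated_hashing <- function(x, ...) {
  npos <- rowSums(x$truth)
  cat(sprintf(paste0("simulated_hashing: %d droplets x %d HTOs ",
                     "(%d SSD, %d MSM, %d negative; seed %d)\n"),
              nrow(x$truth), ncol(x$truth), sum(npos == 1), sum(npos > 1),
              sum(npos == 0), x$params$seed))
  invisible(x)
}

#' Attenuate the true HTO signal
#'
#' Multiplies the counts of the tagging HTO(s) of each droplet by the
#' scaling factor `s` and rounds to the nearest integer; background counts
#' are untouched. Emulates lower-quality hashing data.
#'
#' @param exp A [HashingExperiment].
#' @param truth Binary droplets x HTOs ground-truth matrix.
#' @param s Scaling factor in `(0, 1]`.
#' @return A new [HashingExperiment].
#' @export
attenuate_signal <- function(exp, truth, s) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s > 1)
    stop("s must lie in (0, 1]")
  counts <- exp$counts
  tagged <- truth == 1L
  counts[tagged] <- round(s * counts[tagged])
  HashingExperiment(counts, exp$detected_genes,
                    droplet_ids = exp$droplet_ids,
                    hto_names = exp$hto_names)
}

#' Inject artificial multi-sample doublets
#'
#' Draws pairs of single-sample droplets from different samples and
#' appends one artificial doublet per pair whose HTO counts and
#' detected-gene count are the rounded averages of the two sources; the
#' truth row is the union of the source rows. Source droplets are kept.
#'
#' @param exp A [HashingExperiment].
#' @param truth Binary ground-truth matrix.
#' @param n_doublets Number of doublets to append.
#' @param seed Integer seed for the pair draws.
#' @return A `simulated_hashing` list with the enlarged experiment and
#'   truth (`params` records the seed and doublet count).
#' @export
merge_doublets <- function(exp, truth, n_doublets, seed = 1L) {
  ssd <- which(rowSums(truth) == 1L)
  if (length(ssd) < 2L) stop("need at least 2 single-sample droplets")
  sample_of <- apply(truth[ssd, , drop = FALSE], 1L, which.max)
  if (length(unique(sample_of)) < 2L)
    stop("single-sample droplets must come from at least 2 different samples")
  with_seed(seed, {
    pairs <- matrix(0L, n_doublets, 2L)
    for (k in seq_len(n_doublets)) {
      a <- sample(seq_along(ssd), 1L)
      b <- sample(which(sample_of != sample_of[a]), 1L)
      pairs[k, ] <- c(ssd[a], ssd[b])
    }
    new_counts <- round((exp$counts[pairs[, 1L], , drop = FALSE] +
                           exp$counts[pairs[, 2L], , drop = FALSE]) / 2)
    new_genes <- pmax(1L, round((exp$detected_genes[pairs[, 1L]] +
                                   exp$detected_genes[pairs[, 2L]]) / 2))
    new_truth <- 1L * ((truth[pairs[, 1L], , drop = FALSE] +
                          truth[pairs[, 2L], , drop = FALSE]) > 0L)
    ids <- c(exp$droplet_ids, sprintf("doublet_%04d", seq_len(n_doublets)))
    counts <- rbind(exp$counts, new_counts)
    genes <- c(exp$detected_genes, new_genes)
    truth2 <- rbind(truth, new_truth)
    rownames(truth2) <- ids
    hx <- HashingExperiment(counts, genes, droplet_ids = ids,
                            hto_names = exp$hto_names)
    structure(list(experiment = hx, truth = truth2,
                   params = list(n_doublets = n_doublets, seed = seed)),
              class = "simulated_hashing")
  })
}

# True class label per droplet from the truth matrix.
truth_classes <- function(truth, hto_names = colnames(truth)) {
  npos <- rowSums(truth)
  cls <- ifelse(npos == 0, "negative", ifelse(npos == 1, "SSD", "MSM"))
  assignment <- rep(NA_character_, nrow(truth))
  idx <- which(npos >= 1)
  assignment[idx] <- vapply(idx, function(i)
    paste(hto_names[truth[i, ] == 1L], collapse = ","), character(1))
  data.frame(class = cls, assignment = assignment, stringsAsFactors = FALSE)
}

#' Benchmark metrics for a demultiplexing run
#'
#' * `precision_ssd`: fraction of predicted single-sample droplets whose
#'   predicted sample is exactly correct.
#' * `sensitivity_ssd`: fraction of true single-sample droplets predicted
#'   as a single-sample droplet of any sample (uncertain/negative/MSM
#'   predictions count against it).
#' * `f_ssd`: harmonic mean of the two.
#' * `precision_msm`: fraction of predicted multiplets that are true
#'   multiplets.
#' * `msm_proportion`: fraction of droplets predicted as multiplets.
#'
#' With no predicted SSDs (or MSMs) the corresponding precision is
#' undefined and reported as `NA`, not 0.
#'
#' @param assignments A `droplet_assignment` data.frame (rows aligned with
#'   `truth`).
#' @param truth Binary droplets x HTOs ground-truth matrix.
#' @return List of class `benchmark_result`: the five metrics and a
#'   `confusion` table of true class vs predicted class.
#' @export
benchmark_metrics <- function(assignments, truth) {
  stopifnot(nrow(assignments) == nrow(truth))
  tc <- truth_classes(truth)
  pred_ssd <- assignments$class == "SSD"
  pred_msm <- assignments$class == "MSM"
  true_ssd <- tc$class == "SSD"

  n_pred_ssd <- sum(pred_ssd)
  correct_ssd <- pred_ssd & true_ssd &
    assignments$assignment == tc$assignment
  precision_ssd <- if (n_pred_ssd) sum(correct_ssd) / n_pred_ssd
                   else NA_real_
  sensitivity_ssd <- if (any(true_ssd)) sum(pred_ssd & true_ssd) /
                       sum(true_ssd) else NA_real_
  f_ssd <- if (!is.na(precision_ssd) && !is.na(sensitivity_ssd) &&
               precision_ssd + sensitivity_ssd > 0)
    2 * precision_ssd * sensitivity_ssd / (precision_ssd + sensitivity_ssd)
  else NA_real_
  precision_msm <- if (any(pred_msm))
    sum(pred_msm & tc$class == "MSM") / sum(pred_msm) else NA_real_

  confusion <- table(true = factor(tc$class,
                                   c("SSD", "MSM", "negative")),
                     predicted = factor(assignments$class,
                                        c("SSD", "MSM", "negative",
                                          "uncertain")))
  structure(list(precision_ssd = precision_ssd,
                 sensitivity_ssd = sensitivity_ssd,
                 f_ssd = f_ssd,
                 precision_msm = precision_msm,
                 msm_proportion = sum(pred_msm) / nrow(truth),
                 confusion = confusion),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(paste0("precision_SSD %.4f  sensitivity_SSD %.4f  ",
                     "F_SSD %.4f\nprecision_MSM %s  MSM proportion %.4f\n"),
              x$precision_ssd, x$sensitivity_ssd, x$f_ssd,
              ifelse(is.na(x$precision_msm), "NA",
                     sprintf("%.4f", x$precision_msm)),
              x$msm_proportion))
  print(x$confusion)
  invisible(x)
}

#' Write / read the ground-truth matrix as TSV
#'
#' One row per droplet: `droplet_id` followed by one 0/1 column per HTO.
#'
#' @param truth Binary droplets x HTOs matrix with dimnames.
#' @param path TSV path.
#' @return `path` (writer) or the truth matrix (reader).
#' @export
write_truth <- function(truth, path) {
  dt <- data.table::data.table(droplet_id = rownames(truth))
  for (j in colnames(truth)) dt[[j]] <- truth[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  truth <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(truth) <- "integer"
  rownames(truth) <- dt[[1L]]
  truth
}
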