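#' Container for a cell-hashing experiment
#'
#' Bundles the droplets x HTOs count matrix with the per-droplet number of
#' detected genes. Empty droplets and low-quality cells are assumed to have
#' been removed upstream based on the transcriptome; droplets with zero
#' detected genes are rejected because the number of detected genes enters
#' the regression models through its logarithm.
#'
#' @param counts Non-negative integer matrix, one row per droplet and one
#'   column per HTO. A `Matrix` sparse matrix is accepted and densified.
#' @param detected_genes Positive integer vector, one entry per droplet:
#'   the number of genes with at least one mapped read in the RNA library.
#' @param droplet_ids Optional character vector of unique droplet barcodes;
#'   defaults to rownames of `counts` or `droplet_0001`-style ids.
#' @param hto_names Optional character vector of HTO names; defaults to
#'   colnames of `counts` or `HTO1`, `HTO2`, ...
#' @return An object of class `HashingExperiment`: a list with elements
#'   `counts` (integer matrix with dimnames), `detected_genes` (named
#'   integer vector), `droplet_ids`, `hto_names`.
#' @examples
#' counts <- matrix(rpois(20, 5), nrow = 10, ncol = 2)
#' hx <- HashingExperiment(counts, detected_genes = rep(1500L, 10))
#' dim(hx$counts)
#' @export
HashingExperiment <- function(counts, detected_genes, droplet_ids = NULL,
                              hto_names = NULL) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  m <- nrow(counts)
  n <- ncol(counts)
  if (m < 2L) stop("a HashingExperiment needs at least 2 droplets")
  if (n < 1L) stop("a HashingExperiment needs at least 1 HTO")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("HTO counts must be non-negative integers")
  if (length(detected_genes) != m)
    stop("detected_genes must have one entry per droplet (", m, ")")
  if (anyNA(detected_genes) || any(detected_genes != floor(detected_genes)))
    stop("detected_genes must be integers")
  if (is.null(droplet_ids)) {
    droplet_ids <- rownames(counts)
    if (is.null(droplet_ids))
      droplet_ids <- sprintf("droplet_%04d", seq_len(m))
  }
  if (length(droplet_ids) != m || anyDuplicated(droplet_ids))
    stop("droplet_ids must be unique and have one entry per droplet")
  bad <- which(detected_genes < 1)
  if (length(bad))
    stop("droplet(s) with zero detected genes: ",
         paste(utils::head(droplet_ids[bad], 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "",
         " (the model requires log(detected genes); filter them upstream)")
  if (is.null(hto_names)) {
    hto_names <- colnames(counts)
    if (is.null(hto_names)) hto_names <- paste0("HTO", seq_len(n))
  }
  if (length(hto_names) != n || anyDuplicated(hto_names))
    stop("hto_names must be unique and have one entry per HTO")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(droplet_ids, hto_names)
  detected_genes <- as.integer(detected_genes)
  names(detected_genes) <- droplet_ids
  structure(list(counts = counts,
                 detected_genes = detected_genes,
                 droplet_ids = droplet_ids,
                 hto_names = hto_names),
            class = "HashingExperiment")
}

#' @export
print.HashingExperiment <- function(x, ...) {
  cat(sprintf("HashingExperiment: %d droplets x %d HTOs (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(utils::head(x$hto_names, 8), collapse = ", ")))
  cat(sprintf("detected genes per droplet: median %.0f [%d, %d]\n",
              stats::median(x$detected_genes), min(x$detected_genes),
              max(x$detected_genes)))
  invisible(x)
}

#' @export
dim.HashingExperiment <- function(x) dim(x$counts)

#' Count detected genes per droplet from an RNA count matrix
#'
#' A gene is considered detected in a droplet if it has at least one mapped
#' read. Droplets without any detected gene are a hard error: they cannot
#' enter the regression models (log of zero) and indicate that upstream
#' quality filtering was skipped.
#'
#' @param rna_counts Non-negative count matrix, droplets in rows and genes
#'   in columns (dense or `Matrix` sparse), row order matching the HTO
#'   matrix.
#' @return Positive integer vector of detected-gene counts, named by the
#'   rownames of `rna_counts` when present.
#' @examples
#' rna <- rbind(a = c(0, 0, 3, 1), b = c(1, 1, 1, 0))
#' detected_genes_from_rna(rna)  # a = 2, b = 3
#' @export
detected_genes_from_rna <- function(rna_counts) {
  if (inherits(rna_counts, "Matrix")) {
    x <- Matrix::rowSums(rna_counts > 0)
  } else {
    x <- rowSums(rna_counts > 0)
  }
  bad <- which(x == 0)
  if (length(bad)) {
    ids <- if (!is.null(rownames(rna_counts))) rownames(rna_counts)[bad]
           else as.character(bad)
    stop("droplet(s) with zero detected genes: ",
         paste(utils::head(ids, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  }
  as.integer(x) -> xi
  names(xi) <- rownames(rna_counts)
  xi
}
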