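#' Read a hashing experiment from a Matrix Market directory
#'
#' Reads the Cell Ranger style triplet layout: a Matrix Market file plus
#' `barcodes.tsv` and `features.tsv` sidecars. Matrix orientation is
#' auto-detected by matching dimensions against the number of barcodes and
#' features; a square matrix with equally many barcodes and features is
#' ambiguous and rejected. HTO features are selected either by name
#' (`hto_names`) or, when the features file has a third column, by
#' `feature_type` (Cell Ranger uses `"Antibody Capture"` for hashing
#' antibodies). Detected genes are computed from the `"Gene Expression"`
#' rows when present, otherwise `detected_genes` must be supplied.
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` (a `genes.tsv` features file is also recognized).
#' @param hto_names Optional character vector naming the HTO features.
#' @param feature_type Feature-type label marking HTO rows
#'   (default `"Antibody Capture"`), used when `hto_names` is `NULL` and a
#'   type column exists.
#' @param detected_genes Optional per-droplet detected-gene vector (or path
#'   to a two-column TSV `droplet_id<TAB>detected_genes`), required when the
#'   matrix holds no gene-expression features.
#' @return A [HashingExperiment].
#' @export
read_hashing_mtx <- function(dir, hto_names = NULL,
                             feature_type = "Antibody Capture",
                             detected_genes = NULL) {
  pick <- function(cands) {
    for (f in cands) {
      p <- file.path(dir, f)
      if (file.exists(p)) return(p)
    }
    stop("none of ", paste(cands, collapse = "/"), " found in ", dir)
  }
  mtx_file <- pick(c("matrix.mtx", "matrix.mtx.gz"))
  bc_file <- pick(c("barcodes.tsv", "barcodes.tsv.gz"))
  ft_file <- pick(c("features.tsv", "features.tsv.gz", "genes.tsv"))
  mat <- Matrix::readMM(mtx_file)
  barcodes <- data.table::fread(bc_file, header = FALSE, sep = "\t")[[1]]
  feats <- data.table::fread(ft_file, header = FALSE, sep = "\t")
  nb <- length(barcodes)
  nf <- nrow(feats)
  dims <- dim(mat)
  feat_rows <- identical(dims, c(nf, nb))
  drop_rows <- identical(dims, c(nb, nf))
  if (feat_rows && drop_rows)
    stop("ambiguous matrix orientation: ", nb, " barcodes and ", nf,
         " features with a ", dims[1], " x ", dims[2], " matrix")
  if (!feat_rows && !drop_rows)
    stop("matrix dimensions ", dims[1], " x ", dims[2],
         " match neither barcodes (", nb, ") nor features (", nf, ")")
  if (feat_rows) mat <- Matrix::t(mat)  # to droplets x features
  mat <- as.matrix(mat)
  feat_names <- feats[[min(2L, ncol(feats))]]
  colnames(mat) <- feat_names
  rownames(mat) <- barcodes

  if (!is.null(hto_names)) {
    missing <- setdiff(hto_names, feat_names)
    if (length(missing))
      stop("HTO feature(s) not found: ", paste(missing, collapse = ", "))
    hto_idx <- match(hto_names, feat_names)
  } else if (ncol(feats) >= 3L) {
    hto_idx <- which(feats[[3L]] == feature_type)
    if (!length(hto_idx))
      stop("no features with type '", feature_type, "' in ", ft_file)
  } else {
    hto_idx <- seq_len(ncol(mat))  # whole matrix is the HTO matrix
  }

  if (is.null(detected_genes)) {
    gene_idx <- if (ncol(feats) >= 3L) which(feats[[3L]] == "Gene Expression")
                else integer(0)
    if (!length(gene_idx))
      stop("no gene-expression features in the matrix; ",
           "supply detected_genes explicitly")
    detected_genes <- rowSums(mat[, gene_idx, drop = FALSE] > 0)
  } else if (is.character(detected_genes) && length(detected_genes) == 1L) {
    detected_genes <- read_detected_genes(detected_genes, barcodes)
  }
  HashingExperiment(mat[, hto_idx, drop = FALSE], detected_genes,
                    droplet_ids = barcodes,
                    hto_names = feat_names[hto_idx])
}

#' Read a per-droplet detected-gene TSV
#'
#' Two columns (`droplet_id`, `detected_genes`), with or without a header.
#'
#' @param path TSV path.
#' @param droplet_ids Optional droplet order to align to.
#' @return Named integer vector.
#' @export
read_detected_genes <- function(path, droplet_ids = NULL) {
  tab <- data.table::fread(path, header = "auto")
  if (ncol(tab) < 2L) stop("expected two columns in ", path)
  x <- as.integer(tab[[2L]])
  names(x) <- as.character(tab[[1L]])
  if (!is.null(droplet_ids)) {
    idx <- match(droplet_ids, names(x))
    if (anyNA(idx))
      stop("detected-gene file is missing ", sum(is.na(idx)), " droplet(s)")
    x <- x[idx]
  }
  x
}

#' Read a hashing experiment from a dense delimited table
#'
#' Droplets in rows, HTOs in columns; the first column holds droplet ids
#' when it is non-numeric. The delimiter is sniffed by `data.table::fread`.
#'
#' @param path CSV/TSV path.
#' @param detected_genes Per-droplet detected-gene vector, or path to a TSV
#'   as in [read_detected_genes()], or the name of a column of the table
#'   itself.
#' @return A [HashingExperiment].
#' @export
read_hashing_table <- function(path, detected_genes) {
  tab <- data.table::fread(path, header = TRUE)
  ids <- NULL
  if (!is.numeric(tab[[1L]])) {
    ids <- as.character(tab[[1L]])
    tab <- tab[, -1L, with = FALSE]
  }
  if (is.character(detected_genes) && length(detected_genes) == 1L &&
      detected_genes %in% names(tab)) {
    dg <- as.integer(tab[[detected_genes]])
    tab <- tab[, setdiff(names(tab), detected_genes), with = FALSE]
  } else if (is.character(detected_genes) && length(detected_genes) == 1L) {
    dg <- read_detected_genes(detected_genes, ids)
  } else {
    dg <- detected_genes
  }
  HashingExperiment(as.matrix(tab), dg, droplet_ids = ids,
                    hto_names = names(tab))
}

#' Write a hashing experiment as Matrix Market plus sidecars
#'
#' Emits `matrix.mtx` (features x barcodes, Cell Ranger orientation),
#' `barcodes.tsv`, `features.tsv` (type `"Antibody Capture"`), and
#' `genes.tsv` with the per-droplet detected-gene counts, so that
#' [read_hashing_mtx()] round-trips the object.
#'
#' @param hx A [HashingExperiment].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hashing_mtx <- function(hx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- Matrix::Matrix(t(hx$counts), sparse = TRUE)
  Matrix::writeMM(mat, file.path(dir, "matrix.mtx"))
  data.table::fwrite(data.table::data.table(hx$droplet_ids),
                     file.path(dir, "barcodes.tsv"),
                     col.names = FALSE, sep = "\t")
  data.table::fwrite(data.table::data.table(hx$hto_names, hx$hto_names,
                                            "Antibody Capture"),
                     file.path(dir, "features.tsv"),
                     col.names = FALSE, sep = "\t")
  data.table::fwrite(data.table::data.table(droplet_id = hx$droplet_ids,
                                            detected_genes = hx$detected_genes),
                     file.path(dir, "genes.tsv"), sep = "\t")
  invisible(dir)
}

#' Write per-droplet preprocessing flags
#'
#' One row per droplet with the initial positive-cluster membership and the
#' outlier flag for every HTO.
#'
#' @param hx A [HashingExperiment].
#' @param prep Per-HTO preprocessing list as returned by [preprocess_hto()]
#'   (one element per HTO with `positive_mask` and `outlier_mask`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_preprocess_flags <- function(hx, prep, path) {
  out <- data.table::data.table(droplet_id = hx$droplet_ids)
  for (j in seq_along(prep)) {
    nm <- hx$hto_names[j]
    out[[paste0(nm, ".positive")]] <- prep[[j]]$positive_mask
    out[[paste0(nm, ".outlier")]] <- prep[[j]]$outlier_mask
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
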