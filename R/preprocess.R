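# Preprocessing per HTO: initial k-means clustering and outlier flags.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Initial positive/negative clustering of one HTO
#'
#' k-means with k = 2 on log(y + 1); the cluster with the larger mean count
#' (on the count scale) is the positive cluster. The pseudocount of 1 keeps
#' zero counts admissible. Deterministic given `seed`; `nstart` restarts
#' protect against poor local optima.
#'
#' @param y_j Count vector for one HTO (length = number of droplets).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts (default 10).
#' @return Logical vector: `TRUE` for droplets in the positive cluster.
#' @examples
#' initial_clusters(c(1, 2, 1, 2, 500, 600, 550), seed = 1)
#' @export
initial_clusters <- function(y_j, seed = 1L, nstart = 10L) {
  if (length(y_j) < 2L) stop("need at least 2 droplets")
  ly <- log1p(y_j)
  if (length(unique(ly)) < 2L)
    stop("HTO has no variation: all counts equal")
  km <- with_seed(seed, stats::kmeans(ly, centers = 2L, nstart = nstart))
  mean_counts <- tapply(y_j, km$cluster, mean)
  pos_cluster <- as.integer(names(mean_counts)[which.max(mean_counts)])
  km$cluster == pos_cluster
}

# Tukey upper fence over v: Q3 + 1.5 * IQR, linear-interpolation quantiles.
upper_fence <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Flag outlier droplets for one HTO
#'
#' A droplet is flagged if it lies in the positive cluster with an HTO count
#' above Q3 + 1.5 IQR of the positive-cluster counts, or if its
#' detected-gene count exceeds Q3 + 1.5 IQR over all droplets. Flagged
#' droplets are excluded from model fitting but are still classified.
#'
#' @param y_j Count vector for one HTO.
#' @param x Detected-gene vector.
#' @param positive_mask Logical vector from [initial_clusters()].
#' @return Logical outlier mask.
#' @export
flag_outliers <- function(y_j, x, positive_mask) {
  m <- length(y_j)
  stopifnot(length(x) == m, length(positive_mask) == m)
  out <- x > upper_fence(x)
  if (any(positive_mask)) {
    fence <- upper_fence(y_j[positive_mask])
    out <- out | (positive_mask & y_j > fence)
  }
  out
}

#' Preprocess one HTO: initial clustering plus outlier flags
#'
#' @inheritParams flag_outliers
#' @inheritParams initial_clusters
#' @return List with `positive_mask` and `outlier_mask`.
#' @export
preprocess_hto <- function(y_j, x, seed = 1L, nstart = 10L) {
  pos <- initial_clusters(y_j, seed = seed, nstart = nstart)
  list(positive_mask = pos, outlier_mask = flag_outliers(y_j, x, pos))
}
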