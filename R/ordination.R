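#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: the matrix of
#' `-0.5 * d^2` is double-centered (Gower) and eigendecomposed. Axes are
#' ordered by eigenvalue; coordinates are returned only for strictly
#' positive eigenvalues, scaled so inter-row distances reproduce the
#' centered inner products. Bray-Curtis matrices are generally
#' non-Euclidean, so negative eigenvalues can occur; they are dropped and
#' reported rather than corrected. Axis signs are fixed by making the
#' largest-magnitude coordinate on each axis positive, so outputs are
#' reproducible.
#'
#' @param d square symmetric distance matrix (zero diagonal), or a `dist`
#' @param eps eigenvalues with absolute value below `eps * max(|eig|)` are
#'   treated as numerically zero
#' @return object of class `pcoa_result`: list with `labels`,
#'   `eigenvalues` (all, descending), `coordinates` (rows = observations,
#'   columns = positive axes), `proportion_explained` (over retained axes)
#'   and `negative_eigenvalue_report` (`count`, `most_negative`)
#' @export
pcoa <- function(d, eps = 1e-9) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (any(is.na(d))) stop("NA in distance matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(d)
  if (n < 2) stop("need at least two observations")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  a <- -0.5 * d^2
  # Gower double-centering: B = (I - 11'/n) A (I - 11'/n)
  rm <- rowMeans(a)
  cm <- colMeans(a)
  b <- a - outer(rm, rep(1, n)) - outer(rep(1, n), cm) + mean(a)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  ev <- e$values
  tol <- eps * max(abs(ev), 1e-300)
  pos <- which(ev > tol)
  neg <- ev[ev < -tol]
  coords <- if (length(pos)) {
    e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  } else {
    matrix(0, n, 0)
  }
  # deterministic axis orientation
  if (ncol(coords) > 0) {
    for (j in seq_len(ncol(coords))) {
      i <- which.max(abs(coords[, j]))
      if (coords[i, j] < 0) coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- labels
  colnames(coords) <- if (ncol(coords)) paste0("axis", seq_len(ncol(coords)))
  structure(list(
    labels = labels,
    eigenvalues = ev,
    coordinates = coords,
    proportion_explained = if (length(pos)) ev[pos] / sum(ev[pos]) else numeric(0),
    negative_eigenvalue_report = list(
      count = length(neg),
      most_negative = if (length(neg)) min(neg) else 0)
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d observations, %d positive axes",
              length(x$labels), ncol(x$coordinates)))
  if (ncol(x$coordinates) >= 2) {
    cat(sprintf(" (axis1 %.1f%%, axis2 %.1f%%)",
                100 * x$proportion_explained[1],
                100 * x$proportion_explained[2]))
  }
  cat(sprintf("; %d negative eigenvalue(s)\n",
              x$negative_eigenvalue_report$count))
  invisible(x)
}

#' Cluster recovery score on ordination axes
#'
#' Partitions the first `n_axes` principal coordinates with k-medoids
#' (PAM) and scores agreement with known labels by the adjusted Rand
#' index. Quantifies how cleanly an ordination separates known groups.
#'
#' @param result a [pcoa()] result
#' @param true_labels vector of known group labels, aligned with
#'   `result$labels`
#' @param k number of clusters (>= 2)
#' @param n_axes number of leading axes to cluster on
#' @param seed integer seed (PAM's build phase is deterministic, but the
#'   seed is applied for reproducibility of any sampled start)
#' @return adjusted Rand index in [-1, 1]; 1 means perfect recovery
#' @export
cluster_recovery_score <- function(result, true_labels, k, n_axes = 2,
                                   seed = 1) {
  n <- length(result$labels)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of observations")
  if (length(true_labels) != n) stop("true_labels length mismatch")
  n_axes <- min(n_axes, ncol(result$coordinates))
  if (n_axes < 1) stop("no positive axes available")
  set.seed(seed)
  cl <- cluster::pam(result$coordinates[, seq_len(n_axes), drop = FALSE],
                     k = k, cluster.only = TRUE)
  mclust::adjustedRandIndex(cl, true_labels)
}

#' Ordination scatter table
#'
#' @param result a [pcoa()] result
#' @param groups optional group label per observation
#' @return data frame `label, group, axis1, axis2` for external plotting
#' @export
pcoa_plot_table <- function(result, groups = NULL) {
  co <- result$coordinates
  if (ncol(co) < 2) stop("fewer than two positive axes")
  data.frame(label = result$labels,
             group = if (is.null(groups)) NA_character_ else groups,
             axis1 = co[, 1], axis2 = co[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}
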