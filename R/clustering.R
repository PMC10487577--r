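#' Single-linkage dendrogram of a distance matrix
#'
#' Agglomerative single-linkage clustering: at each step the two clusters
#' at minimum single-link (nearest-member) distance are merged at that
#' distance. Ties are broken by the lexicographically smallest pair of
#' cluster representative labels (a cluster is represented by its smallest
#' member label), so the merge order is fully deterministic.
#'
#' The result is an `hclust`-compatible object (fields `merge`, `height`,
#' `order`, `labels`) so [stats::cutree()] and [ape::as.phylo()] apply.
#'
#' @param d square symmetric distance matrix with labels, or a `dist`
#' @return object of class `c("ms_dendrogram", "hclust")`
#' @export
linkage_single <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (any(is.na(d))) stop("NA in distance matrix")
  n <- nrow(d)
  if (n < 2) stop("need at least two leaves")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active cluster state: hclust id (-leaf or +merge), representative label
  work <- d
  ids <- -seq_len(n)
  reps <- labels
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    best_d <- Inf
    best_key <- NULL
    pair_key <- function(i, j) paste(sort(c(reps[i], reps[j])),
                                     collapse = "\r")
    for (ai in seq_along(idx)) {
      for (aj in seq_along(idx)) {
        if (aj <= ai) next
        i <- idx[ai]; j <- idx[aj]
        dij <- work[i, j]
        if (dij > best_d) next
        key <- pair_key(i, j)
        if (dij < best_d || key < best_key) {
          best_d <- dij
          best <- c(i, j)
          best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    # hclust ordering: singletons (by label index) before prior merges
    pair <- c(ids[i], ids[j])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    height[step] <- best_d
    # single linkage: min distance to the merged cluster
    for (k in idx) {
      if (k == i || k == j) next
      work[i, k] <- work[k, i] <- min(work[i, k], work[j, k])
    }
    ids[i] <- step
    reps[i] <- min(reps[i], reps[j])
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height,
                 order = dendrogram_order(merge, n),
                 labels = labels, method = "single",
                 call = match.call(), dist.method = "user"),
            class = c("ms_dendrogram", "hclust"))
}

# leaf ordering for plotting: left-to-right traversal of the merge tree
dendrogram_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1)
}

#' Serialize a tree to Newick
#'
#' Dendrograms (merge trees with ultrametric heights) get branch lengths
#' `parent height - child height`; phylogenies are written with their
#' stored branch lengths. Support values, when present, are written as
#' internal node labels.
#'
#' @param t an `ms_dendrogram`/`hclust` or an `ape::phylo`
#' @param path optional file; when `NULL` the Newick string is returned
#' @return Newick string (invisibly when written to a file)
#' @export
to_newick <- function(t, path = NULL) {
  phy <- if (inherits(t, "phylo")) t else as_phylo_dendrogram(t)
  txt <- ape::write.tree(phy, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Convert a dendrogram to an ape phylogeny
#'
#' @param t an `ms_dendrogram` or `hclust`
#' @return a rooted `ape::phylo` with branch lengths
#'   `parent height - child height`
#' @export
as_phylo_dendrogram <- function(t) {
  if (!inherits(t, "hclust")) stop("t must be an hclust-style dendrogram")
  phy <- ape::as.phylo(structure(unclass(t), class = "hclust"))
  # ape scales so leaf-to-leaf distance equals the merge height; the merge
  # tree convention here places leaves at height 0 and parents at their
  # merge heights, so edge lengths are doubled
  phy$edge.length <- phy$edge.length * 2
  phy
}

#' Parse a Newick file or string
#'
#' @param x a file path or a Newick string (detected by a terminal `;`)
#' @return an `ape::phylo`
#' @export
from_newick <- function(x) {
  if (grepl(";\\s*$", x)) ape::read.tree(text = x) else ape::read.tree(x)
}

#' Cut a dendrogram into k groups
#'
#' Removes the `k - 1` highest merges and returns the resulting partition.
#' Groups are labeled deterministically by their smallest member label.
#'
#' @param t an `ms_dendrogram`/`hclust`
#' @param k number of groups, `1 <= k <= n`
#' @return a grouping: named character vector mapping each leaf label to
#'   its group id (the group's smallest member label)
#' @export
cut_dendrogram <- function(t, k) {
  n <- length(t$labels)
  if (k < 1 || k > n) stop("k out of range")
  cl <- stats::cutree(structure(unclass(t), class = "hclust"), k = k)
  canonicalize_grouping(stats::setNames(as.character(cl), t$labels))
}

#' Canonicalize a grouping's group ids
#'
#' Relabels each group by its smallest member label so partitions are
#' comparable across runs and methods.
#'
#' @param g named vector: leaf label -> arbitrary group id
#' @return named character vector with deterministic group ids
#' @export
canonicalize_grouping <- function(g) {
  labs <- names(g)
  ids <- vapply(split(labs, g), min, character(1))
  out <- stats::setNames(ids[as.character(g)], labs)
  out[order(labs)]
}
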