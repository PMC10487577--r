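#' Composite correlation index parameters
#'
#' The composite correlation index (CCI) splits the m/z grid into
#' `n_intervals` equal-width contiguous blocks, computes the Pearson
#' correlation between two spectra within each block, and averages the
#' block correlations. Blocks where either spectrum has zero variance are
#' excluded from the mean; negative composites are clamped to 0 so the
#' index lives on the [0, 1] relatedness scale. `n_intervals = 1` recovers
#' the plain (clamped) Pearson correlation.
#'
#' @param n_intervals number of equal-width mass intervals (default 10)
#' @param clamp_negative clamp negative composite values to 0 (default TRUE)
#' @param min_points_per_interval minimum block length in grid points
#' @return object of class `cci_params`
#' @export
cci_params <- function(n_intervals = 10, clamp_negative = TRUE,
                       min_points_per_interval = 2) {
  if (n_intervals < 1) stop("n_intervals must be >= 1")
  structure(list(n_intervals = as.integer(n_intervals),
                 clamp_negative = isTRUE(clamp_negative),
                 min_points_per_interval = min_points_per_interval),
            class = "cci_params")
}

# Split 1..n into n_intervals contiguous blocks as equal as possible
# (remainder spread over the leading blocks).
interval_index <- function(n, n_intervals) {
  if (n_intervals > n) stop("more intervals than grid points")
  sizes <- rep(n %/% n_intervals, n_intervals)
  r <- n %% n_intervals
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  rep(seq_len(n_intervals), times = sizes)
}

#' Pearson correlation of two intensity vectors
#'
#' Thin wrapper around [stats::cor()] that signals zero-variance input
#' explicitly instead of returning `NA`.
#'
#' @param x,y numeric vectors of equal length >= 2
#' @return correlation in [-1, 1], or `NA_real_` when either vector has
#'   zero variance (the caller decides how to treat uninformative blocks)
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Composite correlation index of two spectra
#'
#' @param a,b `grid_spectrum` objects on the same grid
#' @param p a [cci_params()]
#' @return CCI value in [0, 1] (in [-1, 1] if `clamp_negative = FALSE`)
#' @export
cci <- function(a, b, p = cci_params()) {
  if (!identical(unclass(a$grid), unclass(b$grid))) {
    stop("spectra are on different grids")
  }
  cci_vectors(a$intensity, b$intensity, p)
}

cci_vectors <- function(x, y, p = cci_params()) {
  blocks <- interval_index(length(x), p$n_intervals)
  rs <- vapply(seq_len(p$n_intervals), function(i) {
    sel <- blocks == i
    pearson(x[sel], y[sel])
  }, numeric(1))
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0) stop("no informative interval")
  v <- mean(rs)
  if (p$clamp_negative) v <- max(0, v)
  v
}

#' Pairwise CCI similarity matrix
#'
#' Computes all pairwise composite correlation indices over a spectrum
#' set. Block correlations are computed once per interval for the whole
#' set; pairs sharing a zero-variance block exclude that block from their
#' mean.
#'
#' @param set a [spectrum_set()]
#' @param p a [cci_params()]
#' @return symmetric similarity matrix with unit diagonal, labeled
#'   `strain_id.replicate_id`
#' @export
cci_matrix <- function(set, p = cci_params()) {
  m <- intensity_matrix(set)
  if (ncol(m) < 2) stop("need at least two spectra")
  blocks <- interval_index(nrow(m), p$n_intervals)
  n <- ncol(m)
  acc <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (i in seq_len(p$n_intervals)) {
    sub <- m[blocks == i, , drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    ok <- sds > 0
    if (sum(ok) < 1) next
    r <- suppressWarnings(stats::cor(sub[, ok, drop = FALSE]))
    informative <- outer(ok, ok, "&")
    acc[informative] <- acc[informative] + as.vector(r)
    cnt[informative] <- cnt[informative] + 1L
  }
  if (any(cnt == 0)) {
    bad <- which(cnt == 0, arr.ind = TRUE)[1, ]
    stop("no informative interval for pair ", colnames(m)[bad[1]], " / ",
         colnames(m)[bad[2]])
  }
  v <- acc / cnt
  if (p$clamp_negative) v[v < 0] <- 0
  diag(v) <- 1
  v <- (v + t(v)) / 2  # numeric symmetry
  dimnames(v) <- list(colnames(m), colnames(m))
  v
}

#' Bray-Curtis dissimilarity matrix of a spectrum set
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` over the shared grid,
#' bounded in [0, 1] for nonnegative intensities.
#'
#' @param set a [spectrum_set()]
#' @return symmetric distance matrix with zero diagonal
#' @export
bray_curtis_matrix <- function(set) {
  m <- intensity_matrix(set)
  zero <- colSums(m) == 0
  if (any(zero)) {
    stop("all-zero spectrum for: ", paste(colnames(m)[zero], collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' Bin the off-diagonal entries of a similarity matrix
#'
#' Counts matrix cells per similarity bin, counting both orientations of
#' each pair (an n x n matrix contributes n(n-1) cells), as in published
#' CCI-matrix accountings.
#'
#' @param m square similarity matrix
#' @param thresholds ascending cutoffs; `c(0.1, 0.5)` gives bins
#'   `< 0.1`, `0.1-0.5` and `>= 0.5`
#' @return data frame with columns `bin`, `count`, `fraction`
#' @export
cci_summary <- function(m, thresholds = c(0.1, 0.5)) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2) {
    stop("m must be a square matrix with >= 2 rows")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending")
  }
  off <- m[row(m) != col(m)]
  breaks <- c(-Inf, thresholds, Inf)
  labs <- character(length(thresholds) + 1)
  labs[1] <- sprintf("<%g", thresholds[1])
  if (length(thresholds) > 1) {
    for (i in seq_len(length(thresholds) - 1)) {
      labs[i + 1] <- sprintf("%g-%g", thresholds[i], thresholds[i + 1])
    }
  }
  labs[length(labs)] <- sprintf(">=%g", thresholds[length(thresholds)])
  cuts <- cut(off, breaks = breaks, labels = labs, right = FALSE)
  counts <- as.vector(table(cuts))
  data.frame(bin = labs, count = counts, fraction = counts / length(off),
             stringsAsFactors = FALSE)
}

#' Aggregate a replicate-level similarity matrix to strain level
#'
#' Strain-pair similarity is the mean of all cross-replicate pair values;
#' the diagonal is set to 1.
#'
#' @param m replicate-level similarity matrix (labels
#'   `strain_id.replicate_id`)
#' @param strain_ids strain label of each row of `m`
#' @return strain-level similarity matrix labeled by strain
#' @export
aggregate_to_strains <- function(m, strain_ids) {
  stopifnot(length(strain_ids) == nrow(m))
  strains <- unique(strain_ids)
  k <- length(strains)
  out <- matrix(1, k, k, dimnames = list(strains, strains))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      v <- mean(m[strain_ids == strains[i], strain_ids == strains[j]])
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Mean CCI within and between taxonomic levels
#'
#' Summarises a replicate-level CCI matrix into the three tiers the
#' fingerprinting analysis compares: replicate pairs of one strain,
#' strain pairs of different species within one genus, and pairs across
#' genera.
#'
#' @param m replicate-level similarity matrix
#' @param manifest data frame aligned with the rows of `m` (columns
#'   `strain_id`, `species`, `genus`)
#' @return named numeric vector `intra_strain`, `intra_genus_inter_species`,
#'   `inter_genus` (NA for empty tiers)
#' @export
cci_level_means <- function(m, manifest) {
  stopifnot(nrow(manifest) == nrow(m))
  ut <- upper.tri(m)
  same_strain <- outer(manifest$strain_id, manifest$strain_id, "==")
  same_species <- outer(manifest$species, manifest$species, "==")
  same_genus <- outer(manifest$genus, manifest$genus, "==")
  mean_or_na <- function(sel) if (any(sel)) mean(m[sel]) else NA_real_
  c(intra_strain = mean_or_na(ut & same_strain),
    intra_genus_inter_species = mean_or_na(ut & same_genus & !same_species),
    inter_genus = mean_or_na(ut & !same_genus))
}
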