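# Independent re-implementations used as oracles; kept deliberately naive.

# Sliding-window denoiser: re-rank every window from scratch.
naive_denoise <- function(x, w, keep_fraction, step = 1,
                          rule = c("union", "per_window")) {
  rule <- match.arg(rule)
  n <- length(x)
  k <- max(1, min(w, ceiling(keep_fraction * w)))
  starts <- seq(1, n - w + 1, by = step)
  if (starts[length(starts)] != n - w + 1) starts <- c(starts, n - w + 1)
  marked_in <- function(s) {
    idx <- s:(s + w - 1)
    idx[order(-x[idx], idx)][seq_len(k)]
  }
  if (rule == "union") {
    keep <- rep(FALSE, n)
    for (s in starts) keep[marked_in(s)] <- TRUE
    ifelse(keep, x, 0)
  } else {
    out <- x
    for (s in starts) {
      idx <- s:(s + w - 1)
      m <- marked_in(s)
      out[idx] <- 0
      out[m] <- x[m]
    }
    out
  }
}

# Random sparse grid spectrum on a small grid.
random_grid_spectrum <- function(n = 200, density = 0.2,
                                 start = 2000, step = 1) {
  g <- grid_spec(start, start + (n - 1) * step, step)
  x <- numeric(n)
  nz <- sample.int(n, max(1, round(density * n)))
  x[nz] <- rlnorm(length(nz), log(100), 1)
  s <- new_test_grid_spectrum(x, g)
  s
}

new_test_grid_spectrum <- function(x, g, strain = "s", rep_ = "r1",
                                   flags = list(resampled = TRUE,
                                                log_transformed = TRUE,
                                                denoised = FALSE)) {
  structure(list(grid = g, intensity = x, strain_id = strain,
                 replicate_id = rep_, flags = flags),
            class = "grid_spectrum")
}

# Random raw spectrum within a window.
random_raw_spectrum <- function(n_peaks = 30, mz_min = 2000, mz_max = 20000,
                                strain = "s", rep_ = "r1") {
  mz <- sort(sample(seq(mz_min * 10, mz_max * 10), n_peaks)) / 10
  suppressWarnings(raw_spectrum(mz, rlnorm(n_peaks, log(100), 1),
                                strain_id = strain, replicate_id = rep_,
                                mz_min = mz_min, mz_max = mz_max))
}

# Naive O(n^3) single-linkage agglomeration returning cophenetic distances.
naive_single_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- min(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    for (a in clusters[[best[1]]]) {
      for (b in clusters[[best[2]]]) {
        coph[a, b] <- coph[b, a] <- best_d
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# Random additive distance matrix from a random tree; returns both.
random_additive <- function(n_taxa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tree, d = d)
}

# Tiny preset used across tests: 2 genera x 2 species x 2 strains.
small_sim_config <- function(seed = 1, ...) {
  args <- modifyList(list(n_genera = 2, species_per_genus = 2,
                          strains_per_species = 2, replicates = 2,
                          seq_length = 600, seed = seed),
                     list(...))
  do.call(sim_config, args)
}
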