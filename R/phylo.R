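#' Read or build an aligned sequence set
#'
#' An alignment is a character matrix (rows = strains, columns = aligned
#' sites) over `A,C,G,T,N,-`. Sequences must be pre-aligned; this package
#' does not align.
#'
#' @param x a named character vector of equal-length sequences, or a
#'   character matrix
#' @return character matrix of single upper-case characters with strain
#'   ids as row names
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    if (is.null(names(x))) stop("sequences must be named by strain id")
    lens <- nchar(x)
    if (length(unique(lens)) != 1) stop("sequences differ in length")
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate sequence ids")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) stop("unexpected characters in alignment: ",
                        paste(bad, collapse = ", "))
  m
}

#' Read an aligned multi-FASTA
#'
#' @param path FASTA file of equal-length sequences
#' @return alignment matrix (see [as_alignment()])
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  as_alignment(vapply(as.character(dna), paste, "", collapse = ""))
}

#' Write an alignment to FASTA
#'
#' @param aln alignment matrix
#' @param path output file
#' @return `path`, invisibly
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Pairwise evolutionary distances from an alignment
#'
#' Closed-form distances with pairwise deletion of gaps and ambiguous
#' sites: `p` is the raw mismatch fraction, `jc69` the Jukes-Cantor
#' correction `-(3/4) log(1 - 4p/3)`, and `k2p` the Kimura two-parameter
#' distance from transition and transversion fractions.
#'
#' @param aln alignment matrix (see [as_alignment()])
#' @param model `"p"`, `"jc69"` or `"k2p"`
#' @param pairwise_deletion drop gap/N sites per pair (default) rather
#'   than across the whole alignment
#' @return labeled symmetric distance matrix (substitutions/site)
#' @export
pairwise_distance <- function(aln, model = c("p", "jc69", "k2p"),
                              pairwise_deletion = TRUE) {
  model <- match.arg(model)
  aln <- as_alignment(aln)
  if (!pairwise_deletion) {
    ok <- apply(aln, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    if (!any(ok)) stop("no site without gaps or ambiguity")
    aln <- aln[, ok, drop = FALSE]
  }
  dna <- ape::as.DNAbin(tolower(aln))
  ape_model <- c(p = "raw", jc69 = "JC69", k2p = "K80")[[model]]
  d <- ape::dist.dna(dna, model = ape_model, pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1, ]
    stop(sprintf("distance undefined for pair %s / %s (saturation or no comparable sites)",
                 rownames(d)[bad[1]], colnames(d)[bad[2]]))
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` (with `R_i` the row sum over
#' active nodes) is joined; branch lengths to the new node are
#' `d(i, j)/2 +- (R_i - R_j) / (2(r - 2))` and distances to the remaining
#' nodes are `(d(i, k) + d(j, k) - d(i, j)) / 2`. Q-ties are broken by the
#' lexicographically smallest pair of representative labels. Negative
#' branch-length estimates are clamped to zero and the clamped total is
#' reported in attribute `clamped_length`. NJ is exact on additive
#' distance matrices.
#'
#' @param d labeled symmetric distance matrix, `n >= 2`
#' @return unrooted `ape::phylo` with branch lengths (for `n = 2` the two
#'   tips are joined by a degree-2 node splitting the single edge, so the
#'   path length between them equals `d[1, 2]`)
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (any(is.na(d))) stop("NA in distance matrix")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  n <- nrow(d)
  if (n < 2) stop("need at least two taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  clamped <- 0
  fmt <- function(x) sprintf("%.12g", max(0, x))
  clamp <- function(x) {
    if (x < 0) clamped <<- clamped - x
    max(0, x)
  }
  if (n == 2) {
    txt <- sprintf("(%s:%s,%s:%s);", labels[1], fmt(d[1, 2] / 2),
                   labels[2], fmt(d[1, 2] / 2))
    phy <- ape::read.tree(text = txt)
    attr(phy, "clamped_length") <- 0
    return(phy)
  }
  work <- d
  frag <- labels           # newick fragment per active node
  reps <- labels           # representative label (smallest descendant)
  active <- rep(TRUE, n + n - 3)
  active[seq_len(n)] <- TRUE
  if (n > 3) active[(n + 1):(n + n - 3)] <- FALSE
  # grow the matrix to hold internal nodes
  work <- rbind(cbind(work, matrix(0, n, n - 3)),
                matrix(0, n - 3, n + n - 3))
  frag <- c(frag, rep(NA_character_, n - 3))
  reps <- c(reps, rep(NA_character_, n - 3))
  act <- seq_len(n)
  next_id <- n + 1
  while (length(act) > 3) {
    r <- length(act)
    rs <- rowSums(work[act, act, drop = FALSE])
    names(rs) <- NULL
    best <- NULL; best_q <- Inf; best_key <- NULL
    for (ai in seq_len(r - 1)) {
      for (aj in (ai + 1):r) {
        q <- (r - 2) * work[act[ai], act[aj]] - rs[ai] - rs[aj]
        if (q > best_q + 1e-12) next
        key <- paste(sort(c(reps[act[ai]], reps[act[aj]])), collapse = "\r")
        if (q < best_q - 1e-12 || (q <= best_q + 1e-12 && key < best_key)) {
          if (q < best_q) best_q <- q
          best <- c(ai, aj)
          best_key <- key
        }
      }
    }
    i <- act[best[1]]; j <- act[best[2]]
    dij <- work[i, j]
    li <- clamp(dij / 2 + (rs[best[1]] - rs[best[2]]) / (2 * (r - 2)))
    lj <- clamp(dij - (dij / 2 + (rs[best[1]] - rs[best[2]]) / (2 * (r - 2))))
    u <- next_id; next_id <- next_id + 1
    for (k in act) {
      if (k == i || k == j) next
      work[u, k] <- work[k, u] <- (work[i, k] + work[j, k] - dij) / 2
    }
    frag[u] <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    reps[u] <- min(reps[i], reps[j])
    act <- c(setdiff(act, c(i, j)), u)
  }
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- clamp((work[a, b] + work[a, c3] - work[b, c3]) / 2)
  lb <- clamp((work[a, b] + work[b, c3] - work[a, c3]) / 2)
  lc <- clamp((work[a, c3] + work[b, c3] - work[a, b]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a], fmt(la), frag[b], fmt(lb),
                 frag[c3], fmt(lc))
  phy <- ape::read.tree(text = txt)
  attr(phy, "clamped_length") <- clamped
  phy
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal bipartition of the original tree
#' with the fraction of replicates containing it (stored in
#' `node.label`). Replicates whose distance matrix is undefined (e.g.
#' saturation on a resampled column set) are skipped and counted; more
#' than 50% skipped is an error.
#'
#' @param aln alignment matrix
#' @param model distance model, see [pairwise_distance()]
#' @param n_reps number of bootstrap replicates
#' @param seed integer seed
#' @return the NJ tree of the full alignment with supports in
#'   `node.label` and attribute `n_skipped`
#' @export
bootstrap_support <- function(aln, model = "jc69", n_reps = 100, seed = 1) {
  aln <- as_alignment(aln)
  if (n_reps < 1) stop("n_reps must be >= 1")
  tree <- neighbor_joining(pairwise_distance(aln, model))
  set.seed(seed)
  reps <- vector("list", n_reps)
  skipped <- 0
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    t_b <- tryCatch(
      neighbor_joining(pairwise_distance(aln[, cols, drop = FALSE], model)),
      error = function(e) NULL)
    if (is.null(t_b)) skipped <- skipped + 1 else reps[[b]] <- t_b
  }
  reps <- Filter(Negate(is.null), reps)
  if (skipped > n_reps / 2) {
    stop(sprintf("%d of %d bootstrap replicates had undefined distances",
                 skipped, n_reps))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- format(counts / length(reps), trim = TRUE)
  attr(tree, "n_skipped") <- skipped
  tree
}

#' Midpoint-root an unrooted tree
#'
#' @param tree an `ape::phylo`
#' @return rooted `ape::phylo`
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}
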