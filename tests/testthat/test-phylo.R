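aln4 <- function() {
  as_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                 c = "ACGAACGTAC", d = "TCGAACGTAC"))
}

test_that("pairwise distances match closed forms", {
  a <- as_alignment(c(x = "ACGT", y = "ACGT"))
  for (m in c("p", "jc69", "k2p")) {
    expect_equal(unname(pairwise_distance(a, m)["x", "y"]), 0)
  }
  b <- as_alignment(c(x = "ACGT", y = "ACGA"))
  expect_equal(unname(pairwise_distance(b, "p")["x", "y"]), 0.25)
  expect_equal(unname(pairwise_distance(b, "jc69")["x", "y"]),
               -0.75 * log(1 - 4 / 3 * 0.25), tolerance = 1e-10)
  expect_equal(unname(pairwise_distance(b, "jc69")["x", "y"]), 0.3041,
               tolerance = 1e-4)
  # gaps removed pairwise
  g <- as_alignment(c(x = "AC-T", y = "ACGA"))
  expect_equal(unname(pairwise_distance(g, "p")["x", "y"]), 1 / 3,
               tolerance = 1e-10)
  # saturation (p >= 3/4) is an error naming the pair
  s <- as_alignment(c(x = "AAAA", y = "CCCC"))
  expect_error(pairwise_distance(s, "jc69"), "x / y|undefined")
})

test_that("distance matrices are symmetric with zero diagonal", {
  d <- pairwise_distance(aln4(), "jc69")
  expect_identical(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("NJ resolves the worked additive quartet exactly", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t <- neighbor_joining(d)
  # topology (A,B)|(C,D)
  truth <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(robinson_foulds(t, truth), 0)
  # additive: patristic distances reproduce the input
  expect_equal(ape::cophenetic.phylo(t)[LETTERS[1:4], LETTERS[1:4]],
               d, tolerance = 1e-12)
  # branch lengths 1,2,3,4 and internal 1
  expect_setequal(round(t$edge.length, 9), c(1, 2, 3, 4, 1))
})

test_that("NJ handles the two-taxon edge case", {
  d <- matrix(c(0, .3, .3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  t <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(t)["a", "b"], 0.3, tolerance = 1e-12)
})

test_that("NJ is exact on random additive matrices and agrees with ape::nj", {
  set.seed(73)
  for (i in 1:100) {
    ra <- random_additive(sample(5:10, 1))
    t <- neighbor_joining(ra$d)
    expect_equal(robinson_foulds(t, ra$tree), 0)
    labs <- rownames(ra$d)
    expect_equal(ape::cophenetic.phylo(t)[labs, labs], ra$d,
                 tolerance = 1e-9)
    expect_equal(robinson_foulds(t, ape::nj(as.dist(ra$d))), 0)
    # fully resolved unrooted binary tree: n-2 internal nodes, 2n-3 edges
    n <- length(labs)
    expect_equal(t$Nnode, n - 2)
    expect_equal(nrow(t$edge), 2 * n - 3)
  }
})

test_that("negative branch estimates are clamped to zero", {
  # violating the triangle quality forces a negative NJ estimate
  d <- matrix(c(0, 10, 1, 1,
                10, 0, 1, 1,
                1, 1, 0, 1,
                1, 1, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  t <- neighbor_joining(d)
  expect_true(all(t$edge.length >= 0))
  expect_gt(attr(t, "clamped_length"), 0)
})

test_that("bootstrap supports are deterministic fractions in [0, 1]", {
  sq <- simulate_sequences(simulate_hierarchy(small_sim_config(seed = 5)))
  t1 <- bootstrap_support(sq$alignment, "jc69", n_reps = 25, seed = 9)
  t2 <- bootstrap_support(sq$alignment, "jc69", n_reps = 25, seed = 9)
  expect_identical(to_newick(t1), to_newick(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 1))
  one <- bootstrap_support(sq$alignment, "jc69", n_reps = 1, seed = 3)
  s1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 1)))
})

test_that("an invariant split duplicated across blocks gets full support", {
  base <- c(a = paste(rep("A", 40), collapse = ""),
            b = paste(rep("A", 40), collapse = ""),
            c = paste(rep("C", 40), collapse = ""),
            d = paste(rep("C", 40), collapse = ""))
  # differentiate within pairs a bit so the tree is generic
  base["b"] <- sub("^A", "G", base["b"])
  base["d"] <- sub("^C", "G", base["d"])
  aln <- as_alignment(base)
  aln <- cbind(aln, aln)  # duplicate the signal
  t <- bootstrap_support(aln, "p", n_reps = 50, seed = 1)
  sup <- suppressWarnings(as.numeric(t$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup == 1))
})

test_that("topology recovery is insensitive to the distance model", {
  sq <- simulate_sequences(simulate_hierarchy(
    small_sim_config(seed = 11, seq_length = 2000)))
  trees <- lapply(c("p", "jc69", "k2p"), function(m) {
    neighbor_joining(pairwise_distance(sq$alignment, m))
  })
  expect_equal(robinson_foulds(trees[[1]], trees[[2]]), 0)
  expect_equal(robinson_foulds(trees[[2]], trees[[3]]), 0)
  expect_equal(robinson_foulds(trees[[2]], sq$tree), 0)
})
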