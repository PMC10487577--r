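make_spec_pair <- function(x, y, start = 2000) {
  g <- grid_spec(start, start + length(x) - 1, 1)
  list(a = new_test_grid_spectrum(x, g, strain = "a"),
       b = new_test_grid_spectrum(y, g, strain = "b"),
       g = g)
}

test_that("pearson matches hand-computed values and flags zero variance", {
  x <- c(0, 0, 1, 0, 1)
  y <- c(1, 0, 1, 0, 1)
  expect_equal(pearson(x, y), 0.8 / 1.2, tolerance = 1e-12)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_true(is.na(pearson(rep(2, 5), y)))
})

test_that("cci reproduces the two-interval worked example", {
  p <- make_spec_pair(c(1, 2, 3, 4, 5, 0, 0, 1, 0, 1),
                      c(2, 4, 6, 8, 10, 1, 0, 1, 0, 1))
  v <- cci(p$a, p$b, cci_params(n_intervals = 2))
  expect_equal(v, (1 + 2 / 3) / 2, tolerance = 1e-4)
  expect_equal(v, 0.8333, tolerance = 1e-4)
})

test_that("cci is 1 on identical non-constant spectra and reduces to Pearson", {
  set.seed(3)
  x <- rlnorm(100)
  p <- make_spec_pair(x, x)
  expect_equal(cci(p$a, p$b, cci_params(10)), 1, tolerance = 1e-12)
  y <- rlnorm(100)
  p2 <- make_spec_pair(x, y)
  expect_equal(cci(p2$a, p2$b, cci_params(n_intervals = 1)),
               max(0, stats::cor(x, y)), tolerance = 1e-12)
  # uninformative blocks excluded; all-uninformative errors
  p3 <- make_spec_pair(rep(0, 10), rep(0, 10))
  expect_error(cci(p3$a, p3$b, cci_params(2)), "no informative interval")
})

test_that("cci_matrix is symmetric with unit diagonal and matches cci()", {
  set.seed(21)
  h <- simulate_hierarchy(small_sim_config(seed = 21))
  set <- preprocess_set(simulate_spectra(h))
  m <- cci_matrix(set, cci_params(10))
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, ncol(m)))
  expect_true(all(m >= 0 & m <= 1))
  # spot-check against the pairwise implementation
  v <- cci(set$spectra[[1]], set$spectra[[5]], cci_params(10))
  expect_equal(unname(m[1, 5]), v, tolerance = 1e-12)
  # invariance to relabeling: permuting spectra permutes the matrix
  perm <- sample(length(set$spectra))
  set_p <- spectrum_set(set$spectra[perm], set$manifest[perm, ], set$grid)
  m_p <- cci_matrix(set_p, cci_params(10))
  expect_equal(unname(m_p), unname(m[perm, perm]), tolerance = 1e-12)
})

test_that("synthetic preset orders CCI tiers strain > species-in-genus > genus", {
  h <- simulate_hierarchy(sim_config(species_per_genus = 3,
                                     strains_per_species = 2,
                                     replicates = 2, seed = 31))
  set <- preprocess_set(simulate_spectra(h))
  lv <- cci_level_means(cci_matrix(set), set$manifest)
  expect_gt(lv["intra_strain"], lv["intra_genus_inter_species"])
  expect_gt(lv["intra_genus_inter_species"], lv["inter_genus"])
})

test_that("bray_curtis matches the closed form and vegan bounds", {
  g <- grid_spec(2000, 2001, 1)
  set <- spectrum_set(
    list(new_test_grid_spectrum(c(2, 1), g, strain = "a"),
         new_test_grid_spectrum(c(1, 1), g, strain = "b"),
         new_test_grid_spectrum(c(1, 0), g, strain = "c"),
         new_test_grid_spectrum(c(0, 1), g, strain = "d")),
    data.frame(strain_id = c("a", "b", "c", "d"), species = "s",
               genus = "g", replicate_id = paste0("r", 1:4)), g)
  d <- bray_curtis_matrix(set)
  expect_equal(unname(d["a.r1", "b.r2"]), 1 / 5, tolerance = 1e-12)
  expect_equal(unname(d["c.r3", "d.r4"]), 1)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_identical(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  # all-zero spectrum rejected by name
  set$spectra[[2]]$intensity <- c(0, 0)
  expect_error(bray_curtis_matrix(set), "b.r2")
})

test_that("cci_summary counts both orientations of each pair", {
  set.seed(8)
  n <- 10
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  s <- cci_summary(m, thresholds = c(0.1, 0.5))
  expect_equal(sum(s$count), n * (n - 1))  # 90 cells for 10 strains
  expect_equal(sum(s$fraction), 1, tolerance = 1e-12)

  m2 <- matrix(0.05, 4, 4)
  diag(m2) <- 1
  s2 <- cci_summary(m2, c(0.1, 0.5))
  expect_equal(s2$fraction[s2$bin == "<0.1"], 1)
})

test_that("strain aggregation averages cross-replicate blocks", {
  m <- matrix(c(1, .9, .2, .4,
                .9, 1, .3, .1,
                .2, .3, 1, .8,
                .4, .1, .8, 1), 4, 4)
  dimnames(m) <- list(paste0("x", 1:4), paste0("x", 1:4))
  agg <- aggregate_to_strains(m, c("A", "A", "B", "B"))
  expect_equal(unname(agg["A", "B"]), mean(c(.2, .4, .3, .1)))
  expect_equal(unname(diag(agg)), c(1, 1))
})
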