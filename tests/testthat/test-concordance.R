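mani <- function(strains, species) {
  data.frame(strain_id = strains, species = species,
             genus = "g", stringsAsFactors = FALSE)
}

test_that("co-group sets identify monophyletic, mixed and singleton species", {
  # s1 strains a1,a2 monophyletic; s2 strain b1 singleton
  t <- from_newick("((a1:1,a2:1):1,b1:2);")
  m <- mani(c("a1", "a2", "b1"), c("s1", "s1", "s2"))
  cg <- species_cogroup_sets(t, m)
  expect_equal(cg$s1, "s1")
  expect_equal(cg$s2, "s2")

  # interleaved: a1,b1 | a2,b2 inside one clade -> each lists the other
  t2 <- from_newick("(((a1:1,b1:1):1,(a2:1,b2:1):1):1,c1:3);")
  m2 <- mani(c("a1", "a2", "b1", "b2", "c1"),
             c("sA", "sA", "sB", "sB", "sC"))
  cg2 <- species_cogroup_sets(t2, m2)
  expect_equal(cg2$sA, c("sA", "sB"))
  expect_equal(cg2$sB, c("sA", "sB"))
  expect_equal(cg2$sC, "sC")

  expect_error(species_cogroup_sets(t, mani(c("a1", "zz", "b1"),
                                            c("s1", "s1", "s2"))),
               "mismatch")
})

test_that("identical trees give similarity 1; the 20-of-22 case gives 0.909", {
  t <- from_newick("((a1:1,a2:1):1,(b1:1,c1:1):1);")
  m <- mani(c("a1", "a2", "b1", "c1"), c("s1", "s1", "s2", "s3"))
  r <- grouping_similarity(t, t, m)
  expect_equal(r$grouping_similarity, 1.0)
  expect_true(all(r$per_species$consistent))

  # 22 species: two 2-strain species whose strains interleave in tree A but
  # separate in tree B, plus 20 singleton species placed identically ->
  # exactly 20 of 22 species keep their co-group sets
  chain <- function(core) {
    nw <- core
    for (i in 3:22) nw <- sprintf("(%s:1,y%02d:1)", nw, i)
    from_newick(paste0(nw, ";"))
  }
  t_mixed <- chain("((a1:1,b1:1):1,(a2:1,b2:1):1)")
  t_sep <- chain("((a1:1,a2:1):1,(b1:1,b2:1):1)")
  m22 <- mani(c("a1", "a2", "b1", "b2", sprintf("y%02d", 3:22)),
              c("s01", "s01", "s02", "s02", sprintf("s%02d", 3:22)))
  r_swap <- grouping_similarity(t_mixed, t_sep, m22)
  expect_equal(r_swap$n_species, 22)
  expect_equal(r_swap$n_consistent, 20)
  expect_false(any(r_swap$per_species$consistent[
    r_swap$per_species$species %in% c("s01", "s02")]))
  expect_equal(round(100 * r_swap$grouping_similarity, 1), 90.9)
})

test_that("grouping similarity is symmetric and 0 when everything mixes", {
  t1 <- from_newick("((a1:1,b1:1):1,(a2:1,b2:1):1);")
  t2 <- from_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
  m <- mani(c("a1", "a2", "b1", "b2"), c("sA", "sA", "sB", "sB"))
  r12 <- grouping_similarity(t1, t2, m)
  r21 <- grouping_similarity(t2, t1, m)
  expect_equal(r12$grouping_similarity, r21$grouping_similarity)
  expect_equal(r12$grouping_similarity, 0)
})

test_that("sankey table is the contingency table with intact marginals", {
  g1 <- c(a = "A", b = "A", c = "B", d = "B", e = "B")
  g2 <- c(a = "X", b = "Y", c = "Y", d = "Y", e = "Z")
  s <- sankey_table(g1, g2)
  expect_equal(sum(s$count), 5)
  expect_equal(s$count[s$source == "A" & s$target == "Y"], 1)
  # marginals reconstruct group sizes
  expect_equal(tapply(s$count, s$source, sum)[["B"]], 3)
  expect_equal(tapply(s$count, s$target, sum)[["Y"]], 3)

  # identical partitions -> diagonal table
  s2 <- sankey_table(g1, g1)
  expect_equal(nrow(s2), 2)
  # one group vs singletons -> n rows of count 1
  s3 <- sankey_table(setNames(rep("all", 5), names(g1)),
                     setNames(names(g1), names(g1)))
  expect_equal(nrow(s3), 5)
  expect_true(all(s3$count == 1))

  set.seed(4)
  for (i in 1:10) {
    ga <- setNames(sample(letters[1:3], 12, TRUE), paste0("s", 1:12))
    gb <- setNames(sample(letters[1:4], 12, TRUE), paste0("s", 1:12))
    st <- sankey_table(ga, gb)
    expect_equal(sum(st$count), 12)
    expect_equal(as.vector(tapply(st$count, st$source, sum)[names(table(ga))]),
                 as.vector(table(ga)))
  }
})

test_that("robinson_foulds counts bipartition differences with its bounds", {
  t1 <- from_newick("((a:1,b:1):1,(c:1,d:1):1);")
  t2 <- from_newick("((a:1,c:1):1,(b:1,d:1):1);")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)  # distinct quartets
  set.seed(6)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    x <- ape::rtree(n)
    y <- ape::rtree(n)
    y$tip.label <- x$tip.label
    expect_lte(robinson_foulds(x, y), 2 * (n - 3))
  }
  t3 <- from_newick("((a:1,b:1):1,(c:1,e:1):1);")
  expect_error(robinson_foulds(t1, t3), "differ")
})

test_that("cut-based similarity agrees with clean partitions", {
  g_a <- c(a1 = "p", a2 = "p", b1 = "q", b2 = "q")
  g_b <- c(a1 = "u", a2 = "u", b1 = "v", b2 = "v")
  m <- mani(names(g_a), c("sA", "sA", "sB", "sB"))
  r <- grouping_similarity_cut(g_a, g_b, m)
  expect_equal(r$grouping_similarity, 1)
  g_c <- c(a1 = "u", a2 = "v", b1 = "u", b2 = "v")
  r2 <- grouping_similarity_cut(g_a, g_c, m)
  expect_lt(r2$grouping_similarity, 1)
})
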