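asym4 <- "(((A:1,B:1):0.5,C:1.5):0.5,D:2);"

test_that("Newick parsing validates the species-tree contract", {
  tr <- read_species_tree(asym4)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_equal(sort(internal_branches(tr)$length), c(0.5, 0.5))
  # round-trip preserves the topology and lengths
  tr2 <- read_species_tree(ape::write.tree(tr))
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE))
  expect_error(read_species_tree("((A,B),(C,D),(E,F));"), "binary")
  expect_error(read_species_tree("((A:1,A:1):1,(C:1,D:1):1);"), "duplicate")
  expect_error(read_species_tree("((A:1,B:1),(C:1,D:1):1);"),
               "internal branch length")
  expect_error(read_species_tree("((A:1,B:1):1,C:1);"), "k >= 4")
  expect_warning(read_species_tree("((A:1,B:1):0,(C:1,D:1):1);"),
                 "zero-length")
})

test_that("bipartition counts are 2k-3 total and k-3 nontrivial", {
  for (k in c(4, 5, 6, 8, 10, 17, 30)) {
    for (kind in c("caterpillar", "balanced")) {
      tr <- make_fixture(kind, k = k, t_internal = 0.3)
      expect_length(bipartitions(tr, nontrivial_only = FALSE), 2 * k - 3)
      expect_length(bipartitions(tr, nontrivial_only = TRUE), k - 3)
      expect_equal(nrow(internal_branches(tr)), k - 2)
    }
  }
})

test_that("known small trees yield the expected split sets", {
  sym <- read_species_tree("((A:1,B:1):0.5,(C:1,D:1):0.5);")
  expect_equal(bipartitions(sym), "A,B|C,D", ignore_attr = TRUE)
  cat5 <- read_species_tree("((((A:1,B:1):.2,C:1):.2,D:1):.2,E:1);")
  expect_setequal(as.character(bipartitions(cat5)),
                  c("A,B|C,D,E", "A,B,C|D,E"))
})

test_that("bipartitions are invariant to block order and rerooting", {
  tr <- make_fixture("balanced", k = 8, t_internal = 0.4)
  for (tip in c("t1", "t5", "t8")) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_setequal(as.character(bipartitions(rr)),
                    as.character(bipartitions(tr)))
  }
})

test_that("internal branches identify the trivial root branch e_c", {
  # asymmetric 4-taxon: root has leaf child D; branch into (A,B,C) is e_c
  ib <- internal_branches(read_species_tree(asym4))
  expect_equal(sum(ib$is_root_trivial), 1)
  ec <- ib[ib$is_root_trivial, ]
  expect_equal(ec$n_desc, 3)
  expect_false(ec$nontrivial)
  # symmetric 4-taxon: no e_c, both root branches share the split AB|CD
  ib2 <- internal_branches(read_species_tree("((A:1,B:1):0.5,(C:1,D:1):0.7);"))
  expect_equal(sum(ib2$is_root_trivial), 0)
  expect_equal(ib2$split, rep("A,B|C,D", 2))
  # 6-taxon balanced: k_i multiset {2,2,3,3}, no e_c
  ib3 <- internal_branches(make_fixture("balanced", k = 6, t_internal = 0.2))
  expect_equal(sort(ib3$n_desc), c(2, 2, 3, 3))
  expect_equal(sum(ib3$is_root_trivial), 0)
})

test_that("t_min is the minimum over all k-2 internal branches", {
  tr <- read_species_tree(
    "(((A:1,B:1):0.5,C:1):0.2,((D:1,E:1):0.9,F:1):0.4);")
  expect_equal(sort(internal_branches(tr)$length), c(0.2, 0.4, 0.5, 0.9))
  expect_equal(t_min(tr), 0.2)
  expect_equal(t_min(make_fixture("caterpillar", 6, t_internal = 0.2)), 0.2)
})

test_that("bipartition cover detection matches the definition", {
  sp <- read_species_tree("((A:1,B:1):0.5,(C:1,D:1):0.5);")
  expect_true(is_bipartition_cover(sp, sp))     # the tree covers itself
  wrong <- ape::read.tree(text = "(((A,D),B),C);")  # carries A,D|B,C only
  expect_false(is_bipartition_cover(wrong, sp))
  expect_false(is_bipartition_cover(structure(list(), class = "multiPhylo"), sp))
  expect_error(is_bipartition_cover(ape::read.tree(text = "(((A,B),C),E);"), sp),
               "taxon set")
  # monotone: adding gene trees never destroys a cover
  sp8 <- make_fixture("caterpillar", k = 8, t_internal = 0.5)
  gts <- sim_gene_trees(sp8, 40, seed = 11)
  was_cover <- FALSE
  for (m in seq_along(gts)) {
    now <- is_bipartition_cover(gts[seq_len(m)], sp8)
    expect_false(was_cover && !now)
    was_cover <- now
  }
})

test_that("fixtures honor their generator contracts", {
  cat6 <- make_fixture("caterpillar", k = 6, t_internal = 0.2)
  expect_equal(internal_branches(cat6)$length, rep(0.2, 4))
  expect_true(ape::is.rooted(cat6) && ape::is.binary(cat6))
  # determinism of the random fixture
  y1 <- make_fixture("yule", k = 9, lambda = 0.3, seed = 5)
  y2 <- make_fixture("yule", k = 9, lambda = 0.3, seed = 5)
  expect_identical(ape::write.tree(y1), ape::write.tree(y2))
  expect_error(make_fixture("caterpillar", k = 3, t_internal = 1))
  expect_error(make_fixture("yule", k = 6, lambda = -1))
})

test_that("yule fixtures draw internal branches as Exp(2*lambda)", {
  k <- 6; lam <- 0.4; draws <- 2000
  set.seed(83)
  tmins <- replicate(draws, t_min(make_fixture("yule", k = k, lambda = lam)))
  # T_min ~ Exp(2(k-2)lambda): mean 1/(2(k-2)lambda), sd equal to mean
  mu <- 1 / (2 * (k - 2) * lam)
  expect_lt(abs(mean(tmins) - mu), 3 * mu / sqrt(draws))
  ks <- suppressWarnings(
    stats::ks.test(tmins, "pexp", rate = 2 * (k - 2) * lam))
  expect_gt(ks$p.value, 1e-4)
})
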