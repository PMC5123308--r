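asym_nwk <- "(((A:1,B:1):0.5,C:1):0.5,D:1);"

test_that("simulated gene trees are valid rooted binary trees on the taxa", {
  sp <- make_fixture("caterpillar", k = 7, t_internal = 0.3)
  gts <- sim_gene_trees(sp, 25, seed = 2)
  expect_length(gts, 25)
  for (gt in gts) {
    expect_true(ape::is.rooted(gt) && ape::is.binary(gt))
    expect_setequal(gt$tip.label, sp$tip.label)
    expect_true(all(gt$edge.length >= 0))
  }
  # same seed, same trees; different seed, different stream
  again <- sim_gene_trees(sp, 25, seed = 2)
  expect_identical(lapply(gts, ape::write.tree), lapply(again, ape::write.tree))
  other <- sim_gene_trees(sp, 25, seed = 3)
  expect_false(identical(lapply(gts, ape::write.tree),
                         lapply(other, ape::write.tree)))
})

test_that("single-branch lineage counts follow g_{i,j}(T)", {
  reps <- 1e5
  set.seed(71)
  for (cfg in list(c(2, 0.5), c(4, 0.3), c(6, 0.5), c(8, 0.2))) {
    i <- cfg[1]; T <- cfg[2]
    cnt <- splitcover:::sim_branch_exit_counts_cpp(as.integer(i), T,
                                                   as.integer(reps))
    emp <- tabulate(cnt, i) / reps
    theo <- g_ij(i, 1:i, T)
    se <- sqrt(pmax(theo * (1 - theo), 1e-12) / reps)
    expect_true(all(abs(emp - theo) <= 3 * se + 3 / reps))
  }
})

test_that("4-taxon split and topology frequencies match the exact theory", {
  sp <- read_species_tree(asym_nwk)
  reps <- 1e5
  # split frequency at n_s = 1 is P_1^a = 1 - (2/3) exp(-T1)
  est <- estimate_cover_probability(sp, n_s = 1, reps = reps, seed = 5)
  p1 <- p1_asymmetric(0.5)
  expect_lt(abs(est$q_hat - p1), 3 * sqrt(p1 * (1 - p1) / reps))
  # per-topology frequencies of the five AB|CD topologies match the
  # five per-topology probabilities
  enc <- splitcover:::.sim_encoding(sp)
  set.seed(6)
  masks <- splitcover:::sim_clade_masks_cpp(enc$child1, enc$child2, enc$blen,
                                            enc$postorder, enc$ntip,
                                            as.integer(reps))
  sig <- apply(masks, 1, mask_signature)
  theo <- four_taxon_topology_probs("asymmetric", 0.5, 0.5)
  for (topo in names(theo)) {
    freq <- mean(sig == topo_signature(topo, sp$tip.label))
    se <- sqrt(theo[[topo]] * (1 - theo[[topo]]) / reps)
    expect_lt(abs(freq - theo[[topo]]), 3 * se)
  }
})

test_that("empirical cover probability matches the exact 4-taxon P_n", {
  sp <- read_species_tree(asym_nwk)
  est <- estimate_cover_probability(sp, n_s = 10, reps = 1e4, seed = 8)
  pn <- pn_four_taxon("asymmetric", t1 = 0.5, n = 10)
  expect_lt(abs(est$q_hat - pn), 3 * sqrt(pn * (1 - pn) / 1e4))
  # near-zero internal branch: single-tree cover probability approaches 1/3
  tiny <- read_species_tree("(((A:1,B:1):0.000001,C:1):0.5,D:1);")
  est0 <- estimate_cover_probability(tiny, n_s = 1, reps = 1e4, seed = 9)
  expect_lt(abs(est0$q_hat - 1/3), 3 * sqrt((1/3) * (2/3) / 1e4))
  # reproducibility of the estimate
  expect_identical(est$q_hat,
                   estimate_cover_probability(sp, 10, 1e4, seed = 8)$q_hat)
})

test_that("C++ cover counting agrees with the R-level cover definition", {
  sp <- make_fixture("balanced", k = 6, t_internal = 0.4)
  reps <- 300; ns <- 4
  est <- estimate_cover_probability(sp, n_s = ns, reps = reps, seed = 13)
  set.seed(131)
  slow <- mean(replicate(reps,
    is_bipartition_cover(sim_gene_trees(sp, ns), sp)))
  expect_lt(abs(est$q_hat - slow),
            3 * sqrt(0.25 / reps) * 2)  # two independent MC estimates
})

test_that("the cover bound is valid against simulation across the grid", {
  for (k in c(5, 6, 8)) {
    for (tm in c(0.2, 0.5, 1.0)) {
      ae <- suppressWarnings(  # q_hat = 0 rows warn (bound formula <= 0)
        accuracy_experiment(k, tm, reps = 1000, seed = 1000 * k + 10 * tm))
      bound <- as.numeric(cover_prob_bound(k, tm, ae$n_s))
      expect_true(all(bound <= ae$q_hat + 3 * pmax(ae$se, 1e-4)))
      # the bound never undershoots the true requirement
      ratios <- ae$ratio[!is.na(ae$ratio) & ae$q_hat > 0 & ae$q_hat < 1]
      expect_true(all(ratios >= 1))
    }
  }
})

test_that("accuracy ratios are near 1 at k = 4, grow with k, shrink with T", {
  ns <- c(1, 2, 3, 5, 10, 20, 50, 100, 200, 500)
  ae4 <- accuracy_experiment(4, 0.5, n_s = ns, reps = 2000, seed = 21)
  ok4 <- !is.na(ae4$ratio) & ae4$q_hat > 0
  expect_true(all(ae4$ratio[ok4] < 4))      # modest overestimation at k = 4
  med_ratio <- function(k, tm) {
    ae <- suppressWarnings(
      accuracy_experiment(k, tm, n_s = ns, reps = 1000,
                          seed = 7000 + k + round(100 * tm)))
    stats::median(ae$ratio[!is.na(ae$ratio) & ae$q_hat > 0], na.rm = TRUE)
  }
  r4 <- med_ratio(4, 0.2); r6 <- med_ratio(6, 0.2); r8 <- med_ratio(8, 0.2)
  expect_true(r4 < r6 && r6 < r8)           # looser as k grows
  s2 <- med_ratio(6, 0.2); s5 <- med_ratio(6, 0.5); s10 <- med_ratio(6, 1.0)
  expect_true(s2 > s5 && s5 > s10)          # tighter as branches lengthen
})

test_that("degenerate accuracy inputs are handled explicitly", {
  # q_hat = 1 rows are flagged NA rather than plotted as infinite ratios
  ae <- accuracy_experiment(4, 1.0, n_s = c(200, 500), reps = 200, seed = 3)
  expect_true(all(is.na(ae$ratio[ae$q_hat == 1])))
  expect_error(accuracy_experiment(5, 0), "t_min > 0")
})
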