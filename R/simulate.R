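# species-tree encoding handed to the C++ core: children, branch length
# above each node, node heights (time before the most recent tip), and
# a postorder sequence of internal nodes
.sim_encoding <- function(tree) {
  .validate_species_tree(tree)
  k <- length(tree$tip.label)
  nnode <- k + tree$Nnode
  child1 <- child2 <- integer(nnode)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; c <- tree$edge[r, 2]
    if (child1[p] == 0L) child1[p] <- c else child2[p] <- c
  }
  blen <- numeric(nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  depth <- numeric(nnode)  # distance from root, filled preorder
  pre <- (k + 1L)          # root first
  # node heights: root deepest; traverse edges in cladewise order
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (r in seq_len(nrow(tree$edge)))
    depth[tree$edge[r, 2]] <- depth[tree$edge[r, 1]] + tree$edge.length[r]
  height <- max(depth) - depth
  post <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1]))
  list(child1 = child1, child2 = child2, blen = blen, height = height,
       postorder = as.integer(post), ntip = k)
}

# canonical split masks (bit i-1 = tip i; taxon 1 bit cleared) of the
# nontrivial species-tree splits
.need_masks <- function(tree) {
  k <- length(tree$tip.label)
  clades <- .clades_by_node(tree)
  sizes <- lengths(clades)
  child <- tree$edge[, 2]
  keep <- child[sizes[child] >= 2 & sizes[child] <= k - 2]
  masks <- vapply(clades[keep], function(ix) sum(2^(ix - 1)), 0)
  full <- 2^k - 1
  masks <- ifelse(masks %% 2 == 1, full - masks, masks)
  as.integer(unique(masks))
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- .save_rng_state()
    set.seed(seed)
    on.exit(.restore_rng_state(old))
  }
  expr
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Simulates rooted gene trees on a fixed rooted binary species tree
#' with one lineage sampled per species.  Within every species-tree
#' branch carrying `m` lineages, coalescences occur at exponential
#' waiting times with rate `m(m-1)/2`, merging a uniformly chosen pair,
#' truncated at the top of the branch; surviving lineages pass into the
#' parent branch, and above the root coalescence continues until a
#' single lineage remains.  Gene-tree branch lengths are in the same
#' coalescent units as the species tree.
#'
#' @param species_tree A rooted binary species tree (`phylo`) with
#'   branch lengths in coalescent units, `k >= 4` taxa.
#' @param n Number of gene trees to simulate.
#' @param seed Optional integer seed (otherwise the current R RNG
#'   stream is used and advanced).
#' @return A `multiPhylo` of `n` rooted binary gene trees on the
#'   species-tree taxa.
#' @examples
#' sp <- make_fixture("caterpillar", k = 5, t_internal = 0.5)
#' gts <- sim_gene_trees(sp, n = 3, seed = 1)
#' @export
sim_gene_trees <- function(species_tree, n, seed = NULL) {
  stopifnot(n >= 1, n == round(n))
  enc <- .sim_encoding(species_tree)
  raw <- .with_seed(seed,
    sim_gene_trees_cpp(enc$child1, enc$child2, enc$blen, enc$height,
                       enc$postorder, enc$ntip, as.integer(n)))
  trs <- lapply(raw, function(x) {
    tr <- list(edge = x$edge, edge.length = x$edge.length,
               tip.label = species_tree$tip.label, Nnode = enc$ntip - 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- NULL
    tr
  })
  class(trs) <- "multiPhylo"
  trs
}

#' Empirical bipartition-cover probability
#'
#' Estimates \eqn{\hat Q_{n_s}}, the probability that a set of `n_s`
#' coalescent gene trees contains every nontrivial split of the species
#' tree, by simulating `reps` independent gene-tree sets and recording
#' the fraction that form a bipartition cover.
#'
#' @inheritParams sim_gene_trees
#' @param n_s Number of gene trees per set, `>= 1`.
#' @param reps Number of replicate gene-tree sets (default 1000; the
#'   binomial standard error at 1000 is at most ~0.016).
#' @param seed Optional integer seed; same seed and configuration give
#'   the same estimate.
#' @return A list of class `"cover_estimate"` with elements `q_hat`,
#'   `se` (binomial standard error), `covered`, `reps`, `n_s`.
#' @examples
#' sp <- make_fixture("caterpillar", k = 5, t_internal = 0.5)
#' estimate_cover_probability(sp, n_s = 10, reps = 200, seed = 1)
#' @export
estimate_cover_probability <- function(species_tree, n_s, reps = 1000,
                                       seed = NULL) {
  stopifnot(n_s >= 1, n_s == round(n_s), reps >= 1, reps == round(reps))
  enc <- .sim_encoding(species_tree)
  need <- .need_masks(species_tree)
  covered <- .with_seed(seed,
    count_covers_cpp(enc$child1, enc$child2, enc$blen, enc$postorder,
                     enc$ntip, need, as.integer(n_s), as.integer(reps)))
  q_hat <- covered / reps
  structure(list(q_hat = q_hat, se = sqrt(q_hat * (1 - q_hat) / reps),
                 covered = covered, reps = reps, n_s = n_s),
            class = "cover_estimate")
}

#' @export
print.cover_estimate <- function(x, ...) {
  cat(sprintf("Empirical cover probability: q_hat = %.4f (SE %.4f)\n",
              x$q_hat, x$se))
  cat(sprintf("  %d / %d replicate sets of %d gene trees were covers\n",
              x$covered, x$reps, x$n_s))
  invisible(x)
}

#' Accuracy experiment: simulated loci versus the analytical bound
#'
#' Quantifies how conservative the locus upper bound is.  For a
#' caterpillar species tree with all internal branches equal to
#' `t_min`, each gene-tree-set size `n_s` yields an empirical cover
#' probability \eqn{\hat Q_{n_s}}; feeding that probability back into
#' the bound as the target `q` gives `n_b`, the number of loci the
#' bound prescribes for what `n_s` loci actually achieved.  The ratio
#' `n_b / n_s` is the overestimation factor (1 = tight).  Sets in which
#' every replicate was a cover (`q_hat = 1`) make the bound infinite
#' and get `NA` ratios; `q_hat = 0` yields a ratio of 0 with a warning.
#'
#' @param k Number of taxa of the caterpillar species tree.
#' @param t_min Internal branch length (all internal branches), `> 0`.
#' @param n_s Integer vector of gene-tree-set sizes.
#' @param reps Replicate sets per `n_s`.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `n_s`, `q_hat`, `se`, `n_b`
#'   (real-valued bound at `q = q_hat`), `ratio`.
#' @examples
#' accuracy_experiment(k = 4, t_min = 0.5, n_s = c(1, 5, 20),
#'                     reps = 200, seed = 1)
#' @export
accuracy_experiment <- function(k, t_min,
                                n_s = c(1, 2, 3, 5, 10, 20, 50, 100, 200, 500),
                                reps = 1000, seed = NULL) {
  stopifnot(t_min > 0)
  sp <- make_fixture("caterpillar", k = k, t_internal = t_min)
  .with_seed(seed, {
    rows <- lapply(n_s, function(ns) {
      est <- estimate_cover_probability(sp, n_s = ns, reps = reps)
      n_b <- if (est$q_hat >= 1) NA_real_
      else if (est$q_hat <= 0) {
        warning("q_hat = 0 at n_s = ", ns, "; bound formula gives n_b <= 0")
        0
      } else as.numeric(loci_upper_bound(k, t_min, est$q_hat, raw = TRUE))
      data.frame(n_s = ns, q_hat = est$q_hat, se = est$se,
                 n_b = n_b, ratio = n_b / ns)
    })
    do.call(rbind, rows)
  })
}
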