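#' All rooted gene-tree topologies on four taxa
#'
#' Enumerates the 15 rooted binary labeled topologies on a set of four
#' taxa (the possible gene-tree topologies for one lineage sampled per
#' species).
#'
#' @param taxa Character vector of exactly 4 distinct labels.
#' @return A `multiPhylo` of length 15, each topology exactly once.
#' @examples
#' length(enumerate_rooted_topologies(c("A", "B", "C", "D")))  # 15
#' @export
enumerate_rooted_topologies <- function(taxa = c("A", "B", "C", "D")) {
  if (length(taxa) != 4L || anyDuplicated(taxa))
    stop("exactly 4 distinct labels required")
  trs <- phangorn::allTrees(4, rooted = TRUE, tip.label = taxa)
  stopifnot(length(trs) == 15L)
  trs
}

#' Canonical form of a rooted labeled topology
#'
#' Newick string with children ordered by their smallest descendant
#' label, so two `phylo` objects describe the same rooted topology iff
#' their canonical forms are equal.  Branch lengths are ignored.
#'
#' @param tree A rooted binary `phylo`.
#' @return A character scalar, e.g. `"((A,B),(C,D));"`.
#' @export
canonical_topology <- function(tree) {
  .check_rooted_binary(tree)
  k <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= k) return(list(lab = tree$tip.label[node],
                               min = tree$tip.label[node]))
    ch <- lapply(kids[[as.character(node)]], rec)
    ch <- ch[order(vapply(ch, `[[`, "", "min"))]
    list(lab = paste0("(", paste(vapply(ch, `[[`, "", "lab"), collapse = ","), ")"),
         min = ch[[1]]$min)
  }
  paste0(rec(k + 1L)$lab, ";")
}

# g shorthands used by the printed five-term sums
.g21 <- function(t) g_ij(2, 1, t)
.g22 <- function(t) g_ij(2, 2, t)

#' Per-topology probabilities of the five gene trees carrying AB|CD
#'
#' For a four-taxon species tree whose nontrivial split is AB|CD, the
#' split occurs in exactly five of the 15 rooted gene-tree topologies:
#' `((A,B),(C,D))`, `(((A,B),C),D)`, `(((A,B),D),C)`, `(((C,D),A),B)`
#' and `(((C,D),B),A)`.  This returns the multispecies-coalescent
#' probability of each, as a sum of products of lineage-counting
#' probabilities `g_ij` evaluated on the two internal branches --
#' term-by-term, not pre-simplified, so their total provides an
#' independent numerical check of the closed forms in
#' [p1_symmetric()] / [p1_asymmetric()].
#'
#' For the symmetric shape `((A,B):T1,(C,D):T2)`, `t1` and `t2` are the
#' lengths of the branches above the two cherries.  For the asymmetric
#' shape `(((A,B):T1,C):T2,D)`, `t1` is the branch above the (A,B)
#' cherry and `t2` the branch above the (A,B,C) ancestor.
#'
#' @param shape `"symmetric"` or `"asymmetric"` (Fig.-style 4-taxon
#'   shapes).
#' @param t1,t2 Internal branch lengths in coalescent units, `>= 0`.
#' @return Named numeric vector of 5 probabilities; names are canonical
#'   rooted topologies.
#' @export
four_taxon_topology_probs <- function(shape = c("symmetric", "asymmetric"),
                                      t1, t2) {
  shape <- match.arg(shape)
  stopifnot(t1 >= 0, t2 >= 0)
  a1 <- .g21(t1); a2 <- .g22(t1)
  b1 <- .g21(t2); b2 <- .g22(t2)
  if (shape == "symmetric") {
    p <- c(a1 * b1 + (1/3) * a1 * b2 + (1/3) * a2 * b1 + (1/9) * a2 * b2,
           (1/3) * a1 * b2 + (1/18) * a2 * b2,
           (1/3) * a1 * b2 + (1/18) * a2 * b2,
           (1/3) * a2 * b1 + (1/18) * a2 * b2,
           (1/3) * a2 * b1 + (1/18) * a2 * b2)
  } else {
    c1 <- g_ij(3, 1, t2); c2 <- g_ij(3, 2, t2); c3 <- g_ij(3, 3, t2)
    p <- c((1/3) * a1 * b2 + (1/9) * a2 * c2 + (1/9) * a2 * c3,
           a1 * b1 + (1/3) * a1 * b2 + (1/3) * a2 * c1 +
             (1/9) * a2 * c2 + (1/18) * a2 * c3,
           (1/3) * a1 * b2 + (1/9) * a2 * c2 + (1/18) * a2 * c3,
           (1/18) * a2 * c3,
           (1/18) * a2 * c3)
  }
  names(p) <- c("((A,B),(C,D));", "(((A,B),C),D);", "(((A,B),D),C);",
                "(((C,D),A),B);", "(((C,D),B),A);")
  p
}

#' Probability one gene tree carries the split of a symmetric 4-taxon tree
#'
#' For the symmetric species tree `((A,B):T1,(C,D):T2)` the probability
#' that a single coalescent gene tree contains the nontrivial split
#' AB|CD is \deqn{P_1^s = 1 - \tfrac{2}{3} e^{-(T_1 + T_2)},} a function
#' of the length `T1 + T2` of the single internal branch of the
#' unrooted species tree.  `form = "bracketed"` instead sums the five
#' per-topology probabilities of [four_taxon_topology_probs()]; the two
#' routes agree to ~1e-15.
#'
#' @inheritParams four_taxon_topology_probs
#' @param form `"closed"` (default) or `"bracketed"`.
#' @return Probability in `[1/3, 1]`.
#' @export
p1_symmetric <- function(t1, t2, form = c("closed", "bracketed")) {
  form <- match.arg(form)
  stopifnot(t1 >= 0, t2 >= 0)
  if (form == "closed") 1 - (2/3) * exp(-(t1 + t2))
  else sum(four_taxon_topology_probs("symmetric", t1, t2))
}

#' Probability one gene tree carries the split of an asymmetric 4-taxon tree
#'
#' For the asymmetric species tree `(((A,B):T1,C):T2,D)` the probability
#' that a single coalescent gene tree contains AB|CD is
#' \deqn{P_1^a = 1 - \tfrac{2}{3} e^{-T_1},} independent of `T2` (again
#' the exponent is the internal branch of the unrooted species tree).
#' As `T1 -> 0` the three lineages below the root are exchangeable and
#' the probability approaches 1/3.
#'
#' @inheritParams p1_symmetric
#' @return Probability in `[1/3, 1]`.
#' @export
p1_asymmetric <- function(t1, t2 = 0, form = c("closed", "bracketed")) {
  form <- match.arg(form)
  stopifnot(t1 >= 0, t2 >= 0)
  if (form == "closed") 1 - (2/3) * exp(-t1)
  else sum(four_taxon_topology_probs("asymmetric", t1, t2))
}

#' Probability an n-locus gene-tree set covers a 4-taxon species tree
#'
#' Gene trees are conditionally independent given the species tree, so
#' the probability that the single nontrivial split appears in at least
#' one of `n` gene trees is \eqn{P_n = 1 - (1 - P_1)^n}, with \eqn{P_1}
#' from [p1_symmetric()] or [p1_asymmetric()] according to `shape`.
#'
#' @inheritParams four_taxon_topology_probs
#' @param n Number of gene trees (vectorized), `n >= 1`.
#' @return Numeric vector of cover probabilities, increasing in `n`.
#' @examples
#' pn_four_taxon("asymmetric", t1 = 0.5, n = c(1, 10, 50))
#' @export
pn_four_taxon <- function(shape = c("symmetric", "asymmetric"), t1, t2 = 0, n) {
  shape <- match.arg(shape)
  if (any(n < 1) || any(n != round(n))) stop("n must be a positive integer")
  p1 <- if (shape == "symmetric") p1_symmetric(t1, t2) else p1_asymmetric(t1, t2)
  1 - (1 - p1)^n
}
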