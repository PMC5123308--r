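#' Read and validate a species tree from Newick
#'
#' Parses a Newick string or file into an [ape::phylo] object and checks
#' the contract assumed throughout the package: rooted, binary, unique
#' leaf labels, `k >= 4` taxa, and a branch length on every internal
#' (non-pendant) edge.  Branch lengths are interpreted in coalescent
#' time units.  Zero-length internal branches are accepted but flagged
#' with a warning, since the locus bound diverges as `t_min -> 0`.
#'
#' @param x A Newick string (containing "(") or a path to a Newick file.
#' @return An object of class `phylo`.
#' @examples
#' sp <- read_species_tree("(((A:1,B:1):0.5,C:1.5):0.5,D:2);")
#' @export
read_species_tree <- function(x) {
  tr <- .read_newick_one(x)
  .validate_species_tree(tr)
  tr
}

#' Read gene trees from Newick
#'
#' Like [read_species_tree()] but for gene trees: branch lengths are
#' optional and any number of trees may be present (one per line /
#' semicolon-separated).  Each tree must be rooted and binary.
#'
#' @inheritParams read_species_tree
#' @return An object of class `multiPhylo` (possibly of length 1).
#' @export
read_gene_trees <- function(x) {
  trs <- if (is.character(x) && length(x) == 1L && grepl("\\(", x)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(x)
  }
  if (inherits(trs, "phylo")) trs <- c(trs)  # promote to multiPhylo
  if (is.null(trs)) stop("no parseable Newick tree found")
  for (tr in trs) .check_rooted_binary(tr)
  trs
}

.read_newick_one <- function(x) {
  tr <- if (inherits(x, "phylo")) x
  else if (is.character(x) && length(x) == 1L && grepl("\\(", x))
    ape::read.tree(text = x)
  else ape::read.tree(x)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single species tree, got ", length(tr))
    tr <- tr[[1L]]
  }
  if (is.null(tr)) stop("malformed Newick string")
  tr
}

.check_rooted_binary <- function(tr) {
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels")
  if (!ape::is.rooted(tr) || !ape::is.binary(tr))
    stop("tree must be rooted and binary (every internal node bifurcating)")
  invisible(tr)
}

.validate_species_tree <- function(tr) {
  .check_rooted_binary(tr)
  k <- length(tr$tip.label)
  if (k < 4) stop("species tree must have k >= 4 taxa, got ", k)
  if (is.null(tr$edge.length)) stop("species tree lacks branch lengths")
  internal <- tr$edge[, 2] > k
  len <- tr$edge.length[internal]
  if (anyNA(len)) stop("species tree lacking an internal branch length")
  if (any(len < 0)) stop("negative branch length on an internal edge")
  if (any(len == 0))
    warning("zero-length internal branch: locus bounds on this tree are infinite")
  invisible(tr)
}

# tip-index clade (as sorted integer vector) below each node, 1..(ntip+Nnode)
.clades_by_node <- function(tr) {
  k <- length(tr$tip.label)
  pp <- ape::prop.part(tr)  # clades of internal nodes, in node order k+1, ...
  clades <- c(as.list(1:k), lapply(pp, sort))
  clades
}

# canonical string key for the split {tips, complement}; block holding
# the alphabetically smallest taxon is written first, labels sorted
.split_key <- function(tip_idx, labels) {
  k <- length(labels)
  a <- sort(labels[tip_idx])
  b <- sort(labels[-tip_idx])
  first <- sort(c(a[1], b[1]))[1]
  if (first %in% a) paste0(paste(a, collapse = ","), "|", paste(b, collapse = ","))
  else paste0(paste(b, collapse = ","), "|", paste(a, collapse = ","))
}

#' Bipartitions (splits) of a tree
#'
#' Extracts the bipartitions of a rooted binary tree, computed on its
#' unrooted form: every branch is cut and the resulting two-block leaf
#' partition recorded, with the two root-adjacent branches contributing
#' a single shared split.  A `k`-leaf binary tree has `2k - 3` distinct
#' bipartitions, of which `k - 3` are nontrivial (both blocks of size at
#' least 2).  Splits are returned as canonical strings `"A,B|C,D"`
#' (block containing the alphabetically smallest taxon first, labels
#' sorted), so equality is invariant to block order and rerooting.
#'
#' @param tree A rooted binary `phylo` object.
#' @param nontrivial_only If `TRUE` (default), return only nontrivial
#'   splits; requires `k >= 4`.
#' @return Character vector of canonical split keys, with attribute
#'   `taxa` (sorted leaf labels).
#' @examples
#' tr <- read_species_tree("(((A:1,B:1):0.5,C:1.5):0.5,D:2);")
#' bipartitions(tr)                          # "A,B|C,D"
#' length(bipartitions(tr, nontrivial_only = FALSE))  # 2k - 3 = 5
#' @export
bipartitions <- function(tree, nontrivial_only = TRUE) {
  .check_rooted_binary(tree)
  k <- length(tree$tip.label)
  if (nontrivial_only && k < 4)
    stop("nontrivial bipartitions require k >= 4 taxa")
  clades <- .clades_by_node(tree)
  sizes <- lengths(clades)
  child <- tree$edge[, 2]
  keep <- if (nontrivial_only) {
    child[sizes[child] >= 2 & sizes[child] <= k - 2]
  } else child
  keys <- unique(vapply(clades[keep], .split_key, "", labels = tree$tip.label))
  structure(keys, taxa = sort(tree$tip.label))
}

#' Internal branches of a species tree
#'
#' Tabulates the `k - 2` internal (non-pendant) branches
#' \eqn{e_1, \dots, e_{k-2}} of a rooted binary species tree: branch
#' length \eqn{T_i}, number of descendant taxa \eqn{k_i}, the induced
#' split, whether that split is nontrivial, and the flag for the branch
#' \eqn{e_c} whose split is trivial -- present exactly when one side of
#' the root is a single leaf.  When both root children are internal
#' nodes, the two root-adjacent branches map to the same nontrivial
#' split and no branch is flagged.
#'
#' @param tree A rooted binary species tree (`phylo`), `k >= 4`.
#' @return A `data.frame` with one row per internal branch and columns
#'   `edge` (row index into `tree$edge`), `length`, `n_desc`, `split`,
#'   `nontrivial`, `is_root_trivial`.
#' @export
internal_branches <- function(tree) {
  .validate_species_tree(tree)
  k <- length(tree$tip.label)
  root <- k + 1L
  clades <- .clades_by_node(tree)
  sizes <- lengths(clades)
  idx <- which(tree$edge[, 2] > k)          # edges whose child is internal
  child <- tree$edge[idx, 2]
  stopifnot(length(idx) == k - 2L)
  n_desc <- sizes[child]
  key <- vapply(clades[child], .split_key, "", labels = tree$tip.label)
  nontrivial <- n_desc >= 2 & n_desc <= k - 2
  root_children <- tree$edge[tree$edge[, 1] == root, 2]
  root_has_leaf_child <- any(root_children <= k)
  is_ec <- root_has_leaf_child & tree$edge[idx, 1] == root
  data.frame(edge = idx, length = tree$edge.length[idx], n_desc = n_desc,
             split = key, nontrivial = nontrivial, is_root_trivial = is_ec,
             stringsAsFactors = FALSE)
}

#' Shortest internal branch length
#'
#' Returns \eqn{T_{\min}}, the minimum length over all `k - 2` internal
#' branches of the species tree -- including, when present, the
#' root-adjacent branch whose split is trivial.
#'
#' @inheritParams internal_branches
#' @return A single non-negative number in coalescent time units.
#' @export
t_min <- function(tree) {
  min(internal_branches(tree)$length)
}

#' Does a gene-tree set cover all species-tree bipartitions?
#'
#' A gene-tree set is a *bipartition cover* of a species tree if each of
#' the `k - 3` nontrivial species-tree splits occurs (as an unrooted
#' split) in at least one gene tree in the set.
#'
#' @param gene_trees A `multiPhylo`, list of `phylo`, or single `phylo`;
#'   all on the same taxon set as `species_tree`.  An empty set is
#'   allowed and never a cover for `k > 3`.
#' @param species_tree A rooted binary species tree (`phylo`), `k >= 4`.
#' @return `TRUE` or `FALSE`.
#' @export
is_bipartition_cover <- function(gene_trees, species_tree) {
  need <- bipartitions(species_tree, nontrivial_only = TRUE)
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (length(gene_trees) == 0L) return(FALSE)
  taxa <- attr(need, "taxa")
  seen <- character(0)
  for (gt in gene_trees) {
    if (!setequal(gt$tip.label, taxa))
      stop("gene tree taxon set does not match the species tree")
    seen <- union(seen, bipartitions(gt, nontrivial_only = TRUE))
    if (all(need %in% seen)) return(TRUE)
  }
  all(need %in% seen)
}

#' Species-tree fixtures: caterpillar, balanced, Yule
#'
#' Builds a labeled species tree of a standard shape for simulation
#' studies.  `"caterpillar"` is the fully pectinate (ladder) topology,
#' the hardest case for gene-tree discordance; `"balanced"` splits the
#' taxa as evenly as possible at every node; `"yule"` draws a uniform
#' random rooted topology and assigns each internal branch an
#' independent Exp(rate `2 * lambda`) length, the internal-branch-length
#' distribution of the Yule pure-birth speciation process.  For
#' `"caterpillar"` and `"balanced"` every internal branch is set to
#' `t_internal`.  Pendant branches are set to 1 coalescent unit: with
#' one lineage sampled per species no coalescence can occur on a pendant
#' branch, so pendant lengths affect neither the gene-tree topology
#' distribution nor any bound, but Newick output needs a concrete value.
#'
#' @param kind One of `"caterpillar"`, `"balanced"`, `"yule"`.
#' @param k Number of taxa, `k >= 4`.  Taxa are labeled `t1..tk`.
#' @param t_internal Internal branch length in coalescent units
#'   (caterpillar/balanced), `> 0`.
#' @param lambda Yule speciation rate per coalescent time unit
#'   (`kind = "yule"`), `> 0`.
#' @param seed Optional integer seed (`kind = "yule"`); same seed, same
#'   tree.
#' @return A rooted binary `phylo` with `k - 2` internal branches.
#' @examples
#' make_fixture("caterpillar", k = 6, t_internal = 0.2)
#' @export
make_fixture <- function(kind = c("caterpillar", "balanced", "yule"),
                         k, t_internal = NULL, lambda = NULL, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(k) == 1L, k == round(k), k >= 4)
  labels <- paste0("t", seq_len(k))
  if (kind == "yule") {
    stopifnot(is.numeric(lambda), lambda > 0)
    if (!is.null(seed)) {
      old <- .save_rng_state(); on.exit(.restore_rng_state(old))
      set.seed(seed)
    }
    tr <- ape::rtopology(k, rooted = TRUE, tip.label = labels)
    tr <- .set_fixture_lengths(tr, internal = stats::rexp(k - 2, rate = 2 * lambda))
  } else {
    stopifnot(is.numeric(t_internal), t_internal > 0)
    nwk <- if (kind == "caterpillar") .caterpillar_newick(labels)
           else .balanced_newick(labels)
    tr <- ape::read.tree(text = nwk)
    tr <- .set_fixture_lengths(tr, internal = rep(t_internal, k - 2))
  }
  tr
}

.caterpillar_newick <- function(labels) {
  s <- paste0("(", labels[1], ",", labels[2], ")")
  for (lab in labels[-(1:2)]) s <- paste0("(", s, ",", lab, ")")
  paste0(s, ";")
}

.balanced_newick <- function(labels) {
  build <- function(lab) {
    n <- length(lab)
    if (n == 1L) return(lab)
    h <- ceiling(n / 2)
    paste0("(", build(lab[1:h]), ",", build(lab[(h + 1):n]), ")")
  }
  paste0(build(labels), ";")
}

# assign pendant = 1.0 and the given internal lengths (edge order of tr$edge)
.set_fixture_lengths <- function(tr, internal) {
  k <- length(tr$tip.label)
  len <- rep(1.0, nrow(tr$edge))
  len[tr$edge[, 2] > k] <- internal
  tr$edge.length <- len
  tr
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
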