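.check_bound_domain <- function(k, t_min) {
  stopifnot(length(k) == 1L, k == round(k))
  if (k < 4) stop("k >= 4 taxa required")
  if (length(t_min) != 1L || is.na(t_min) || t_min < 0)
    stop("t_min must be a single non-negative number")
}

#' Lower bound on the probability of the least likely bipartition
#'
#' For a `k`-taxon species tree with shortest internal branch `t_min`,
#' the probability that any given nontrivial split appears in at least
#' one of `n` independent coalescent gene trees is at least
#' \deqn{1 - [1 - g_{k-2,1}(T_{\min})]^n :}
#' a split is certainly observed if all lineages below its branch
#' coalesce to one on that branch, the branch carries at most `k - 2`
#' lineages, and `g_ij(i, 1, t)` decreases in `i` and increases in `t`.
#'
#' @param k Number of taxa, `>= 4`.
#' @param t_min Shortest internal branch length, coalescent units.
#' @param n Number of gene trees (vectorized), `>= 0`.
#' @return Numeric vector of probability lower bounds.
#' @export
min_split_prob_bound <- function(k, t_min, n) {
  .check_bound_domain(k, t_min)
  if (any(n < 0) || any(n != round(n))) stop("n must be a non-negative integer")
  # exp(n * log1p(-g)) rather than (1-g)^n: keeps full precision for
  # tiny g and matches the log form inverted by loci_upper_bound()
  1 - exp(n * log1p(-g_ij(k - 2, 1, t_min)))
}

#' Lower bound on the bipartition-cover probability Q_n
#'
#' Bonferroni (union) bound over the `k - 3` nontrivial splits of a
#' `k`-taxon species tree, combined with [min_split_prob_bound()]:
#' \deqn{Q_n \ge 1 - (k-3)\,[1 - g_{k-2,1}(T_{\min})]^n.}
#' The bound depends on the species tree only through `k` and `t_min`
#' and holds for every topology.  For small `n` the right-hand side can
#' be negative, in which case only the trivial `Q_n >= 0` is available:
#' the returned value is clamped to `[0, 1]` and the raw value kept in
#' attribute `raw`.
#'
#' @inheritParams min_split_prob_bound
#' @return Numeric vector of clamped lower bounds on the cover
#'   probability, with attributes `raw` (unclamped) and `g`
#'   (the \eqn{g_{k-2,1}(T_{\min})} value used).
#' @examples
#' cover_prob_bound(k = 6, t_min = 0.5, n = 50)
#' @export
cover_prob_bound <- function(k, t_min, n) {
  .check_bound_domain(k, t_min)
  if (any(n < 0) || any(n != round(n))) stop("n must be a non-negative integer")
  g <- g_ij(k - 2, 1, t_min)
  raw <- 1 - (k - 3) * exp(n * log1p(-g))
  structure(pmin(pmax(raw, 0), 1), raw = raw, g = g)
}

#' Upper bound on the number of loci needed for a bipartition cover
#'
#' Inverts the cover-probability bound: the smallest `n` for which the
#' guaranteed lower bound on \eqn{Q_n} reaches a target probability `q`
#' satisfies \deqn{n = \frac{\log[(1-q)/(k-3)]}{\log[1 -
#' g_{k-2,1}(T_{\min})]}.}
#' With this many gene trees, a random gene-tree set is a bipartition
#' cover of *any* `k`-taxon species tree whose shortest internal branch
#' is at least `t_min`, with probability at least `q`.  The integer
#' bound is the ceiling of the real value (floored at 0); `raw = TRUE`
#' returns the real value itself.
#'
#' @inheritParams min_split_prob_bound
#' @param q Target cover probability, `0 < q < 1`.
#' @param raw If `TRUE` return the real-valued solution instead of the
#'   integer ceiling.
#' @return Number of loci (integer-valued unless `raw = TRUE`), with
#'   attribute `g`.  `Inf` if `g_{k-2,1}(t_min)` underflows to 0.
#' @examples
#' loci_upper_bound(k = 4, t_min = 1, q = 0.99)    # 5
#' loci_upper_bound(k = 30, t_min = 0.5, q = 0.99999)
#' @export
loci_upper_bound <- function(k, t_min, q, raw = FALSE) {
  .check_bound_domain(k, t_min)
  if (length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
    stop("q must lie strictly between 0 and 1")
  if (t_min == 0)
    stop("unbounded: t_min = 0 gives g = 0, no finite number of loci suffices")
  g <- g_ij(k - 2, 1, t_min)
  if (g == 0) {  # underflow guard (extremely short branch, many taxa)
    warning("g underflowed to 0; bound is infinite")
    return(structure(Inf, g = g))
  }
  n_real <- log((1 - q) / (k - 3)) / log1p(-g)
  val <- if (raw) n_real else max(0, ceiling(n_real))
  structure(val, g = g)
}

#' Locus-bound surface over taxa and minimum branch length
#'
#' Evaluates [loci_upper_bound()] on a grid of taxon counts and
#' `t_min` values at fixed target probability `q`, giving the table
#' behind log10(n)-versus-k plots.
#'
#' @param k Integer vector of taxon counts (default `4:30`).
#' @param t_min Numeric vector of minimum internal branch lengths
#'   (default `c(1, 0.5, 0.2, 0.1)`).
#' @param q Target cover probability.
#' @return A `data.frame` with columns `k`, `t_min`, `g`, `n_real`, `n`.
#' @examples
#' head(bound_surface(q = 0.99))
#' @export
bound_surface <- function(k = 4:30, t_min = c(1, 0.5, 0.2, 0.1), q = 0.99) {
  grid <- expand.grid(k = k, t_min = t_min, KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(kk, tt) {
    n_real <- loci_upper_bound(kk, tt, q, raw = TRUE)
    c(g = as.numeric(attr(n_real, "g")), n_real = as.numeric(n_real),
      n = max(0, ceiling(as.numeric(n_real))))
  }, grid$k, grid$t_min)
  cbind(grid, as.data.frame(t(res)))
}
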