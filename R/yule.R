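#' Empirically motivated Yule speciation rates
#'
#' Speciation rates (events per coalescent time unit) used as anchors
#' when studying how the minimum internal branch length scales with
#' clade size: great apes ~0.5, primates ~0.28, warblers ~0.14.
#'
#' @format Named numeric vector of length 3.
#' @export
yule_presets <- c(great_apes = 0.5, primates = 0.28, warblers = 0.14)

#' Expected minimum internal branch length under the Yule process
#'
#' Under the Yule pure-birth speciation model at rate `lambda`, each of
#' the `k - 2` internal branch lengths of a `k`-taxon species tree is
#' independently Exp(rate `2 * lambda`) distributed (Stadler-Steel), so
#' their minimum is Exp(rate `2 * (k - 2) * lambda`) and
#' \deqn{E[T_{\min}] = \frac{1}{2 (k-2) \lambda}.}
#'
#' @param k Number of taxa, `>= 4` (vectorized).
#' @param lambda Speciation rate per coalescent time unit, `> 0`
#'   (vectorized).
#' @return Expected minimum internal branch length, coalescent units.
#' @examples
#' yule_expected_t_min(k = 15, lambda = 0.2)  # ~0.19
#' @export
yule_expected_t_min <- function(k, lambda) {
  if (any(k < 4) || any(k != round(k))) stop("k >= 4 required")
  if (any(lambda <= 0)) stop("lambda must be > 0")
  1 / (2 * (k - 2) * lambda)
}

#' Sample the minimum internal branch length under the Yule process
#'
#' Draws `draws` independent realizations of \eqn{T_{\min}}, each the
#' minimum of `k - 2` iid Exp(rate `2 * lambda`) branch lengths.
#'
#' @inheritParams yule_expected_t_min
#' @param draws Number of samples, `>= 1`.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `draws`.
#' @export
yule_sample_t_min <- function(k, lambda, draws, seed = NULL) {
  stopifnot(length(k) == 1L, length(lambda) == 1L, draws >= 1)
  if (k < 4 || k != round(k)) stop("k >= 4 required")
  if (lambda <= 0) stop("lambda must be > 0")
  if (!is.null(seed)) {
    old <- .save_rng_state(); on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  # min of k-2 iid Exp(2*lambda) is Exp(2*(k-2)*lambda)
  stats::rexp(draws, rate = 2 * (k - 2) * lambda)
}

#' Locus bound at the Yule-expected minimum branch length
#'
#' Plug-in pipeline from a speciation rate to a locus requirement:
#' `lambda` determines \eqn{E[T_{\min}] = 1/[2(k-2)\lambda]}, which is
#' substituted for `t_min` in [loci_upper_bound()].  Note this is the
#' bound at the *expected* minimum branch length, not the expectation
#' of the bound.
#'
#' @inheritParams yule_expected_t_min
#' @param q Target cover probability (default 0.99).
#' @param raw If `TRUE` return the real-valued bound.
#' @return Number of loci, as in [loci_upper_bound()].
#' @examples
#' yule_loci_bound(k = 15, lambda = 0.2)
#' @export
yule_loci_bound <- function(k, lambda, q = 0.99, raw = FALSE) {
  stopifnot(length(k) == 1L, length(lambda) == 1L)
  loci_upper_bound(k, yule_expected_t_min(k, lambda), q, raw = raw)
}
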