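---
title: "How many gene trees until every species-tree split is seen?"
author: "splitcover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many gene trees until every species-tree split is seen?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitcover)
```

## The problem

Summary methods for species-tree inference, ASTRAL among them, estimate a
species tree from a collection of gene trees, one per locus. ASTRAL's
search space is constrained to species trees whose bipartitions (splits)
are drawn from the splits observed in the input gene trees. The method is
statistically consistent under the multispecies coalescent (MSC) because,
as loci accumulate, the probability that every nontrivial split of the
true species tree appears in at least one gene tree — that the gene-tree
set is a *bipartition cover* — approaches one. Consistency, however, says
nothing about how many loci are enough. This package implements an
analytical answer: a lower bound on the cover probability $Q_n$ of an
$n$-locus gene-tree set, and its inversion into an upper bound on the
number of loci needed to reach a target cover probability $q$.

Throughout, species trees are rooted, binary, with one lineage sampled
per species, and branch lengths in coalescent time units (generations
divided by the number of gene copies, $2N$ for diploids).

## The coalescent primitive $g_{i,j}(T)$

Everything rests on the Kingman lineage-counting probability: the chance
that $i$ lineages entering a population leave exactly $j$ after time $T$,

$$g_{i,j}(T) = \sum_{k=j}^{i}
  e^{-k(k-1)T/2}\,\frac{(2k-1)(-1)^{k-j}\, j_{(k-1)}\, i_{[k]}}
  {j!\,(k-j)!\, i_{(k)}},$$

with $a_{(k)}$ and $a_{[k]}$ rising and falling factorials. `g_ij()`
implements this sum directly.

**Numerical design.** The sum is alternating: for short branches and many
lineages a result of order $10^{-4}$ or far less emerges from terms of
order 1, and double precision can lose most or all significant digits.
`g_ij()` therefore (i) evaluates coefficients as products of small
rational factors (no factorial overflow up to $i$ well beyond the
supported 30), (ii) accumulates terms with compensated Kahan summation,
and (iii) whenever the computed magnitude falls below $10^{-3}$ of the
largest term — i.e. more than three digits cancelled — recomputes the
value by *uniformization* of the pure-death chain on lineage counts
(death rate $m(m-1)/2$ from state $m$). The uniformization series has
all-non-negative terms, so it cannot cancel, and yields relative accuracy
near $10^{-12}$ even for probabilities at the underflow edge
($g_{28,1}(0.01)\approx 6\times 10^{-34}$). The test suite pins `g_ij()`
against a frozen 60-significant-digit evaluation of the spectral sum and
against the independent hypoexponential-CDF representation of
$g_{i,1}(T)$ (the waiting time from $i$ lineages to 1 is a sum of
independent exponentials with rates $m(m-1)/2$, $m = i,\dots,2$).

## Exact four-taxon theory

A four-taxon species tree has a single nontrivial split, AB|CD, present
in 5 of the 15 rooted gene-tree topologies. For the symmetric shape
(`((A,B):T1,(C,D):T2)`) and the asymmetric shape
(`(((A,B):T1,C):T2,D)`), the five per-topology probabilities are sums of
products of $g_{2,j}$ and $g_{3,j}$ values on the two internal branches;
`four_taxon_topology_probs()` codes them term by term, exactly as
tabulated, rather than in simplified form. Their totals collapse to

$$P_1^s = 1 - \tfrac{2}{3}e^{-(T_1+T_2)}, \qquad
  P_1^a = 1 - \tfrac{2}{3}e^{-T_1},$$

the exponent being in each case the single internal branch of the
*unrooted* species tree. Keeping the bracketed and closed forms as
separate code paths turns their agreement (tested to $10^{-12}$ on a
random $(T_1,T_2)$ grid) into a genuine cross-check of both the $g$
implementation and the transcription of the five terms. Since gene trees
are conditionally independent given the species tree,
$P_n = 1 - (1-P_1)^n$, and as $T_1 \to 0$ the asymmetric probability
tends to $1/3$ (three exchangeable lineages). These exact values are the
ground truth against which the general bound and the simulator are
validated at $k = 4$.

## The general bound and its inversion

For $k > 4$ the splits of a species tree are dependent, and exact cover
probabilities would require monophyly computations the package
deliberately leaves out of scope. Instead:

* **Least-likely split.** A split is certainly observed in a gene tree
  if all lineages below its branch coalesce to one on that branch; a
  branch carries at most $k-2$ lineages and is at least $T_{\min}$ long
  (the shortest internal branch, minimized over all $k-2$ internal
  branches). Since $g_{i,1}(T)$ decreases in $i$ and increases in $T$,
  every split satisfies
  $Q_{i,n} \ge 1 - [1 - g_{k-2,1}(T_{\min})]^n$
  (`min_split_prob_bound()`).
* **All splits at once.** Bonferroni's inequality disregards the
  dependence among the $k-3$ splits:
  $$Q_n \ge 1 - (k-3)\,[1 - g_{k-2,1}(T_{\min})]^n$$
  (`cover_prob_bound()`). For small $n$ the right-hand side is negative
  and only $Q_n \ge 0$ remains; the function clamps and keeps the raw
  value as an attribute.
* **Inversion.** Setting $Q_n = q$,
  $$n = \frac{\log[(1-q)/(k-3)]}{\log[1 - g_{k-2,1}(T_{\min})]}$$
  (`loci_upper_bound()`), an upper bound on the loci needed for cover
  probability $q$, valid for *every* $k$-taxon topology with shortest
  internal branch $T_{\min}$.

Numerical choices: the real-valued $n$ is reported via `raw = TRUE`; the
integer bound is its ceiling (a "number of gene trees" must be an
integer, and the ceiling preserves the guarantee). Both directions use
the same `exp(n * log1p(-g))` form, so plugging the returned $n$ back
into the probability bound reproduces $\ge q$ exactly rather than up to
mismatched rounding — important when $g$ is $10^{-7}$ and $n$ runs to
$10^6$ and beyond. `t_min = 0` or $q = 1$ are reported as explicit
unbounded outcomes, not numeric overflow. `k = 4` is admitted
($k-3 = 1$), where the bound has the exact four-taxon theory as its
comparator.

Two grid points worth remembering (`bound_surface()` tabulates the
whole $k \times T_{\min}$ grid): with $q = 0.99999$ and
$T_{\min} = 0.5$, 30 taxa need at most 2129 loci; with $q = 0.99$ and
$T_{\min} = 0.1$, 12 taxa already need $4.5\times 10^6$ — beyond the
$10^4$–$10^5$ independent loci a genome offers. A caveat surfaced while
tabulating: at $T_{\min} = 0.1$ the bound crosses $10^4$ between $k = 6$
(2426 loci) and $k = 7$ (11787 loci), so "up to 8 taxa stay under
$10^4$" holds at $T_{\min} = 0.2$ (2568 loci at $k = 8$) but not at
$T_{\min} = 0.1$ ($4.9 \times 10^4$ at $k = 8$).

## The MSC simulator and the accuracy experiment

`sim_gene_trees()` draws gene trees directly under the MSC: lineages
enter at the species-tree tips, and within each branch carrying $m$
lineages a uniformly chosen pair coalesces after an Exp($m(m-1)/2$)
waiting time, truncated at the top of the branch; above the root the
process runs until one lineage remains. This direct simulation induces
the same gene-tree topology distribution as sampling from the exact
multinomial over topologies, so simulation-based comparisons hold within
Monte-Carlo error rather than exactly. The core is C++ (via Rcpp), with
splits carried as bitmasks (hence the $k \le 30$ support limit, ample
for the bound's useful range); `estimate_cover_probability()` counts
covering replicate sets without building tree objects, which is what
makes replicate counts of $10^4$ and the full validity grids cheap. The
simulator's own correctness oracle is the theory it feeds: single-branch
exit counts must follow $g_{i,j}(T)$, and four-taxon split and
per-topology frequencies must match the exact probabilities — both are
asserted at $10^5$ replicates (binomial 3-SE criterion) in the tests.

`accuracy_experiment()` reproduces the bound-tightness protocol on
caterpillar species trees (the high-discordance worst case) with all
internal branches set to $T_{\min}$: for each gene-tree-set size $n_s$
it estimates $\hat Q_{n_s}$ from replicate sets, feeds $\hat Q_{n_s}$
back into the locus bound as the target $q$ to get $n_b$, and reports
the overestimation factor $n_b/n_s$. Sets with $\hat Q = 1$ make the
bound infinite and are flagged `NA` rather than plotted; $\hat Q = 0$
yields ratio 0 with a warning. The tests run the full grid
$k \in \{5,6,8\}$, $T_{\min} \in \{0.2, 0.5, 1.0\}$,
$n_s \in \{1,2,3,5,10,20,50,100,200,500\}$ at $10^3$ replicate sets
(binomial SE $\le 1.6\%$; $10^4$ is a function argument away) and check
the qualitative laws: ratios $\ge 1$ always (the bound never
undershoots), near-tight at $k = 4$, growing with $k$, shrinking as
$T_{\min}$ grows.

## Yule branch lengths

To say something about *expected* study conditions rather than a fixed
tree, the Yule pure-birth model at speciation rate $\lambda$ makes the
$k-2$ internal branch lengths iid Exp($2\lambda$), so
$T_{\min} \sim \mathrm{Exp}(2(k-2)\lambda)$ and
$E[T_{\min}] = 1/[2(k-2)\lambda]$ (`yule_expected_t_min()`,
`yule_sample_t_min()`). `yule_loci_bound()` chains
$\lambda \to E[T_{\min}] \to n$: a plug-in of the expectation into the
bound, not the expectation of the bound — the sampling function exists
precisely so users can see the distributional spread the plug-in hides.
Documented rate anchors ship as `yule_presets`: great apes 0.5, primates
0.28, warblers 0.14 events per coalescent unit (the warbler value is
carried as published; no attempt is made to re-derive it from the
per-million-year rate). At the warbler rate and $k = 15$, the plug-in
bound is $1.4\times 10^4$ loci — genome-scale but attainable; at
$\lambda = 0.5$ it is far beyond any genome, which is also the regime
where the bound is at its most conservative.

## Fixtures and what the tests do and do not show

`make_fixture()` builds caterpillar and balanced topologies with all
internal branches equal to `t_internal`, and Yule trees with
Exp($2\lambda$) internal branches on a uniformly drawn rooted topology
(the Yule theory above needs only the branch-length law, so topology
choice is immaterial to everything tested). Pendant branches default to
1.0 coalescent unit: with one lineage per species no coalescence can
happen on a pendant branch, so pendant lengths affect neither the
gene-tree topology distribution nor any bound — the value exists only so
that Newick output is well-formed. All fixtures are deterministic under
a seed.

The synthetic setting matches the model exactly: true gene trees,
one lineage per species, no estimation error, free recombination between
loci, complete taxon overlap. Passing tests therefore certify the
mathematics and the implementation, not robustness to gene-tree
estimation error, missing taxa, or intra-locus recombination — on real
data the bound speaks only to the sampling component of the problem, and
conservatively at that.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <s> --out <path>` recomputes, from the
installed package alone: the four-taxon topology counts (15 / 5), the
$T_1 \to 0$ limit $1/3$, the locus bounds at the reference grid points
$(k=30, T_{\min}=0.5, q=0.99999)$, $(8, 0.2, 0.99)$, $(12, 0.1, 0.99)$
and $(4, 1, 0.99)$, the Yule expectations at $(k=15, \lambda=0.2)$ and
$(8, 0.5)$, and simulation-based checks ($10^4$ replicates): the
empirical four-taxon split frequency against $P_1^a$, an empirical cover
probability against the analytical bound, and one $n_b/n_s$ accuracy
ratio.
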