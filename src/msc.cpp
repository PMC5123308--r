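// Multispecies-coalescent gene-tree simulation on a fixed rooted binary
// species tree, one lineage sampled per species.  Hot loops live here;
// the R wrappers in R/simulate.R do validation and object assembly.
//
// Species-tree encoding (prepared in R, 1-based node ids as in ape):
//   nodes 1..ntip are leaves, ntip+1 the root, ntip+2.. internal;
//   child1/child2: children of each internal node (0 for leaves);
//   blen[v]: length of the branch above node v (ignored for the root);
//   height[v]: time of node v before the reference point (root highest);
//   postorder: internal nodes only, children before parents, root last.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Kingman coalescent within one branch: lineages coalesce pairwise at
// rate m(m-1)/2, truncated at duration T (T = Inf runs to one lineage).
// Masks variant: a lineage is the bitmask of its descendant taxa; every
// merge records the resulting clade mask.
static void coalesce_masks(std::vector<unsigned>& lin, double T,
                           std::vector<unsigned>& clades) {
  double t = 0.0;
  while (lin.size() >= 2) {
    int m = (int)lin.size();
    t += R::exp_rand() / (0.5 * m * (m - 1));
    if (t > T) break;
    int a = (int)(unif_rand() * m); if (a >= m) a = m - 1;
    int b = (int)(unif_rand() * (m - 1)); if (b >= m - 1) b = m - 2;
    if (b >= a) ++b;
    unsigned merged = lin[a] | lin[b];
    clades.push_back(merged);
    lin[a] = merged;
    lin[b] = lin.back();
    lin.pop_back();
  }
}

// one gene tree's clade masks (ntip - 1 merges, root included)
static void sim_tree_masks(const IntegerVector& child1,
                           const IntegerVector& child2,
                           const NumericVector& blen,
                           const IntegerVector& postorder, int ntip,
                           std::vector<unsigned>& clades,
                           std::vector<std::vector<unsigned> >& pool) {
  clades.clear();
  int root = ntip + 1;
  for (int idx = 0; idx < postorder.size(); ++idx) {
    int v = postorder[idx];
    std::vector<unsigned>& lin = pool[v];
    lin.clear();
    int ch[2] = { child1[v - 1], child2[v - 1] };
    for (int s = 0; s < 2; ++s) {
      int c = ch[s];
      if (c <= ntip) {                      // pendant branch: one lineage
        lin.push_back(1u << (c - 1));
      } else {                              // child subtree's survivors
        std::vector<unsigned>& sub = pool[c];
        coalesce_masks(sub, blen[c - 1], clades);
        lin.insert(lin.end(), sub.begin(), sub.end());
      }
    }
    if (v == root)
      coalesce_masks(lin, R_PosInf, clades); // above the root: run to one
  }
}

// canonical unrooted split mask: complement so that taxon 1's bit is 0
static inline unsigned canon(unsigned mask, unsigned full) {
  return (mask & 1u) ? (full & ~mask) : mask;
}

// [[Rcpp::export]]
IntegerMatrix sim_clade_masks_cpp(IntegerVector child1, IntegerVector child2,
                                  NumericVector blen, IntegerVector postorder,
                                  int ntip, int reps) {
  IntegerMatrix out(reps, ntip - 1);
  std::vector<unsigned> clades;
  std::vector<std::vector<unsigned> > pool(2 * ntip);
  for (int r = 0; r < reps; ++r) {
    sim_tree_masks(child1, child2, blen, postorder, ntip, clades, pool);
    for (int m = 0; m < ntip - 1; ++m) out(r, m) = (int)clades[m];
  }
  return out;
}

// [[Rcpp::export]]
int count_covers_cpp(IntegerVector child1, IntegerVector child2,
                     NumericVector blen, IntegerVector postorder, int ntip,
                     IntegerVector need_masks, int ns, int reps) {
  unsigned full = (ntip >= 32) ? 0xffffffffu : ((1u << ntip) - 1u);
  std::vector<unsigned> need(need_masks.begin(), need_masks.end());
  for (size_t i = 0; i < need.size(); ++i) need[i] = canon(need[i], full);
  std::sort(need.begin(), need.end());
  std::vector<unsigned> clades;
  std::vector<std::vector<unsigned> > pool(2 * ntip);
  std::vector<char> hit(need.size());
  int covered = 0;
  for (int r = 0; r < reps; ++r) {
    std::fill(hit.begin(), hit.end(), 0);
    size_t nhit = 0;
    for (int g = 0; g < ns && nhit < need.size(); ++g) {
      sim_tree_masks(child1, child2, blen, postorder, ntip, clades, pool);
      for (size_t m = 0; m < clades.size(); ++m) {
        unsigned cm = canon(clades[m], full);
        std::vector<unsigned>::iterator it =
          std::lower_bound(need.begin(), need.end(), cm);
        if (it != need.end() && *it == cm) {
          size_t j = it - need.begin();
          if (!hit[j]) { hit[j] = 1; ++nhit; }
        }
      }
    }
    if (nhit == need.size()) ++covered;
  }
  return covered;
}

// [[Rcpp::export]]
IntegerVector sim_branch_exit_counts_cpp(int i, double T, int reps) {
  IntegerVector out(reps);
  std::vector<unsigned> lin;
  std::vector<unsigned> clades;
  for (int r = 0; r < reps; ++r) {
    lin.clear();
    for (int m = 0; m < i; ++m) lin.push_back(1u << (m % 31));
    clades.clear();
    coalesce_masks(lin, T, clades);
    out[r] = (int)lin.size();
  }
  return out;
}

// Full gene trees, with node heights, for R-level phylo assembly.
// Lineage = provisional gene-node id; merges record children + height.
struct Merge { int a, b; double h; };

static void coalesce_nodes(std::vector<int>& lin, double h0, double T,
                           int ntip, std::vector<Merge>& merges) {
  double t = 0.0;
  while (lin.size() >= 2) {
    int m = (int)lin.size();
    t += R::exp_rand() / (0.5 * m * (m - 1));
    if (t > T) break;
    int a = (int)(unif_rand() * m); if (a >= m) a = m - 1;
    int b = (int)(unif_rand() * (m - 1)); if (b >= m - 1) b = m - 2;
    if (b >= a) ++b;
    Merge mg; mg.a = lin[a]; mg.b = lin[b]; mg.h = h0 + t;
    merges.push_back(mg);
    lin[a] = ntip + (int)merges.size();     // provisional id of new node
    lin[b] = lin.back();
    lin.pop_back();
  }
}

// [[Rcpp::export]]
List sim_gene_trees_cpp(IntegerVector child1, IntegerVector child2,
                        NumericVector blen, NumericVector height,
                        IntegerVector postorder, int ntip, int ntrees) {
  List out(ntrees);
  int root = ntip + 1;
  for (int tr = 0; tr < ntrees; ++tr) {
    std::vector<Merge> merges;
    std::vector<std::vector<int> > pool(2 * ntip);
    for (int idx = 0; idx < postorder.size(); ++idx) {
      int v = postorder[idx];
      std::vector<int>& lin = pool[v];
      lin.clear();
      int ch[2] = { child1[v - 1], child2[v - 1] };
      for (int s = 0; s < 2; ++s) {
        int c = ch[s];
        if (c <= ntip) lin.push_back(c);
        else {
          std::vector<int>& sub = pool[c];
          coalesce_nodes(sub, height[c - 1], blen[c - 1], ntip, merges);
          lin.insert(lin.end(), sub.begin(), sub.end());
        }
      }
      if (v == root)
        coalesce_nodes(lin, height[v - 1], R_PosInf, ntip, merges);
    }
    int nm = (int)merges.size();            // == ntip - 1
    // renumber internal nodes by decreasing height: root becomes ntip+1
    std::vector<int> ord(nm);
    for (int m = 0; m < nm; ++m) ord[m] = m;
    std::vector<double> hh(nm);
    for (int m = 0; m < nm; ++m) hh[m] = merges[m].h;
    std::stable_sort(ord.begin(), ord.end(),
                     [&hh](int x, int y) { return hh[x] > hh[y]; });
    std::vector<int> newid(nm);
    for (int r = 0; r < nm; ++r) newid[ord[r]] = ntip + 1 + r;
    IntegerMatrix edge(2 * ntip - 2, 2);
    NumericVector elen(2 * ntip - 2);
    int e = 0;
    for (int m = 0; m < nm; ++m) {
      int kids[2] = { merges[m].a, merges[m].b };
      for (int s = 0; s < 2; ++s) {
        int c = kids[s];
        double ch_h = (c <= ntip) ? height[c - 1] : merges[c - ntip - 1].h;
        edge(e, 0) = newid[m];
        edge(e, 1) = (c <= ntip) ? c : newid[c - ntip - 1];
        elen[e] = merges[m].h - ch_h;
        ++e;
      }
    }
    out[tr] = List::create(Named("edge") = edge,
                           Named("edge.length") = elen);
  }
  return out;
}
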