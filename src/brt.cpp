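#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Gradient boosted regression trees for Bernoulli response with per-feature
// monotone constraints. Trees are grown greedily on Newton gradients
// (g = y - p, h = p(1-p)); monotonicity is enforced the usual way for
// constrained tree ensembles: a split on a constrained feature is rejected
// unless the child Newton weights are correctly ordered, and each node
// carries [lo, hi] bounds that clamp every leaf value beneath it.

namespace {

struct Node {
  int feature;   // -1 for leaf
  double split;  // go left if x <= split
  int left, right;
  double value;  // leaf value (link scale, unshrunk)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const std::vector<double>& g;
  const std::vector<double>& h;
  const IntegerVector& mono;
  int max_depth, min_obs;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const std::vector<double>& g_,
              const std::vector<double>& h_, const IntegerVector& mono_,
              int max_depth_, int min_obs_)
      : X(X_), g(g_), h(h_), mono(mono_), max_depth(max_depth_),
        min_obs(min_obs_) {}

  static double weight(double G, double H, double lo, double hi) {
    double w = (H > 1e-10) ? G / H : 0.0;
    return std::min(hi, std::max(lo, w));
  }

  int build(std::vector<int>& rows, int depth, double lo, double hi) {
    double G = 0.0, H = 0.0;
    for (int r : rows) { G += g[r]; H += h[r]; }
    const int node_id = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, weight(G, H, lo, hi)});
    if (depth >= max_depth || (int)rows.size() < 2 * min_obs) return node_id;

    const int p = X.ncol();
    double best_gain = 1e-12;
    int best_f = -1;
    double best_split = 0.0;
    const double parent_score = (H > 1e-10) ? G * G / H : 0.0;

    std::vector<int> ord;
    for (int f = 0; f < p; ++f) {
      ord = rows;
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return X(a, f) < X(b, f); });
      double GL = 0.0, HL = 0.0;
      const int nrow = (int)ord.size();
      for (int k = 0; k < nrow - 1; ++k) {
        GL += g[ord[k]]; HL += h[ord[k]];
        if (X(ord[k], f) == X(ord[k + 1], f)) continue;
        const int nl = k + 1, nr_ = nrow - nl;
        if (nl < min_obs || nr_ < min_obs) continue;
        const double GR = G - GL, HR = H - HL;
        if (HL <= 1e-10 || HR <= 1e-10) continue;
        if (mono[f] != 0) {
          const double wl = weight(GL, HL, lo, hi);
          const double wr = weight(GR, HR, lo, hi);
          if (mono[f] * (wr - wl) < 0) continue;
        }
        const double gain = GL * GL / HL + GR * GR / HR - parent_score;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_split = 0.5 * (X(ord[k], f) + X(ord[k + 1], f));
        }
      }
    }
    if (best_f < 0) return node_id;

    std::vector<int> lrows, rrows;
    double GL = 0.0, HL = 0.0;
    for (int r : rows) {
      if (X(r, best_f) <= best_split) { lrows.push_back(r); GL += g[r]; HL += h[r]; }
      else rrows.push_back(r);
    }
    double llo = lo, lhi = hi, rlo = lo, rhi = hi;
    if (mono[best_f] != 0) {
      const double wl = weight(GL, HL, lo, hi);
      const double wr = weight(G - GL, H - HL, lo, hi);
      const double mid = 0.5 * (wl + wr);
      if (mono[best_f] > 0) { lhi = std::min(hi, mid); rlo = std::max(lo, mid); }
      else                  { llo = std::max(lo, mid); rhi = std::min(hi, mid); }
    }
    const int li = build(lrows, depth + 1, llo, lhi);
    const int ri = build(rrows, depth + 1, rlo, rhi);
    nodes[node_id].feature = best_f;
    nodes[node_id].split = best_split;
    nodes[node_id].left = li;
    nodes[node_id].right = ri;
    return node_id;
  }
};

double tree_predict_row(const NumericMatrix& tree, const NumericMatrix& X,
                        int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    node = (X(row, (int)tree(node, 0)) <= tree(node, 1)) ? (int)tree(node, 2)
                                                         : (int)tree(node, 3);
  }
  return tree(node, 4);
}

double tree_predict_rowv(const std::vector<Node>& nodes, const NumericMatrix& X,
                         int row) {
  int node = 0;
  while (nodes[node].feature >= 0) {
    node = (X(row, nodes[node].feature) <= nodes[node].split)
               ? nodes[node].left : nodes[node].right;
  }
  return nodes[node].value;
}

double bernoulli_deviance(const std::vector<double>& F, const IntegerVector& y) {
  double dev = 0.0;
  const int n = (int)F.size();
  for (int i = 0; i < n; ++i) {
    double p = 1.0 / (1.0 + std::exp(-F[i]));
    p = std::min(1.0 - 1e-12, std::max(1e-12, p));
    dev += y[i] == 1 ? -2.0 * std::log(p) : -2.0 * std::log(1.0 - p);
  }
  return dev / n;
}

}  // namespace

// [[Rcpp::export]]
List brt_fit_cpp(NumericMatrix X, IntegerVector y, IntegerVector mono,
                 int n_trees, double shrinkage, int depth, double bag_fraction,
                 int min_obs, int seed, NumericMatrix Xval, IntegerVector yval,
                 IntegerVector checkpoints) {
  const int n = X.nrow(), nval = Xval.nrow();
  double pbar = 0.0;
  for (int i = 0; i < n; ++i) pbar += y[i];
  pbar = std::min(1.0 - 1e-6, std::max(1e-6, pbar / n));
  const double init = std::log(pbar / (1.0 - pbar));

  std::vector<double> F(n, init), Fval(nval, init), g(n), h(n);
  std::mt19937 rng((unsigned)seed);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  const int bag_n = std::max(1, (int)std::floor(bag_fraction * n));

  List trees(n_trees);
  const int ncp = checkpoints.size();
  NumericVector val_dev(ncp, NA_REAL), train_dev(ncp, NA_REAL);
  int cp = 0;

  for (int m = 0; m < n_trees; ++m) {
    for (int i = 0; i < n; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = y[i] - p;
      h[i] = std::max(1e-10, p * (1.0 - p));
    }
    std::shuffle(perm.begin(), perm.end(), rng);
    std::vector<int> bag(perm.begin(), perm.begin() + bag_n);

    TreeBuilder tb(X, g, h, mono, depth, std::min(min_obs, std::max(1, bag_n / 2)));
    tb.nodes.reserve(64);
    tb.build(bag, 0, -1e12, 1e12);

    NumericMatrix tm((int)tb.nodes.size(), 5);
    for (size_t k = 0; k < tb.nodes.size(); ++k) {
      tm(k, 0) = tb.nodes[k].feature;
      tm(k, 1) = tb.nodes[k].split;
      tm(k, 2) = tb.nodes[k].left;
      tm(k, 3) = tb.nodes[k].right;
      tm(k, 4) = tb.nodes[k].value;
    }
    trees[m] = tm;

    for (int i = 0; i < n; ++i) F[i] += shrinkage * tree_predict_rowv(tb.nodes, X, i);
    for (int i = 0; i < nval; ++i)
      Fval[i] += shrinkage * tree_predict_rowv(tb.nodes, Xval, i);

    while (cp < ncp && checkpoints[cp] == m + 1) {
      train_dev[cp] = bernoulli_deviance(F, y);
      if (nval > 0) val_dev[cp] = bernoulli_deviance(Fval, yval);
      ++cp;
    }
  }
  return List::create(_["trees"] = trees, _["init"] = init,
                      _["train_deviance"] = train_dev,
                      _["valid_deviance"] = val_dev);
}

// [[Rcpp::export]]
NumericVector brt_predict_cpp(List trees, double init, NumericMatrix X,
                              double shrinkage, int n_trees) {
  const int n = X.nrow();
  NumericVector F(n, init);
  const int m_use = std::min((int)trees.size(), n_trees);
  for (int m = 0; m < m_use; ++m) {
    NumericMatrix tm = trees[m];
    for (int i = 0; i < n; ++i) F[i] += shrinkage * tree_predict_row(tm, X, i);
  }
  return F;
}
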