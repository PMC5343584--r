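#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Yearly occupancy automaton on binary suitability.
//
// suit: cells x years (0/1). dist: symmetric along-coast distances (km).
// Year 1 seeds occupancy with suitability. For t > 1, cell i is present iff
// suitable(i, t) AND
//   (1) latency: own presence at some year tau in {t-1, ..., t-L}
//       (latency_window = false restricts to tau = t-L exactly), OR
//   (2) rescue: some j != i present at t-1 with dist(i, j) <= D.
// L = 0 disables condition (1) entirely.
// [[Rcpp::export]]
IntegerMatrix occupancy_automaton_cpp(IntegerMatrix suit, NumericMatrix dist,
                                      double D, int L,
                                      bool latency_window = true) {
  const int n = suit.nrow(), T = suit.ncol();
  IntegerMatrix occ(n, T);
  for (int i = 0; i < n; ++i) occ(i, 0) = suit(i, 0);
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < n; ++i) {
      if (suit(i, t) == 0) { occ(i, t) = 0; continue; }
      bool present = false;
      if (L >= 1) {
        if (latency_window) {
          for (int lag = 1; lag <= L && t - lag >= 0; ++lag)
            if (occ(i, t - lag) == 1) { present = true; break; }
        } else {
          if (t - L >= 0 && occ(i, t - L) == 1) present = true;
        }
      }
      if (!present && D >= 0) {
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          if (occ(j, t - 1) == 1 && dist(i, j) <= D) { present = true; break; }
        }
      }
      occ(i, t) = present ? 1 : 0;
    }
  }
  return occ;
}

// TSS surface over a (D, L) grid, scored against pooled records.
//
// rec_i / rec_t are 0-based (cell, year) indices, rec_p the observed 0/1.
// Neighbour lists are pre-sorted by distance once so each (D, L) run touches
// only the cells within range. Returns tss[iD, iL].
// [[Rcpp::export]]
NumericMatrix tss_surface_cpp(IntegerMatrix suit, NumericMatrix dist,
                              NumericVector Ds, IntegerVector Ls,
                              IntegerVector rec_i, IntegerVector rec_t,
                              IntegerVector rec_p,
                              bool latency_window = true) {
  const int n = suit.nrow(), T = suit.ncol();
  const int nD = Ds.size(), nL = Ls.size(), nr = rec_i.size();

  // neighbour order by distance, self excluded
  std::vector<std::vector<int> > nb_idx(n);
  std::vector<std::vector<double> > nb_dist(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> ord;
    ord.reserve(n - 1);
    for (int j = 0; j < n; ++j) if (j != i) ord.push_back(j);
    const int ii = i;
    NumericMatrix::Row di = dist(i, _);
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      (void)ii; return di[a] < di[b];
    });
    nb_idx[i] = ord;
    nb_dist[i].resize(ord.size());
    for (size_t k = 0; k < ord.size(); ++k) nb_dist[i][k] = di[ord[k]];
  }

  NumericMatrix tss(nD, nL);
  std::vector<int> occ(n * T);
  std::vector<int> ncut(n);
  for (int iD = 0; iD < nD; ++iD) {
    const double D = Ds[iD];
    for (int i = 0; i < n; ++i) {
      ncut[i] = (int)(std::upper_bound(nb_dist[i].begin(), nb_dist[i].end(), D)
                      - nb_dist[i].begin());
    }
    for (int iL = 0; iL < nL; ++iL) {
      const int L = Ls[iL];
      for (int i = 0; i < n; ++i) occ[i] = suit(i, 0);
      for (int t = 1; t < T; ++t) {
        const int prev = (t - 1) * n, cur = t * n;
        for (int i = 0; i < n; ++i) {
          if (suit(i, t) == 0) { occ[cur + i] = 0; continue; }
          bool present = false;
          if (L >= 1) {
            if (latency_window) {
              for (int lag = 1; lag <= L && t - lag >= 0; ++lag)
                if (occ[(t - lag) * n + i] == 1) { present = true; break; }
            } else if (t - L >= 0 && occ[(t - L) * n + i] == 1) {
              present = true;
            }
          }
          if (!present) {
            const std::vector<int>& nbi = nb_idx[i];
            const int m = ncut[i];
            for (int k = 0; k < m; ++k)
              if (occ[prev + nbi[k]] == 1) { present = true; break; }
          }
          occ[cur + i] = present ? 1 : 0;
        }
      }
      int tp = 0, fp = 0, tn = 0, fn = 0;
      for (int r = 0; r < nr; ++r) {
        const int pred = occ[rec_t[r] * n + rec_i[r]];
        if (rec_p[r] == 1) { if (pred == 1) ++tp; else ++fn; }
        else               { if (pred == 1) ++fp; else ++tn; }
      }
      const double sens = (tp + fn) > 0 ? (double)tp / (tp + fn) : NA_REAL;
      const double spec = (tn + fp) > 0 ? (double)tn / (tn + fp) : NA_REAL;
      tss(iD, iL) = sens + spec - 1.0;
    }
  }
  return tss;
}
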