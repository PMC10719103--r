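#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Brute-force k-nearest-neighbour search between two point sets.
// ref: n x d, query: m x d. Returns 1-based indices into ref and Euclidean
// distances, both m x k. When exclude_self is true, ref row `self_index[i]`
// (1-based; 0 = none) is skipped for query row i — used for within-set search.
// [[Rcpp::export]]
List knn_brute(NumericMatrix ref, NumericMatrix query, int k,
               IntegerVector self_index) {
  const int n = ref.nrow(), m = query.nrow(), d = ref.ncol();
  if (k < 1) stop("k must be >= 1");
  if (k > n) stop("k (%d) exceeds number of reference points (%d)", k, n);
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<double> d2(n);
  std::vector<int> ord(n);
  const bool has_self = self_index.size() == m;
  for (int i = 0; i < m; ++i) {
    const int skip = has_self ? self_index[i] - 1 : -1;
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = query(i, c) - ref(j, c);
        s += diff * diff;
      }
      d2[j] = (j == skip) ? R_PosInf : s;
    }
    const int kk = std::min(k, has_self && skip >= 0 ? n - 1 : n);
    if (kk < k) stop("k exceeds available neighbours after excluding self");
    for (int j = 0; j < n; ++j) ord[j] = j;
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) {
                        if (d2[a] != d2[b]) return d2[a] < d2[b];
                        return a < b;  // deterministic tie-break
                      });
    for (int j = 0; j < k; ++j) {
      idx(i, j) = ord[j] + 1;
      dist(i, j) = std::sqrt(d2[ord[j]]);
    }
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

static inline int64_t grid_key(int bx, int by) {
  return (static_cast<int64_t>(bx) << 32) ^ static_cast<uint32_t>(by);
}

typedef std::unordered_map<int64_t, std::vector<int> > Grid;

static Grid build_grid(const NumericVector& x, const NumericVector& y,
                       double cell) {
  Grid g;
  g.reserve(x.size());
  for (int i = 0; i < x.size(); ++i) {
    const int bx = (int)std::floor(x[i] / cell);
    const int by = (int)std::floor(y[i] / cell);
    g[grid_key(bx, by)].push_back(i);
  }
  return g;
}

// Counts of unordered within-radius pairs for every (type, type) combination
// in a single 2D point set. type: 0-based integer type codes, ntypes total.
// Returns an ntypes x ntypes matrix, filled on and above the diagonal
// (row <= col after sorting each pair's type codes). Distance <= r counts.
// Points in different sections must be pre-separated by a large coordinate
// offset before calling.
// [[Rcpp::export]]
NumericMatrix cross_type_pair_counts(NumericVector x, NumericVector y,
                                     IntegerVector type, int ntypes,
                                     double r) {
  const int n = x.size();
  NumericMatrix out(ntypes, ntypes);
  if (n == 0) return out;
  const double r2 = r * r;
  Grid g = build_grid(x, y, r);
  for (int i = 0; i < n; ++i) {
    const int bx = (int)std::floor(x[i] / r);
    const int by = (int)std::floor(y[i] / r);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        Grid::const_iterator it = g.find(grid_key(bx + dx, by + dy));
        if (it == g.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          const double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= r2) {
            int a = type[i], b = type[j];
            if (a > b) std::swap(a, b);
            out(a, b) += 1.0;
          }
        }
      }
    }
  }
  return out;
}

// All cross-set pairs (i from set 1, j from set 2) with distance <= r.
// Returns a 2-column 1-based index matrix. Sections must be pre-offset.
// [[Rcpp::export]]
IntegerMatrix pairs_within_radius(NumericVector x1, NumericVector y1,
                                  NumericVector x2, NumericVector y2,
                                  double r) {
  const int n1 = x1.size();
  std::vector<int> ai, bj;
  if (n1 > 0 && x2.size() > 0) {
    const double r2 = r * r;
    Grid g = build_grid(x2, y2, r);
    for (int i = 0; i < n1; ++i) {
      const int bx = (int)std::floor(x1[i] / r);
      const int by = (int)std::floor(y1[i] / r);
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          Grid::const_iterator it = g.find(grid_key(bx + dx, by + dy));
          if (it == g.end()) continue;
          for (int j : it->second) {
            const double ddx = x1[i] - x2[j], ddy = y1[i] - y2[j];
            if (ddx * ddx + ddy * ddy <= r2) {
              ai.push_back(i + 1);
              bj.push_back(j + 1);
            }
          }
        }
      }
    }
  }
  IntegerMatrix out(ai.size(), 2);
  for (size_t p = 0; p < ai.size(); ++p) {
    out(p, 0) = ai[p];
    out(p, 1) = bj[p];
  }
  return out;
}
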