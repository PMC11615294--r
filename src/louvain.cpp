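// Generic Louvain over a dense symmetric quality matrix, plus fast
// variation-of-information helpers used by the Markov-time scale scan.
//
// The quality of a partition is sum_{u,v: c_u == c_v} Q[u,v], diagonal
// included. Q may contain negative entries (it is a stability matrix,
// not an adjacency matrix), so the usual sparse-graph Louvain shortcuts
// do not apply; node moves are evaluated by scanning dense rows.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  int unif(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

// One Louvain level: greedy node moves on dense Q (row-major, n x n).
// memb holds community labels in [0, n). Returns true if any move was made.
bool moveNodes(const std::vector<double>& Q, int n, std::vector<int>& memb,
               XorShift64& rng, double tol) {
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rng.unif(i + 1)]);

  std::vector<double> s(n);
  bool any = false, improved = true;
  int sweeps = 0;
  while (improved && sweeps < 200) {
    improved = false;
    ++sweeps;
    for (int oi = 0; oi < n; ++oi) {
      const int u = order[oi];
      const int cu = memb[u];
      std::fill(s.begin(), s.end(), 0.0);
      const double* qrow = &Q[static_cast<size_t>(u) * n];
      for (int v = 0; v < n; ++v)
        if (v != u) s[memb[v]] += qrow[v];
      // Moving u to community c changes quality by 2*(s[c] - s[cu]);
      // an unused label c has s[c] == 0 and represents a fresh singleton.
      double best = s[cu];
      int bestc = cu;
      for (int c = 0; c < n; ++c)
        if (s[c] > best + tol) { best = s[c]; bestc = c; }
      if (bestc != cu) {
        memb[u] = bestc;
        improved = true;
        any = true;
      }
    }
  }
  return any;
}

// Relabel memb to 0..k-1 (by ascending old label); returns k.
int compact(std::vector<int>& memb) {
  std::vector<int> lab(memb);
  std::sort(lab.begin(), lab.end());
  lab.erase(std::unique(lab.begin(), lab.end()), lab.end());
  std::vector<int> map(memb.empty() ? 0 : *std::max_element(memb.begin(), memb.end()) + 1, -1);
  for (size_t i = 0; i < lab.size(); ++i) map[lab[i]] = static_cast<int>(i);
  for (size_t i = 0; i < memb.size(); ++i) memb[i] = map[memb[i]];
  return static_cast<int>(lab.size());
}

// Full multi-level Louvain for one run. Returns final membership of the
// original nodes and writes the achieved quality (within-community sum of
// Q, diagonal included) to *quality.
std::vector<int> louvainRun(const std::vector<double>& Q0, int n0,
                            uint64_t seed, double tol, double* quality) {
  std::vector<double> Q(Q0);
  int n = n0;
  std::vector<int> global(n0);
  for (int i = 0; i < n0; ++i) global[i] = i;
  XorShift64 rng(seed);

  for (int level = 0; level < 64; ++level) {
    std::vector<int> memb(n);
    for (int i = 0; i < n; ++i) memb[i] = i;
    moveNodes(Q, n, memb, rng, tol);
    const int k = compact(memb);
    for (int i = 0; i < n0; ++i) global[i] = memb[global[i]];
    if (k == n) break; // no merges: converged
    // Aggregate Q into k x k community-block sums.
    std::vector<double> Qa(static_cast<size_t>(k) * k, 0.0);
    for (int u = 0; u < n; ++u) {
      const double* qrow = &Q[static_cast<size_t>(u) * n];
      double* arow = &Qa[static_cast<size_t>(memb[u]) * k];
      for (int v = 0; v < n; ++v) arow[memb[v]] += qrow[v];
    }
    Q.swap(Qa);
    n = k;
  }
  // Quality = sum of diagonal blocks of the final aggregated matrix.
  double q = 0.0;
  for (int c = 0; c < n; ++c) q += Q[static_cast<size_t>(c) * n + c];
  *quality = q;
  return global;
}

double viFromMemberships(const int* a, const int* b, int n) {
  int ka = 0, kb = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] + 1 > ka) ka = a[i] + 1;
    if (b[i] + 1 > kb) kb = b[i] + 1;
  }
  std::vector<double> joint(static_cast<size_t>(ka) * kb, 0.0);
  std::vector<double> pa(ka, 0.0), pb(kb, 0.0);
  const double inv = 1.0 / n;
  for (int i = 0; i < n; ++i) {
    joint[static_cast<size_t>(a[i]) * kb + b[i]] += inv;
    pa[a[i]] += inv;
    pb[b[i]] += inv;
  }
  double vi = 0.0;
  for (int i = 0; i < ka; ++i)
    for (int j = 0; j < kb; ++j) {
      const double r = joint[static_cast<size_t>(i) * kb + j];
      if (r > 0.0)
        vi -= r * (std::log(r / pa[i]) + std::log(r / pb[j]));
    }
  return std::max(vi, 0.0);
}

} // namespace

// [[Rcpp::export(name = ".louvainEnsembleCpp")]]
List louvainEnsembleCpp(NumericMatrix Q, int nRuns, double seed) {
  const int n = Q.nrow();
  if (Q.ncol() != n) stop("quality matrix must be square");
  std::vector<double> Qv(static_cast<size_t>(n) * n);
  double qmax = 0.0;
  for (int u = 0; u < n; ++u)
    for (int v = 0; v < n; ++v) {
      const double val = Q(u, v);
      Qv[static_cast<size_t>(u) * n + v] = val;
      if (std::fabs(val) > qmax) qmax = std::fabs(val);
    }
  // move tolerance scales with the magnitude of the quality matrix so that
  // deep-decay (tiny-Q) scales are not merged on floating-point noise
  const double tol = 1e-12 * std::max(qmax, 1e-300);

  IntegerMatrix memb(n, nRuns);
  NumericVector qual(nRuns);
  const uint64_t base = static_cast<uint64_t>(seed);
  for (int r = 0; r < nRuns; ++r) {
    double q;
    std::vector<int> m =
        louvainRun(Qv, n, base * 0x100000001B3ULL + 0x9E3779B9ULL * (r + 1), tol, &q);
    for (int i = 0; i < n; ++i) memb(i, r) = m[i];
    qual[r] = q;
  }
  return List::create(_["memberships"] = memb, _["quality"] = qual);
}

// [[Rcpp::export(name = ".viCpp")]]
double viCpp(IntegerVector a, IntegerVector b) {
  const int n = a.size();
  if (b.size() != n) stop("partitions must cover the same cells");
  // relabel to dense 0-based ids
  std::vector<int> av(n), bv(n);
  {
    std::vector<int> ua(a.begin(), a.end()), ub(b.begin(), b.end());
    std::sort(ua.begin(), ua.end());
    ua.erase(std::unique(ua.begin(), ua.end()), ua.end());
    std::sort(ub.begin(), ub.end());
    ub.erase(std::unique(ub.begin(), ub.end()), ub.end());
    for (int i = 0; i < n; ++i) {
      av[i] = static_cast<int>(std::lower_bound(ua.begin(), ua.end(), a[i]) - ua.begin());
      bv[i] = static_cast<int>(std::lower_bound(ub.begin(), ub.end(), b[i]) - ub.begin());
    }
  }
  return viFromMemberships(av.data(), bv.data(), n);
}

// Mean VI over all ordered pairs of columns (the m*m average, diagonal
// zeros included), matching VI_g = (1/m^2) sum_{i,j} VI(P_i, P_j).
// [[Rcpp::export(name = ".viEnsembleMeanCpp")]]
double viEnsembleMeanCpp(IntegerMatrix memb) {
  const int n = memb.nrow(), m = memb.ncol();
  std::vector<std::vector<int>> cols(m, std::vector<int>(n));
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) cols[j][i] = memb(i, j);
    std::vector<int> tmp(cols[j]);
    std::sort(tmp.begin(), tmp.end());
    tmp.erase(std::unique(tmp.begin(), tmp.end()), tmp.end());
    for (int i = 0; i < n; ++i)
      cols[j][i] = static_cast<int>(
          std::lower_bound(tmp.begin(), tmp.end(), cols[j][i]) - tmp.begin());
  }
  double total = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j)
      total += viFromMemberships(cols[i].data(), cols[j].data(), n);
  return 2.0 * total / (static_cast<double>(m) * m);
}
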