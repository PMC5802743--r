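// Candidate scoring kernel for the maximum-likelihood source locators.
//
// For each candidate source s: build the BFS tree rooted at s (frontier
// processed in ascending vertex id, so each node's parent is its
// smallest-id neighbor at the previous depth), derive the deterministic
// delay vector from tree depths and the delay covariance from shared tree
// edges between observer paths, then evaluate the Gaussian (or linearized)
// log-score. The full PTVA-LI scan evaluates this for every node, which is
// why this lives in C++ with in-place LAPACK factorizations: the
// per-candidate cost is O(E + K^2 D + K^3) and the Cholesky dominates at
// realistic observer counts.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static void bfs_levels(int n, const int* ptr, const int* idx, int root,
                       std::vector<int>& parent, std::vector<int>& depth) {
  std::fill(parent.begin(), parent.end(), -1);
  std::fill(depth.begin(), depth.end(), -1);
  depth[root] = 0;
  std::vector<int> level, nxt;
  level.push_back(root);
  int d = 0;
  while (!level.empty()) {
    std::sort(level.begin(), level.end());
    nxt.clear();
    for (size_t li = 0; li < level.size(); ++li) {
      int u = level[li];
      for (int j = ptr[u]; j < ptr[u + 1]; ++j) {
        int w = idx[j];
        if (depth[w] < 0) {
          depth[w] = d + 1;
          parent[w] = u;
          nxt.push_back(w);
        }
      }
    }
    level.swap(nxt);
    ++d;
  }
}

// length of the common prefix of two root->observer paths; the prefix ends
// at the LCA, so tree distance = depth_i + depth_k - 2 * (prefix - 1)
static inline int common_prefix(const std::vector<int>& a,
                                const std::vector<int>& b) {
  size_t L = 0, lim = std::min(a.size(), b.size());
  while (L < lim && a[L] == b[L]) ++L;
  return static_cast<int>(L);
}

// [[Rcpp::export]]
NumericVector score_candidates_cpp(IntegerVector ptr, IntegerVector idx,
                                   int n, IntegerVector candidates,
                                   IntegerVector observers, NumericVector d,
                                   double mu, double sigma2, bool gaussian) {
  const int K = observers.size();
  const int m = K - 1;
  if (d.size() != m) stop("delay vector length must be K - 1");
  const int nc = candidates.size();
  NumericVector out(nc);

  std::vector<int> parent(n), depth(n);
  std::vector< std::vector<int> > paths(K);
  std::vector<double> lambda(m * m), fact(m * m), mus(m), dT1(K);
  std::vector<double> z(m), z2(m);
  const int inc = 1;

  for (int c = 0; c < nc; ++c) {
    int s = candidates[c];
    if (s < 0 || s >= n) stop("candidate out of range");
    bfs_levels(n, ptr.begin(), idx.begin(), s, parent, depth);

    bool reachable = true;
    for (int k = 0; k < K; ++k) {
      if (depth[observers[k]] < 0) { reachable = false; break; }
    }
    if (!reachable) { out[c] = R_NegInf; continue; }

    for (int k = 0; k < K; ++k) {
      paths[k].clear();
      int v = observers[k];
      while (v >= 0) { paths[k].push_back(v); v = parent[v]; }
      std::reverse(paths[k].begin(), paths[k].end());
    }

    const int d1 = depth[observers[0]];
    for (int k = 0; k < K; ++k) {
      dT1[k] = d1 + depth[observers[k]] - 2.0 * (common_prefix(paths[0], paths[k]) - 1);
    }
    // upper triangle of the covariance, column-major: entry (i-1, k-1),
    // i <= k, is sigma2 * (shared edges of tree paths o1->o_i and o1->o_k)
    for (int k = 1; k < K; ++k) {
      mus[k - 1] = mu * (depth[observers[k]] - d1);
      for (int i = 1; i <= k; ++i) {
        double dTik = (i == k) ? 0.0
          : depth[observers[i]] + depth[observers[k]] -
            2.0 * (common_prefix(paths[i], paths[k]) - 1);
        lambda[(k - 1) * m + (i - 1)] = sigma2 * 0.5 * (dT1[i] + dT1[k] - dTik);
      }
    }

    std::copy(lambda.begin(), lambda.end(), fact.begin());
    int info = 0;
    F77_CALL(dpotrf)("U", &m, fact.data(), &m, &info FCONE);
    if (info != 0) {
      std::copy(lambda.begin(), lambda.end(), fact.begin());
      for (int i = 0; i < m; ++i) fact[i * m + i] += 1e-8 * sigma2;
      F77_CALL(dpotrf)("U", &m, fact.data(), &m, &info FCONE);
      if (info != 0) { out[c] = R_NegInf; continue; }
    }

    if (gaussian) {
      double logdet_half = 0.0;
      for (int i = 0; i < m; ++i) logdet_half += std::log(fact[i * m + i]);
      for (int i = 0; i < m; ++i) z[i] = d[i] - mus[i];
      // z := R^{-T} (d - mu_s), so |z|^2 is the Mahalanobis quadratic
      F77_CALL(dtrsv)("U", "T", "N", &m, fact.data(), &m, z.data(), &inc
                      FCONE FCONE FCONE);
      double quad = F77_CALL(ddot)(&m, z.data(), &inc, z.data(), &inc);
      out[c] = -logdet_half - 0.5 * quad;
    } else {
      for (int i = 0; i < m; ++i) {
        z[i] = mus[i];
        z2[i] = d[i] - 0.5 * mus[i];
      }
      F77_CALL(dtrsv)("U", "T", "N", &m, fact.data(), &m, z.data(), &inc
                      FCONE FCONE FCONE);
      F77_CALL(dtrsv)("U", "T", "N", &m, fact.data(), &m, z2.data(), &inc
                      FCONE FCONE FCONE);
      out[c] = F77_CALL(ddot)(&m, z.data(), &inc, z2.data(), &inc);
    }
  }
  return out;
}
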