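#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Swap-based maximisation of the mean genomic relationship within groups.
//
// G: relationship block over the n = n_a*n_g + n_surplus candidate animals.
// Scored groups are 0..n_g-1 (size n_a each); when n_surplus > 0 an extra
// unscored pool (index n_g) holds the surplus animals and takes part in
// exchanges, with groups sampled proportional to their size. Each round
// starts from a fresh random assignment and ends after `threshold`
// consecutive non-improving proposals; a failed animal pair is excluded
// from re-proposal until any swap is accepted. The best assignment over
// all rounds is returned (group 0 = surplus pool in the output).
// [[Rcpp::export]]
List supervised_cluster_cpp(NumericMatrix G, int n_a, int n_g,
                            int n_surplus, int rounds, int threshold) {
  const int n = G.nrow();
  if (G.ncol() != n) stop("G block must be square");
  if (n != n_a * n_g + n_surplus)
    stop("G block order (%d) != n_a*n_g + n_surplus (%d)",
         n, n_a * n_g + n_surplus);
  if (n_g < 2) stop("need at least two groups");
  const bool has_sur = n_surplus > 0;
  const int n_groups = n_g + (has_sur ? 1 : 0);
  const double n_pairs = (double)n_g * n_a * (n_a - 1) / 2.0;
  const double eps = 1e-12;
  const double* g = G.begin();

  std::vector<int> group_of(n), best_group(n), perm(n);
  std::vector<std::vector<int>> members((size_t)n_groups);
  std::unordered_set<long long> tabu;
  tabu.reserve(256);
  double bestS = R_NegInf;

  for (int r = 0; r < rounds; ++r) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i)
      std::swap(perm[i], perm[runif_int(i + 1)]);
    for (int gr = 0; gr < n_groups; ++gr) members[gr].clear();
    for (int i = 0; i < n; ++i) {
      int gr = (i < n_a * n_g) ? i / n_a : n_g;
      group_of[perm[i]] = gr;
      members[gr].push_back(perm[i]);
    }
    double S = 0.0;
    for (int gr = 0; gr < n_g; ++gr)
      for (int u = 1; u < n_a; ++u)
        for (int v = 0; v < u; ++v)
          S += g[members[gr][u] + (size_t)n * members[gr][v]];

    int fails = 0;
    long tabu_draws = 0;
    tabu.clear();
    while (fails < threshold) {
      int g1, g2;
      if (has_sur) {
        // sample two distinct groups with probability ~ group size
        int r1 = runif_int(n);
        g1 = (r1 < n_a * n_g) ? r1 / n_a : n_g;
        int sz1 = (int)members[g1].size();
        int r2 = runif_int(n - sz1);
        g2 = -1;
        for (int gr = 0; gr < n_groups; ++gr) {
          if (gr == g1) continue;
          int sz = (int)members[gr].size();
          if (r2 < sz) { g2 = gr; break; }
          r2 -= sz;
        }
      } else {
        g1 = runif_int(n_g);
        g2 = runif_int(n_g - 1);
        if (g2 >= g1) ++g2;
      }
      int ia = runif_int((int)members[g1].size());
      int ib = runif_int((int)members[g2].size());
      int a = members[g1][ia], b = members[g2][ib];
      long long key = (long long)std::min(a, b) * n + std::max(a, b);
      if (tabu.count(key)) {
        if (++tabu_draws > 200000) break;  // landscape exhausted
        continue;
      }
      double delta = 0.0;
      if (g1 < n_g) {
        const std::vector<int>& m1 = members[g1];
        for (size_t u = 0; u < m1.size(); ++u) {
          if (m1[u] == a) continue;
          delta += g[b + (size_t)n * m1[u]] - g[a + (size_t)n * m1[u]];
        }
      }
      if (g2 < n_g) {
        const std::vector<int>& m2 = members[g2];
        for (size_t u = 0; u < m2.size(); ++u) {
          if (m2[u] == b) continue;
          delta += g[a + (size_t)n * m2[u]] - g[b + (size_t)n * m2[u]];
        }
      }
      if (delta > eps) {
        members[g1][ia] = b;
        members[g2][ib] = a;
        group_of[a] = g2;
        group_of[b] = g1;
        S += delta;
        fails = 0;
        tabu.clear();
      } else {
        ++fails;
        tabu.insert(key);
      }
    }
    if (S > bestS) {
      bestS = S;
      best_group = group_of;
    }
  }

  IntegerVector grp(n);
  for (int i = 0; i < n; ++i)
    grp[i] = (best_group[i] >= n_g) ? 0 : best_group[i] + 1;
  return List::create(_["group"] = grp, _["objective"] = bestS / n_pairs);
}
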