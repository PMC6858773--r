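#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Haplotypes are stored as raw matrices: one row per locus, two columns per
// individual (maternal/paternal haplotype), alleles coded 0/1. Loci must be
// sorted by chromosome then position; chr_first/chr_last give the 0-based
// inclusive locus index range of each chromosome (first > last when empty).

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// One meiosis under the Haldane model: crossover count per chromosome is
// Poisson(length in Morgans), crossover positions uniform, no interference;
// chromosomes segregate independently.
static void meiose(const Rbyte* h1, const Rbyte* h2, Rbyte* out,
                   const double* pos,
                   const int* chr_first, const int* chr_last,
                   const double* chr_len, int n_chr) {
  for (int c = 0; c < n_chr; ++c) {
    int a = chr_first[c], b = chr_last[c];
    if (a > b) continue;
    int cur = (unif_rand() < 0.5) ? 1 : 0;
    int nco = (int) R::rpois(chr_len[c] / 100.0);
    if (nco == 0) {
      const Rbyte* h = cur ? h2 : h1;
      std::copy(h + a, h + b + 1, out + a);
      continue;
    }
    std::vector<double> xo((size_t)nco);
    for (int k = 0; k < nco; ++k) xo[k] = unif_rand() * chr_len[c];
    std::sort(xo.begin(), xo.end());
    int k = 0;
    for (int j = a; j <= b; ++j) {
      while (k < nco && xo[k] <= pos[j]) { cur ^= 1; ++k; }
      out[j] = cur ? h2[j] : h1[j];
    }
  }
}

// Gametes for a vector of parents (1-based column-pair indices into haps).
// [[Rcpp::export]]
RawMatrix gametes_cpp(RawMatrix haps, IntegerVector parent,
                      NumericVector pos, IntegerVector chr_first,
                      IntegerVector chr_last, NumericVector chr_len) {
  const int L = haps.nrow(), n = parent.size(), n_chr = chr_len.size();
  RawMatrix out(L, n);
  const Rbyte* X = haps.begin();
  for (int i = 0; i < n; ++i) {
    size_t p = (size_t)(parent[i] - 1);
    meiose(X + 2 * p * L, X + (2 * p + 1) * L, out.begin() + (size_t)i * L,
           pos.begin(), chr_first.begin(), chr_last.begin(),
           chr_len.begin(), n_chr);
  }
  return out;
}

// Wright-Fisher drift phase: n_ind diploids, random mating with distinct
// parents, candidate loci initialised as independent Bernoulli(0.5) alleles.
// The final generation is expanded to n_out individuals by one extra round
// of random mating of the drift population.
// [[Rcpp::export]]
RawMatrix drift_phase_cpp(int n_ind, int generations, int n_out,
                          NumericVector pos, IntegerVector chr_first,
                          IntegerVector chr_last, NumericVector chr_len) {
  const size_t L = (size_t)pos.size();
  const int n_chr = chr_len.size();
  std::vector<Rbyte> cur(L * 2 * n_ind), nxt(L * 2 * n_ind);
  for (size_t t = 0; t < cur.size(); ++t)
    cur[t] = (unif_rand() < 0.5) ? 1 : 0;
  for (int g = 0; g < generations; ++g) {
    for (int i = 0; i < n_ind; ++i) {
      int p1 = runif_int(n_ind);
      int p2 = runif_int(n_ind - 1);
      if (p2 >= p1) ++p2;
      meiose(&cur[2 * (size_t)p1 * L], &cur[(2 * (size_t)p1 + 1) * L],
             &nxt[2 * (size_t)i * L],
             pos.begin(), chr_first.begin(), chr_last.begin(),
             chr_len.begin(), n_chr);
      meiose(&cur[2 * (size_t)p2 * L], &cur[(2 * (size_t)p2 + 1) * L],
             &nxt[(2 * (size_t)i + 1) * L],
             pos.begin(), chr_first.begin(), chr_last.begin(),
             chr_len.begin(), n_chr);
    }
    std::swap(cur, nxt);
  }
  RawMatrix out((int)L, 2 * n_out);
  for (int i = 0; i < n_out; ++i) {
    int p1 = runif_int(n_ind);
    int p2 = runif_int(n_ind - 1);
    if (p2 >= p1) ++p2;
    meiose(&cur[2 * (size_t)p1 * L], &cur[(2 * (size_t)p1 + 1) * L],
           out.begin() + 2 * (size_t)i * L,
           pos.begin(), chr_first.begin(), chr_last.begin(),
           chr_len.begin(), n_chr);
    meiose(&cur[2 * (size_t)p2 * L], &cur[(2 * (size_t)p2 + 1) * L],
           out.begin() + (2 * (size_t)i + 1) * L,
           pos.begin(), chr_first.begin(), chr_last.begin(),
           chr_len.begin(), n_chr);
  }
  return out;
}
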