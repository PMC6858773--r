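#include <Rcpp.h>
using namespace Rcpp;

// Allele frequency of the "1" allele at the requested loci (1-based indices)
// over all haplotype columns of haps.
// [[Rcpp::export]]
NumericVector freq_cpp(RawMatrix haps, IntegerVector loci) {
  const int H = haps.ncol(), m = loci.size();
  const size_t L = (size_t)haps.nrow();
  std::vector<double> s((size_t)m, 0.0);
  const Rbyte* X = haps.begin();
  for (int h = 0; h < H; ++h) {
    const Rbyte* col = X + (size_t)h * L;
    for (int k = 0; k < m; ++k) s[k] += col[loci[k] - 1];
  }
  NumericVector p(m);
  for (int k = 0; k < m; ++k) p[k] = s[k] / H;
  return p;
}

// Centered dosage matrix, loci in rows and animals in columns, entry =
// dosage - 2 p_j, ready for crossprod() to give MM'.
// [[Rcpp::export]]
NumericMatrix centered_dosage_cpp(RawMatrix haps, IntegerVector animals,
                                  IntegerVector loci, NumericVector p) {
  const int n = animals.size(), m = loci.size();
  const size_t L = (size_t)haps.nrow();
  NumericMatrix out(m, n);
  const Rbyte* X = haps.begin();
  for (int i = 0; i < n; ++i) {
    size_t a = (size_t)(animals[i] - 1);
    const Rbyte* c1 = X + 2 * a * L;
    const Rbyte* c2 = X + (2 * a + 1) * L;
    double* o = out.begin() + (size_t)i * m;
    for (int k = 0; k < m; ++k) {
      int lk = loci[k] - 1;
      o[k] = (double)c1[lk] + (double)c2[lk] - 2.0 * p[k];
    }
  }
  return out;
}

// Raw integer dosages (0/1/2), animals in rows, loci in columns.
// [[Rcpp::export]]
IntegerMatrix dosage_int_cpp(RawMatrix haps, IntegerVector animals,
                             IntegerVector loci) {
  const int n = animals.size(), m = loci.size();
  const size_t L = (size_t)haps.nrow();
  IntegerMatrix out(n, m);
  const Rbyte* X = haps.begin();
  for (int i = 0; i < n; ++i) {
    size_t a = (size_t)(animals[i] - 1);
    const Rbyte* c1 = X + 2 * a * L;
    const Rbyte* c2 = X + (2 * a + 1) * L;
    for (int k = 0; k < m; ++k) {
      int lk = loci[k] - 1;
      out(i, k) = (int)c1[lk] + (int)c2[lk];
    }
  }
  return out;
}
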