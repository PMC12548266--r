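// Optimal-matching edit distance between categorical state sequences:
// full O(nm) dynamic program over substitutions (custom cost matrix) and
// insertions/deletions (constant cost).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// a, b: 0-based state indices into the substitution matrix (sub is the
// flattened k x k cost matrix, row-major by first state).
static double om_core(const std::vector<int>& a, const std::vector<int>& b,
                      const std::vector<double>& sub, int k, double indel) {
  const size_t n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = j * indel;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = i * indel;
    const double* srow = &sub[(size_t)a[i - 1] * k];
    for (size_t j = 1; j <= m; ++j) {
      double d = prev[j - 1] + srow[b[j - 1]];
      double del = prev[j] + indel;
      double ins = cur[j - 1] + indel;
      if (del < d) d = del;
      if (ins < d) d = ins;
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static std::vector<double> flatten(const NumericMatrix& sub) {
  const int k = sub.nrow();
  std::vector<double> f((size_t)k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) f[(size_t)i * k + j] = sub(i, j);
  return f;
}

static std::vector<int> to0(const IntegerVector& x) {
  std::vector<int> v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v[i] = x[i] - 1;
  return v;
}

// [[Rcpp::export]]
double om_raw_c(IntegerVector a, IntegerVector b, NumericMatrix sub,
                double indel) {
  return om_core(to0(a), to0(b), flatten(sub), sub.nrow(), indel);
}

// [[Rcpp::export]]
NumericMatrix om_pairwise_c(List seqs, NumericMatrix sub, double indel,
                            bool normalize) {
  const int n = seqs.size();
  std::vector<std::vector<int> > s(n);
  for (int i = 0; i < n; ++i) s[i] = to0(as<IntegerVector>(seqs[i]));
  const std::vector<double> f = flatten(sub);
  const int k = sub.nrow();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = om_core(s[i], s[j], f, k, indel);
      if (normalize) {
        size_t L = s[i].size() > s[j].size() ? s[i].size() : s[j].size();
        d = L > 0 ? d / (double)L : 0.0;
      }
      out(i, j) = d;
      out(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
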