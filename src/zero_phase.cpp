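#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter; coefficients pre-padded to a
// common length with a[0] = 1.
static void iir_inplace(const double* b, const double* a, int nz,
                        double* x, size_t n) {
  std::vector<double> zv(nz + 1, 0.0);
  double* z = zv.data();
  for (size_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 1; k <= nz; ++k) {
      z[k - 1] = b[k] * xi + z[k] - a[k] * yi;
    }
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering with odd-reflection padding
// of `npad` samples at each end to absorb filter transients.
// [[Rcpp::export(name = ".zp_filter_cpp")]]
NumericVector zp_filter_cpp(NumericVector b, NumericVector a,
                            NumericVector x, int npad) {
  const int n = x.size();
  if (n == 0) return x;
  if (npad > n - 1) npad = n - 1;
  if (npad < 0) npad = 0;
  if (a.size() == 0 || a[0] == 0.0) stop("invalid filter: a[0] must be nonzero");
  const int nz = std::max(b.size(), a.size()) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int k = 0; k < b.size(); ++k) bb[k] = b[k] / a[0];
  for (int k = 0; k < a.size(); ++k) aa[k] = a[k] / a[0];
  std::vector<double> xp(n + 2 * npad);
  for (int i = 0; i < npad; ++i) xp[i] = 2.0 * x[0] - x[npad - i];
  for (int i = 0; i < n; ++i) xp[npad + i] = x[i];
  for (int i = 0; i < npad; ++i) xp[npad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  iir_inplace(bb.data(), aa.data(), nz, xp.data(), xp.size());
  std::reverse(xp.begin(), xp.end());
  iir_inplace(bb.data(), aa.data(), nz, xp.data(), xp.size());
  std::reverse(xp.begin(), xp.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = xp[npad + i];
  return out;
}
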