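#include <Rcpp.h>
using namespace Rcpp;

// Fused scale-dependent step: for every scale, build the Fourier-domain
// daughter wavelet by downsampled lookup into the a0 = 2 mother table and
// multiply it into the signal spectrum in the same pass, so no daughter is
// ever materialized. Column s of the result holds spectrum * daughter(a_s)
// over the full padded grid; the negative-frequency half is zero (analytic
// wavelet). The fractional lookup index (a/2) * k is resolved by linear
// interpolation between the two neighbouring table entries; reads past the
// table end are treated as zero (Gaussian tail).
// [[Rcpp::export]]
ComplexMatrix fcwt_fill_coefs(const ComplexVector& spectrum,
                              const NumericVector& table,
                              const NumericVector& scales) {
  const R_xlen_t K = spectrum.size();
  if (table.size() != K) stop("mother table and spectrum length differ");
  const R_xlen_t half = K / 2;
  const int m = scales.size();
  ComplexMatrix out(K, m);
  for (int s = 0; s < m; ++s) {
    const double half_a = scales[s] * 0.5;
    if (half_a < 1.0) stop("scale below a_min = 2");
    Rcomplex* col = &out(0, s);
    for (R_xlen_t k = 0; k <= half; ++k) {
      const double pos = half_a * static_cast<double>(k);
      const R_xlen_t i0 = static_cast<R_xlen_t>(pos);
      const double frac = pos - static_cast<double>(i0);
      const double lo = (i0 < K) ? table[i0] : 0.0;
      const double hi = (i0 + 1 < K) ? table[i0 + 1] : 0.0;
      const double w = lo + frac * (hi - lo);
      col[k].r = spectrum[k].r * w;
      col[k].i = spectrum[k].i * w;
    }
    for (R_xlen_t k = half + 1; k < K; ++k) { col[k].r = 0.0; col[k].i = 0.0; }
  }
  return out;
}

namespace {

// Divide-and-conquer row sweep for one DP column transition.
// best[i] = max_j prev[j] - penalty * (i - j)^2, arg[i] = leftmost argmax.
// The quadratic transition cost is concave in (i - j), so the leftmost argmax
// is nondecreasing in i and the sweep is O(m log m).
void dc_transition(const std::vector<double>& prev, double penalty,
                   int lo, int hi, int jlo, int jhi,
                   std::vector<double>& best, std::vector<int>& arg) {
  if (lo > hi) return;
  const int mid = (lo + hi) / 2;
  double b = R_NegInf;
  int jb = jlo;
  for (int j = jlo; j <= jhi; ++j) {
    const double d = static_cast<double>(mid - j);
    const double v = prev[j] - penalty * d * d;
    if (v > b) { b = v; jb = j; }
  }
  best[mid] = b;
  arg[mid] = jb;
  dc_transition(prev, penalty, lo, mid - 1, jlo, jb, best, arg);
  dc_transition(prev, penalty, mid + 1, hi, jb, jhi, best, arg);
}

} // namespace

// Optimal ridge path through a power matrix (rows = scale bins, cols = time):
// maximize sum_b power[r(b), b] - penalty * sum_b (r(b+1) - r(b))^2 by dynamic
// programming over rows. Returns 1-based row indices, one per column. Ties are
// broken toward the smaller row index.
// [[Rcpp::export]]
IntegerVector ridge_dp_path(const NumericMatrix& power, double penalty) {
  const int m = power.nrow();
  const int n = power.ncol();
  if (m < 1 || n < 1) stop("empty power matrix");
  if (penalty < 0) stop("penalty must be >= 0");

  std::vector<double> dp(m), best(m);
  std::vector<int> arg(m);
  IntegerMatrix parent(m, n);
  for (int i = 0; i < m; ++i) dp[i] = power(i, 0);

  for (int b = 1; b < n; ++b) {
    dc_transition(dp, penalty, 0, m - 1, 0, m - 1, best, arg);
    for (int i = 0; i < m; ++i) {
      parent(i, b) = arg[i];
      dp[i] = power(i, b) + best[i];
    }
  }

  int r = 0;
  for (int i = 1; i < m; ++i) if (dp[i] > dp[r]) r = i;
  IntegerVector path(n);
  for (int b = n - 1; b >= 0; --b) {
    path[b] = r + 1;
    if (b > 0) r = parent(r, b);
  }
  return path;
}
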