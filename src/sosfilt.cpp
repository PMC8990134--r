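#include <Rcpp.h>
using namespace Rcpp;

// Forward IIR filtering through cascaded biquads (transposed direct form II).
// sos: K x 6 matrix, rows (b0 b1 b2 a0 a1 a2), a0 == 1.
// zi: K x 2 initial conditions (already scaled), modified in place per section.
static void sosfilt_inplace(const NumericMatrix& sos, std::vector<double>& x,
                            std::vector<std::array<double, 2>>& zi) {
  const int K = sos.nrow();
  const size_t n = x.size();
  for (int k = 0; k < K; ++k) {
    const double b0 = sos(k, 0), b1 = sos(k, 1), b2 = sos(k, 2);
    const double a1 = sos(k, 4), a2 = sos(k, 5);
    double z1 = zi[k][0], z2 = zi[k][1];
    for (size_t i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      x[i] = yi;
    }
    zi[k][0] = z1;
    zi[k][1] = z2;
  }
}

// Steady-state (unit step) state vector per biquad, as in lfilter_zi.
static std::vector<std::array<double, 2>> sos_zi(const NumericMatrix& sos,
                                                 double scale) {
  const int K = sos.nrow();
  std::vector<std::array<double, 2>> zi(K);
  double gain = 1.0;  // cumulative DC gain of preceding sections
  for (int k = 0; k < K; ++k) {
    const double b0 = sos(k, 0), b1 = sos(k, 1), b2 = sos(k, 2);
    const double a1 = sos(k, 4), a2 = sos(k, 5);
    const double num = b0 + b1 + b2, den = 1.0 + a1 + a2;
    const double yss = (std::abs(den) > 1e-300) ? num / den : 0.0;
    const double x0 = scale * gain;
    const double z2 = b2 * x0 - a2 * yss * x0;
    const double z1 = b1 * x0 - a1 * yss * x0 + z2;
    zi[k][0] = z1;
    zi[k][1] = z2;
    gain *= yss;
  }
  return zi;
}

// [[Rcpp::export(name = ".sosfiltfilt_cpp")]]
NumericVector sosfiltfilt_cpp(NumericMatrix sos, NumericVector x, int padlen) {
  const int n = x.size();
  if (padlen >= n) padlen = n - 1;
  if (padlen < 0) padlen = 0;
  const int m = n + 2 * padlen;
  std::vector<double> ext(m);
  // odd (antisymmetric) extension about the end points
  for (int i = 0; i < padlen; ++i)
    ext[i] = 2.0 * x[0] - x[padlen - i];
  for (int i = 0; i < n; ++i) ext[padlen + i] = x[i];
  for (int i = 0; i < padlen; ++i)
    ext[padlen + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  auto zi = sos_zi(sos, ext[0]);
  sosfilt_inplace(sos, ext, zi);
  std::reverse(ext.begin(), ext.end());
  zi = sos_zi(sos, ext[0]);
  sosfilt_inplace(sos, ext, zi);
  std::reverse(ext.begin(), ext.end());

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ext[padlen + i];
  return out;
}

// [[Rcpp::export(name = ".sosfilt_cpp")]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  std::vector<std::array<double, 2>> zi(sos.nrow(), {0.0, 0.0});
  sosfilt_inplace(sos, v, zi);
  return NumericVector(v.begin(), v.end());
}
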