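#include <Rcpp.h>
using namespace Rcpp;

// Convolution of a piecewise-linear curve with a decaying exponential:
//   y(t) = int_0^t c(s) * exp(-a * (t - s)) ds
// evaluated at every knot of the curve. The curve is linear between knots
// and zero before the first knot. Exact for the interpolant; the recursion
//   y[i+1] = y[i] * exp(-a*dt) + (segment integral)
// avoids any quadrature error and is unconditionally stable for a >= 0.
// [[Rcpp::export]]
NumericVector conv_plexp(NumericVector time, NumericVector value, double a) {
  int n = time.size();
  if (value.size() != n) stop("time and value lengths differ");
  if (a < 0) stop("exponential rate must be non-negative");
  NumericVector y(n);
  if (n == 0) return y;
  y[0] = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double dt = time[i + 1] - time[i];
    if (dt <= 0) stop("time grid must be strictly increasing");
    double c0 = value[i];
    double c1 = value[i + 1];
    double m = (c1 - c0) / dt;
    double seg;
    if (a == 0.0) {
      seg = 0.5 * (c0 + c1) * dt;
      y[i + 1] = y[i] + seg;
    } else {
      double x = a * dt;
      double E = std::exp(-x);
      // (1 - E)/a, stable for small x
      double g1 = -std::expm1(-x) / a;
      // (dt - (1 - E)/a)/a; series for small x to avoid cancellation
      double g2;
      if (x < 1e-5) {
        g2 = dt * dt * (0.5 - x / 6.0 + x * x / 24.0);
      } else {
        g2 = (dt - g1) / a;
      }
      seg = c0 * g1 + m * g2;
      y[i + 1] = y[i] * E + seg;
    }
  }
  return y;
}
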