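#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-form II transposed IIR filter, forward pass (a[0] assumed 1 after
// normalization here).
static void iir_pass(const std::vector<double> &b,
                     const std::vector<double> &a, std::vector<double> &x) {
  const int nb = b.size(), na = a.size();
  const int nstate = std::max(nb, na) - 1;
  std::vector<double> z(nstate, 0.0);
  for (size_t n = 0; n < x.size(); ++n) {
    double xn = x[n];
    double yn = b[0] * xn + (nstate ? z[0] : 0.0);
    for (int k = 0; k < nstate; ++k) {
      double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
      double ak = (k + 1 < na) ? a[k + 1] : 0.0;
      double znext = (k + 1 < nstate) ? z[k + 1] : 0.0;
      z[k] = bk * xn + znext - ak * yn;
    }
    x[n] = yn;
  }
}

// Zero-phase (forward-backward) IIR filtering with edge reflection
// padding of npad samples on both sides.
// [[Rcpp::export]]
NumericVector iir_filtfilt_cpp(NumericVector x, NumericVector b,
                               NumericVector a, int npad) {
  const int n = x.size();
  if (npad > n - 1) npad = n - 1;
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  for (size_t k = 0; k < bb.size(); ++k) bb[k] /= a[0];
  for (size_t k = 0; k < aa.size(); ++k) aa[k] /= a[0];
  std::vector<double> w(n + 2 * npad);
  // odd reflection around the end points reduces edge transients
  for (int i = 0; i < npad; ++i) {
    w[i] = 2.0 * x[0] - x[npad - i];
  }
  for (int i = 0; i < n; ++i) w[npad + i] = x[i];
  for (int i = 0; i < npad; ++i) {
    w[npad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  }
  iir_pass(bb, aa, w);
  std::reverse(w.begin(), w.end());
  iir_pass(bb, aa, w);
  std::reverse(w.begin(), w.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = w[npad + i];
  return out;
}

// Polyphase rational resampling core: y[m] = sum_k h[k] * u[m*q + k - d]
// where u is x upsampled by zero-stuffing (factor p) and d centres the
// (odd, symmetric) FIR kernel. Only the taps hitting non-zero samples of
// u are visited.
// [[Rcpp::export]]
NumericVector fir_resample_cpp(NumericVector x, NumericVector h, int p,
                               int q, int nout, int offset) {
  const int nh = h.size();
  const int d = (nh - 1) / 2;
  const int nx = x.size();
  NumericVector y(nout);
  for (int m = 0; m < nout; ++m) {
    // index into the zero-stuffed sequence of h[0]
    const long long base = (long long)m * q + offset - d;
    double acc = 0.0;
    // u[base + k] nonzero iff (base + k) % p == 0
    long long r = base % p;
    if (r < 0) r += p;
    int k0 = (int)((p - r) % p);
    for (int k = k0; k < nh; k += p) {
      long long j = (base + k) / p;
      if (j >= 0 && j < nx) acc += h[k] * x[j];
    }
    y[m] = acc;
  }
  return y;
}
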