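#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Accumulate |windowed sliding DFT|^2 over all window positions.
//
// Uk0:  (nbins+1) x ncol complex matrix, bins 0..nbins of the L-point DFT of
//       the FIRST window of each column (unwindowed).
// X:    full time series, nrow >= L, one column per signal.
// L:    window length; hop: window start increment; K: number of windows.
// taps: frequency-domain window taps (c0, c1): w[n] = c0 + 2*c1*cos(2*pi*n/L)
//       (c1 = 0 gives a rectangular window).
//
// Returns nbins x ncol real matrix of sums over windows of |Y_w(k)|^2 for
// bins k = 0..nbins-1. The unit-shift recursion
//   U_k(s+1) = (U_k(s) - x[s] + x[s+L]) * exp(2*pi*i*k/L)
// is exact; windowing is applied in the frequency domain:
//   Y_w(k) = c0*U(k) + c1*(U(k-1) + U(k+1)),  U(-1) = conj(U(1)) for real x.
// [[Rcpp::export(name = ".welch_accum")]]
NumericMatrix welch_accum(ComplexMatrix Uk0, NumericMatrix X,
                          int L, int hop, int K, NumericVector taps) {
  const int nb1 = Uk0.nrow();      // nbins + 1
  const int nb = nb1 - 1;
  const int nc = Uk0.ncol();
  const double c0 = taps[0], c1 = taps[1];

  std::vector<std::complex<double> > ph(nb1);
  for (int k = 0; k < nb1; ++k) {
    double a = 2.0 * M_PI * k / L;
    ph[k] = std::complex<double>(std::cos(a), std::sin(a));
  }

  NumericMatrix out(nb, nc);
  std::vector<std::complex<double> > U(nb1);

  for (int c = 0; c < nc; ++c) {
    for (int k = 0; k < nb1; ++k) {
      Rcomplex z = Uk0(k, c);
      U[k] = std::complex<double>(z.r, z.i);
    }
    double *acc = &out(0, c);
    const double *x = &X(0, c);
    int s = 0;                      // current window start (0-based)
    for (int win = 0; win < K; ++win) {
      if (win > 0) {
        for (int step = 0; step < hop; ++step) {
          double d = x[s + L] - x[s];
          for (int k = 0; k < nb1; ++k) U[k] = (U[k] + d) * ph[k];
          ++s;
        }
      }
      // bin 0: U(-1) = conj(U(1))
      {
        std::complex<double> y = c0 * U[0] + c1 * (std::conj(U[1]) + U[1]);
        acc[0] += std::norm(y);
      }
      for (int k = 1; k < nb; ++k) {
        std::complex<double> y = c0 * U[k] + c1 * (U[k - 1] + U[k + 1]);
        acc[k] += std::norm(y);
      }
    }
  }
  return out;
}
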