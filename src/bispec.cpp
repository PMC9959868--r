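#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate the bispectrum S(k1,k2) = F(k1) F(k2) conj(F(k1+k2)) along the
// lines k2 = a*k1, a = s/n_slopes (s = 1..n_slopes), over grid frequencies
// 0 < k1 <= 1/(1+a) with the Nyquist frequency normalised to 1 (grid index
// N/2). S is interpolated linearly between bracketing grid k2 values, i.e.
// each contribution is a convex combination of two all-grid bispectrum
// values, which keeps the integral exactly invariant under circular shifts
// of the length-N signal. Complex products are expanded into real/imaginary
// arithmetic (the throughput-critical kernel of feature extraction).
// [[Rcpp::export]]
ComplexVector bispec_line_integrals(ComplexVector F, int n_slopes) {
  const int N = F.size();
  const int half = N / 2;
  std::vector<double> fr(N), fi(N);
  for (int i = 0; i < N; ++i) { fr[i] = F[i].r; fi[i] = F[i].i; }

  ComplexVector out(n_slopes);
  for (int s = 1; s <= n_slopes; ++s) {
    const double a = double(s) / double(n_slopes);
    const int jmax = int(std::floor(double(half) / (1.0 + a) + 1e-12));
    double acc_r = 0.0, acc_i = 0.0;
    for (int j1 = 1; j1 <= jmax; ++j1) {
      const double k2 = a * j1;
      const int j2 = int(k2);
      const double w = k2 - j2;
      const double ar = fr[j1], ai = fi[j1];

      // (1-w) * F(j1) F(j2) conj(F(j1+j2))
      {
        const double br = fr[j2], bi = fi[j2];
        const double cr = fr[j1 + j2], ci = -fi[j1 + j2];
        const double abr = ar * br - ai * bi;
        const double abi = ar * bi + ai * br;
        acc_r += (1.0 - w) * (abr * cr - abi * ci);
        acc_i += (1.0 - w) * (abr * ci + abi * cr);
      }
      if (w > 0.0) {
        const double br = fr[j2 + 1], bi = fi[j2 + 1];
        const double cr = fr[j1 + j2 + 1], ci = -fi[j1 + j2 + 1];
        const double abr = ar * br - ai * bi;
        const double abi = ar * bi + ai * br;
        acc_r += w * (abr * cr - abi * ci);
        acc_i += w * (abr * ci + abi * cr);
      }
    }
    out[s - 1].r = acc_r;
    out[s - 1].i = acc_i;
  }
  return out;
}
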