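#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

typedef std::complex<double> cplx;

// exp(z) avoiding the full complex routine when z is purely real or purely
// imaginary — with real SLDs the wave vectors are one or the other, so
// every exponent below falls in one of the cheap branches.
static inline cplx cexp_fast(const cplx& z) {
  if (z.imag() == 0.0) return cplx(std::exp(z.real()), 0.0);
  if (z.real() == 0.0) return cplx(std::cos(z.imag()), std::sin(z.imag()));
  return std::exp(z);
}

// Specular reflectivity of a stratified medium by the Parratt recursion,
// evaluated bottom-up from the backing medium for numerical stability.
//
// q     : wave-vector transfer values (A^-1)
// rho   : layer SLDs in true A^-2 units, length nl >= 2, rho[0] = fronting,
//         rho[nl-1] = backing
// d     : layer thicknesses (A); d[0] and d[nl-1] are ignored
// sigma : interfacial roughness (A), length nl-1; sigma[i] belongs to the
//         interface between layer i and layer i+1 (Nevot-Croce damping of
//         the Fresnel coefficient)
//
// The wave vector inside layer j is k_j = sqrt((q/2)^2 - 4 pi (rho_j -
// rho_0)); the branch with nonnegative imaginary part is taken so that
// evanescent waves decay below the critical edge.
// [[Rcpp::export]]
NumericVector parratt_kernel(NumericVector q, NumericVector rho,
                             NumericVector d, NumericVector sigma) {
  const int nq = q.size();
  const int nl = rho.size();
  if (nl < 2) stop("need at least fronting and backing media");
  if (d.size() != nl) stop("d must have one entry per layer");
  if (sigma.size() != nl - 1) stop("sigma must have one entry per interface");

  // 4 pi (rho_j - rho_0), hoisted out of the Q loop
  std::vector<double> c4(nl);
  for (int j = 0; j < nl; ++j) c4[j] = 4.0 * M_PI * (rho[j] - rho[0]);

  NumericVector R(nq);
  std::vector<cplx> k(nl);

  for (int iq = 0; iq < nq; ++iq) {
    const double k0 = q[iq] / 2.0;
    const double k0sq = k0 * k0;
    for (int j = 0; j < nl; ++j) {
      const double a = k0sq - c4[j];
      k[j] = (a >= 0.0) ? cplx(std::sqrt(a), 0.0)
                        : cplx(0.0, std::sqrt(-a));
    }
    cplx Rj(0.0, 0.0);  // no wave returns from the backing
    for (int j = nl - 2; j >= 0; --j) {
      const cplx num = k[j] - k[j + 1];
      const cplx den = k[j] + k[j + 1];
      cplx rj(0.0, 0.0);
      if (num != cplx(0.0, 0.0)) {
        rj = num / den;
        if (sigma[j] > 0.0)
          rj *= cexp_fast(-2.0 * k[j] * k[j + 1] * sigma[j] * sigma[j]);
      }
      cplx phased = Rj;
      if (j + 1 <= nl - 2 && phased != cplx(0.0, 0.0) && d[j + 1] > 0.0)
        phased *= cexp_fast(cplx(0.0, 2.0) * k[j + 1] * d[j + 1]);
      Rj = (rj + phased) / (1.0 + rj * phased);
    }
    double RR = std::norm(Rj);
    if (RR > 1.0) RR = 1.0;
    R[iq] = RR;
  }
  return R;
}
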