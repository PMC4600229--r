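#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cd;

// Exact specular reflectivity of a slab stack by the Abeles characteristic-
// matrix method, with Nevot-Croce Gaussian roughness damping on every
// interface amplitude.  SLDs are real (absorption neglected) and given in
// 1e-6 A^-2; q in A^-1; thickness/roughness in A.
//
// Media are indexed 0..n+1 (0 = fronting, n+1 = backing).  sigma[j] is the
// roughness of the interface between media j and j+1 (j = 0..n), i.e. each
// layer's top interface followed by the backing interface.
// [[Rcpp::export]]
NumericVector abeles_cpp(NumericVector q,
                         NumericVector d,
                         NumericVector rho,
                         NumericVector sigma,
                         double rho_front,
                         double rho_back) {
  const int nq = q.size();
  const int nl = d.size();
  if (rho.size() != nl)
    stop("rho and d must have equal length");
  if (sigma.size() != nl + 1)
    stop("sigma must have length n_layers + 1");

  std::vector<double> rhos(nl + 2);
  rhos[0] = rho_front * 1e-6;
  for (int j = 0; j < nl; ++j) rhos[j + 1] = rho[j] * 1e-6;
  rhos[nl + 1] = rho_back * 1e-6;

  NumericVector out(nq);
  std::vector<cd> kz(nl + 2);
  const cd I(0.0, 1.0);

  for (int i = 0; i < nq; ++i) {
    const double k02 = q[i] * q[i] / 4.0;
    for (int j = 0; j < nl + 2; ++j) {
      const double arg = k02 - 4.0 * M_PI * (rhos[j] - rhos[0]);
      kz[j] = arg >= 0.0 ? cd(std::sqrt(arg), 0.0) : cd(0.0, std::sqrt(-arg));
    }

    cd M11(1.0, 0.0), M12(0.0, 0.0), M21(0.0, 0.0), M22(1.0, 0.0);
    for (int j = 0; j <= nl; ++j) {
      const cd den = kz[j] + kz[j + 1];
      cd r(0.0, 0.0);
      if (std::abs(den) > 0.0)
        r = (kz[j] - kz[j + 1]) / den *
            std::exp(-2.0 * kz[j] * kz[j + 1] * sigma[j] * sigma[j]);
      // phase across medium j (the fronting medium carries no phase)
      cd ei(1.0, 0.0);
      if (j > 0 && d[j - 1] > 0.0) ei = std::exp(I * kz[j] * d[j - 1]);
      const cd emi = 1.0 / ei;
      const cd a11 = ei, a12 = r * ei, a21 = r * emi, a22 = emi;
      const cd n11 = M11 * a11 + M12 * a21;
      const cd n12 = M11 * a12 + M12 * a22;
      const cd n21 = M21 * a11 + M22 * a21;
      const cd n22 = M21 * a12 + M22 * a22;
      M11 = n11; M12 = n12; M21 = n21; M22 = n22;
    }
    double R = std::norm(M21 / M11);
    if (R > 1.0) R = 1.0;
    if (R < 0.0) R = 0.0;
    out[i] = R;
  }
  return out;
}
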