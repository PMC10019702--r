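#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Euler-Maruyama integration of the coupled amplitude / angular-frequency
// oscillator network:
//   dz_j = [ (A + i*w_j - |z_j|^2) z_j + G * sum_i C_ij (z_i - z_j) ] dt
//          + beta * dW_j            (complex, independent re/im increments)
//   dw_j = [ w0_j - F * w_j + M * sum_i C_ij arg(z_i) ] dt
// The frequency equation is deterministic; arg() is the principal value.
// Uses R's RNG so results are reproducible through set.seed().
// [[Rcpp::export]]
List simulate_hopf_cpp(NumericMatrix C, ComplexVector z0, NumericVector w0,
                       double A, double G, double F, double M, double beta,
                       double dt, int nSteps, int sampleEvery,
                       int firstSample) {
  const int N = C.nrow();
  if (C.ncol() != N || z0.size() != N || w0.size() != N)
    stop("dimension mismatch between connectome, z0 and omega0");

  std::vector<std::complex<double> > z(N), znew(N);
  std::vector<double> w(N), wnew(N), th(N);
  for (int j = 0; j < N; ++j) {
    z[j] = std::complex<double>(z0[j].r, z0[j].i);
    w[j] = w0[j];
  }

  int nSamples = 0;
  for (int s = firstSample; s <= nSteps; s += sampleEvery) ++nSamples;
  ComplexMatrix zout(N, nSamples);
  NumericMatrix wout(N, nSamples);

  const double sqdt = std::sqrt(dt) * beta;
  RNGScope scope;
  int col = 0;
  for (int s = 1; s <= nSteps; ++s) {
    for (int j = 0; j < N; ++j) th[j] = std::arg(z[j]);
    for (int j = 0; j < N; ++j) {
      std::complex<double> coup(0.0, 0.0);
      double phase = 0.0;
      for (int i = 0; i < N; ++i) {
        const double c = C(j, i);
        if (c != 0.0) {
          coup += c * (z[i] - z[j]);
          phase += c * th[i];
        }
      }
      const double r2 = std::norm(z[j]);
      std::complex<double> drift =
          (std::complex<double>(A - r2, w[j])) * z[j] + G * coup;
      znew[j] = z[j] + dt * drift;
      if (beta > 0.0)
        znew[j] += std::complex<double>(sqdt * norm_rand(),
                                        sqdt * norm_rand());
      wnew[j] = w[j] + dt * (w0[j] - F * w[j] + M * phase);
    }
    z = znew;
    w = wnew;
    bool record = (s >= firstSample) &&
                  ((s - firstSample) % sampleEvery == 0);
    if (record) {
      for (int j = 0; j < N; ++j) {
        if (!std::isfinite(z[j].real()) || !std::isfinite(z[j].imag()) ||
            !std::isfinite(w[j]))
          stop("non-finite state at step %d (region %d); parameters A=%g "
               "G=%g F=%g M=%g", s, j + 1, A, G, F, M);
        Rcomplex rc; rc.r = z[j].real(); rc.i = z[j].imag();
        zout(j, col) = rc;
        wout(j, col) = w[j];
      }
      ++col;
    }
  }
  return List::create(_["z"] = zout, _["omega"] = wout);
}
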