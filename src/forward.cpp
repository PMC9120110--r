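#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Band-limited single-scattering optoacoustic forward model.
// Each absorbing voxel contributes a precomputed bipolar pulse delayed by
// the one-way travel time to the detector, weighted by a depth-dependent
// Gaussian lateral sensitivity and 1/distance spherical spreading. Vertical
// breathing displacement is evaluated at each A-line's acquisition time and
// applied as a rigid translation of the object.
//
// vox: n x 3 voxel centres (um, detector frame: z = depth below detector)
// kern: pulse kernel oversampled by `os`; kc = 0-based index of t = 0
// [[Rcpp::export]]
NumericMatrix forward_simulate_cpp(NumericMatrix vox, NumericVector amp,
                                   NumericVector posx, NumericVector posy,
                                   NumericVector t_acq, int n_samples,
                                   double fs, double c_um_s,
                                   NumericVector kern, int os, int kc,
                                   double m_amp, double m_period,
                                   double m_drift, double m_phase,
                                   double focal, double w0, double zr,
                                   double cutoff) {
  const int nv = vox.nrow(), np = posx.size(), nk = kern.size();
  const int half = nk / os / 2 + 2;
  NumericMatrix out(n_samples, np);
  for (int p = 0; p < np; ++p) {
    double dz = 0.0;
    if (m_amp != 0.0 || m_drift != 0.0)
      dz = m_amp * std::sin(2.0 * M_PI * t_acq[p] / m_period + m_phase) +
           m_drift * t_acq[p];
    const double px = posx[p], py = posy[p];
    for (int v = 0; v < nv; ++v) {
      const double dx = vox(v, 0) - px, dy = vox(v, 1) - py;
      const double z = vox(v, 2) + dz;
      if (z <= 0.0) continue;
      const double rel = (z - focal) / zr;
      const double sig = w0 * std::sqrt(1.0 + rel * rel);
      const double dlat2 = dx * dx + dy * dy;
      const double cut = cutoff * sig;
      if (dlat2 > cut * cut) continue;
      const double d = std::sqrt(dlat2 + z * z);
      const double w = std::exp(-dlat2 / (2.0 * sig * sig));
      const double a = amp[v] * w / (d / 1000.0);
      const double tau = d / c_um_s * fs;  // delay in samples
      const int j0 = std::max(0, (int)std::floor(tau) - half);
      const int j1 = std::min(n_samples - 1, (int)std::ceil(tau) + half);
      for (int j = j0; j <= j1; ++j) {
        const long ki = std::lround((j - tau) * os) + kc;
        if (ki >= 0 && ki < nk) out(j, p) += a * kern[ki];
      }
    }
  }
  return out;
}
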