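#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sensitivity-weighted delay-and-sum beamforming onto a regular voxel
// grid. For each voxel the signal of every scan position within the
// lateral sensitivity support is sampled at the one-way delay
// |voxel - position| / c (linear interpolation in time) and accumulated
// with a Gaussian lateral weight; the sum is normalized by the total
// weight. Voxels with empty support are set to zero and counted.
//
// sig: n_samples x n_positions matrix of (band-passed) A-lines
// gx, gy: lateral voxel-centre coordinates (um)
// gz: voxel-centre depths below the detector plane (um)
// [[Rcpp::export]]
List beamform_cpp(NumericMatrix sig, NumericVector posx, NumericVector posy,
                  NumericVector gx, NumericVector gy, NumericVector gz,
                  double fs, double c_um_s, double focal, double w0,
                  double zr, double cutoff) {
  const int np = posx.size(), ns = sig.nrow();
  const int nx = gx.size(), ny = gy.size(), nz = gz.size();
  NumericVector img(nx * ny * nz);
  int empty = 0;
  for (int k = 0; k < nz; ++k) {
    const double z = gz[k];
    const double rel = (z - focal) / zr;
    const double sgm = w0 * std::sqrt(1.0 + rel * rel);
    const double cut2 = cutoff * sgm * cutoff * sgm;
    const double inv2s2 = 1.0 / (2.0 * sgm * sgm);
    for (int j = 0; j < ny; ++j) {
      const double y = gy[j];
      for (int i = 0; i < nx; ++i) {
        const double x = gx[i];
        double acc = 0.0, wsum = 0.0;
        for (int p = 0; p < np; ++p) {
          const double dx = x - posx[p], dy = y - posy[p];
          const double dlat2 = dx * dx + dy * dy;
          if (dlat2 > cut2) continue;
          const double d = std::sqrt(dlat2 + z * z);
          const double tau = d / c_um_s * fs;
          const int t0 = (int)std::floor(tau);
          if (t0 < 0 || t0 + 1 >= ns) continue;
          const double fr = tau - t0;
          const double s = (1.0 - fr) * sig(t0, p) + fr * sig(t0 + 1, p);
          const double w = std::exp(-dlat2 * inv2s2);
          acc += w * s;
          wsum += w;
        }
        if (wsum > 0.0)
          img[i + nx * (j + (long)ny * k)] = acc / wsum;
        else
          ++empty;
      }
    }
  }
  img.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(_["image"] = img, _["empty_voxels"] = empty);
}
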