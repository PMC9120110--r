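#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of a 3D logical mask (iterative
// flood fill). Returns an integer array of labels, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::vector<long> stack;
  int next = 0;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const long cur = stack.back();
      stack.pop_back();
      const int z = cur / ((long)nx * ny);
      const int rem = cur - (long)z * nx * ny;
      const int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                zz < 0 || zz >= nz) continue;
            const long t = xx + (long)nx * (yy + (long)ny * zz);
            if (mask[t] && lab[t] == 0) {
              lab[t] = next;
              stack.push_back(t);
            }
          }
    }
  }
  return lab;
}
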