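#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate the discretized line integrals behind the Biot-Savart law and
// the magnetic vector potential.  `src` holds sub-segment midpoints (m x 3),
// `dl` the signed sub-segment vectors (m x 3), `pts` the evaluation points
// (n x 3).  Returns n x 3 sums: dl x d / |d|^3 (field) or dl / |d|
// (potential), with d the vector from the source to the evaluation point.
// The mu0*I*w/4pi prefactor is applied on the R side.  Points closer than
// `min_dist` to any source midpoint abort with the offending point index.
// [[Rcpp::export]]
NumericMatrix bs_kernel(NumericMatrix src, NumericMatrix dl,
                        NumericMatrix pts, bool potential, double min_dist) {
  const int m = src.nrow(), n = pts.nrow();
  NumericMatrix out(n, 3);
  const double md2 = min_dist * min_dist;
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double ax = 0.0, ay = 0.0, az = 0.0;
    for (int j = 0; j < m; ++j) {
      const double dx = px - src(j, 0);
      const double dy = py - src(j, 1);
      const double dz = pz - src(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < md2)
        stop("evaluation point %d is within min_distance of the wire", i + 1);
      if (potential) {
        const double inv = 1.0 / std::sqrt(r2);
        ax += dl(j, 0) * inv;
        ay += dl(j, 1) * inv;
        az += dl(j, 2) * inv;
      } else {
        const double inv3 = 1.0 / (r2 * std::sqrt(r2));
        ax += (dl(j, 1) * dz - dl(j, 2) * dy) * inv3;
        ay += (dl(j, 2) * dx - dl(j, 0) * dz) * inv3;
        az += (dl(j, 0) * dy - dl(j, 1) * dx) * inv3;
      }
    }
    out(i, 0) = ax;
    out(i, 1) = ay;
    out(i, 2) = az;
  }
  return out;
}
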