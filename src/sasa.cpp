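// Solvent-accessible surface area by deterministic sphere sampling.
//
// Each bead is expanded by the probe radius; a fixed Fibonacci-lattice
// point set is placed on the expanded sphere and points buried inside any
// neighbouring expanded sphere are discarded.  The accessible area is the
// surviving point fraction times the expanded-sphere area.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector sasa_points_cpp(NumericMatrix pos, NumericVector radius,
                              LogicalVector measure, double probe,
                              int npoints, NumericMatrix frame) {
  int n = pos.nrow();
  if (n == 0) stop("no beads");
  // Fibonacci sphere lattice, oriented by the caller-supplied body frame
  // so the sampling co-rotates with the structure
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npoints; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    double u = r * std::cos(th), v = r * std::sin(th), w = z;
    px[k] = frame(0, 0) * u + frame(0, 1) * v + frame(0, 2) * w;
    py[k] = frame(1, 0) * u + frame(1, 1) * v + frame(1, 2) * w;
    pz[k] = frame(2, 0) * u + frame(2, 1) * v + frame(2, 2) * w;
  }
  NumericVector area(n);
  for (int i = 0; i < n; ++i) {
    area[i] = NA_REAL;
    if (!measure[i]) continue;
    double Ri = radius[i] + probe;
    // neighbours whose expanded sphere can bury points of sphere i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double Rj = radius[j] + probe;
      double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1),
             dz = pos(j, 2) - pos(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double rr = Ri + Rj;
      if (d2 < rr * rr) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double x = pos(i, 0) + Ri * px[k];
      double y = pos(i, 1) + Ri * py[k];
      double z = pos(i, 2) + Ri * pz[k];
      bool buried = false;
      for (int j : nb) {
        double Rj = radius[j] + probe;
        double dx = x - pos(j, 0), dy = y - pos(j, 1), dz = z - pos(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        double R2 = Rj * Rj;
        // points exactly on a coincident surface are kept by the
        // lower-index bead only, so duplicated spheres count once
        if (d2 < R2 * (1 - 1e-12) ||
            (d2 < R2 * (1 + 1e-12) && j < i)) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / npoints;
  }
  return area;
}
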