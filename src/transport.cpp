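#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Piecewise log-log linear interpolation on an increasing table.
// Below the table -> first y; above -> last y.
static inline double interp_loglog(const double *xs, const double *ys,
                                   int n, double x) {
  if (x <= xs[0]) return ys[0];
  if (x >= xs[n - 1]) return ys[n - 1];
  // binary search for the bracketing interval
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (xs[mid] <= x) lo = mid; else hi = mid;
  }
  double t = (std::log(x) - std::log(xs[lo])) /
             (std::log(xs[hi]) - std::log(xs[lo]));
  return std::exp(std::log(ys[lo]) + t * (std::log(ys[hi]) - std::log(ys[lo])));
}

//' Straight-line condensed-history beta transport on a voxel grid.
//'
//' Electrons start inside the central voxel with given energies and isotropic
//' directions and are slowed continuously along straight tracks using a
//' range-energy table for unit-density water-equivalent medium.  Energy is
//' deposited at segment midpoints; once a track leaves the (convex) grid the
//' residual energy is tallied as escaped.  All stochastic input (energies,
//' positions, directions) is sampled in R, so results are a deterministic
//' function of the arguments.
//'
//' @noRd
// [[Rcpp::export]]
List cpp_transport_beta(NumericVector E0,
                        NumericMatrix pos,   // cm, relative to grid centre
                        NumericMatrix dir,   // unit vectors
                        IntegerVector dims,
                        NumericVector vox,   // cm per axis
                        NumericVector tabE,  // MeV, increasing
                        NumericVector tabR,  // cm, increasing
                        double cutoff,       // MeV: deposit locally below this
                        double step_cm) {
  const int n = E0.size();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cx = (nx - 1) / 2, cy = (ny - 1) / 2, cz = (nz - 1) / 2;
  const double vx = vox[0], vy = vox[1], vz = vox[2];
  const int nt = tabE.size();
  const double *tE = tabE.begin(), *tR = tabR.begin();
  const double Rmin = tR[0];

  NumericVector dep(static_cast<R_xlen_t>(nx) * ny * nz);
  double escaped = 0.0;

  for (int i = 0; i < n; ++i) {
    double E = E0[i];
    double x = pos(i, 0), y = pos(i, 1), z = pos(i, 2);
    double ux = dir(i, 0), uy = dir(i, 1), uz = dir(i, 2);
    double Rres = interp_loglog(tE, tR, nt, E);

    for (;;) {
      if (E <= cutoff) {
        // terminal local deposition
        int ix = (int)std::floor(x / vx + 0.5) + cx;
        int iy = (int)std::floor(y / vy + 0.5) + cy;
        int iz = (int)std::floor(z / vz + 0.5) + cz;
        if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz)
          dep[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)] += E;
        else
          escaped += E;
        break;
      }
      double s = step_cm < Rres ? step_cm : Rres;
      double mx = x + ux * s * 0.5, my = y + uy * s * 0.5, mz = z + uz * s * 0.5;
      double Rnew = Rres - s;
      double Enew = (Rnew <= Rmin) ? 0.0 : interp_loglog(tR, tE, nt, Rnew);
      if (Enew > E) Enew = E;  // guard against interpolation wiggle
      double dE = E - Enew;

      int ix = (int)std::floor(mx / vx + 0.5) + cx;
      int iy = (int)std::floor(my / vy + 0.5) + cy;
      int iz = (int)std::floor(mz / vz + 0.5) + cz;
      if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
        dep[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)] += dE;
      } else {
        // convex grid: once outside, the straight track never re-enters
        escaped += E;
        E = 0.0;
        break;
      }
      x += ux * s; y += uy * s; z += uz * s;
      E = Enew; Rres = Rnew;
      if (E <= 0.0) break;
    }
  }

  return List::create(_["deposit"] = dep, _["escaped"] = escaped);
}
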