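#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Successive-over-relaxation solve of the linearized Poisson-Boltzmann
// equation on a regular grid with face-centred dielectric values.
//
// Node equation (finite volume, spacing h):
//   phi0 = (sum_f eps_f * phi_nb + src0) / (sum_f eps_f + kap0)
// where src = 4 pi ke q / h at charged nodes and kap holds the screening
// term eps_out * kappa^2 * h^2 at solvent nodes (zero ionic strength gives
// kap = 0). Boundary nodes are Dirichlet and never updated. Red-black
// ordering keeps the sweep order deterministic.
//
// phi: nx*ny*nz potential array (initialised with boundary values)
// epsx: (nx-1)*ny*nz, epsy: nx*(ny-1)*nz, epsz: nx*ny*(nz-1)
// Returns the converged phi; attribute "iterations" and "residual".
// [[Rcpp::export]]
NumericVector pb_sor_solve(NumericVector phi, NumericVector epsx,
                           NumericVector epsy, NumericVector epsz,
                           NumericVector src, NumericVector kap,
                           int nx, int ny, int nz,
                           double omega, double tol, int max_iter) {
  NumericVector out = clone(phi);
  double *p = REAL(out);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *s = REAL(src), *kp = REAL(kap);
  const int sx = 1, sy = nx, sz = nx * ny;
  auto idx = [&](int i, int j, int k) { return i + nx * (j + ny * k); };
  auto exi = [&](int i, int j, int k) { return i + (nx - 1) * (j + ny * k); };
  auto eyi = [&](int i, int j, int k) { return i + nx * (j + (ny - 1) * k); };
  auto ezi = [&](int i, int j, int k) { return i + nx * (j + ny * k); };

  double maxdiff = R_PosInf;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    maxdiff = 0.0;
    for (int colour = 0; colour < 2; ++colour) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int istart = 1 + ((j + k + colour) % 2);
          for (int i = istart; i < nx - 1; i += 2) {
            int c = idx(i, j, k);
            double exm = ex[exi(i - 1, j, k)], exp_ = ex[exi(i, j, k)];
            double eym = ey[eyi(i, j - 1, k)], eyp = ey[eyi(i, j, k)];
            double ezm = ez[ezi(i, j, k - 1)], ezp = ez[ezi(i, j, k)];
            double denom = exm + exp_ + eym + eyp + ezm + ezp + kp[c];
            double rhs = exm * p[c - sx] + exp_ * p[c + sx] +
                         eym * p[c - sy] + eyp * p[c + sy] +
                         ezm * p[c - sz] + ezp * p[c + sz] + s[c];
            double nv = (1.0 - omega) * p[c] + omega * rhs / denom;
            double diff = std::fabs(nv - p[c]);
            if (diff > maxdiff) maxdiff = diff;
            p[c] = nv;
          }
        }
      }
    }
    if (maxdiff < tol) break;
  }
  out.attr("iterations") = iter + 1;
  out.attr("residual") = maxdiff;
  out.attr("converged") = (maxdiff < tol);
  return out;
}
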