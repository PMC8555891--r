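// 3D staggered-grid (pressure-velocity) acoustic solver with thermoelastic
// forcing. Heterogeneous bulk modulus and density; rigid walls are encoded
// as zero inverse density on the blocked faces, free surfaces by zero bulk
// modulus (pressure pinned at 0) in the outside cells.
//
//   dp/dt = -K div(v) + K * beta * dT/dt        (cells)
//   dv/dt = -(1/rho) grad(p)                    (faces)
//
// Displacement is integrated on the faces; the maximum principal
// logarithmic strain (from displacement gradients) and maximum principal
// strain rate (from velocity gradients) are evaluated on brain-masked cells
// every `strain_every` steps.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// largest eigenvalue of a symmetric 3x3 (analytic, Smith's method)
static double sym3_max_eig(double a11, double a22, double a33,
                           double a12, double a13, double a23) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) return std::max(a11, std::max(a22, a33));
  double q = (a11 + a22 + a33) / 3.0;
  double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
  double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  if (p == 0.0) return q;
  // det(B)/2 with B = (A - qI)/p
  double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
  double c12 = a12 / p, c13 = a13 / p, c23 = a23 / p;
  double r = 0.5 * (c11 * (c22 * c33 - c23 * c23)
                  - c12 * (c12 * c33 - c23 * c13)
                  + c13 * (c12 * c23 - c22 * c13));
  r = std::max(-1.0, std::min(1.0, r));
  double phi = std::acos(r) / 3.0;
  return q + 2.0 * p * std::cos(phi);
}

// [[Rcpp::export(name = ".acoustic_core")]]
List acoustic_core(NumericVector Kc, NumericVector forc,
                   NumericVector irx, NumericVector iry, NumericVector irz,
                   IntegerVector mask, IntegerVector dims,
                   double dx, double dt, double tau_d, int nsteps,
                   IntegerVector probe_idx, int probe_every,
                   int strain_every, bool track_strain) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  const double inv_dx = 1.0 / dx;
  std::vector<double> p(N, 0), vx(N, 0), vy(N, 0), vz(N, 0);
  std::vector<double> ux, uy, uz;
  if (track_strain) { ux.assign(N, 0); uy.assign(N, 0); uz.assign(N, 0); }
  NumericVector minp(N);

  auto idx = [&](int i, int j, int k) -> size_t {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };

  const int np = probe_idx.size();
  const int nrec = nsteps / probe_every + 1;
  NumericMatrix ptrace(nrec, np);
  NumericVector ptimes(nrec);
  int irec = 0;
  std::vector<double> mps_hist, rate_hist, strain_times;

  for (int s = 0; s < nsteps; ++s) {
    double t0 = s * dt, t1 = (s + 1) * dt;
    // thermal forcing: fraction of the linear ramp covered by this step
    double f = 0.0;
    if (t0 < tau_d) f = (std::min(t1, tau_d) - t0) / tau_d;
    // ---- pressure update ----
    for (int k = 1; k < nz; ++k)
    for (int j = 1; j < ny; ++j)
    for (int i = 1; i < nx; ++i) {
      size_t id = idx(i, j, k);
      if (Kc[id] == 0.0) continue;
      double divv = (vx[id] - vx[idx(i - 1, j, k)] +
                     vy[id] - vy[idx(i, j - 1, k)] +
                     vz[id] - vz[idx(i, j, k - 1)]) * inv_dx;
      p[id] += -dt * Kc[id] * divv + f * forc[id];
      if (p[id] < minp[id]) minp[id] = p[id];
    }
    // ---- velocity (and displacement) update ----
    for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
    for (int i = 0; i < nx - 1; ++i) {
      size_t id = idx(i, j, k);
      if (irx[id] != 0.0)
        vx[id] -= dt * irx[id] * (p[idx(i + 1, j, k)] - p[id]) * inv_dx;
      if (iry[id] != 0.0)
        vy[id] -= dt * iry[id] * (p[idx(i, j + 1, k)] - p[id]) * inv_dx;
      if (irz[id] != 0.0)
        vz[id] -= dt * irz[id] * (p[idx(i, j, k + 1)] - p[id]) * inv_dx;
      if (track_strain) {
        ux[id] += vx[id] * dt; uy[id] += vy[id] * dt; uz[id] += vz[id] * dt;
      }
    }
    // ---- recording ----
    if ((s + 1) % probe_every == 0 || s == nsteps - 1) {
      if (irec < nrec) {
        for (int q = 0; q < np; ++q) ptrace(irec, q) = p[probe_idx[q]];
        ptimes[irec] = t1;
        ++irec;
      }
    }
    if (track_strain && ((s + 1) % strain_every == 0)) {
      double mps = 0.0, rate = 0.0;
      for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        size_t id = idx(i, j, k);
        if (!mask[id]) continue;
        // centre-interpolated face fields and their gradients
        auto grads = [&](std::vector<double> &fx, std::vector<double> &fy,
                         std::vector<double> &fz, double &e11, double &e22,
                         double &e33, double &e12, double &e13, double &e23) {
          e11 = (fx[id] - fx[idx(i - 1, j, k)]) * inv_dx;
          e22 = (fy[id] - fy[idx(i, j - 1, k)]) * inv_dx;
          e33 = (fz[id] - fz[idx(i, j, k - 1)]) * inv_dx;
          // cell-centre values of each component at neighbours
          auto cx = [&](int ii, int jj, int kk) {
            return 0.5 * (fx[idx(ii, jj, kk)] + fx[idx(ii - 1, jj, kk)]); };
          auto cy = [&](int ii, int jj, int kk) {
            return 0.5 * (fy[idx(ii, jj, kk)] + fy[idx(ii, jj - 1, kk)]); };
          auto cz = [&](int ii, int jj, int kk) {
            return 0.5 * (fz[idx(ii, jj, kk)] + fz[idx(ii, jj, kk - 1)]); };
          double dxy = (cx(i, j + 1, k) - cx(i, j - 1, k)) * 0.5 * inv_dx;
          double dyx = (cy(i + 1, j, k) - cy(i - 1, j, k)) * 0.5 * inv_dx;
          double dxz = (cx(i, j, k + 1) - cx(i, j, k - 1)) * 0.5 * inv_dx;
          double dzx = (cz(i + 1, j, k) - cz(i - 1, j, k)) * 0.5 * inv_dx;
          double dyz = (cy(i, j, k + 1) - cy(i, j, k - 1)) * 0.5 * inv_dx;
          double dzy = (cz(i, j + 1, k) - cz(i, j - 1, k)) * 0.5 * inv_dx;
          e12 = 0.5 * (dxy + dyx);
          e13 = 0.5 * (dxz + dzx);
          e23 = 0.5 * (dyz + dzy);
        };
        double e11, e22, e33, e12, e13, e23;
        grads(ux, uy, uz, e11, e22, e33, e12, e13, e23);
        double lam = sym3_max_eig(e11, e22, e33, e12, e13, e23);
        double lmps = std::log1p(std::max(lam, -0.999999));
        if (lmps > mps) mps = lmps;
        grads(vx, vy, vz, e11, e22, e33, e12, e13, e23);
        double lr = sym3_max_eig(e11, e22, e33, e12, e13, e23);
        if (lr > rate) rate = lr;
      }
      mps_hist.push_back(mps);
      rate_hist.push_back(rate);
      strain_times.push_back(t1);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["ptrace"] = ptrace, _["ptimes"] = ptimes, _["nrec"] = irec,
    _["minp"] = minp,
    _["mps"] = NumericVector(mps_hist.begin(), mps_hist.end()),
    _["strain_rate"] = NumericVector(rate_hist.begin(), rate_hist.end()),
    _["strain_times"] = NumericVector(strain_times.begin(), strain_times.end()),
    _["p_final"] = NumericVector(p.begin(), p.end()));
}
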