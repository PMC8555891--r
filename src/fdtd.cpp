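// Scattered-field FDTD (Yee grid) with CPML absorbing boundaries.
// The incident plane wave (vertical Ez polarization, propagation along a
// horizontal axis) enters analytically as a volumetric source term in the
// Ez update wherever the material differs from vacuum; magnetic updates
// carry no source because the medium is non-magnetic everywhere.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double C0   = 299792458.0;
static const double EPS0 = 8.8541878128e-12;
static const double MU0  = 1.25663706212e-6;
static const double ETA0 = 376.730313668;

struct Cpml {
  // per-position recursion coefficients at integer (E) and half (H) points
  std::vector<double> bE, cE, bH, cH;
};

static Cpml cpml_axis(int n, int npml, double dx, double dt,
                      double grading, double alpha) {
  Cpml c;
  c.bE.assign(n, 0.0); c.cE.assign(n, 0.0);
  c.bH.assign(n, 0.0); c.cH.assign(n, 0.0);
  double smax = 0.8 * (grading + 1.0) / (ETA0 * dx);
  auto coef = [&](double depth, double &b, double &cc) {
    if (depth <= 0) { b = 0; cc = 0; return; }
    double d = depth / npml;
    double s = smax * std::pow(d, grading);
    b = std::exp(-(s + alpha) * dt / EPS0);
    cc = s * (b - 1.0) / (s + alpha);
  };
  for (int i = 0; i < n; ++i) {
    double dl = npml - i;            // depth at integer position, low side
    double dh = i - (n - 1 - npml);  // high side
    coef(std::max(dl, dh), c.bE[i], c.cE[i]);
    double dl2 = npml - (i + 0.5);
    double dh2 = (i + 0.5) - (n - 1 - npml);
    coef(std::max(dl2, dh2), c.bH[i], c.cH[i]);
  }
  return c;
}

// incident Ez and its time derivative at retarded time tr (raised-cosine
// turn-on over ramp_T seconds)
static inline void incident(double tr, double w, double E0, double ramp_T,
                            double &e, double &dedt) {
  if (tr <= 0) { e = 0; dedt = 0; return; }
  double s = 1.0, ds = 0.0;
  if (tr < ramp_T) {
    s  = 0.5 * (1.0 - std::cos(M_PI * tr / ramp_T));
    ds = 0.5 * M_PI / ramp_T * std::sin(M_PI * tr / ramp_T);
  }
  double cw = std::cos(w * tr), sw = std::sin(w * tr);
  e = E0 * s * cw;
  dedt = E0 * (ds * cw - s * w * sw);
}

// [[Rcpp::export(name = ".fdtd_core")]]
List fdtd_core(NumericVector caEx, NumericVector cbEx,
               NumericVector caEy, NumericVector cbEy,
               NumericVector caEz, NumericVector cbEz,
               NumericVector srcA, NumericVector srcSig,
               IntegerVector dims, double dx, double dt,
               double freq, double E0,
               int prop_axis, int prop_sign,
               int npml, double grading, double alpha,
               int steps_per_cycle, int min_cycles, int max_cycles,
               double tol, double ramp_cycles) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  const double w = 2.0 * M_PI * freq;
  const double T = 1.0 / freq;
  const double ramp_T = ramp_cycles * T;
  const double dtm = dt / MU0;

  std::vector<double> Ex(N,0), Ey(N,0), Ez(N,0), Hx(N,0), Hy(N,0), Hz(N,0);
  // CPML memory arrays
  std::vector<double> pEzx(N,0), pEzy(N,0), pExy(N,0), pExz(N,0),
                      pEyz(N,0), pEyx(N,0),
                      pHxy(N,0), pHxz(N,0), pHyz(N,0), pHyx(N,0),
                      pHzx(N,0), pHzy(N,0);
  Cpml cx = cpml_axis(nx, npml, dx, dt, grading, alpha);
  Cpml cy = cpml_axis(ny, npml, dx, dt, grading, alpha);
  Cpml cz = cpml_axis(nz, npml, dx, dt, grading, alpha);

  NumericVector SEx(N), SEy(N), SEz(N);  // cycle-mean squared totals
  const int nprop = (prop_axis == 0) ? nx : ny;
  std::vector<double> einc(nprop), dinc(nprop);

  auto idx = [&](int i, int j, int k) -> size_t {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };
  auto fill_incident = [&](double t) {
    for (int q = 0; q < nprop; ++q) {
      double dist = (prop_sign > 0) ? q * dx : (nprop - 1 - q) * dx;
      incident(t - dist / C0, w, E0, ramp_T, einc[q], dinc[q]);
    }
  };

  const double inv_dx = 1.0 / dx;
  double prev_metric = -1.0;
  bool converged = false;
  int cycles_run = 0;
  std::vector<double> metrics;
  bool accumulating = false;
  long step_global = 0;

  for (int cyc = 0; cyc < max_cycles && !accumulating; ++cyc) {
    // last allowed cycle: accumulate even if not converged (flagged below)
    bool acc = converged || (cyc == max_cycles - 1);
    accumulating = acc;
    double cycsum = 0.0;
    if (acc) { std::fill(SEx.begin(), SEx.end(), 0.0);
               std::fill(SEy.begin(), SEy.end(), 0.0);
               std::fill(SEz.begin(), SEz.end(), 0.0); }
    for (int s = 0; s < steps_per_cycle; ++s, ++step_global) {
      double t_half = (step_global + 0.5) * dt;
      double t_new  = (step_global + 1.0) * dt;
      fill_incident(t_half);
      // ---- E update ----
      for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = idx(i, j, k);
        // Ex: needs j-1, k-1
        if (j > 0 && k > 0) {
          double dHzy = (Hz[id] - Hz[idx(i, j - 1, k)]) * inv_dx;
          double dHyz = (Hy[id] - Hy[idx(i, j, k - 1)]) * inv_dx;
          if (cy.cE[j] != 0) { pExy[id] = cy.bE[j] * pExy[id] + cy.cE[j] * dHzy; }
          if (cz.cE[k] != 0) { pExz[id] = cz.bE[k] * pExz[id] + cz.cE[k] * dHyz; }
          Ex[id] = caEx[id] * Ex[id] +
                   cbEx[id] * (dHzy - dHyz + pExy[id] - pExz[id]);
        }
        // Ey: needs i-1, k-1
        if (i > 0 && k > 0) {
          double dHxz = (Hx[id] - Hx[idx(i, j, k - 1)]) * inv_dx;
          double dHzx = (Hz[id] - Hz[idx(i - 1, j, k)]) * inv_dx;
          if (cz.cE[k] != 0) { pEyz[id] = cz.bE[k] * pEyz[id] + cz.cE[k] * dHxz; }
          if (cx.cE[i] != 0) { pEyx[id] = cx.bE[i] * pEyx[id] + cx.cE[i] * dHzx; }
          Ey[id] = caEy[id] * Ey[id] +
                   cbEy[id] * (dHxz - dHzx + pEyz[id] - pEyx[id]);
        }
        // Ez: needs i-1, j-1 (+ incident source in material)
        if (i > 0 && j > 0) {
          double dHyx = (Hy[id] - Hy[idx(i - 1, j, k)]) * inv_dx;
          double dHxy = (Hx[id] - Hx[idx(i, j - 1, k)]) * inv_dx;
          if (cx.cE[i] != 0) { pEzx[id] = cx.bE[i] * pEzx[id] + cx.cE[i] * dHyx; }
          if (cy.cE[j] != 0) { pEzy[id] = cy.bE[j] * pEzy[id] + cy.cE[j] * dHxy; }
          double curl = dHyx - dHxy + pEzx[id] - pEzy[id];
          double src = 0.0;
          if (srcA[id] != 0.0 || srcSig[id] != 0.0) {
            int q = (prop_axis == 0) ? i : j;
            src = srcA[id] * dinc[q] + srcSig[id] * einc[q];
          }
          Ez[id] = caEz[id] * Ez[id] + cbEz[id] * (curl - src);
        }
      }
      // ---- H update ----
      for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = idx(i, j, k);
        if (j < ny - 1 && k < nz - 1) {
          double dEzy = (Ez[idx(i, j + 1, k)] - Ez[id]) * inv_dx;
          double dEyz = (Ey[idx(i, j, k + 1)] - Ey[id]) * inv_dx;
          if (cy.cH[j] != 0) { pHxy[id] = cy.bH[j] * pHxy[id] + cy.cH[j] * dEzy; }
          if (cz.cH[k] != 0) { pHxz[id] = cz.bH[k] * pHxz[id] + cz.cH[k] * dEyz; }
          Hx[id] -= dtm * (dEzy - dEyz + pHxy[id] - pHxz[id]);
        }
        if (i < nx - 1 && k < nz - 1) {
          double dExz = (Ex[idx(i, j, k + 1)] - Ex[id]) * inv_dx;
          double dEzx = (Ez[idx(i + 1, j, k)] - Ez[id]) * inv_dx;
          if (cz.cH[k] != 0) { pHyz[id] = cz.bH[k] * pHyz[id] + cz.cH[k] * dExz; }
          if (cx.cH[i] != 0) { pHyx[id] = cx.bH[i] * pHyx[id] + cx.cH[i] * dEzx; }
          Hy[id] -= dtm * (dExz - dEzx + pHyz[id] - pHyx[id]);
        }
        if (i < nx - 1 && j < ny - 1) {
          double dEyx = (Ey[idx(i + 1, j, k)] - Ey[id]) * inv_dx;
          double dExy = (Ex[idx(i, j + 1, k)] - Ex[id]) * inv_dx;
          if (cx.cH[i] != 0) { pHzx[id] = cx.bH[i] * pHzx[id] + cx.cH[i] * dEyx; }
          if (cy.cH[j] != 0) { pHzy[id] = cy.bH[j] * pHzy[id] + cy.cH[j] * dExy; }
          Hz[id] -= dtm * (dEyx - dExy + pHzx[id] - pHzy[id]);
        }
      }
      // ---- accumulation at E time t_new ----
      if (acc) {
        fill_incident(t_new);
        for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = idx(i, j, k);
          int q = (prop_axis == 0) ? i : j;
          double ezt = Ez[id] + einc[q];
          SEx[id] += Ex[id] * Ex[id];
          SEy[id] += Ey[id] * Ey[id];
          SEz[id] += ezt * ezt;
        }
      } else {
        for (size_t id = 0; id < N; ++id) cycsum += Ez[id] * Ez[id];
      }
      Rcpp::checkUserInterrupt();
    }
    ++cycles_run;
    if (!acc) {
      double metric = std::sqrt(cycsum / ((double)N * steps_per_cycle));
      metrics.push_back(metric);
      if (cyc + 1 >= min_cycles && prev_metric > 0) {
        double rel = std::fabs(metric - prev_metric) /
                     std::max(metric, 1e-300);
        if (rel < tol || metric < 1e-12 * E0) converged = true;
      }
      if (metric < 1e-12 * E0 && cyc + 1 >= min_cycles) converged = true;
      prev_metric = metric;
    }
  }
  double inv = 1.0 / steps_per_cycle;
  for (size_t id = 0; id < N; ++id) {
    SEx[id] *= inv; SEy[id] *= inv; SEz[id] *= inv;
  }
  return List::create(_["SEx"] = SEx, _["SEy"] = SEy, _["SEz"] = SEz,
                      _["converged"] = converged,
                      _["cycles"] = cycles_run,
                      _["metrics"] = NumericVector(metrics.begin(), metrics.end()));
}
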