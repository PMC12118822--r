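// Reference engine: overdamped Langevin (Brownian) dynamics for a
// bead-spring chromatin fiber with soft DPD-style repulsion, harmonic
// bonds, optional bending stiffness, cylindrical confinement wall,
// spool wall (excludes backbone beads from the axial core), axial end
// tethers, azimuthal pins and periodic boundaries; plus the
// Gaussian-perturbation contact sampler used for in-silico Hi-C.
//
// Reduced units: length = 1 bead diameter, energy = kT, friction = 1,
// so dx = F dt + sqrt(2 T dt) * N(0,1).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double min_image(double d, double L) {
  if (L <= 0) return d;
  d -= L * std::round(d / L);
  return d;
}

struct CellList {
  double cell;
  int nx, ny, nz;
  double x0, y0, z0, Lx, Ly, Lz;
  bool periodic;
  std::vector<int> head;   // first bead in cell, -1 empty
  std::vector<int> next;   // linked list

  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double cutoff,
             const double* box) {
    int n = (int)x.size();
    periodic = box != nullptr;
    cell = cutoff;
    if (periodic) {
      Lx = box[0]; Ly = box[1]; Lz = box[2];
      x0 = 0; y0 = 0; z0 = 0;
      nx = std::max(1, (int)std::floor(Lx / cell));
      ny = std::max(1, (int)std::floor(Ly / cell));
      nz = std::max(1, (int)std::floor(Lz / cell));
    } else {
      double xmin = 1e300, ymin = 1e300, zmin = 1e300;
      double xmax = -1e300, ymax = -1e300, zmax = -1e300;
      for (int i = 0; i < n; ++i) {
        xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
        ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
        zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
      }
      x0 = xmin; y0 = ymin; z0 = zmin;
      Lx = xmax - xmin + 1e-9; Ly = ymax - ymin + 1e-9;
      Lz = zmax - zmin + 1e-9;
      nx = std::max(1, (int)std::floor(Lx / cell) + 1);
      ny = std::max(1, (int)std::floor(Ly / cell) + 1);
      nz = std::max(1, (int)std::floor(Lz / cell) + 1);
    }
    head.assign((size_t)nx * ny * nz, -1);
    next.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(x[i], y[i], z[i]);
      next[i] = head[c];
      head[c] = i;
    }
  }

  inline int wrap_idx(int c, int nmax) const {
    if (periodic) { c %= nmax; if (c < 0) c += nmax; return c; }
    return (c < 0 || c >= nmax) ? -1 : c;
  }
  inline int cell_of(double xi, double yi, double zi) const {
    double fx = xi - x0, fy = yi - y0, fz = zi - z0;
    if (periodic) {
      fx -= Lx * std::floor(fx / Lx);
      fy -= Ly * std::floor(fy / Ly);
      fz -= Lz * std::floor(fz / Lz);
    }
    int cx = std::min(nx - 1, std::max(0, (int)(fx / cell)));
    int cy = std::min(ny - 1, std::max(0, (int)(fy / cell)));
    int cz = std::min(nz - 1, std::max(0, (int)(fz / cell)));
    return (cz * ny + cy) * nx + cx;
  }
  template <class F>
  void for_pairs(const std::vector<double>& x, const std::vector<double>& y,
                 const std::vector<double>& z, double cutoff, F&& fun) const {
    double c2 = cutoff * cutoff;
    const double* box = periodic ? &Lx : nullptr;
    for (int cz = 0; cz < nz; ++cz)
      for (int cy = 0; cy < ny; ++cy)
        for (int cx = 0; cx < nx; ++cx) {
          int c = (cz * ny + cy) * nx + cx;
          for (int i = head[c]; i != -1; i = next[i]) {
            // same cell (half)
            for (int j = next[i]; j != -1; j = next[j])
              maybe(i, j, x, y, z, c2, box, fun);
            // half of the neighbor cells
            static const int offs[13][3] = {
              {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
              {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
            for (int o = 0; o < 13; ++o) {
              int ax = wrap_idx(cx + offs[o][0], nx);
              int ay = wrap_idx(cy + offs[o][1], ny);
              int az = wrap_idx(cz + offs[o][2], nz);
              if (ax < 0 || ay < 0 || az < 0) continue;
              int c2i = (az * ny + ay) * nx + ax;
              if (c2i == c) continue;
              for (int j = head[c2i]; j != -1; j = next[j])
                maybe(i, j, x, y, z, c2, box, fun);
            }
          }
        }
  }
  template <class F>
  inline void maybe(int i, int j, const std::vector<double>& x,
                    const std::vector<double>& y,
                    const std::vector<double>& z, double c2,
                    const double* box, F&& fun) const {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    if (box) {
      dx = min_image(dx, box[0]);
      dy = min_image(dy, box[1]);
      dz = min_image(dz, box[2]);
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < c2) fun(i, j, dx, dy, dz, r2);
  }
};

// one-sided Gaussian wall: potential eps*exp(-u^2/(2 s^2)) on the soft
// side (u >= 0), harmonic continuation eps*(1 + u^2/(2 s^2)) on the hard
// side; returns dU/du
static inline double wall_dUdu(double u, double eps, double s) {
  double s2 = s * s;
  if (u >= 0) return -eps * u / s2 * std::exp(-u * u / (2 * s2));
  return eps * u / s2;  // harmonic growth on the forbidden side (u < 0)
}

// [[Rcpp::export]]
List cpp_brownian(NumericMatrix pos,
                  IntegerVector bond_i, IntegerVector bond_j,
                  NumericVector bond_k, NumericVector bond_l0,
                  double angle_k,
                  double rep_A, double rep_cut,
                  NumericVector box,
                  IntegerVector fixed,
                  Nullable<List> cylinder_,
                  Nullable<List> spool_,
                  IntegerVector spool_beads,
                  double tether_force,
                  int tether_lo, int tether_hi,
                  IntegerVector pin_bead, NumericVector pin_theta,
                  NumericVector pin_kappa,
                  IntegerVector lateral_bead, double lateral_force,
                  double dt, int n_steps, double temperature,
                  int seed, int save_every) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }

  bool has_box = box.size() == 3;
  double boxv[3];
  if (has_box) { boxv[0] = box[0]; boxv[1] = box[1]; boxv[2] = box[2]; }

  std::vector<char> is_fixed(n, 0);
  for (int q = 0; q < fixed.size(); ++q) is_fixed[fixed[q] - 1] = 1;

  bool has_cyl = cylinder_.isNotNull();
  double cylR = 0, cylL = 0, cylEps = 0, cylSig = 0;
  if (has_cyl) {
    List cyl(cylinder_);
    cylR = as<double>(cyl["R"]); cylL = as<double>(cyl["L"]);
    cylEps = as<double>(cyl["eps"]); cylSig = as<double>(cyl["sigma"]);
  }
  bool has_spool = spool_.isNotNull();
  double spR = 0, spEps = 0, spSig = 0;
  std::vector<char> on_spool(n, 0);
  if (has_spool) {
    List sp(spool_);
    spR = as<double>(sp["R"]); spEps = as<double>(sp["eps"]);
    spSig = as<double>(sp["sigma"]);
    for (int q = 0; q < spool_beads.size(); ++q)
      on_spool[spool_beads[q] - 1] = 1;
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> fx(n), fy(n), fz(n);
  CellList cl;
  double noise = std::sqrt(2.0 * temperature * dt);
  int nb = bond_i.size();

  List frames;
  for (int step = 0; step < n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    // bonds
    for (int b = 0; b < nb; ++b) {
      int i = bond_i[b] - 1, j = bond_j[b] - 1;
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      if (has_box) {
        dx = min_image(dx, boxv[0]); dy = min_image(dy, boxv[1]);
        dz = min_image(dz, boxv[2]);
      }
      double r = std::sqrt(dx * dx + dy * dy + dz * dz) + 1e-12;
      double f = -bond_k[b] * (r - bond_l0[b]) / r;
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
      fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
    }

    // bending along the backbone chain (consecutive beads), U = k (1 + cos t)
    if (angle_k > 0) {
      for (int i = 1; i < n - 1; ++i) {
        double ax = x[i-1]-x[i], ay = y[i-1]-y[i], az = z[i-1]-z[i];
        double bx2 = x[i+1]-x[i], by2 = y[i+1]-y[i], bz2 = z[i+1]-z[i];
        if (has_box) {
          ax = min_image(ax, boxv[0]); ay = min_image(ay, boxv[1]);
          az = min_image(az, boxv[2]);
          bx2 = min_image(bx2, boxv[0]); by2 = min_image(by2, boxv[1]);
          bz2 = min_image(bz2, boxv[2]);
        }
        double la = std::sqrt(ax*ax+ay*ay+az*az) + 1e-12;
        double lb = std::sqrt(bx2*bx2+by2*by2+bz2*bz2) + 1e-12;
        double ct = (ax*bx2+ay*by2+az*bz2)/(la*lb);
        // dU/d(cos t) = k ; grad of cos t wrt positions
        double gax = bx2/(la*lb) - ct*ax/(la*la);
        double gay = by2/(la*lb) - ct*ay/(la*la);
        double gaz = bz2/(la*lb) - ct*az/(la*la);
        double gbx = ax/(la*lb) - ct*bx2/(lb*lb);
        double gby = ay/(la*lb) - ct*by2/(lb*lb);
        double gbz = az/(la*lb) - ct*bz2/(lb*lb);
        fx[i-1] -= angle_k * gax; fy[i-1] -= angle_k * gay; fz[i-1] -= angle_k * gaz;
        fx[i+1] -= angle_k * gbx; fy[i+1] -= angle_k * gby; fz[i+1] -= angle_k * gbz;
        fx[i]   += angle_k * (gax + gbx);
        fy[i]   += angle_k * (gay + gby);
        fz[i]   += angle_k * (gaz + gbz);
      }
    }

    // soft repulsion F = A (1 - r/rc) rhat
    if (rep_A > 0) {
      cl.build(x, y, z, rep_cut, has_box ? boxv : nullptr);
      cl.for_pairs(x, y, z, rep_cut,
        [&](int i, int j, double dx, double dy, double dz, double r2) {
          double r = std::sqrt(r2) + 1e-12;
          double f = rep_A * (1.0 - r / rep_cut) / r;
          fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
          fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
        });
    }

    // confining cylinder (axis z, centered at origin)
    if (has_cyl) {
      for (int i = 0; i < n; ++i) {
        double r = std::sqrt(x[i]*x[i] + y[i]*y[i]) + 1e-12;
        double u = cylR - r;  // distance inside the radial wall
        double dU = wall_dUdu(u, cylEps, cylSig);  // dU/du
        double fr = dU;       // F_r = -dU/dr = dU/du
        fx[i] += fr * x[i] / r; fy[i] += fr * y[i] / r;
        double uz = cylL / 2 - std::fabs(z[i]);
        double dUz = wall_dUdu(uz, cylEps, cylSig);
        fz[i] += (z[i] > 0 ? dUz : -dUz);
      }
    }

    // spool wall: pushes backbone beads outward from the axial core
    if (has_spool) {
      for (int i = 0; i < n; ++i) {
        if (!on_spool[i]) continue;
        double r = std::sqrt(x[i]*x[i] + y[i]*y[i]) + 1e-12;
        double u = r - spR;   // distance outside the spool surface
        double fr = -wall_dUdu(u, spEps, spSig);  // F_r = -dU/dr
        fx[i] += fr * x[i] / r; fy[i] += fr * y[i] / r;
      }
    }

    // axial end tethers
    if (tether_force != 0 && tether_lo >= 1)
      fz[tether_lo - 1] -= tether_force;
    if (tether_force != 0 && tether_hi >= 1)
      fz[tether_hi - 1] += tether_force;

    // azimuthal pins, U = kappa (1 - cos(theta - theta0))
    for (int q = 0; q < pin_bead.size(); ++q) {
      int i = pin_bead[q] - 1;
      double r2 = x[i]*x[i] + y[i]*y[i];
      if (r2 < 1e-8) continue;
      double th = std::atan2(y[i], x[i]);
      double s = pin_kappa[q] * std::sin(th - pin_theta[q]);
      fx[i] += s * y[i] / r2;
      fy[i] -= s * x[i] / r2;
    }

    // constant lateral force (+y), e.g. cohesion pins
    for (int q = 0; q < lateral_bead.size(); ++q)
      fy[lateral_bead[q] - 1] += lateral_force;

    // Brownian update; the deterministic displacement is clamped to
    // 0.25 length units per step, which keeps stiff multi-bond junctions
    // (k_eff * dt near the overdamped-Euler stability limit) stable
    // without affecting equilibrium statistics in the common case
    for (int i = 0; i < n; ++i) {
      if (is_fixed[i]) continue;
      double dx = fx[i] * dt, dy = fy[i] * dt, dz = fz[i] * dt;
      double dr = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dr > 0.25) { dx *= 0.25 / dr; dy *= 0.25 / dr; dz *= 0.25 / dr; }
      x[i] += dx + noise * gauss(rng);
      y[i] += dy + noise * gauss(rng);
      z[i] += dz + noise * gauss(rng);
    }

    if ((step & 1023) == 0) {
      for (int i = 0; i < n; ++i)
        if (std::fabs(x[i]) > 1e6 || std::fabs(y[i]) > 1e6 ||
            std::fabs(z[i]) > 1e6)
          stop("integration diverged at step %d (|coord| > 1e6)", step);
      Rcpp::checkUserInterrupt();
    }
    if (save_every > 0 && ((step + 1) % save_every == 0)) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) { fr(i,0)=x[i]; fr(i,1)=y[i]; fr(i,2)=z[i]; }
      frames.push_back(fr);
    }
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0)=x[i]; out(i,1)=y[i]; out(i,2)=z[i]; }
  return List::create(_["pos"] = out, _["frames"] = frames);
}

// Gaussian-perturbation contact sampling: jitter every bead by an
// isotropic Gaussian (sd sigma per axis), find pairs within the cutoff,
// repeat n_reps times, and report per-pair contact counts.
// [[Rcpp::export]]
DataFrame cpp_contacts(NumericMatrix pos, double sigma, double cutoff,
                       int n_reps, int seed, NumericVector box,
                       int min_sep) {
  int n = pos.nrow();
  if (cutoff <= 0) stop("cutoff must be > 0");
  bool has_box = box.size() == 3;
  double boxv[3];
  if (has_box) { boxv[0]=box[0]; boxv[1]=box[1]; boxv[2]=box[2]; }
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::unordered_map<uint64_t, int> counts;
  std::vector<double> x(n), y(n), z(n);
  CellList cl;
  for (int rep = 0; rep < n_reps; ++rep) {
    for (int i = 0; i < n; ++i) {
      x[i] = pos(i,0) + sigma * gauss(rng);
      y[i] = pos(i,1) + sigma * gauss(rng);
      z[i] = pos(i,2) + sigma * gauss(rng);
    }
    cl.build(x, y, z, cutoff, has_box ? boxv : nullptr);
    cl.for_pairs(x, y, z, cutoff,
      [&](int i, int j, double, double, double, double) {
        int a = std::min(i, j), b = std::max(i, j);
        if (b - a < min_sep) return;
        counts[((uint64_t)a << 32) | (uint64_t)b]++;
      });
    if ((rep & 7) == 0) Rcpp::checkUserInterrupt();
  }

  size_t m = counts.size();
  IntegerVector oi(m), oj(m);
  NumericVector freq(m);
  size_t q = 0;
  for (auto& kv : counts) {
    oi[q] = (int)(kv.first >> 32) + 1;
    oj[q] = (int)(kv.first & 0xffffffffu) + 1;
    freq[q] = (double)kv.second / n_reps;
    ++q;
  }
  return DataFrame::create(_["i"] = oi, _["j"] = oj, _["freq"] = freq);
}
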