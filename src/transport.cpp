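// Monte Carlo photon transport over a voxel grid for CT acquisitions.
//
// Woodcock (delta) tracking through the density/material grid; photoelectric
// absorption (local deposit), incoherent scatter sampled from the
// free-electron Klein-Nishina distribution by Kahn's method (transferred
// energy deposited locally -- kerma approximation), coherent scatter as a
// forward-cone direction change. Photons are terminated below the energy
// cutoff (remainder deposited) or on leaving the grid. Uses R's RNG so a
// set.seed() in the caller makes runs bit-reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  double sx, sy, sz;       // spacing, mm
  double ox, oy, oz;       // origin (centre of first voxel), mm
  const double* density;   // g/cm^3
  const int* material;     // 0-based

  // box bounds (voxel edges)
  double x0() const { return ox - 0.5 * sx; }
  double y0() const { return oy - 0.5 * sy; }
  double z0() const { return oz - 0.5 * sz; }
  double x1() const { return x0() + nx * sx; }
  double y1() const { return y0() + ny * sy; }
  double z1() const { return z0() + nz * sz; }

  bool inside(double x, double y, double z) const {
    return x > x0() && x < x1() && y > y0() && y < y1() && z > z0() && z < z1();
  }
  long index(double x, double y, double z) const {
    int ix = (int)std::floor((x - x0()) / sx);
    int iy = (int)std::floor((y - y0()) / sy);
    int iz = (int)std::floor((z - z0()) / sz);
    if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
    if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
    if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
    return (long)ix + (long)nx * ((long)iy + (long)ny * (long)iz);
  }
};

// advance a ray from outside to the box surface; returns false on miss
bool enter_box(const Grid& g, double& x, double& y, double& z,
               double dx, double dy, double dz) {
  if (g.inside(x, y, z)) return true;
  double tmin = 0.0, tmax = 1e30;
  const double lo[3] = {g.x0(), g.y0(), g.z0()};
  const double hi[3] = {g.x1(), g.y1(), g.z1()};
  const double p[3] = {x, y, z};
  const double d[3] = {dx, dy, dz};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p[a] <= lo[a] || p[a] >= hi[a]) return false;
    } else {
      double t1 = (lo[a] - p[a]) / d[a];
      double t2 = (hi[a] - p[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmax <= tmin || tmax <= 0) return false;
  double t = tmin + 1e-6;
  x += t * dx; y += t * dy; z += t * dz;
  return g.inside(x, y, z);
}

// rotate unit vector (ux,uy,uz) by polar angle (cost) about itself with
// uniform azimuth phi
void rotate_direction(double& ux, double& uy, double& uz,
                      double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  double wx, wy, wz;
  if (std::fabs(uz) < 0.99999) {
    double rho = std::sqrt(ux * ux + uy * uy);
    wx = ux * cost + sint * (ux * uz * cosp - uy * sinp) / rho;
    wy = uy * cost + sint * (uy * uz * cosp + ux * sinp) / rho;
    wz = uz * cost - rho * sint * cosp;
  } else {
    wx = sint * cosp;
    wy = sint * sinp;
    wz = (uz > 0 ? cost : -cost);
  }
  double n = std::sqrt(wx * wx + wy * wy + wz * wz);
  ux = wx / n; uy = wy / n; uz = wz / n;
}

// Kahn's rejection sampling of the Klein-Nishina ratio r = E/E'
double sample_kahn(double e_kev, double& cost) {
  double alpha = e_kev / 510.998950;
  for (int it = 0; it < 10000; ++it) {
    double x1 = unif_rand(), x2 = unif_rand(), x3 = unif_rand();
    if (x1 <= (1.0 + 2.0 * alpha) / (9.0 + 2.0 * alpha)) {
      double r = 1.0 + 2.0 * alpha * x2;
      if (x3 <= 4.0 * (r - 1.0) / (r * r)) {
        cost = 1.0 - (r - 1.0) / alpha;
        return r;
      }
    } else {
      double r = (1.0 + 2.0 * alpha) / (1.0 + 2.0 * alpha * x2);
      double c = 1.0 - (r - 1.0) / alpha;
      if (x3 <= 0.5 * (c * c + 1.0 / r)) {
        cost = c;
        return r;
      }
    }
  }
  cost = 1.0;
  return 1.0;
}

double interp_table(const NumericVector& xs, const NumericVector& ys, double x) {
  int n = xs.size();
  if (x <= xs[0]) return ys[0];
  if (x >= xs[n - 1]) return ys[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (xs[mid] <= x) lo = mid; else hi = mid;
  }
  double f = (x - xs[lo]) / (xs[hi] - xs[lo]);
  return ys[lo] + f * (ys[hi] - ys[lo]);
}

} // namespace

// [[Rcpp::export(name = ".mc_transport")]]
List mc_transport(NumericVector density, IntegerVector material,
                  IntegerVector dims, NumericVector spacing,
                  NumericVector origin,
                  NumericMatrix xs_total, NumericMatrix xs_pe,
                  NumericMatrix xs_incoh, NumericMatrix xs_coh,
                  double e_grid_min,
                  NumericVector spec_energy, NumericVector spec_cdf,
                  double focus_iso_mm, double fan_half, double cone_half,
                  NumericVector bowtie_angle, NumericVector bowtie_t_mm,
                  NumericVector mu_al_per_mm,
                  int mode, double z_start_mm, double z_end_mm,
                  double pitch, double collimation_mm, double start_angle,
                  NumericVector slice_weight,
                  double iso_x, double iso_y,
                  int n_photons, double cutoff_kev, bool track_scatter) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.density = REAL(density);
  g.material = INTEGER(material);

  const int n_e = xs_total.nrow();
  const int n_mat = xs_total.ncol();
  const long n_vox = (long)g.nx * g.ny * g.nz;

  // per-material max density, then per-energy majorant (1/mm)
  std::vector<double> rho_max(n_mat, 0.0);
  for (long v = 0; v < n_vox; ++v) {
    int m = g.material[v];
    if (g.density[v] > rho_max[m]) rho_max[m] = g.density[v];
  }
  std::vector<double> sig_max(n_e, 1e-12);
  for (int ie = 0; ie < n_e; ++ie) {
    for (int m = 0; m < n_mat; ++m) {
      double s = xs_total(ie, m) * rho_max[m] / 10.0; // 1/mm
      if (s > sig_max[ie]) sig_max[ie] = s;
    }
  }

  NumericVector edep(n_vox);
  double* ed = REAL(edep);
  double emitted = 0.0, escaped = 0.0, discarded = 0.0;
  const int n_spec = spec_energy.size();
  const double cone_tan_half = std::tan(cone_half);
  RNGScope rng;

  for (int ip = 0; ip < n_photons; ++ip) {
    // --- source sampling -------------------------------------------------
    double zsrc, phi_src;
    double wgt = 1.0;
    if (mode == 0) {            // helical
      double u = unif_rand();
      zsrc = z_start_mm + u * (z_end_mm - z_start_mm);
      phi_src = start_angle +
        2.0 * M_PI * (zsrc - z_start_mm) / (pitch * collimation_mm);
      int isl = (int)std::lround((zsrc - g.oz) / g.sz);
      if (isl < 0) isl = 0;
      if (isl >= slice_weight.size()) isl = slice_weight.size() - 1;
      wgt *= slice_weight[isl];
    } else if (mode == 1) {     // axial, one rotation at z_start
      zsrc = z_start_mm;
      phi_src = 2.0 * M_PI * unif_rand();
    } else {                    // stationary tube
      zsrc = z_start_mm;
      phi_src = start_angle;
    }
    double sxp = iso_x + focus_iso_mm * std::cos(phi_src);
    double syp = iso_y + focus_iso_mm * std::sin(phi_src);
    // central ray towards the isocenter axis
    double cx = iso_x - sxp, cy = iso_y - syp;
    double cn = std::sqrt(cx * cx + cy * cy);
    cx /= cn; cy /= cn;
    // fan angle (in-plane) and cone angle (longitudinal)
    double ua = fan_half * (2.0 * unif_rand() - 1.0);
    double va = cone_half * (2.0 * unif_rand() - 1.0);
    double ca = std::cos(ua), sa = std::sin(ua);
    double dx = cx * ca - cy * sa;
    double dy = cx * sa + cy * ca;
    double dz = std::tan(va) / std::sqrt(1.0 + std::pow(std::tan(va), 2));
    double rxy = std::sqrt(1.0 - dz * dz);
    dx *= rxy; dy *= rxy;
    (void)cone_tan_half;

    // energy
    double ux = unif_rand();
    int ibin = 0;
    while (ibin < n_spec - 1 && spec_cdf[ibin] < ux) ++ibin;
    double e_kev = spec_energy[ibin];

    // bowtie survival weight at this fan angle
    double t_bow = interp_table(bowtie_angle, bowtie_t_mm, std::fabs(ua));
    if (t_bow > 0) {
      int ie0 = (int)std::lround(e_kev - e_grid_min);
      if (ie0 < 0) ie0 = 0;
      if (ie0 >= mu_al_per_mm.size()) ie0 = mu_al_per_mm.size() - 1;
      wgt *= std::exp(-mu_al_per_mm[ie0] * t_bow);
    }

    emitted += e_kev * wgt;

    double x = sxp, y = syp, z = zsrc;
    if (!enter_box(g, x, y, z, dx, dy, dz)) {
      escaped += e_kev * wgt;
      continue;
    }

    // --- transport --------------------------------------------------------
    bool alive = true;
    int hops = 0;
    while (alive && ++hops < 100000) {
      int ie = (int)std::lround(e_kev - e_grid_min);
      if (ie < 0) ie = 0;
      if (ie >= n_e) ie = n_e - 1;
      double smax = sig_max[ie];
      double step = -std::log(unif_rand()) / smax;
      x += step * dx; y += step * dy; z += step * dz;
      if (!g.inside(x, y, z)) {
        escaped += e_kev * wgt;
        break;
      }
      long v = g.index(x, y, z);
      int m = g.material[v];
      double rho = g.density[v];
      double sig_vox = xs_total(ie, m) * rho / 10.0;
      if (unif_rand() * smax > sig_vox) continue; // virtual collision
      // real interaction: choose type
      double pe = xs_pe(ie, m), inc = xs_incoh(ie, m), coh = xs_coh(ie, m);
      double r = unif_rand() * (pe + inc + coh);
      if (r < pe) {
        ed[v] += e_kev * wgt;                       // photoelectric
        alive = false;
      } else if (r < pe + inc) {                    // incoherent (Compton)
        double cost;
        double ratio = sample_kahn(e_kev, cost);
        double e_new = e_kev / ratio;
        ed[v] += (e_kev - e_new) * wgt;
        if (!track_scatter) {
          discarded += e_new * wgt;
          alive = false;
        } else if (e_new < cutoff_kev) {
          ed[v] += e_new * wgt;
          alive = false;
        } else {
          e_kev = e_new;
          rotate_direction(dx, dy, dz, cost, 2.0 * M_PI * unif_rand());
        }
      } else {                                      // coherent (Rayleigh)
        if (!track_scatter) {
          // narrow-beam (primary-only) mode: any scattered photon leaves
          // the beam, coherent included
          discarded += e_kev * wgt;
          alive = false;
        } else {
          double theta = (M_PI / 6.0) * unif_rand();  // forward cone <= 30 deg
          rotate_direction(dx, dy, dz, std::cos(theta),
                           2.0 * M_PI * unif_rand());
        }
      }
    }
  }

  return List::create(_["edep_kev"] = edep, _["emitted_kev"] = emitted,
                      _["escaped_kev"] = escaped,
                      _["discarded_kev"] = discarded);
}
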