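// Overdamped center-based simulation core.
//
// Cells are spheres (discs in 2D) whose velocity is the sum of pairwise
// adhesion/repulsion contributions, rigid-wall repulsion, and an active
// motility term.  Positions are integrated with explicit Euler.  All
// randomness goes through R's RNG so runs are reproducible from set.seed().
//
// Type codes: 0 = AXIAL, 1 = PSM, 2 = POSTERIOR.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct BinGrid {
  double h, x0, y0, z0;
  int nx, ny, nz;
  std::vector<int> head, nxt;

  void build(const std::vector<double> &px, const std::vector<double> &py,
             const std::vector<double> &pz, int n, double cutoff, int dim) {
    h = cutoff;
    double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
    double zmin = pz[0], zmax = pz[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
      ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
      zmin = std::min(zmin, pz[i]); zmax = std::max(zmax, pz[i]);
    }
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = std::max(1, (int)std::floor((xmax - xmin) / h) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / h) + 1);
    nz = (dim == 3) ? std::max(1, (int)std::floor((zmax - zmin) / h) + 1) : 1;
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int b = index_of(px[i], py[i], pz[i]);
      nxt[i] = head[b];
      head[b] = i;
    }
  }
  inline int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  inline int index_of(double x, double y, double z) const {
    int ix = clampi((int)std::floor((x - x0) / h), 0, nx - 1);
    int iy = clampi((int)std::floor((y - y0) / h), 0, ny - 1);
    int iz = clampi((int)std::floor((z - z0) / h), 0, nz - 1);
    return (iz * ny + iy) * nx + ix;
  }
};

inline void unit_direction(int dim, double *out) {
  if (dim == 2) {
    double th = R::runif(0.0, 2.0 * M_PI);
    out[0] = std::cos(th); out[1] = std::sin(th); out[2] = 0.0;
  } else {
    double n = 0.0;
    do {
      out[0] = R::norm_rand(); out[1] = R::norm_rand(); out[2] = R::norm_rand();
      n = std::sqrt(out[0]*out[0] + out[1]*out[1] + out[2]*out[2]);
    } while (n < 1e-12);
    out[0] /= n; out[1] /= n; out[2] /= n;
  }
}

} // namespace

// Full simulation segment.  Walls are half-spaces: a point p is inside wall k
// when dot(normal_k, p) - offset_k >= 0, with normal_k the inward unit normal.
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, IntegerVector type, IntegerVector id,
             NumericVector radius, NumericVector adh_dist,
             NumericMatrix crep, NumericMatrix cadh, NumericVector motility,
             double boundary_rep,
             NumericMatrix wall_normal, NumericVector wall_offset,
             double dt, int persistence, double step_clamp,
             int n_iter, int iter0, int record_every,
             double influx_rate, double pd_halfwidth, double pd_depth,
             double pd_zlo, double pd_zhi, double min_spacing,
             double new_radius, double new_adh, int next_id,
             int dim, bool use_bins,
             double ap_bin_width, int n_ap_bins) {
  int n = pos.nrow();
  int nw = wall_normal.nrow();

  std::vector<double> px(n), py(n), pz(n, 0.0), rad(radius.begin(), radius.end());
  std::vector<double> adh(adh_dist.begin(), adh_dist.end());
  std::vector<int> ty(type.begin(), type.end()), ids(id.begin(), id.end());
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1);
    if (dim == 3) pz[i] = pos(i, 2);
  }
  std::vector<double> mdx(n, 0.0), mdy(n, 0.0), mdz(n, 0.0);

  std::vector<int> axial_idx;
  for (int i = 0; i < n; ++i) if (ty[i] == 0) axial_idx.push_back(i);
  int n_axial = (int)axial_idx.size();

  double max_adh = 0.0;
  for (int i = 0; i < n; ++i) max_adh = std::max(max_adh, adh[i]);
  max_adh = std::max(max_adh, new_adh);
  double cutoff = 2.0 * max_adh;

  int n_chunks = (n_iter + record_every - 1) / record_every;
  NumericMatrix impulse(n_chunks, n_ap_bins);
  NumericVector len_series(n_iter), force_series(n_iter);

  List snapshots;
  auto take_snapshot = [&](int iter_label) {
    int m = (int)px.size();
    NumericMatrix sp(m, dim);
    IntegerVector sid(m), sty(m);
    for (int i = 0; i < m; ++i) {
      sp(i, 0) = px[i]; sp(i, 1) = py[i];
      if (dim == 3) sp(i, 2) = pz[i];
      sid[i] = ids[i]; sty[i] = ty[i];
    }
    snapshots.push_back(List::create(_["iter"] = iter_label, _["pos"] = sp,
                                     _["id"] = sid, _["type"] = sty));
  };
  take_snapshot(iter0);

  int n_added = 0, n_skipped = 0, n_clamped = 0;
  BinGrid grid;
  std::vector<double> fx, fy, fz, bx, by, bz;

  for (int it = 0; it < n_iter; ++it) {
    n = (int)px.size();

    // 1. motility direction redraws (cell order, so the RNG stream is fixed)
    if (it % persistence == 0) {
      double d3[3];
      for (int i = 0; i < n; ++i) {
        if (motility[ty[i]] > 0.0) {
          unit_direction(dim, d3);
          mdx[i] = d3[0]; mdy[i] = d3[1]; mdz[i] = d3[2];
        }
      }
    }

    // 2. progenitor influx: new PSM cells inside the current PD region
    if (influx_rate > 0.0 && n_axial > 0) {
      int k = (int)R::rpois(influx_rate);
      for (int c = 0; c < k; ++c) {
        double ax_max = -1e30;
        for (int a = 0; a < n_axial; ++a)
          ax_max = std::max(ax_max, px[axial_idx[a]]);
        // posterior end of the PD: just anterior of the posterior-cap front
        // (the cap yields by sliding), clear of the axial tip
        double cap_front = 1e30;
        for (int j = 0; j < n; ++j)
          if (ty[j] == 2) cap_front = std::min(cap_front, px[j]);
        double hi = (cap_front < 1e29) ? cap_front : ax_max + pd_depth;
        double lo = std::max(ax_max + 0.5 * pd_depth,
                             hi - 0.5 * pd_depth);
        if (hi <= lo) hi = lo + 0.25 * pd_depth;
        bool placed = false;
        for (int att = 0; att < 10 && !placed; ++att) {
          double xn = lo + R::runif(0.0, 1.0) * (hi - lo);
          double yn = (2.0 * R::runif(0.0, 1.0) - 1.0) * 0.95 * pd_halfwidth;
          double zn = (dim == 3) ? R::runif(pd_zlo, pd_zhi) : 0.0;
          bool ok = true;
          for (int j = 0; j < (int)px.size() && ok; ++j) {
            double ddx = px[j] - xn, ddy = py[j] - yn, ddz = pz[j] - zn;
            if (ddx*ddx + ddy*ddy + ddz*ddz < min_spacing * min_spacing) ok = false;
          }
          if (ok) {
            px.push_back(xn); py.push_back(yn); pz.push_back(zn);
            ty.push_back(1); ids.push_back(next_id++);
            rad.push_back(new_radius); adh.push_back(new_adh);
            double d3[3]; unit_direction(dim, d3);
            mdx.push_back(d3[0]); mdy.push_back(d3[1]); mdz.push_back(d3[2]);
            ++n_added; placed = true;
          }
        }
        if (!placed) ++n_skipped;
      }
      n = (int)px.size();
    }

    // 3. pairwise interaction forces (velocity contributions)
    fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0);
    bx.assign(n, 0.0); by.assign(n, 0.0); bz.assign(n, 0.0);

    auto pair_force = [&](int i, int j) {
      double ddx = px[i] - px[j], ddy = py[i] - py[j], ddz = pz[i] - pz[j];
      double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
      double Rsum = rad[i] + rad[j];
      double Asum = adh[i] + adh[j];
      if (d2 >= Asum * Asum) return;
      double d = std::sqrt(d2);
      double ux, uy, uz;
      if (d < 1e-12) {
        // coincident centers: seeded random separation direction
        double d3[3]; unit_direction(dim, d3);
        ux = d3[0]; uy = d3[1]; uz = d3[2]; d = 0.0;
      } else {
        ux = ddx / d; uy = ddy / d; uz = ddz / d;
      }
      double mag = 0.0; // along j->i on cell i
      if (d < Rsum) {
        double t = 1.0 - d / Rsum;
        mag = crep(ty[i], ty[j]) * t * t;
      } else {
        double t = 1.0 - d / Asum;
        mag = -cadh(ty[i], ty[j]) * t * t;
      }
      fx[i] += mag * ux; fy[i] += mag * uy; fz[i] += mag * uz;
      fx[j] -= mag * ux; fy[j] -= mag * uy; fz[j] -= mag * uz;
    };

    if (use_bins) {
      grid.build(px, py, pz, n, cutoff, dim);
      for (int i = 0; i < n; ++i) {
        int ix = grid.clampi((int)std::floor((px[i] - grid.x0) / grid.h), 0, grid.nx - 1);
        int iy = grid.clampi((int)std::floor((py[i] - grid.y0) / grid.h), 0, grid.ny - 1);
        int iz = grid.clampi((int)std::floor((pz[i] - grid.z0) / grid.h), 0, grid.nz - 1);
        for (int dz = -1; dz <= 1; ++dz) {
          int jz = iz + dz;
          if (jz < 0 || jz >= grid.nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int jy = iy + dy;
            if (jy < 0 || jy >= grid.ny) continue;
            for (int dxo = -1; dxo <= 1; ++dxo) {
              int jx = ix + dxo;
              if (jx < 0 || jx >= grid.nx) continue;
              for (int j = grid.head[(size_t)(jz * grid.ny + jy) * grid.nx + jx];
                   j >= 0; j = grid.nxt[j]) {
                if (j > i) pair_force(i, j);
              }
            }
          }
        }
      }
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) pair_force(i, j);
    }

    // 4. wall repulsion; PSM impulses tallied into AP bins per chunk
    int chunk = it / record_every;
    for (int i = 0; i < n; ++i) {
      for (int w = 0; w < nw; ++w) {
        double d = wall_normal(w, 0) * px[i] + wall_normal(w, 1) * py[i] +
                   (dim == 3 ? wall_normal(w, 2) * pz[i] : 0.0) - wall_offset[w];
        if (d < rad[i]) {
          double dd = d < 0.0 ? 0.0 : d;
          double t = 1.0 - dd / rad[i];
          double mag = boundary_rep * t * t;
          bx[i] += mag * wall_normal(w, 0);
          by[i] += mag * wall_normal(w, 1);
          if (dim == 3) bz[i] += mag * wall_normal(w, 2);
          if (ty[i] == 1) {
            int b = (int)std::floor(px[i] / ap_bin_width);
            if (b < 0) b = 0;
            if (b >= n_ap_bins) b = n_ap_bins - 1;
            impulse(chunk, b) += mag;
          }
        }
      }
    }

    // 5. readouts: axis length and A->P interaction force on the 4
    //    posterior-most axial cells (cell-cell contributions only)
    if (n_axial >= 4) {
      int top[4] = {-1, -1, -1, -1};
      for (int a = 0; a < n_axial; ++a) {
        int i = axial_idx[a];
        for (int s = 0; s < 4; ++s) {
          if (top[s] < 0 || px[i] > px[top[s]]) {
            for (int t2 = 3; t2 > s; --t2) top[t2] = top[t2 - 1];
            top[s] = i;
            break;
          }
        }
      }
      double lsum = 0.0, fsum = 0.0;
      for (int s = 0; s < 4; ++s) { lsum += px[top[s]]; fsum += fx[top[s]]; }
      len_series[it] = lsum / 4.0;
      force_series[it] = fsum;
    } else {
      len_series[it] = NA_REAL;
      force_series[it] = NA_REAL;
    }

    // 6. Euler update with a per-step displacement clamp for stiff contacts
    for (int i = 0; i < n; ++i) {
      double vx = fx[i] + bx[i] + motility[ty[i]] * mdx[i];
      double vy = fy[i] + by[i] + motility[ty[i]] * mdy[i];
      double vz = (dim == 3) ? fz[i] + bz[i] + motility[ty[i]] * mdz[i] : 0.0;
      if (!R_finite(vx) || !R_finite(vy) || !R_finite(vz))
        stop("non-finite velocity for cell id %d at iteration %d",
             ids[i], iter0 + it + 1);
      double sx = vx * dt, sy = vy * dt, sz = vz * dt;
      double sn = std::sqrt(sx*sx + sy*sy + sz*sz);
      if (sn > step_clamp) {
        double f = step_clamp / sn;
        sx *= f; sy *= f; sz *= f;
      }
      px[i] += sx; py[i] += sy; pz[i] += sz;
      // keep cells inside rigid walls
      for (int w = 0; w < nw; ++w) {
        double d = wall_normal(w, 0) * px[i] + wall_normal(w, 1) * py[i] +
                   (dim == 3 ? wall_normal(w, 2) * pz[i] : 0.0) - wall_offset[w];
        if (d < 0.0) {
          px[i] -= d * wall_normal(w, 0);
          py[i] -= d * wall_normal(w, 1);
          if (dim == 3) pz[i] -= d * wall_normal(w, 2);
          ++n_clamped;
        }
      }
    }

    if ((it + 1) % record_every == 0 || it == n_iter - 1)
      take_snapshot(iter0 + it + 1);
  }

  n = (int)px.size();
  NumericMatrix fpos(n, dim);
  IntegerVector fid(n), fty(n);
  NumericVector frad(n), fadh(n);
  for (int i = 0; i < n; ++i) {
    fpos(i, 0) = px[i]; fpos(i, 1) = py[i];
    if (dim == 3) fpos(i, 2) = pz[i];
    fid[i] = ids[i]; fty[i] = ty[i]; frad[i] = rad[i]; fadh[i] = adh[i];
  }

  return List::create(
    _["pos"] = fpos, _["id"] = fid, _["type"] = fty,
    _["radius"] = frad, _["adh_dist"] = fadh,
    _["snapshots"] = snapshots,
    _["length_series"] = len_series,
    _["force_series"] = force_series,
    _["impulse"] = impulse,
    _["n_added"] = n_added, _["n_skipped"] = n_skipped,
    _["n_clamped"] = n_clamped, _["next_id"] = next_id);
}
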