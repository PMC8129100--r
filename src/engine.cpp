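#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <vector>

using namespace Rcpp;

// All three force laws share one shape: strength * 0.01^(d / tau), i.e. the
// magnitude drops to 1% of its maximum at d = tau.
static const double LN001 = std::log(0.01);

static inline double decay(double d, double tau) {
  return std::exp(LN001 * d / tau);
}

// logistic movement-freedom; u = (t - delay) / constant
static inline double freedom(double u) {
  if (u > 0.0) {
    double e = std::exp(-u);
    return e / (1.0 + e);
  }
  return 1.0 / (1.0 + std::exp(u));
}

// [[Rcpp::export]]
double cpp_movement_freedom(double t, double delay, double constant) {
  return freedom((t - delay) / constant);
}

struct ForcePars {
  double A, tau_a, R, tau_r, S, tau_s, g;
  double as[2][2]; // as[type_i][type_j], 0 = neuron, 1 = astrocyte
};

static ForcePars unpack_pars(const List &par) {
  ForcePars p;
  p.A = as<double>(par["A"]);
  p.tau_a = as<double>(par["tau_a"]);
  p.R = as<double>(par["R"]);
  p.tau_r = as<double>(par["tau_r"]);
  p.S = as<double>(par["S"]);
  p.tau_s = as<double>(par["tau_s"]);
  p.g = as<double>(par["g"]);
  NumericMatrix as_(as<NumericMatrix>(par["AS"]));
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      p.as[i][j] = as_(i, j);
  return p;
}

// Pairwise + anchor forces on every cell.  Cells are scanned through an
// x-sorted sliding window with a cutoff at the distance where the decay term
// falls below 1e-4 (two length constants), beyond which a pair contributes
// less than the displacement resolution.  Pair (i, j) is evaluated once; the
// repulsion is antisymmetric while the attraction felt by each partner is
// scaled by its own type-pair constant.
// Piecewise-linear table of exp(ln(0.01) * d / tau) over [0, cutoff]; the
// 0.05 um grid keeps the relative interpolation error below 1e-6, far under
// the displacement resolution of the dynamics.
struct DecayTable {
  double h, inv_h;
  std::vector<double> v;
  void build(double tau, double cutoff) {
    h = 0.05;
    inv_h = 1.0 / h;
    size_t n = (size_t)std::ceil(cutoff / h) + 2;
    v.resize(n);
    for (size_t i = 0; i < n; ++i) v[i] = std::exp(LN001 * (i * h) / tau);
  }
  inline double operator()(double d) const {
    double u = d * inv_h;
    size_t i = (size_t)u;
    if (i + 1 >= v.size()) return v.back();
    double f = u - i;
    return v[i] + f * (v[i + 1] - v[i]);
  }
};

static void accumulate_forces(const std::vector<double> &x,
                              const std::vector<double> &y,
                              const std::vector<double> &z,
                              const IntegerVector &type,
                              const std::vector<int> &ord,
                              const NumericMatrix &anchors,
                              const std::vector<int> &aord,
                              const ForcePars &p,
                              double cutoff_mult,
                              const DecayTable *tab_a,
                              const DecayTable *tab_r,
                              std::vector<double> &fx,
                              std::vector<double> &fy,
                              std::vector<double> &fz) {
  const int n = (int)x.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);

  const double cutoff = cutoff_mult * std::max(p.tau_a, p.tau_r);
  const double cut2 = cutoff * cutoff;
  const double eps = 1e-9;

  const bool cells_interact = (p.A != 0.0 || p.R != 0.0);
  if (cells_interact) {
    for (int a = 0; a < n; ++a) {
      const int i = ord[a];
      const double xi = x[i], yi = y[i], zi = z[i];
      const int ti = type[i];
      for (int b = a + 1; b < n; ++b) {
        const int j = ord[b];
        const double dx = x[j] - xi;
        if (dx > cutoff) break;
        const double dy = y[j] - yi;
        const double dz = z[j] - zi;
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > cut2) continue;
        const int tj = type[j];
        const double d = std::sqrt(d2);
        if (d < eps) {
          // coincident cells: direction undefined; attraction contributes
          // nothing, full repulsion along a random unit vector so they part
          double ux, uy, uz, nrm;
          do {
            ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
            nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          } while (nrm < eps);
          ux /= nrm; uy /= nrm; uz /= nrm;
          fx[i] -= p.R * ux; fy[i] -= p.R * uy; fz[i] -= p.R * uz;
          fx[j] += p.R * ux; fy[j] += p.R * uy; fz[j] += p.R * uz;
          continue;
        }
        const double att = p.A * (tab_a ? (*tab_a)(d)
                                        : std::exp(LN001 * d / p.tau_a));
        const double rep = p.R * (tab_r ? (*tab_r)(d)
                                        : std::exp(LN001 * d / p.tau_r));
        const double ux = dx / d, uy = dy / d, uz = dz / d;
        const double mi = p.as[ti][tj] * att - rep; // on i, toward j
        const double mj = p.as[tj][ti] * att - rep; // on j, toward i
        fx[i] += mi * ux; fy[i] += mi * uy; fz[i] += mi * uz;
        fx[j] -= mj * ux; fy[j] -= mj * uy; fz[j] -= mj * uz;
      }
    }
  }

  const int na = anchors.nrow();
  if (na > 0 && p.S != 0.0) {
    const double scut = cutoff_mult * p.tau_s;
    const double scut2 = scut * scut;
    // anchors sorted by x; binary search the window for each cell
    for (int i = 0; i < n; ++i) {
      const double xi = x[i], yi = y[i], zi = z[i];
      int lo = 0, hi = na;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (anchors(aord[mid], 0) < xi - scut) lo = mid + 1; else hi = mid;
      }
      for (int b = lo; b < na; ++b) {
        const int m = aord[b];
        const double dx = anchors(m, 0) - xi;
        if (dx > scut) break;
        const double dy = anchors(m, 1) - yi;
        const double dz = -zi;
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > scut2) continue;
        const double d = std::sqrt(d2);
        if (d < eps) continue; // undefined direction: no contribution
        const double m_s = p.S * std::exp(LN001 * d / p.tau_s) / d;
        fx[i] += m_s * dx; fy[i] += m_s * dy; fz[i] += m_s * dz;
      }
    }
  }
}

static std::vector<int> order_by(const std::vector<double> &v) {
  std::vector<int> ord(v.size());
  for (size_t i = 0; i < v.size(); ++i) ord[i] = (int)i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&v](int a, int b) { return v[a] < v[b]; });
  return ord;
}

// [[Rcpp::export]]
NumericMatrix cpp_net_forces(NumericMatrix pos, IntegerVector type,
                             NumericMatrix anchors, List par,
                             double cutoff_mult = 1e9) {
  const int n = pos.nrow();
  ForcePars p = unpack_pars(par);
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
  }
  std::vector<int> ord = order_by(x);
  std::vector<double> ax(anchors.nrow());
  for (int i = 0; i < anchors.nrow(); ++i) ax[i] = anchors(i, 0);
  std::vector<int> aord = order_by(ax);
  accumulate_forces(x, y, z, type, ord, anchors, aord, p, cutoff_mult,
                    nullptr, nullptr, fx, fy, fz);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  return out;
}

// confinement kind: 0 = slit (x in [0,L], y in [0,W]), 1 = disk (radius rad,
// centre at origin).  z >= 0 always; the top is open.
static inline void clamp_pos(int kind, double L, double W, double rad,
                             double &px, double &py, double &pz) {
  if (kind == 0) {
    if (px < 0.0) px = 0.0; else if (px > L) px = L;
    if (py < 0.0) py = 0.0; else if (py > W) py = W;
  } else {
    double r = std::sqrt(px * px + py * py);
    if (r > rad) {
      px *= rad / r;
      py *= rad / r;
    }
  }
  if (pz < 0.0) pz = 0.0;
}

// [[Rcpp::export]]
List cpp_run_simulation(NumericMatrix pos0, IntegerVector type,
                        NumericMatrix anchors, List par,
                        int total_time, double stiffening_delay,
                        double stiffening_constant,
                        int conf_kind, double L, double W, double rad,
                        int snapshot_every, double max_step) {
  const int n = pos0.nrow();
  ForcePars p = unpack_pars(par);
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  std::vector<double> ax(anchors.nrow());
  for (int i = 0; i < anchors.nrow(); ++i) ax[i] = anchors(i, 0);
  std::vector<int> aord = order_by(ax);

  std::vector<NumericMatrix> snaps;
  std::vector<int> snap_steps;

  const double cutoff = 2.0 * std::max(p.tau_a, p.tau_r);
  DecayTable tab_a, tab_r;
  tab_a.build(p.tau_a, cutoff);
  tab_r.build(p.tau_r, cutoff);

  for (int t = 1; t <= total_time; ++t) {
    const double k = freedom((t - stiffening_delay) / stiffening_constant);
    std::vector<int> ord = order_by(x);
    accumulate_forces(x, y, z, type, ord, anchors, aord, p, 2.0,
                      &tab_a, &tab_r, fx, fy, fz);
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(fx[i]) || !std::isfinite(fy[i]) ||
          !std::isfinite(fz[i]))
        stop("non-finite force on cell %d at step %d", i + 1, t);
      double dx = k * fx[i], dy = k * fy[i], dz = k * fz[i];
      if (max_step > 0.0) {
        // bounded migration speed: cap the force-driven displacement
        const double mag = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (mag > max_step) {
          const double sc = max_step / mag;
          dx *= sc; dy *= sc; dz *= sc;
        }
      }
      x[i] += dx;
      y[i] += dy;
      z[i] += dz - p.g;
      clamp_pos(conf_kind, L, W, rad, x[i], y[i], z[i]);
    }
    if ((snapshot_every > 0 && t % snapshot_every == 0) || t == total_time) {
      NumericMatrix s(n, 3);
      for (int i = 0; i < n; ++i) {
        s(i, 0) = x[i]; s(i, 1) = y[i]; s(i, 2) = z[i];
      }
      snaps.push_back(s);
      snap_steps.push_back(t);
    }
  }

  List out_snaps(snaps.size());
  for (size_t s = 0; s < snaps.size(); ++s) out_snaps[s] = snaps[s];
  return List::create(_["snapshots"] = out_snaps,
                      _["steps"] = wrap(snap_steps));
}

// Random placement with a hard-core minimum spacing, via rejection sampling
// over a uniform occupancy grid (cell side = spacing, 27/9-neighbourhood
// check).  kind: 0 slit volume, 1 disk volume, 2 slit floor (z = 0),
// 3 disk floor.  Draws come from R's RNG so set.seed() governs the layout.
// [[Rcpp::export]]
NumericMatrix cpp_place_points(int n, int kind, double L, double W,
                               double H, double rad, double spacing,
                               int max_attempts) {
  const bool volume = (kind == 0 || kind == 1);
  const bool disk = (kind == 1 || kind == 3);
  const double x0 = disk ? -rad : 0.0;
  const double y0 = disk ? -rad : 0.0;
  const double xext = disk ? 2.0 * rad : L;
  const double yext = disk ? 2.0 * rad : W;
  const double zext = volume ? H : 0.0;
  const double s2 = spacing * spacing;

  const int gx = std::max(1, (int)std::ceil(xext / spacing));
  const int gy = std::max(1, (int)std::ceil(yext / spacing));
  const int gz = std::max(1, volume ? (int)std::ceil(zext / spacing) : 1);
  std::vector<std::vector<int> > grid((size_t)gx * gy * gz);

  NumericMatrix out(n, volume ? 3 : 2);
  std::vector<double> px(n), py(n), pz(n);

  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int attempt = 0; attempt < max_attempts; ++attempt) {
      double cx, cy, cz = 0.0;
      if (disk) {
        // uniform in the disk by rejection from the bounding square
        do {
          cx = x0 + unif_rand() * xext;
          cy = y0 + unif_rand() * yext;
        } while (cx * cx + cy * cy > rad * rad);
      } else {
        cx = unif_rand() * xext;
        cy = unif_rand() * yext;
      }
      if (volume) cz = unif_rand() * zext;

      const int ix = std::min(gx - 1, (int)((cx - x0) / spacing));
      const int iy = std::min(gy - 1, (int)((cy - y0) / spacing));
      const int iz = std::min(gz - 1, volume ? (int)(cz / spacing) : 0);
      bool ok = true;
      for (int dx = -1; dx <= 1 && ok; ++dx) {
        const int jx = ix + dx;
        if (jx < 0 || jx >= gx) continue;
        for (int dy = -1; dy <= 1 && ok; ++dy) {
          const int jy = iy + dy;
          if (jy < 0 || jy >= gy) continue;
          for (int dz = -1; dz <= 1 && ok; ++dz) {
            const int jz = iz + dz;
            if (jz < 0 || jz >= gz) continue;
            const std::vector<int> &cell =
                grid[(size_t)jx + (size_t)gx * (jy + (size_t)gy * jz)];
            for (size_t q = 0; q < cell.size(); ++q) {
              const int j = cell[q];
              const double ddx = px[j] - cx, ddy = py[j] - cy,
                           ddz = pz[j] - cz;
              if (ddx * ddx + ddy * ddy + ddz * ddz < s2) {
                ok = false;
                break;
              }
            }
          }
        }
      }
      if (ok) {
        px[i] = cx; py[i] = cy; pz[i] = cz;
        grid[(size_t)ix + (size_t)gx * (iy + (size_t)gy * iz)].push_back(i);
        placed = true;
        break;
      }
    }
    if (!placed)
      stop("packing infeasible: placed %d of %d points at spacing %.1f",
           i, n, spacing);
    out(i, 0) = px[i];
    out(i, 1) = py[i];
    if (volume) out(i, 2) = pz[i];
  }
  return out;
}

// Full 2D cross-correlation of two equal-shape images with zero padding:
// C(k, l) = sum_{m,n} X(m, n) * Y(m - k, n - l),
// k in -(M-1)..(M-1), l in -(N-1)..(N-1); element [k + M, l + N] of the
// returned (2M-1) x (2N-1) matrix (1-based), so the centre holds sum(X * Y).
// [[Rcpp::export]]
NumericMatrix cpp_xcorr2d(NumericMatrix X, NumericMatrix Y) {
  const int M = X.nrow(), N = X.ncol();
  if (Y.nrow() != M || Y.ncol() != N)
    stop("images must have identical dimensions");
  NumericMatrix C(2 * M - 1, 2 * N - 1);
  for (int k = -(M - 1); k <= M - 1; ++k) {
    const int mlo = std::max(0, k), mhi = std::min(M, M + k);
    for (int l = -(N - 1); l <= N - 1; ++l) {
      const int nlo = std::max(0, l), nhi = std::min(N, N + l);
      double acc = 0.0;
      for (int m = mlo; m < mhi; ++m)
        for (int nn = nlo; nn < nhi; ++nn)
          acc += X(m, nn) * Y(m - k, nn - l);
      C(k + M - 1, l + N - 1) = acc;
    }
  }
  return C;
}

// Connected-component labelling of a binary mask.  dims has length 2 or 3;
// connectivity: 4 or 8 (2D), 6 or 26 (3D).  Labels are assigned in
// column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nd = dims.size();
  if (nd != 2 && nd != 3) stop("mask must be 2- or 3-dimensional");
  const int dx = dims[0], dy = dims[1], dz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t total = (R_xlen_t)dx * dy * dz;
  if (mask.size() != total) stop("mask length does not match dims");

  std::vector<std::array<int, 3> > offs;
  const bool full = (nd == 2) ? (connectivity == 8) : (connectivity == 26);
  for (int ox = -1; ox <= 1; ++ox)
    for (int oy = -1; oy <= 1; ++oy)
      for (int oz = (nd == 3 ? -1 : 0); oz <= (nd == 3 ? 1 : 0); ++oz) {
        if (ox == 0 && oy == 0 && oz == 0) continue;
        const int manh = std::abs(ox) + std::abs(oy) + std::abs(oz);
        if (!full && manh != 1) continue;
        offs.push_back({{ox, oy, oz}});
      }

  IntegerVector lab(total, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < total; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int cz = (int)(cur / ((R_xlen_t)dx * dy));
      const int rem = (int)(cur % ((R_xlen_t)dx * dy));
      const int cy = rem / dx;
      const int cx = rem % dx;
      for (size_t o = 0; o < offs.size(); ++o) {
        const int nx = cx + offs[o][0], ny = cy + offs[o][1],
                  nz = cz + offs[o][2];
        if (nx < 0 || nx >= dx || ny < 0 || ny >= dy || nz < 0 || nz >= dz)
          continue;
        const R_xlen_t idx = nx + (R_xlen_t)dx * (ny + (R_xlen_t)dy * nz);
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Index pair (1-based) at maximum Euclidean distance among row points.
// [[Rcpp::export]]
List cpp_max_pair_distance(NumericMatrix pts) {
  const int n = pts.nrow(), d = pts.ncol();
  if (n < 2) stop("need at least two points");
  double best = -1.0;
  int bi = 0, bj = 1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double acc = 0.0;
      for (int c = 0; c < d; ++c) {
        const double dd = pts(i, c) - pts(j, c);
        acc += dd * dd;
      }
      if (acc > best) {
        best = acc;
        bi = i;
        bj = j;
      }
    }
  return List::create(_["i"] = bi + 1, _["j"] = bj + 1,
                      _["distance"] = std::sqrt(best));
}
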