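// Compiled simulation core: contact bookkeeping, pathway integration,
// mechanics and cell cycle, orchestrated with operator splitting at the
// pathway step size (default 0.01 min). The R surface exposes the same
// formulas as plain functions; tests cross-check both routes.
//
// Units: um, min, pN (1 Pa = 1 pN/um^2).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

struct Site {
  int partner;
  double area, prev_area, EBc;
};

struct Cell {
  int id;
  double x, y, r, expr, E, B, EB;
  int phase;  // 0 = G1, 1 = REST, 2 = M
  double clock_, rest, pressure;
  bool arrested;
  int sibling;  // -1 = none
  bool alive;
  std::vector<Site> sites;
};

struct Params {
  double nu_p, nu_n, rho_c, rho_u, rho_d, gamma;
  double R, sigma, Emod, eta, noise_amp, pthresh;
  double tG1, tM, rest_min, rest_max;
  int variant;  // 1, 2, 3
  bool ci, cycle_on, collapse_on;
  double dt, cap, min_frac, collapse_frac, drain_tol, sat_frac;
  int max_substeps;
};

static const double FORCE_REF = 210000.0;  // pN at the calibration anchor

// ---- geometry -------------------------------------------------------------

static double contact_area(double d, double Ri, double Rj) {
  if (d >= Ri + Rj) return 0.0;
  double rmin = std::min(Ri, Rj);
  double a2;
  if (d <= std::fabs(Ri - Rj)) {
    a2 = rmin * rmin;
  } else {
    double t = d * d - Rj * Rj + Ri * Ri;
    a2 = (4.0 * d * d * Ri * Ri - t * t) / (4.0 * d * d);
    if (a2 < 0.0) a2 = 0.0;
    if (a2 > rmin * rmin) a2 = rmin * rmin;
  }
  return M_PI * a2;
}

static double natural_distance(double Ri, double Rj) {
  // contact-circle radius equal to pi * mean radius / 6
  double a = M_PI * (Ri + Rj) / 12.0;
  double mi = std::min(Ri, Rj);
  if (a >= mi) return 0.0;
  return std::sqrt(Ri * Ri - a * a) + std::sqrt(Rj * Rj - a * a);
}

static double hertz(double d, double Ri, double Rj, const Params &P) {
  double h = Ri + Rj - d;
  if (h <= 0.0) return 0.0;
  double pref = std::sqrt(Ri * Rj / (Ri + Rj)) /
                (0.75 * 2.0 * (1.0 - P.sigma * P.sigma) / P.Emod);
  return h * std::sqrt(h) * pref;
}

static double bond_force(double m, int variant) {
  double anchor = (variant == 1) ? 15.0 : 80.0;
  return m / anchor * FORCE_REF;
}

// ---- world helpers --------------------------------------------------------

static bool m_siblings(const Cell &a, const Cell &b) {
  return a.sibling == b.id && a.phase == 2 && b.phase == 2;
}

static Site *find_site(Cell &c, int partner) {
  for (auto &s : c.sites)
    if (s.partner == partner) return &s;
  return nullptr;
}

static double drag(double r, const Params &P) {
  return 6.0 * M_PI * (P.eta / 60.0) * r;  // pN min / um
}

// grid-based candidate pairs with d < Ri + Rj (skips nothing else)
static void find_pairs(const std::vector<Cell> &cells, double bin,
                       std::vector<std::pair<int, int>> &out) {
  out.clear();
  int n = (int)cells.size();
  if (n < 2) return;
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(n * 2);
  auto key = [bin](double x, double y) {
    int64_t ix = (int64_t)std::floor(x / bin);
    int64_t iy = (int64_t)std::floor(y / bin);
    return (ix << 32) ^ (iy & 0xffffffffLL);
  };
  for (int i = 0; i < n; ++i) grid[key(cells[i].x, cells[i].y)].push_back(i);
  for (int i = 0; i < n; ++i) {
    int64_t ix = (int64_t)std::floor(cells[i].x / bin);
    int64_t iy = (int64_t)std::floor(cells[i].y / bin);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        int64_t k = ((ix + dx) << 32) ^ ((iy + dy) & 0xffffffffLL);
        auto it = grid.find(k);
        if (it == grid.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          double ddx = cells[i].x - cells[j].x, ddy = cells[i].y - cells[j].y;
          double d2 = ddx * ddx + ddy * ddy;
          double reach = cells[i].r + cells[j].r;
          if (d2 < reach * reach) out.push_back({i, j});
        }
      }
  }
}

// ---- bookkeeping ----------------------------------------------------------

static void bookkeeping(std::vector<Cell> &cells,
                        std::vector<int> &id2idx,
                        std::vector<std::pair<int, int>> &pairs,
                        const Params &P) {
  for (auto &c : cells)
    for (auto &s : c.sites) {
      s.prev_area = s.area;
      s.area = 0.0;
    }
  find_pairs(cells, 2.0 * P.R, pairs);
  for (auto &pr : pairs) {
    Cell &a = cells[pr.first];
    Cell &b = cells[pr.second];
    if (m_siblings(a, b)) continue;
    double d = std::hypot(a.x - b.x, a.y - b.y);
    double area = contact_area(d, a.r, b.r);
    if (area <= 0.0 && d < a.r + b.r) area = 1e-12;  // grazing overlap
    if (d >= a.r + b.r) continue;
    Site *sa = find_site(a, b.id);
    if (!sa) {
      a.sites.push_back({b.id, area, 0.0, 0.0});
    } else {
      sa->area = area;
    }
    Site *sb = find_site(b, a.id);
    if (!sb) {
      b.sites.push_back({a.id, area, 0.0, 0.0});
    } else {
      sb->area = area;
    }
  }
  // drop drained detached sites (residue back to the cytosol pool)
  for (auto &c : cells) {
    for (size_t k = 0; k < c.sites.size();) {
      Site &s = c.sites[k];
      bool partner_alive =
          s.partner < (int)id2idx.size() && id2idx[s.partner] >= 0;
      bool drained = s.area <= 0.0 && s.EBc < P.drain_tol;
      bool mirror_drained = true;
      if (partner_alive) {
        Cell &p = cells[id2idx[s.partner]];
        Site *ms = find_site(p, c.id);
        if (ms && (ms->area > 0.0 || ms->EBc >= P.drain_tol))
          mirror_drained = false;
      }
      if (drained && mirror_drained) {
        c.EB += s.EBc;
        c.sites[k] = c.sites.back();
        c.sites.pop_back();
      } else {
        ++k;
      }
    }
  }
}

// ---- pathway --------------------------------------------------------------

// one Euler substep with exact-conservation flux limiting
static void pathway_substep(Cell &c, const Params &P, double h) {
  int n = (int)c.sites.size();
  double bind = P.nu_p * c.E * c.B;
  double diss = P.nu_n * c.EB;
  if (bind > 0.0) {
    double lim = 1.0;
    if (bind * h > c.E) lim = c.E / (bind * h);
    if (bind * h > c.B) lim = std::min(lim, c.B / (bind * h));
    bind *= lim;
  }
  if (n == 0) {
    if (diss * h > c.EB && diss > 0.0) diss = c.EB / h;
    double dE = -bind + diss;
    c.E += h * dE;
    c.B += h * dE;
    c.EB += h * (bind - diss);
    if (c.E < 0) c.E = 0;
    if (c.B < 0) c.B = 0;
    if (c.EB < 0) c.EB = 0;
    return;
  }
  std::vector<double> ci(n), di(n), rin(n, 0.0), rout(n, 0.0);
  double total = 0.0;
  for (auto &s : c.sites) total += s.EBc;
  double surface = 4.0 * M_PI * c.r * c.r;
  double sat_global =
      std::max(0.0, 1.0 - total / (P.sat_frac * c.expr));
  double sum_c = 0.0;
  for (int i = 0; i < n; ++i) {
    const Site &s = c.sites[i];
    double a_c = 0.0, a_d = 0.0;
    if (s.area > s.prev_area)
      a_c = (s.area - s.prev_area) / std::max(s.area, 1e-12);
    else if (s.prev_area > s.area)
      a_d = (s.prev_area - s.area) / std::max(s.prev_area, 1e-12);
    if (a_c > 1.0) a_c = 1.0;
    if (a_d > 1.0) a_d = 1.0;
    double sat = (P.variant == 1)
                     ? std::max(0.0, 1.0 - s.EBc / (c.expr / 6.0))
                     : sat_global;
    ci[i] = (P.rho_c * a_c + P.rho_u * s.area / surface) * c.EB * sat;
    di[i] = P.rho_d * a_d * s.EBc;
    sum_c += ci[i];
  }
  double out_EB = diss + sum_c;
  if (out_EB * h > c.EB && out_EB > 0.0) {
    double sc = c.EB / (out_EB * h);
    diss *= sc;
    sum_c = 0.0;
    for (int i = 0; i < n; ++i) {
      ci[i] *= sc;
      sum_c += ci[i];
    }
  }
  // pairwise redistribution between attached sites (Models 2/3)
  std::vector<double> transfer;
  if (P.variant != 1 && n > 1) {
    transfer.assign((size_t)n * n, 0.0);
    for (int i = 0; i < n; ++i) {
      if (c.sites[i].area <= 0.0) continue;
      for (int j = 0; j < n; ++j) {
        if (i == j || c.sites[j].area <= 0.0) continue;
        double diff = c.sites[i].EBc - c.sites[j].EBc;
        if (diff > 0.0) transfer[(size_t)i * n + j] = P.gamma * diff;
      }
    }
    for (int i = 0; i < n; ++i) {
      double out_site = di[i];
      for (int j = 0; j < n; ++j) out_site += transfer[(size_t)i * n + j];
      if (out_site * h > c.sites[i].EBc && out_site > 0.0) {
        double sc = c.sites[i].EBc / (out_site * h);
        di[i] *= sc;
        for (int j = 0; j < n; ++j) transfer[(size_t)i * n + j] *= sc;
      }
    }
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        rout[i] += transfer[(size_t)i * n + j];
        rin[j] += transfer[(size_t)i * n + j];
      }
  } else {
    for (int i = 0; i < n; ++i) {
      if (di[i] * h > c.sites[i].EBc && di[i] > 0.0)
        di[i] = c.sites[i].EBc / h;
    }
  }
  double sum_d = 0.0;
  for (int i = 0; i < n; ++i) sum_d += di[i];
  double dE = -bind + diss;
  c.E += h * dE;
  c.B += h * dE;
  c.EB += h * (bind - diss - sum_c + sum_d);
  for (int i = 0; i < n; ++i)
    c.sites[i].EBc += h * (ci[i] - di[i] + rin[i] - rout[i]);
  if (c.E < 0) c.E = 0;
  if (c.B < 0) c.B = 0;
  if (c.EB < 0) c.EB = 0;
  for (auto &s : c.sites)
    if (s.EBc < 0) s.EBc = 0;
}

static void pathway_step(Cell &c, const Params &P) {
  // choose substeps so no pool loses more than half its content per substep
  double max_frac = 0.0;
  {
    double bind = P.nu_p * c.E * c.B;
    double diss = P.nu_n * c.EB;
    double sum_c = 0.0, surface = 4.0 * M_PI * c.r * c.r, total = 0.0;
    for (auto &s : c.sites) total += s.EBc;
    double sat_global = std::max(0.0, 1.0 - total / (P.sat_frac * c.expr));
    for (auto &s : c.sites) {
      double a_c = 0.0, a_d = 0.0;
      if (s.area > s.prev_area)
        a_c = std::min(1.0, (s.area - s.prev_area) / std::max(s.area, 1e-12));
      else if (s.prev_area > s.area)
        a_d = std::min(1.0,
                       (s.prev_area - s.area) / std::max(s.prev_area, 1e-12));
      double sat = (P.variant == 1)
                       ? std::max(0.0, 1.0 - s.EBc / (c.expr / 6.0))
                       : sat_global;
      sum_c += (P.rho_c * a_c + P.rho_u * s.area / surface) * c.EB * sat;
      double out_site = P.rho_d * a_d * s.EBc +
                        ((P.variant != 1) ? P.gamma * total : 0.0);
      if (s.EBc > 1e-12)
        max_frac = std::max(max_frac, out_site * P.dt / s.EBc);
    }
    if (c.E > 1e-12) max_frac = std::max(max_frac, bind * P.dt / c.E);
    if (c.B > 1e-12) max_frac = std::max(max_frac, bind * P.dt / c.B);
    if (c.EB > 1e-12)
      max_frac = std::max(max_frac, (diss + sum_c) * P.dt / c.EB);
  }
  int n_sub = 1;
  while (max_frac / n_sub > 0.5 && n_sub < 16) n_sub *= 2;
  double h = P.dt / n_sub;
  for (int k = 0; k < n_sub; ++k) pathway_substep(c, P, h);
}

// ---- mechanics ------------------------------------------------------------

static void compute_forces(std::vector<Cell> &cells,
                           const std::vector<int> &id2idx, const Params &P,
                           std::vector<double> &fx, std::vector<double> &fy) {
  int n = (int)cells.size();
  fx.assign(n, 0.0);
  fy.assign(n, 0.0);
  for (auto &c : cells) c.pressure = 0.0;
  for (int i = 0; i < n; ++i) {
    Cell &a = cells[i];
    for (auto &s : a.sites) {
      if (s.partner >= (int)id2idx.size()) continue;
      int j = id2idx[s.partner];
      if (j < 0 || j <= i) continue;  // each pair once, dead partners skip
      Cell &b = cells[j];
      if (m_siblings(a, b)) continue;
      double dx = b.x - a.x, dy = b.y - a.y;
      double d = std::hypot(dx, dy);
      if (d < 1e-9) continue;
      double ux = dx / d, uy = dy / d;
      double frep = hertz(d, a.r, b.r, P);
      double fadh = 0.0;
      if (P.variant != 3) {
        // Models 1/2: constantly active adhesive pull. Model 3 bonds act as
        // separation constraints, applied during motion integration instead.
        Site *mirror = find_site(b, a.id);
        double m = std::min(s.EBc, mirror ? mirror->EBc : 0.0);
        fadh = bond_force(m, P.variant);
      }
      double f = fadh - frep;
      fx[i] += f * ux;
      fy[i] += f * uy;
      fx[j] -= f * ux;
      fy[j] -= f * uy;
      a.pressure += frep;
      b.pressure += frep;
    }
  }
}

// Model 3 separation-force framework: a bonded pair beyond its natural
// state resists separation. The constraint cancels the separating
// component of the pair's relative velocity with an equal-and-opposite
// centre-line force capped at the bond separation force; bonds never
// actively compress. A few Gauss-Seidel sweeps resolve pair coupling.
struct BondPair {
  int i, j;
  double ux, uy, budget, used;
};

static void collect_bonds(std::vector<Cell> &cells,
                          const std::vector<int> &id2idx, const Params &P,
                          std::vector<BondPair> &bonds) {
  bonds.clear();
  int n = (int)cells.size();
  for (int i = 0; i < n; ++i) {
    Cell &a = cells[i];
    for (auto &s : a.sites) {
      if (s.partner >= (int)id2idx.size()) continue;
      int j = id2idx[s.partner];
      if (j < 0 || j <= i) continue;
      Cell &b = cells[j];
      if (m_siblings(a, b)) continue;
      double dx = b.x - a.x, dy = b.y - a.y;
      double d = std::hypot(dx, dy);
      if (d < 1e-9 || d <= natural_distance(a.r, b.r)) continue;
      Site *mirror = find_site(b, a.id);
      double m = std::min(s.EBc, mirror ? mirror->EBc : 0.0);
      if (m <= 0.0) continue;
      bonds.push_back({i, j, dx / d, dy / d, bond_force(m, P.variant), 0.0});
    }
  }
}

static void separation_projection(std::vector<Cell> &cells,
                                  std::vector<BondPair> &bonds,
                                  const Params &P, std::vector<double> &vx,
                                  std::vector<double> &vy) {
  for (int sweep = 0; sweep < 4; ++sweep) {
    double worst = 0.0;
    for (auto &bp : bonds) {
      double gi = drag(cells[bp.i].r, P), gj = drag(cells[bp.j].r, P);
      double s = (vx[bp.j] - vx[bp.i]) * bp.ux + (vy[bp.j] - vy[bp.i]) * bp.uy;
      double f;
      if (s > 0.0) {
        f = std::min(s / (1.0 / gi + 1.0 / gj), bp.budget - bp.used);
      } else if (bp.used > 0.0 && s < 0.0) {
        // relax over-applied resistance if the pair started re-approaching
        f = std::max(s / (1.0 / gi + 1.0 / gj), -bp.used);
      } else {
        continue;
      }
      bp.used += f;
      vx[bp.i] += f / gi * bp.ux;
      vy[bp.i] += f / gi * bp.uy;
      vx[bp.j] -= f / gj * bp.ux;
      vy[bp.j] -= f / gj * bp.uy;
      worst = std::max(worst, std::fabs(f));
    }
    if (worst < 1e-9) break;
  }
}

// M-phase dumb-bell rigidity: the two daughter lobes keep their
// centre-to-centre separation (R, the parent diameter over 2 on each
// side) until division completes. External forces translate and rotate
// the dumb-bell but cannot squeeze the lobes into each other.
static void enforce_dumbbell(std::vector<Cell> &cells,
                             const std::vector<int> &id2idx,
                             const Params &P) {
  for (auto &a : cells) {
    if (a.phase != 2 || a.sibling < 0) continue;
    if (a.sibling < a.id) continue;  // handle each pair once
    if (a.sibling >= (int)id2idx.size()) continue;
    int j = id2idx[a.sibling];
    if (j < 0) continue;
    Cell &b = cells[j];
    if (b.phase != 2) continue;
    double mx = (a.x + b.x) / 2.0, my = (a.y + b.y) / 2.0;
    double dx = a.x - b.x, dy = a.y - b.y;
    double d = std::hypot(dx, dy);
    double ux = 1.0, uy = 0.0;
    if (d > 1e-9) {
      ux = dx / d;
      uy = dy / d;
    }
    double half = P.R / 2.0;
    a.x = mx + half * ux;
    a.y = my + half * uy;
    b.x = mx - half * ux;
    b.y = my - half * uy;
  }
}

static void enforce_floor(std::vector<Cell> &cells, const Params &P) {
  int n = (int)cells.size();
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dmin = P.min_frac * (cells[i].r + cells[j].r);
      double dx = cells[j].x - cells[i].x, dy = cells[j].y - cells[i].y;
      double d = std::hypot(dx, dy);
      if (d < dmin) {
        double ux, uy;
        if (d < 1e-9) {
          ux = 1.0;
          uy = 0.0;
          d = dmin;
        } else {
          ux = dx / d;
          uy = dy / d;
        }
        double push = (dmin - d) / 2.0;
        cells[i].x -= ux * push;
        cells[i].y -= uy * push;
        cells[j].x += ux * push;
        cells[j].y += uy * push;
      }
    }
}

static void mechanics(std::vector<Cell> &cells, const std::vector<int> &id2idx,
                      const Params &P) {
  int n = (int)cells.size();
  if (n == 0) return;
  std::vector<double> nx(n, 0.0), ny(n, 0.0);
  if (P.noise_amp > 0.0)
    for (int i = 0; i < n; ++i) {
      nx[i] = R::rnorm(0.0, P.noise_amp);
      ny[i] = R::rnorm(0.0, P.noise_amp);
    }
  std::vector<double> fx, fy;
  std::vector<BondPair> bonds;
  double remaining = P.dt;
  int steps = 0;
  while (remaining > 1e-12 && steps < P.max_substeps) {
    ++steps;
    compute_forces(cells, id2idx, P, fx, fy);
    double vmax = 0.0;
    std::vector<double> vx(n), vy(n);
    for (int i = 0; i < n; ++i) {
      double g = drag(cells[i].r, P);
      vx[i] = (fx[i] + nx[i]) / g;
      vy[i] = (fy[i] + ny[i]) / g;
    }
    if (P.variant == 3) {
      collect_bonds(cells, id2idx, P, bonds);
      separation_projection(cells, bonds, P, vx, vy);
    }
    for (int i = 0; i < n; ++i)
      vmax = std::max(vmax, std::hypot(vx[i], vy[i]));
    double dt_s = (vmax > 0.0) ? std::min(remaining, P.cap / vmax) : remaining;
    std::vector<double> px(n), py(n);
    for (int i = 0; i < n; ++i) {
      px[i] = cells[i].x;
      py[i] = cells[i].y;
      double ddx = vx[i] * dt_s, ddy = vy[i] * dt_s;
      double mag = std::hypot(ddx, ddy);
      if (mag > P.cap) {
        ddx *= P.cap / mag;
        ddy *= P.cap / mag;
      }
      cells[i].x += ddx;
      cells[i].y += ddy;
    }
    if (P.cycle_on) enforce_dumbbell(cells, id2idx, P);
    if (!P.collapse_on && n <= 16) enforce_floor(cells, P);
    remaining -= dt_s;
    // a statically pinned or equilibrated configuration stays put for the
    // rest of the step (forces are frozen within it): stop sub-stepping
    double moved = 0.0;
    for (int i = 0; i < n; ++i)
      moved = std::max(moved, std::hypot(cells[i].x - px[i],
                                         cells[i].y - py[i]));
    if (moved < 1e-7) break;
  }
  compute_forces(cells, id2idx, P, fx, fy);  // refresh pressure post-motion
}

// ---- cell cycle -----------------------------------------------------------

static void division_axis(Cell &c, std::vector<Cell> &cells,
                          const std::vector<int> &id2idx, const Params &P,
                          double &ax, double &ay) {
  double mxx = 0.0, mxy = 0.0, myy = 0.0, tot = 0.0;
  for (auto &s : c.sites) {
    if (s.partner >= (int)id2idx.size()) continue;
    int j = id2idx[s.partner];
    if (j < 0) continue;
    Cell &b = cells[j];
    double dx = b.x - c.x, dy = b.y - c.y;
    double d = std::hypot(dx, dy);
    if (d < 1e-9 || d >= c.r + b.r) continue;
    double f = hertz(d, c.r, b.r, P);
    if (f <= 0.0) continue;
    double ux = dx / d, uy = dy / d;
    mxx += f * ux * ux;
    mxy += f * ux * uy;
    myy += f * uy * uy;
    tot += f;
  }
  if (tot <= 0.0 ||
      (std::fabs(mxy) < 1e-12 * tot && std::fabs(mxx - myy) < 1e-12 * tot)) {
    double ang = R::runif(0.0, 2.0 * M_PI);
    ax = std::cos(ang);
    ay = std::sin(ang);
    return;
  }
  double theta = 0.5 * std::atan2(2.0 * mxy, mxx - myy);
  ax = std::cos(theta);
  ay = std::sin(theta);
}

static void cycle_and_divide(std::vector<Cell> &cells,
                             std::vector<int> &id2idx, const Params &P,
                             int &next_id) {
  double Rdiv = P.R / std::cbrt(2.0);
  std::vector<Cell> daughters;
  for (auto &c : cells) {
    if (!c.alive) continue;
    if (c.phase == 2) {  // M
      c.clock_ += P.dt;
      if (c.clock_ >= P.tM) {
        c.phase = 0;
        c.clock_ = 0.0;
        c.sibling = -1;
      }
    } else if (c.phase == 0) {  // G1
      c.clock_ += P.dt;
      double frac = std::min(1.0, c.clock_ / P.tG1);
      c.r = Rdiv + (P.R - Rdiv) * frac;
      if (c.clock_ >= P.tG1) {
        c.phase = 1;
        c.clock_ = 0.0;
        if (c.rest < 0.0) c.rest = R::runif(P.rest_min, P.rest_max);
      }
    } else {  // REST
      c.r = P.R;
      if (c.rest < 0.0) c.rest = R::runif(P.rest_min, P.rest_max);
      c.clock_ += P.dt;
      if (c.clock_ >= c.rest) {
        if (P.ci && c.pressure > P.pthresh) {
          c.arrested = true;  // hold; re-checked every step
        } else {
          c.arrested = false;
          // divide at M entry: replace by two dumb-bell daughters
          double ax, ay;
          division_axis(c, cells, id2idx, P, ax, ay);
          double EB_pool = c.EB;
          for (auto &s : c.sites) EB_pool += s.EBc;
          int idA = next_id++, idB = next_id++;
          for (int k = 0; k < 2; ++k) {
            Cell d;
            double sgn = (k == 0) ? 1.0 : -1.0;
            d.id = (k == 0) ? idA : idB;
            d.x = c.x + sgn * (P.R / 2.0) * ax;
            d.y = c.y + sgn * (P.R / 2.0) * ay;
            d.r = Rdiv;
            d.expr = c.expr;
            d.E = c.E;
            d.B = c.B;
            d.EB = EB_pool;
            d.phase = 2;
            d.clock_ = 0.0;
            d.rest = -1.0;
            d.pressure = 0.0;
            d.arrested = false;
            d.sibling = (k == 0) ? idB : idA;
            d.alive = true;
            daughters.push_back(d);
          }
          c.alive = false;
        }
      }
    }
  }
  if (!daughters.empty() ||
      std::any_of(cells.begin(), cells.end(),
                  [](const Cell &c) { return !c.alive; })) {
    std::vector<Cell> kept;
    kept.reserve(cells.size() + daughters.size());
    for (auto &c : cells)
      if (c.alive) kept.push_back(std::move(c));
    for (auto &d : daughters) kept.push_back(std::move(d));
    cells.swap(kept);
    int maxid = 0;
    for (auto &c : cells) maxid = std::max(maxid, c.id);
    id2idx.assign(maxid + 1, -1);
    for (int i = 0; i < (int)cells.size(); ++i) id2idx[cells[i].id] = i;
  }
}

// ---- collapse -------------------------------------------------------------

static bool collapsed(std::vector<Cell> &cells, const Params &P,
                      std::vector<std::pair<int, int>> &pairs) {
  find_pairs(cells, 2.0 * P.R, pairs);
  for (auto &pr : pairs) {
    Cell &a = cells[pr.first];
    Cell &b = cells[pr.second];
    if (m_siblings(a, b)) continue;
    double d = std::hypot(a.x - b.x, a.y - b.y);
    if (d < P.collapse_frac * (a.r + b.r)) return true;
  }
  return false;
}

// ---- snapshots ------------------------------------------------------------

static List snapshot(const std::vector<Cell> &cells,
                     const std::vector<int> &id2idx, const Params &P,
                     double time, const std::string &status) {
  int n = (int)cells.size();
  IntegerVector id(n), sibling(n);
  NumericVector x(n), y(n), radius(n), expr(n), E(n), B(n), EB(n), clk(n),
      rest(n), pressure(n);
  CharacterVector phase(n);
  LogicalVector arrested(n);
  const char *phases[3] = {"G1", "REST", "M"};
  int ncon = 0;
  for (auto &c : cells) ncon += (int)c.sites.size();
  IntegerVector ci(ncon), cj(ncon);
  NumericVector area(ncon), prev_area(ncon), ebi(ncon), ebj(ncon),
      force(ncon);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    const Cell &c = cells[i];
    id[i] = c.id;
    x[i] = c.x;
    y[i] = c.y;
    radius[i] = c.r;
    expr[i] = c.expr;
    E[i] = c.E;
    B[i] = c.B;
    EB[i] = c.EB;
    phase[i] = phases[c.phase];
    clk[i] = c.clock_;
    rest[i] = (c.rest < 0.0) ? NA_REAL : c.rest;
    arrested[i] = c.arrested;
    sibling[i] = (c.sibling < 0) ? NA_INTEGER : c.sibling;
    pressure[i] = c.pressure;
    for (auto &s : c.sites) {
      int jj = (s.partner < (int)id2idx.size()) ? id2idx[s.partner] : -1;
      // each live pair once (smaller id reports); dead-partner draining
      // sites always reported by the surviving cell
      if (jj >= 0 && s.partner < c.id) continue;
      double mirror = 0.0;
      if (jj >= 0) {
        const Cell &b = cells[jj];
        for (auto &ms : b.sites)
          if (ms.partner == c.id) mirror = ms.EBc;
      }
      ci[k] = c.id;
      cj[k] = s.partner;
      area[k] = s.area;
      prev_area[k] = s.prev_area;
      ebi[k] = s.EBc;
      ebj[k] = mirror;
      // separation force via the bond map (Model 3 gating not applied:
      // this is the dual-pipette-comparable quantity)
      force[k] = bond_force(std::min(s.EBc, mirror), P.variant);
      ++k;
    }
  }
  DataFrame cdf = DataFrame::create(
      _["id"] = id, _["x"] = x, _["y"] = y, _["radius"] = radius,
      _["expression"] = expr, _["E"] = E, _["B"] = B, _["EB"] = EB,
      _["phase"] = phase, _["phase_clock"] = clk, _["rest_duration"] = rest,
      _["arrested"] = arrested, _["sibling"] = sibling,
      _["pressure"] = pressure, _["stringsAsFactors"] = false);
  DataFrame con;
  if (k > 0) {
    con = DataFrame::create(
        _["cell_i"] = ci[Range(0, k - 1)], _["cell_j"] = cj[Range(0, k - 1)],
        _["area"] = area[Range(0, k - 1)],
        _["prev_area"] = prev_area[Range(0, k - 1)],
        _["EBc_i"] = ebi[Range(0, k - 1)], _["EBc_j"] = ebj[Range(0, k - 1)],
        _["force_pN"] = force[Range(0, k - 1)]);
  } else {
    con = DataFrame::create(_["cell_i"] = IntegerVector(0),
                            _["cell_j"] = IntegerVector(0),
                            _["area"] = NumericVector(0),
                            _["prev_area"] = NumericVector(0),
                            _["EBc_i"] = NumericVector(0),
                            _["EBc_j"] = NumericVector(0),
                            _["force_pN"] = NumericVector(0));
  }
  return List::create(_["time"] = time, _["cells"] = cdf, _["contacts"] = con,
                      _["status"] = status);
}

// ---- main entry -----------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_colony(DataFrame cells_df, DataFrame contacts_df, List cfg) {
  Params P;
  List kin = cfg["kinetic"], mech = cfg["mech"], cyc = cfg["cycle"];
  P.nu_p = kin["nu_p"];
  P.nu_n = kin["nu_n"];
  P.rho_c = kin["rho_c"];
  P.rho_u = kin["rho_u"];
  P.rho_d = kin["rho_d"];
  P.gamma = kin["gamma"];
  P.R = mech["R"];
  P.sigma = mech["sigma"];
  P.Emod = mech["E_mod"];
  P.eta = mech["eta"];
  P.noise_amp = mech["noise_amp"];
  P.pthresh = mech["pressure_threshold"];
  P.tG1 = cyc["t_G1"];
  P.tM = cyc["t_M"];
  P.rest_min = cyc["rest_min"];
  P.rest_max = cyc["rest_max"];
  P.variant = cfg["variant_code"];
  P.ci = cfg["contact_inhibition"];
  P.cycle_on = cfg["cycle_enabled"];
  P.collapse_on = cfg["collapse_check"];
  P.dt = cfg["dt"];
  P.cap = cfg["displacement_cap"];
  P.min_frac = cfg["min_distance_frac"];
  P.collapse_frac = cfg["collapse_frac"];
  P.drain_tol = cfg["drain_tol"];
  P.max_substeps = cfg["max_substeps"];
  P.sat_frac = cfg["sat_fraction"];
  int64_t n_steps = (int64_t)cfg["n_steps"];
  int snap_every = cfg["snap_every"];
  IntegerVector forced = cfg["forced_steps"];
  std::vector<int64_t> forced_steps(forced.begin(), forced.end());

  // initial cells
  IntegerVector c_id = cells_df["id"], c_sib = cells_df["sibling"],
                c_phase = cells_df["phase_code"];
  NumericVector c_x = cells_df["x"], c_y = cells_df["y"],
                c_r = cells_df["radius"], c_expr = cells_df["expression"],
                c_E = cells_df["E"], c_B = cells_df["B"], c_EB = cells_df["EB"],
                c_clk = cells_df["phase_clock"],
                c_rest = cells_df["rest_duration"];
  LogicalVector c_arr = cells_df["arrested"];
  std::vector<Cell> cells(c_id.size());
  int next_id = 1;
  for (int i = 0; i < c_id.size(); ++i) {
    Cell &c = cells[i];
    c.id = c_id[i];
    c.x = c_x[i];
    c.y = c_y[i];
    c.r = c_r[i];
    c.expr = c_expr[i];
    c.E = c_E[i];
    c.B = c_B[i];
    c.EB = c_EB[i];
    c.phase = c_phase[i];
    c.clock_ = c_clk[i];
    c.rest = NumericVector::is_na(c_rest[i]) ? -1.0 : c_rest[i];
    c.arrested = c_arr[i];
    c.sibling = IntegerVector::is_na(c_sib[i]) ? -1 : c_sib[i];
    c.pressure = 0.0;
    c.alive = true;
    next_id = std::max(next_id, c.id + 1);
  }
  std::vector<int> id2idx(next_id, -1);
  for (int i = 0; i < (int)cells.size(); ++i) id2idx[cells[i].id] = i;
  // initial contacts
  if (contacts_df.nrows() > 0) {
    IntegerVector ki = contacts_df["cell_i"], kj = contacts_df["cell_j"];
    NumericVector ka = contacts_df["area"], kp = contacts_df["prev_area"],
                  kei = contacts_df["EBc_i"], kej = contacts_df["EBc_j"];
    for (int r = 0; r < ki.size(); ++r) {
      int i = id2idx[ki[r]], j = id2idx[kj[r]];
      if (i < 0 || j < 0) continue;
      cells[i].sites.push_back({kj[r], ka[r], kp[r], kei[r]});
      cells[j].sites.push_back({ki[r], ka[r], kp[r], kej[r]});
    }
  }

  // scheduled cell introductions
  DataFrame intro = cfg["introduce"];
  int n_intro = intro.nrows();
  std::vector<int64_t> intro_step;
  NumericVector it_time, it_dx, it_dy, it_area, it_r, it_expr;
  IntegerVector it_target;
  if (n_intro > 0) {
    it_time = intro["time"];
    it_target = intro["target"];
    it_dx = intro["dir_x"];
    it_dy = intro["dir_y"];
    it_area = intro["area"];
    it_r = intro["radius"];
    it_expr = intro["expression"];
    for (int r = 0; r < n_intro; ++r)
      intro_step.push_back((int64_t)std::llround(it_time[r] / P.dt));
  }

  std::vector<std::pair<int, int>> pairs;
  List snaps;
  std::string status = "running";
  auto want_snap = [&](int64_t k) {
    if (snap_every > 0 && k % snap_every == 0) return true;
    if (k == n_steps) return true;
    for (auto f : forced_steps)
      if (f == k) return true;
    return false;
  };
  if (want_snap(0) || n_steps == 0)
    snaps.push_back(snapshot(cells, id2idx, P, 0.0, status));

  for (int64_t k = 1; k <= n_steps; ++k) {
    // scheduled introductions at the start of the step
    for (int r = 0; r < n_intro; ++r) {
      if (intro_step[r] == k - 1) {
        int t = (it_target[r] < (int)id2idx.size()) ? id2idx[it_target[r]] : -1;
        Cell nc;
        nc.id = next_id++;
        nc.r = it_r[r];
        nc.expr = it_expr[r];
        nc.E = nc.expr;
        nc.B = 100.0;
        nc.EB = 0.0;
        nc.phase = 1;
        nc.clock_ = 0.0;
        nc.rest = -1.0;
        nc.arrested = false;
        nc.sibling = -1;
        nc.pressure = 0.0;
        nc.alive = true;
        if (t >= 0) {
          double a2 = it_area[r] / M_PI;
          double dd = std::sqrt(cells[t].r * cells[t].r - a2) +
                      std::sqrt(nc.r * nc.r - a2);
          double nm = std::hypot(it_dx[r], it_dy[r]);
          nc.x = cells[t].x + dd * it_dx[r] / nm;
          nc.y = cells[t].y + dd * it_dy[r] / nm;
        } else {
          nc.x = 0.0;
          nc.y = 0.0;
        }
        cells.push_back(nc);
        id2idx.resize(next_id, -1);
        id2idx[nc.id] = (int)cells.size() - 1;
      }
    }

    bookkeeping(cells, id2idx, pairs, P);
    for (auto &c : cells) pathway_step(c, P);
    mechanics(cells, id2idx, P);
    if (P.cycle_on) cycle_and_divide(cells, id2idx, P, next_id);
    if (P.collapse_on && collapsed(cells, P, pairs)) {
      status = "collapsed";
      snaps.push_back(snapshot(cells, id2idx, P, k * P.dt, status));
      break;
    }
    if (want_snap(k)) {
      std::string st = (k == n_steps) ? "done" : "running";
      snaps.push_back(snapshot(cells, id2idx, P, k * P.dt, st));
    }
    if (k % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  if (status != "collapsed") status = "done";
  return List::create(_["snapshots"] = snaps, _["status"] = status);
}
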