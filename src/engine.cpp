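// Core mechanics of the ring-of-bodies cell model and its adhesion kinetics.
// Every operation is exported individually (thin R wrappers add validation)
// and cpp_run() fuses them into the per-step simulation loop.  All random
// draws come from R's RNG stream so set.seed() controls whole trajectories.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int RING_N = 10;

// uniform bin grid over [-ext, ext]^2 with linked-list membership
struct BinGrid {
  double ext, h;
  int nside;
  int cur = 0;
  std::vector<int> head, nxt, stamp;  // stamped lazy clearing across steps
  void build(const double* x, const double* y, int n, double ext_,
             double h_) {
    ext = ext_;
    h = h_;
    int ns = std::max(1, (int)std::ceil(2.0 * ext / h));
    if (ns != nside || (int)head.size() != ns * ns) {
      nside = ns;
      head.assign((size_t)nside * nside, -1);
      stamp.assign((size_t)nside * nside, 0);
      cur = 0;
    }
    if ((int)nxt.size() < n) nxt.assign(n, -1);
    ++cur;
    for (int i = 0; i < n; ++i) {
      int b = bin_of(x[i], y[i]);
      if (stamp[b] != cur) {
        stamp[b] = cur;
        head[b] = -1;
      }
      nxt[i] = head[b];
      head[b] = i;
    }
  }
  inline int first(int b) const { return stamp[b] == cur ? head[b] : -1; }
  inline int clampi(int v) const {
    return v < 0 ? 0 : (v >= nside ? nside - 1 : v);
  }
  inline int bin_of(double px, double py) const {
    int ix = clampi((int)std::floor((px + ext) / h));
    int iy = clampi((int)std::floor((py + ext) / h));
    return iy * nside + ix;
  }
};

// Box-Muller pair of exact standard normals drawn from R's uniform
// stream (much cheaper than norm_rand's inversion; still reproducible
// under set.seed)
inline void norm_pair(double& a, double& b) {
  double u, v, s;
  do {
    u = 2.0 * unif_rand() - 1.0;
    v = 2.0 * unif_rand() - 1.0;
    s = u * u + v * v;
  } while (s >= 1.0 || s == 0.0);
  double f = std::sqrt(-2.0 * std::log(s) / s);
  a = u * f;
  b = v * f;
}

inline double eff_unhook(double P, double t, double s) {
  if (!std::isfinite(s)) return P;
  double z = t / s;
  return P * std::exp(-0.5 * z * z);
}

// ring bodies are stored cell-major: body j of cell i is row i*RING_N + j
void do_random_move(double* rx, double* ry, double* cx, double* cy, int n,
                    double sb, double sc) {
  for (int i = 0; i < n; ++i) {
    double dx = 0.0, dy = 0.0;
    if (sc > 0) {
      norm_pair(dx, dy);
      dx *= sc;
      dy *= sc;
    }
    cx[i] += dx;
    cy[i] += dy;
    for (int j = 0; j < RING_N; ++j) {
      int idx = i * RING_N + j;
      double bx = dx, by = dy;
      if (sb > 0) {
        double gx, gy;
        norm_pair(gx, gy);
        bx += gx * sb;
        by += gy * sb;
      }
      rx[idx] += bx;
      ry[idx] += by;
    }
  }
}

void do_update_edge(double* rx, double* ry, double* cx, double* cy,
                    double* ex, double* ey, int n, double v, double p) {
  for (int i = 0; i < n; ++i) {
    if (p > 0 && unif_rand() < p) {
      double th = 2.0 * M_PI * unif_rand();
      ex[i] = std::cos(th);
      ey[i] = std::sin(th);
    }
    if (v != 0) {
      double dx = v * ex[i], dy = v * ey[i];
      cx[i] += dx;
      cy[i] += dy;
      for (int j = 0; j < RING_N; ++j) {
        int idx = i * RING_N + j;
        rx[idx] += dx;
        ry[idx] += dy;
      }
    }
  }
}

// linked bodies pulled toward their midpoint by k/2 * (separation - rest)
void do_hook_constraint(double* rx, double* ry, const int* partner, int nb,
                        double k, double rest) {
  for (int a = 0; a < nb; ++a) {
    int b = partner[a];
    if (b > a) {
      double dx = rx[b] - rx[a], dy = ry[b] - ry[a];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > rest && d > 1e-12) {
        double mv = 0.5 * k * (d - rest) / d;
        rx[a] += mv * dx;
        ry[a] += mv * dy;
        rx[b] -= mv * dx;
        ry[b] -= mv * dy;
      }
    }
  }
}

// position-based relaxation of centroid-to-body radius and neighbour chord
// constraints; corrections split equally so hook pulls on bodies drag the
// whole cell.  Convergence is checked before correcting, so a regular
// decagon is an exact fixed point.  Returns number of non-converged cells.
int do_enforce(double* rx, double* ry, double* cx, double* cy, int n,
               double r_cell, double tol, int max_iter) {
  const double chord = 2.0 * r_cell * std::sin(M_PI / RING_N);
  const double tol_abs = tol * r_cell;
  int nonconv = 0;
  for (int i = 0; i < n; ++i) {
    bool ok = false;
    for (int iter = 0; iter <= max_iter; ++iter) {
      double maxerr = 0.0;
      for (int j = 0; j < RING_N; ++j) {
        int idx = i * RING_N + j;
        double dx = rx[idx] - cx[i], dy = ry[idx] - cy[i];
        double d = std::sqrt(dx * dx + dy * dy);
        double err = std::fabs(d - r_cell);
        if (err > maxerr) maxerr = err;
      }
      if (maxerr <= tol_abs) {
        ok = true;
        break;
      }
      if (iter == max_iter) break;
      // radial pass (Gauss-Seidel, equal split body/centroid)
      for (int j = 0; j < RING_N; ++j) {
        int idx = i * RING_N + j;
        double dx = rx[idx] - cx[i], dy = ry[idx] - cy[i];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < 1e-12) {
          // degenerate: nudge body outward along a fixed direction
          double th = 2.0 * M_PI * j / RING_N;
          rx[idx] = cx[i] + 1e-6 * std::cos(th);
          ry[idx] = cy[i] + 1e-6 * std::sin(th);
          continue;
        }
        double corr = 0.5 * (d - r_cell) / d;
        rx[idx] -= corr * dx;
        ry[idx] -= corr * dy;
        cx[i] += corr * dx;
        cy[i] += corr * dy;
      }
      // neighbour-spacing pass (keeps the decagon regular and ordered)
      for (int j = 0; j < RING_N; ++j) {
        int a = i * RING_N + j;
        int b = i * RING_N + (j + 1) % RING_N;
        double dx = rx[b] - rx[a], dy = ry[b] - ry[a];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < 1e-12) continue;
        double corr = 0.5 * (d - chord) / d;
        rx[a] += corr * dx;
        ry[a] += corr * dy;
        rx[b] -= corr * dx;
        ry[b] -= corr * dy;
      }
    }
    if (!ok) ++nonconv;
  }
  return nonconv;
}

void shift_cell(double* rx, double* ry, double* cx, double* cy, int i,
                double dx, double dy) {
  cx[i] += dx;
  cy[i] += dy;
  for (int j = 0; j < RING_N; ++j) {
    int idx = i * RING_N + j;
    rx[idx] += dx;
    ry[idx] += dy;
  }
}

// stochastic volume exclusion on centroid separation < 2 r_cell
void do_exclusion(double* rx, double* ry, double* cx, double* cy, int n,
                  double r_cell, double p_repel, double k_repel, double ext,
                  BinGrid& grid) {
  if (p_repel <= 0 || n < 2) return;
  const double dc = 2.0 * r_cell;
  grid.build(cx, cy, n, ext, dc);
  for (int i = 0; i < n; ++i) {
    int bx = grid.clampi((int)std::floor((cx[i] + grid.ext) / grid.h));
    int by = grid.clampi((int)std::floor((cy[i] + grid.ext) / grid.h));
    for (int oy = -1; oy <= 1; ++oy) {
      int yy = by + oy;
      if (yy < 0 || yy >= grid.nside) continue;
      for (int ox = -1; ox <= 1; ++ox) {
        int xx = bx + ox;
        if (xx < 0 || xx >= grid.nside) continue;
        for (int j = grid.first(yy * grid.nside + xx); j >= 0;
             j = grid.nxt[j]) {
          if (j <= i) continue;
          double dx = cx[j] - cx[i], dy = cy[j] - cy[i];
          double d = std::sqrt(dx * dx + dy * dy);
          if (d < dc && d > 1e-12) {
            if (p_repel >= 1.0 || unif_rand() < p_repel) {
              double mv = k_repel * (dc - d) / d;
              shift_cell(rx, ry, cx, cy, i, -mv * dx, -mv * dy);
              shift_cell(rx, ry, cx, cy, j, mv * dx, mv * dy);
            }
          }
        }
      }
    }
  }
}

void do_confine(double* rx, double* ry, double* cx, double* cy, int n,
                double R_field) {
  for (int i = 0; i < n; ++i) {
    double d = std::sqrt(cx[i] * cx[i] + cy[i] * cy[i]);
    if (d > R_field) {
      double s = R_field / d - 1.0;
      shift_cell(rx, ry, cx, cy, i, s * cx[i], s * cy[i]);
    }
  }
}

void do_break(int* partner, int* age, int nb, double unhook, double seize) {
  for (int a = 0; a < nb; ++a) {
    int b = partner[a];
    if (b > a) {
      bool broke = false;
      if (unhook > 0) {
        double p = eff_unhook(unhook, (double)age[a], seize);
        if (unif_rand() < p) broke = true;
      }
      if (broke) {
        partner[a] = -1;
        partner[b] = -1;
        age[a] = 0;
        age[b] = 0;
      } else {
        ++age[a];
        ++age[b];
      }
    }
  }
}

// greedy, deterministic formation: bodies scanned in index order, each
// unlinked body links its nearest eligible unlinked body within range
// (ties: lowest owning cell id, then lowest body index)
void do_form(const double* rx, const double* ry, const int* cell_of,
             const int* type_of_cell, int* partner, int* age, int nb,
             double hook_range, double p_hook, bool like_only, double ext,
             BinGrid& grid) {
  if (hook_range <= 0 || p_hook <= 0 || nb < 2) return;
  double h = std::max(hook_range, 0.25);
  grid.build(rx, ry, nb, ext, h);
  const double r2 = hook_range * hook_range;
  for (int a = 0; a < nb; ++a) {
    if (partner[a] >= 0) continue;
    int bx = grid.clampi((int)std::floor((rx[a] + grid.ext) / grid.h));
    int by = grid.clampi((int)std::floor((ry[a] + grid.ext) / grid.h));
    int best = -1, best_cell = -1;
    double best_d2 = 0.0;
    for (int oy = -1; oy <= 1; ++oy) {
      int yy = by + oy;
      if (yy < 0 || yy >= grid.nside) continue;
      for (int ox = -1; ox <= 1; ++ox) {
        int xx = bx + ox;
        if (xx < 0 || xx >= grid.nside) continue;
        for (int b = grid.first(yy * grid.nside + xx); b >= 0;
             b = grid.nxt[b]) {
          if (b == a || partner[b] >= 0) continue;
          if (cell_of[b] == cell_of[a]) continue;
          if (like_only && type_of_cell[cell_of[b]] != type_of_cell[cell_of[a]])
            continue;
          double dx = rx[b] - rx[a], dy = ry[b] - ry[a];
          double d2 = dx * dx + dy * dy;
          if (d2 > r2) continue;
          bool better = false;
          if (best < 0 || d2 < best_d2) {
            better = true;
          } else if (d2 == best_d2) {
            if (cell_of[b] < best_cell ||
                (cell_of[b] == best_cell && b < best))
              better = true;
          }
          if (better) {
            best = b;
            best_cell = cell_of[b];
            best_d2 = d2;
          }
        }
      }
    }
    if (best >= 0) {
      if (p_hook >= 1.0 || unif_rand() < p_hook) {
        partner[a] = best;
        partner[best] = a;
        age[a] = 1;
        age[best] = 1;
      }
    }
  }
}

IntegerVector partner_to_c(const IntegerVector& p) {
  IntegerVector out(p.size());
  for (int i = 0; i < p.size(); ++i) out[i] = p[i] - 1;  // 0 (none) -> -1
  return out;
}

IntegerVector partner_to_r(const IntegerVector& p) {
  IntegerVector out(p.size());
  for (int i = 0; i < p.size(); ++i) out[i] = p[i] + 1;
  return out;
}

}  // namespace

// [[Rcpp::export]]
double cpp_effective_unhook(double P, double t, double s) {
  return eff_unhook(P, t, s);
}

// [[Rcpp::export]]
List cpp_random_move(NumericMatrix ring, NumericMatrix cent,
                     double sigma_body, double sigma_centre) {
  NumericMatrix r = clone(ring), c = clone(cent);
  int n = c.nrow(), nb = r.nrow();
  do_random_move(r.begin(), r.begin() + nb, c.begin(), c.begin() + n, n,
                 sigma_body, sigma_centre);
  return List::create(_["ring"] = r, _["cent"] = c);
}

// [[Rcpp::export]]
List cpp_update_edge(NumericMatrix ring, NumericMatrix cent,
                     NumericMatrix edge, double v_edge, double p_new_edge) {
  NumericMatrix r = clone(ring), c = clone(cent), e = clone(edge);
  int n = c.nrow(), nb = r.nrow();
  do_update_edge(r.begin(), r.begin() + nb, c.begin(), c.begin() + n,
                 e.begin(), e.begin() + n, n, v_edge, p_new_edge);
  return List::create(_["ring"] = r, _["cent"] = c, _["edge"] = e);
}

// [[Rcpp::export]]
NumericMatrix cpp_hook_constraint(NumericMatrix ring, IntegerVector partner,
                                  double k_hook, double rest) {
  NumericMatrix r = clone(ring);
  IntegerVector p = partner_to_c(partner);
  int nb = r.nrow();
  do_hook_constraint(r.begin(), r.begin() + nb, p.begin(), nb, k_hook, rest);
  return r;
}

// [[Rcpp::export]]
List cpp_enforce_constraints(NumericMatrix ring, NumericMatrix cent,
                             double r_cell, double tol, int max_iter) {
  NumericMatrix r = clone(ring), c = clone(cent);
  int n = c.nrow(), nb = r.nrow();
  int nonconv = do_enforce(r.begin(), r.begin() + nb, c.begin(),
                           c.begin() + n, n, r_cell, tol, max_iter);
  return List::create(_["ring"] = r, _["cent"] = c,
                      _["n_nonconverged"] = nonconv);
}

// [[Rcpp::export]]
List cpp_apply_exclusion(NumericMatrix ring, NumericMatrix cent,
                         double r_cell, double p_repel, double k_repel,
                         double R_field) {
  NumericMatrix r = clone(ring), c = clone(cent);
  int n = c.nrow(), nb = r.nrow();
  BinGrid grid;
  do_exclusion(r.begin(), r.begin() + nb, c.begin(), c.begin() + n, n,
               r_cell, p_repel, k_repel, R_field + 4.0 * r_cell, grid);
  return List::create(_["ring"] = r, _["cent"] = c);
}

// [[Rcpp::export]]
List cpp_confine(NumericMatrix ring, NumericMatrix cent, double R_field) {
  NumericMatrix r = clone(ring), c = clone(cent);
  int n = c.nrow(), nb = r.nrow();
  do_confine(r.begin(), r.begin() + nb, c.begin(), c.begin() + n, n, R_field);
  return List::create(_["ring"] = r, _["cent"] = c);
}

// [[Rcpp::export]]
List cpp_break_hooks(IntegerVector partner, IntegerVector age, double unhook,
                     double seize) {
  IntegerVector p = partner_to_c(partner), a = clone(age);
  do_break(p.begin(), a.begin(), p.size(), unhook, seize);
  return List::create(_["partner"] = partner_to_r(p), _["age"] = a);
}

// [[Rcpp::export]]
List cpp_form_hooks(NumericMatrix ring, IntegerVector cell_of_body,
                    IntegerVector type_of_cell, IntegerVector partner,
                    IntegerVector age, double hook_range, double p_hook,
                    bool like_only, double ext) {
  NumericMatrix r = clone(ring);
  IntegerVector p = partner_to_c(partner), a = clone(age);
  IntegerVector cof(cell_of_body.size());
  for (int i = 0; i < cof.size(); ++i) cof[i] = cell_of_body[i] - 1;
  int nb = r.nrow();
  BinGrid grid;
  do_form(r.begin(), r.begin() + nb, cof.begin(), type_of_cell.begin(),
          p.begin(), a.begin(), nb, hook_range, p_hook, like_only, ext, grid);
  return List::create(_["partner"] = partner_to_r(p), _["age"] = a);
}

// Fused simulation loop.  state: cent, ring, edge, partner (1-based, 0 =
// unlinked), age, type (1/2 per cell).  Step order: leading edge, random
// move, hook constraint, ring constraints, exclusion, confinement, hook
// breakage, hook formation.  Centroid snapshots every snapshot_every steps
// (including t = t0 and, when divisible, the final step).
// [[Rcpp::export]]
List cpp_run(List state, List mpar, List epar, List apar, int n_steps,
             int snapshot_every, int t0) {
  NumericMatrix cent = clone(as<NumericMatrix>(state["cent"]));
  NumericMatrix ring = clone(as<NumericMatrix>(state["ring"]));
  NumericMatrix edge = clone(as<NumericMatrix>(state["edge"]));
  IntegerVector partner = partner_to_c(as<IntegerVector>(state["partner"]));
  IntegerVector age = clone(as<IntegerVector>(state["hook_age"]));
  IntegerVector type = as<IntegerVector>(state["type"]);

  const int n = cent.nrow(), nb = ring.nrow();
  double* cx = cent.begin();
  double* cy = cent.begin() + n;
  double* rx = ring.begin();
  double* ry = ring.begin() + nb;
  double* ex = edge.begin();
  double* ey = edge.begin() + n;

  const double sb = mpar["sigma_body"], sc = mpar["sigma_centre"];
  const double ve = mpar["v_edge"], pe = mpar["p_new_edge"];
  const double r_cell = mpar["r_cell"], R_field = mpar["R_field"];
  const double tol = mpar["tol"];
  const int max_iter = mpar["max_iter"];
  const double p_repel = epar["p_repel"], k_repel = epar["k_repel"];
  const double unhook = apar["unhook"], seize = apar["seize"];
  const double hook_range = apar["hook_range"], p_hook = apar["p_hook"];
  const bool like_only = apar["like_type_only"];
  const double k_hook = apar["k_hook"], hook_rest = apar["hook_rest"];
  const double ext = R_field + 4.0 * r_cell;

  std::vector<int> cell_of(nb);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < RING_N; ++j) cell_of[i * RING_N + j] = i;

  const int n_snap = n_steps / snapshot_every + 1;
  NumericVector snaps((R_xlen_t)n * 2 * n_snap);
  IntegerVector snap_times(n_snap);
  int isnap = 0;
  long nonconv_total = 0;
  BinGrid grid_c, grid_b;

  auto record = [&](int t) {
    double* s = snaps.begin() + (R_xlen_t)isnap * n * 2;
    for (int i = 0; i < n; ++i) {
      s[i] = cx[i];
      s[n + i] = cy[i];
    }
    snap_times[isnap] = t0 + t;
    ++isnap;
  };
  record(0);

  for (int t = 1; t <= n_steps; ++t) {
    do_update_edge(rx, ry, cx, cy, ex, ey, n, ve, pe);
    do_random_move(rx, ry, cx, cy, n, sb, sc);
    do_hook_constraint(rx, ry, partner.begin(), nb, k_hook, hook_rest);
    nonconv_total +=
        do_enforce(rx, ry, cx, cy, n, r_cell, tol, max_iter);
    do_exclusion(rx, ry, cx, cy, n, r_cell, p_repel, k_repel, ext, grid_c);
    do_confine(rx, ry, cx, cy, n, R_field);
    do_break(partner.begin(), age.begin(), nb, unhook, seize);
    do_form(rx, ry, cell_of.data(), type.begin(), partner.begin(),
            age.begin(), nb, hook_range, p_hook, like_only, ext, grid_b);
    if (t % snapshot_every == 0) record(t);
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  snaps.attr("dim") = IntegerVector::create(n, 2, n_snap);
  return List::create(
      _["cent"] = cent, _["ring"] = ring, _["edge"] = edge,
      _["partner"] = partner_to_r(partner), _["age"] = age,
      _["snaps"] = snaps, _["snap_times"] = snap_times,
      _["n_nonconverged"] = (double)nonconv_total);
}
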