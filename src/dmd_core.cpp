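// Event-driven discrete molecular dynamics core.
//
// Beads move ballistically between instantaneous events: hard-core
// collisions, bonded square-well wall reflections, hydropathy well-edge
// crossings, hydrogen-bond formation/escape, and cell-list crossings.
// Events live in a binary min-heap keyed by (time, bead a, bead b) with
// lazy invalidation through per-bead event counters.  All lengths are in
// Angstrom, energies in E_HB, masses in M_bead; the internal clock runs in
// reduced time t0 = A * sqrt(M_bead / E_HB).  The caller converts to
// simulation time units.
//
// Everything is deterministic: no random numbers are drawn here.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

enum EvType {
  EV_CELL = 0,   // bead crosses a cell boundary
  EV_CORE = 1,   // hard-core reflection
  EV_BMIN = 2,   // bonded constraint, inner wall
  EV_BMAX = 3,   // bonded constraint, outer wall
  EV_WIN  = 4,   // hydropathy well edge, entering
  EV_WOUT = 5,   // hydropathy well edge, leaving
  EV_HBATT = 6,  // hydrogen-bond formation attempt at the outer window edge
  EV_HBMIN = 7,  // hydrogen-bond inner window wall
  EV_HBOUT = 8   // hydrogen-bond escape attempt at the outer window edge
};

struct Ev {
  double t;
  int a, b;          // bead indices; b < 0 marks a cell crossing
  int type;
  uint32_t ca, cb;   // per-bead event counters at scheduling time
  double d;          // target distance
  double du;         // potential step if the crossing succeeds
};

struct EvLater {
  bool operator()(const Ev& x, const Ev& y) const {
    if (x.t != y.t) return x.t > y.t;
    if (x.a != y.a) return x.a > y.a;
    return x.b > y.b;
  }
};

struct Engine {
  int n;
  double box;
  std::vector<double> rx, ry, rz, vx, vy, vz, tl, mass;
  std::vector<uint32_t> cnt;

  // bonded constraints as adjacency lists
  struct Bond { int j; double dmin, dmax; };
  std::vector<std::vector<Bond>> bonds;

  // nonbonded
  std::vector<double> core;       // per-bead hard-core diameter
  std::vector<int> welltype;      // -1 none, else row into eps
  std::vector<double> eps;        // nt x nt step energies
  int nt;
  double hp_cutoff;

  // hydrogen bonds
  std::vector<int> hb_role;       // 0 none, 1 donor N, 2 acceptor C
  std::vector<int> fl1, fl2;      // flanking beads (-1 none)
  std::vector<int> pep, res;      // peptide id, residue index
  std::vector<int> hb_partner;    // -1 free
  double hb_depth, hb_rmin, hb_rmax, flank_lo, flank_hi;

  bool interactions_on;

  // per-bead sorted exclusion lists (bonded + local pairs)
  std::vector<std::vector<int>> excl_of;

  // cell list.  Cells are sized for the hard-core reach; pairs capable of
  // long-range steps (hydropathy wells, hydrogen bonds) are scanned over a
  // wider shell chosen so that any pair outside it is beyond the largest
  // cutoff.
  int ncell;                       // per axis; 1 => brute force
  double cellw;
  std::vector<int> cell_of, cell_head, cell_next, cell_prev;
  std::vector<uint8_t> longrange;  // bead can engage a well or HB
  std::vector<int> offx, offy, offz;  // scan offsets, inner 27 first
  int n_inner;                     // 27

  // bookkeeping
  std::vector<Ev> heap;
  double t_cur, U, KE;
  long long n_events, n_checks;
  long long type_count[9] = {0};

  bool excluded(int i, int j) const {
    const std::vector<int>& v = excl_of[i];
    for (int k : v) if (k == j) return true;
    return false;
  }

  double wrap(double x) const {
    x -= box * std::floor(x / box);
    if (x >= box) x -= box;
    if (x < 0) x += box;
    return x;
  }
  double mind(double d) const {
    if (d > 0.5 * box) d -= box;
    else if (d < -0.5 * box) d += box;
    return d;
  }

  void pos_at(int i, double t, double& x, double& y, double& z) const {
    double dt = t - tl[i];
    x = rx[i] + vx[i] * dt; y = ry[i] + vy[i] * dt; z = rz[i] + vz[i] * dt;
  }

  void advance(int i, double t) {
    double dt = t - tl[i];
    rx[i] = wrap(rx[i] + vx[i] * dt);
    ry[i] = wrap(ry[i] + vy[i] * dt);
    rz[i] = wrap(rz[i] + vz[i] * dt);
    tl[i] = t;
  }

  // ---- cell list -------------------------------------------------------
  int cell_index(double x, double y, double z) const {
    int cx = (int)(x / cellw), cy = (int)(y / cellw), cz = (int)(z / cellw);
    if (cx >= ncell) cx = ncell - 1; if (cy >= ncell) cy = ncell - 1;
    if (cz >= ncell) cz = ncell - 1;
    if (cx < 0) cx = 0; if (cy < 0) cy = 0; if (cz < 0) cz = 0;
    return (cx * ncell + cy) * ncell + cz;
  }
  void cell_insert(int i) {
    int c = cell_index(rx[i], ry[i], rz[i]);
    cell_of[i] = c;
    cell_next[i] = cell_head[c];
    cell_prev[i] = -1;
    if (cell_head[c] >= 0) cell_prev[cell_head[c]] = i;
    cell_head[c] = i;
  }
  void cell_remove(int i) {
    int c = cell_of[i];
    if (cell_prev[i] >= 0) cell_next[cell_prev[i]] = cell_next[i];
    else cell_head[c] = cell_next[i];
    if (cell_next[i] >= 0) cell_prev[cell_next[i]] = cell_prev[i];
  }

  void build_offsets(int shell) {
    offx.clear(); offy.clear(); offz.clear();
    // inner 27 first, then the long-range shell
    for (int pass = 0; pass < 2; ++pass)
      for (int dx = -shell; dx <= shell; ++dx)
        for (int dy = -shell; dy <= shell; ++dy)
          for (int dz = -shell; dz <= shell; ++dz) {
            bool inner = std::abs(dx) <= 1 && std::abs(dy) <= 1 &&
                         std::abs(dz) <= 1;
            if ((pass == 0) != inner) continue;
            offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
          }
    n_inner = 27;
  }

  // can pair (i, j) engage a long-range step (well or hydrogen bond)?
  bool pair_longrange(int i, int j) const {
    if (welltype[i] >= 0 && welltype[j] >= 0) return true;
    return (hb_role[i] == 1 && hb_role[j] == 2) ||
           (hb_role[i] == 2 && hb_role[j] == 1);
  }

  template <typename F> void for_neighbours(int i, F f) {
    if (ncell == 1) {
      for (int j = 0; j < n; ++j) if (j != i) f(j);
      return;
    }
    int c = cell_of[i];
    int cx = c / (ncell * ncell), cy = (c / ncell) % ncell, cz = c % ncell;
    bool lr = interactions_on && longrange[i];
    int n_off = lr ? (int)offx.size() : n_inner;
    for (int k = 0; k < n_off; ++k) {
      int ex = cx + offx[k]; if (ex < 0) ex += ncell;
      else if (ex >= ncell) ex -= ncell;
      int ey = cy + offy[k]; if (ey < 0) ey += ncell;
      else if (ey >= ncell) ey -= ncell;
      int ez = cz + offz[k]; if (ez < 0) ez += ncell;
      else if (ez >= ncell) ez -= ncell;
      int cc = (ex * ncell + ey) * ncell + ez;
      bool outer = k >= n_inner;
      for (int j = cell_head[cc]; j >= 0; j = cell_next[j]) {
        if (j == i) continue;
        if (outer && !pair_longrange(i, j)) continue;
        f(j);
      }
    }
  }

  // ---- event prediction ------------------------------------------------
  // Every pair holds its earliest event in the heap (scheduled from both
  // sides; duplicates are removed lazily via the per-bead counters).  A
  // bead's counter bump invalidates all its stored events, and its
  // reschedule re-predicts every pair it participates in, so each live
  // pair is always covered.
  struct Cand {
    double t = -1.0;
    int b = -2, type = -1;
    double d = 0, du = 0;
  };

  void push_ev(double t, int a, int b, int type, double d, double du) {
    Ev e{t, a, b, type, cnt[a], b >= 0 ? cnt[b] : 0u, d, du};
    heap.push_back(e);
    std::push_heap(heap.begin(), heap.end(), EvLater());
  }

  // earliest crossing of |dr + dv t| = d coming from outside (smaller root)
  static double hit_from_above(double r2, double bq, double v2, double d) {
    if (bq >= 0 || v2 <= 0) return -1.0;
    double d2 = d * d;
    if (r2 <= d2) return -1.0;
    double disc = bq * bq - v2 * (r2 - d2);
    if (disc <= 0) return -1.0;
    return (-bq - std::sqrt(disc)) / v2;
  }
  // crossing of |dr + dv t| = d from inside (larger root; robust to fp)
  static double hit_from_below(double r2, double bq, double v2, double d) {
    if (v2 <= 0) return -1.0;
    double d2 = d * d;
    double disc = bq * bq - v2 * (r2 - d2);
    if (disc < 0) return -1.0;
    double t = (-bq + std::sqrt(disc)) / v2;
    return t > 0 ? t : -1.0;
  }

  // fold the earliest event for pair (i, j) into bead i's candidate;
  // bd != nullptr marks a bonded pair (never reached via the cell scan,
  // because bonded pairs are excluded there)
  void predict_pair(int i, int j, const Bond* bd, Cand& best) {
    ++n_checks;
    double tb = std::max(tl[i], tl[j]);
    double xi, yi, zi, xj, yj, zj;
    pos_at(i, tb, xi, yi, zi);
    pos_at(j, tb, xj, yj, zj);
    double dx = mind(xj - xi), dy = mind(yj - yi), dz = mind(zj - zi);
    double dvx = vx[j] - vx[i], dvy = vy[j] - vy[i], dvz = vz[j] - vz[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    double bq = dx * dvx + dy * dvy + dz * dvz;
    double v2 = dvx * dvx + dvy * dvy + dvz * dvz;
    if (v2 <= 0) return;

    auto consider = [&](double trel, int type, double d, double du) {
      if (trel < 0) return;
      double tev = tb + trel;
      if (tev < t_cur) tev = t_cur;
      if (best.t < 0 || tev < best.t) {
        best.t = tev; best.b = j; best.type = type; best.d = d; best.du = du;
      }
    };

    if (bd != nullptr) {
      consider(hit_from_above(r2, bq, v2, bd->dmin), EV_BMIN, bd->dmin, 0.0);
      consider(hit_from_below(r2, bq, v2, bd->dmax), EV_BMAX, bd->dmax, 0.0);
    } else {
      double dc = 0.5 * (core[i] + core[j]);
      bool hb_pair = false;
      if (interactions_on) {
        int dn = -1, ac = -1;
        if (hb_role[i] == 1 && hb_role[j] == 2) { dn = i; ac = j; }
        else if (hb_role[j] == 1 && hb_role[i] == 2) { dn = j; ac = i; }
        if (dn >= 0 &&
            (pep[dn] != pep[ac] || std::abs(res[dn] - res[ac]) >= 2)) {
          hb_pair = true;
          double w2 = hb_rmax * hb_rmax;
          if (hb_partner[dn] == ac) {  // currently bonded
            consider(hit_from_above(r2, bq, v2, hb_rmin), EV_HBMIN, hb_rmin, 0.0);
            consider(hit_from_below(r2, bq, v2, hb_rmax), EV_HBOUT, hb_rmax,
                     hb_depth);
          } else if (r2 > w2 + w2 * 1e-9 ||
                     (r2 > w2 - w2 * 1e-9 && bq < 0)) {
            consider(hit_from_above(r2, bq, v2, hb_rmax), EV_HBATT, hb_rmax,
                     -hb_depth);
            consider(hit_from_above(r2, bq, v2, dc), EV_CORE, dc, 0.0);
          } else {
            // unbonded inside the window (legacy of a stage with the bond
            // off, or partner taken): hard core only
            consider(hit_from_above(r2, bq, v2, dc), EV_CORE, dc, 0.0);
          }
        }
      }
      if (!hb_pair) {
        double e = 0.0;
        if (interactions_on && welltype[i] >= 0 && welltype[j] >= 0)
          e = eps[welltype[i] * nt + welltype[j]];
        if (e != 0.0) {
          // near the cutoff the side is decided by the motion, with a
          // band far above position round-off: misclassifying a freshly
          // crossed pair as still outside would re-apply the energy step
          double c2 = hp_cutoff * hp_cutoff;
          double band = c2 * 1e-9;
          bool inside = (r2 < c2 - band) || (r2 < c2 + band && bq < 0);
          if (inside) {
            consider(hit_from_above(r2, bq, v2, dc), EV_CORE, dc, 0.0);
            consider(hit_from_below(r2, bq, v2, hp_cutoff), EV_WOUT,
                     hp_cutoff, -e);
          } else {
            consider(hit_from_above(r2, bq, v2, hp_cutoff), EV_WIN,
                     hp_cutoff, e);
            consider(hit_from_above(r2, bq, v2, dc), EV_CORE, dc, 0.0);
          }
        } else {
          consider(hit_from_above(r2, bq, v2, dc), EV_CORE, dc, 0.0);
        }
      }
    }
  }

  void predict_cell(int i, Cand& best) {
    if (ncell == 1) return;
    double t_min = -1.0;
    double pos[3] = {rx[i], ry[i], rz[i]};
    double vel[3] = {vx[i], vy[i], vz[i]};
    int c = cell_of[i];
    int cc[3] = {c / (ncell * ncell), (c / ncell) % ncell, c % ncell};
    for (int k = 0; k < 3; ++k) {
      if (vel[k] == 0) continue;
      // offset within the cell, taken in the cell's nearest periodic
      // image: a bead wrapped across the box boundary may sit a full box
      // length from its cell's nominal coordinates
      double off = pos[k] - cc[k] * cellw;
      off -= box * std::round(off / box);
      double t = (vel[k] > 0) ? (cellw - off) / vel[k] : -off / vel[k];
      if (t < 0) t = 0;   // at a wall (fp): fire now, the nudge corrects
      if (t_min < 0 || t < t_min) t_min = t;
    }
    if (t_min >= 0) {
      double tev = std::max(tl[i] + std::max(t_min, 0.0), t_cur);
      if (best.t < 0 || tev < best.t) {
        best.t = tev; best.b = -1; best.type = EV_CELL; best.d = 0;
        best.du = 0;
      }
    }
  }

  void push_cand(int i, const Cand& c) {
    if (c.t >= 0) push_ev(c.t, i, c.b, c.type, c.d, c.du);
  }

  // re-predict and push every event bead i participates in
  void schedule(int i, bool halve = false) {
    Cand cc;
    predict_cell(i, cc);
    push_cand(i, cc);
    for (const Bond& bd : bonds[i]) {
      if (halve && bd.j < i) continue;
      Cand c;
      predict_pair(i, bd.j, &bd, c);
      push_cand(i, c);
    }
    for_neighbours(i, [&](int j) {
      if (halve && j < i) return;
      if (excluded(i, j)) return;
      Cand c;
      predict_pair(i, j, nullptr, c);
      push_cand(i, c);
    });
  }

  void reschedule(int i) {
    ++cnt[i];
    schedule(i);
  }

  void rebuild_heap() {
    heap.clear();
    for (int i = 0; i < n; ++i) ++cnt[i];
    for (int i = 0; i < n; ++i) schedule(i, true);
  }

  void compact_heap() {
    std::vector<Ev> keep;
    keep.reserve(heap.size() / 2);
    for (const Ev& e : heap) {
      if (e.ca == cnt[e.a] && (e.b < 0 || e.cb == cnt[e.b])) keep.push_back(e);
    }
    heap.swap(keep);
    std::make_heap(heap.begin(), heap.end(), EvLater());
  }

  // ---- event resolution ------------------------------------------------
  double flank_dist(int f, int other, double t) const {
    double x1, y1, z1, x2, y2, z2;
    pos_at(f, t, x1, y1, z1);
    pos_at(other, t, x2, y2, z2);
    double dx = mind(x2 - x1), dy = mind(y2 - y1), dz = mind(z2 - z1);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  bool hb_geometry_ok(int dn, int ac, double t) const {
    int f[4] = {fl1[dn], fl2[dn], fl1[ac], fl2[ac]};
    int o[4] = {ac, ac, dn, dn};
    for (int k = 0; k < 4; ++k) {
      if (f[k] < 0) return false;
      double d = flank_dist(f[k], o[k], t);
      if (d < flank_lo || d > flank_hi) return false;
    }
    return true;
  }

  void resolve_pair(const Ev& e) {
    int i = e.a, j = e.b;
    advance(i, e.t); advance(j, e.t);
    double dx = mind(rx[j] - rx[i]), dy = mind(ry[j] - ry[i]),
           dz = mind(rz[j] - rz[i]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0) stop("coincident beads at an event");
    double nx = dx / r, ny = dy / r, nz = dz / r;
    double dvx = vx[j] - vx[i], dvy = vy[j] - vy[i], dvz = vz[j] - vz[i];
    double s = dvx * nx + dvy * ny + dvz * nz;  // radial relative speed
    double mu = mass[i] * mass[j] / (mass[i] + mass[j]);
    double s2 = s * s;
    double sp = -s;  // default: elastic reflection
    double du = 0.0;

    switch (e.type) {
      case EV_CORE: case EV_BMIN: case EV_BMAX: case EV_HBMIN:
        break;
      case EV_WIN: case EV_WOUT: {
        // e.du is the potential step if the crossing succeeds
        double need = 2.0 * e.du / mu;
        if (s2 > need) {
          double mag = std::sqrt(s2 - need);
          sp = (s > 0) ? mag : -mag;
          du = e.du;
        }
        break;
      }
      case EV_HBATT: {
        int dn = hb_role[i] == 1 ? i : j;
        int ac = hb_role[i] == 1 ? j : i;
        if (hb_partner[dn] < 0 && hb_partner[ac] < 0 &&
            hb_geometry_ok(dn, ac, e.t)) {
          sp = -std::sqrt(s2 + 2.0 * hb_depth / mu);
          du = -hb_depth;
          hb_partner[dn] = ac; hb_partner[ac] = dn;
        }
        break;
      }
      case EV_HBOUT: {
        double need = 2.0 * hb_depth / mu;
        if (s2 > need) {
          sp = std::sqrt(s2 - need);
          du = hb_depth;
          int dn = hb_role[i] == 1 ? i : j;
          int ac = hb_role[i] == 1 ? j : i;
          hb_partner[dn] = -1; hb_partner[ac] = -1;
        }
        break;
      }
      default:
        stop("unknown pair event type");
    }
    double imp = mu * (sp - s);
    vx[i] -= imp * nx / mass[i]; vy[i] -= imp * ny / mass[i];
    vz[i] -= imp * nz / mass[i];
    vx[j] += imp * nx / mass[j]; vy[j] += imp * ny / mass[j];
    vz[j] += imp * nz / mass[j];
    KE += 0.5 * mu * (sp * sp - s2);
    U += du;
    reschedule(i);
    reschedule(j);
  }

  void resolve_cell(const Ev& e) {
    int i = e.a;
    advance(i, e.t);
    cell_remove(i);
    // nudge along the velocity so a bead exactly on a boundary lands in
    // the cell it is entering, not the one it leaves
    double h = 1e-9 * cellw;
    double x = wrap(rx[i] + (vx[i] > 0 ? h : vx[i] < 0 ? -h : 0));
    double y = wrap(ry[i] + (vy[i] > 0 ? h : vy[i] < 0 ? -h : 0));
    double z = wrap(rz[i] + (vz[i] > 0 ? h : vz[i] < 0 ? -h : 0));
    int c = cell_index(x, y, z);
    cell_of[i] = c;
    cell_next[i] = cell_head[c];
    cell_prev[i] = -1;
    if (cell_head[c] >= 0) cell_prev[cell_head[c]] = i;
    cell_head[c] = i;
    reschedule(i);
  }

  double kinetic_exact() const {
    double k = 0;
    for (int i = 0; i < n; ++i)
      k += 0.5 * mass[i] *
           (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    return k;
  }

  int hb_count() const {
    int c = 0;
    for (int i = 0; i < n; ++i) if (hb_partner[i] >= 0) ++c;
    return c / 2;
  }

  bool debug_check = false;

  void check_overlaps() {
    if (ncell > 1) {
      for (int i = 0; i < n; ++i) {
        double x, y, z;
        pos_at(i, t_cur, x, y, z);
        int cx = (int)(wrap(x) / cellw), cy = (int)(wrap(y) / cellw),
            cz = (int)(wrap(z) / cellw);
        int c = cell_of[i];
        int ox = c / (ncell * ncell), oy = (c / ncell) % ncell,
            oz = c % ncell;
        int dx = std::min(std::abs(cx - ox), ncell - std::abs(cx - ox));
        int dy = std::min(std::abs(cy - oy), ncell - std::abs(cy - oy));
        int dz = std::min(std::abs(cz - oz), ncell - std::abs(cz - oz));
        if (dx > 1 || dy > 1 || dz > 1) {
          Rprintf("CELL DESYNC t=%.6f bead %d stored (%d,%d,%d) actual (%d,%d,%d) pos (%.3f,%.3f,%.3f) tl=%.6f vel (%.3f,%.3f,%.3f) cnt=%u\n",
                  t_cur, i, ox, oy, oz, cx, cy, cz, x, y, z, tl[i],
                  vx[i], vy[i], vz[i], cnt[i]);
          for (const Ev& e : heap) {
            if (e.a == i || e.b == i) {
              Rprintf("  heap ev t=%.6f a=%d b=%d type=%d ca=%u cb=%u valid=%d\n",
                      e.t, e.a, e.b, e.type, e.ca, e.cb,
                      (int)(e.ca == cnt[e.a] &&
                            (e.b < 0 || e.cb == cnt[e.b])));
            }
          }
          stop("debug: cell desync");
        }
      }
    }
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (excluded(i, j)) continue;
        double xi, yi, zi, xj, yj, zj;
        pos_at(i, t_cur, xi, yi, zi);
        pos_at(j, t_cur, xj, yj, zj);
        double dx = mind(xj - xi), dy = mind(yj - yi), dz = mind(zj - zi);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double dc = 0.5 * (core[i] + core[j]);
        if (r < dc - 1e-7) {
          Rprintf("OVERLAP t=%.6f pair (%d,%d) r=%.6f core=%.2f cells %d %d cnt %u %u\n",
                  t_cur, i, j, r, dc, cell_of[i], cell_of[j], cnt[i], cnt[j]);
          Rprintf("  ri=(%.4f %.4f %.4f) vi=(%.4f %.4f %.4f) tl=%.6f\n",
                  rx[i], ry[i], rz[i], vx[i], vy[i], vz[i], tl[i]);
          Rprintf("  rj=(%.4f %.4f %.4f) vj=(%.4f %.4f %.4f) tl=%.6f\n",
                  rx[j], ry[j], rz[j], vx[j], vy[j], vz[j], tl[j]);
          stop("debug: hard-core overlap detected");
        }
      }
  }

  // process heap events up to time t_stop
  void integrate_to(double t_stop, long long max_events) {
    while (!heap.empty() && heap.front().t <= t_stop) {
      std::pop_heap(heap.begin(), heap.end(), EvLater());
      Ev e = heap.back();
      heap.pop_back();
      if (e.ca != cnt[e.a] || (e.b >= 0 && e.cb != cnt[e.b])) continue;
      t_cur = e.t;
      ++type_count[e.type];
      if (e.b < 0) resolve_cell(e); else resolve_pair(e);
      if (debug_check) check_overlaps();
      if (++n_events > max_events) {
        Rprintf("event counts by type (cell,core,bmin,bmax,win,wout,"
                "hbatt,hbmin,hbout):\n");
        for (int k = 0; k < 9; ++k) Rprintf(" %lld", type_count[k]);
        Rprintf("\nat t=%.6f\n", t_cur);
        stop("event budget exceeded (%lld events); possible starvation",
             n_events);
      }
      if (heap.size() > (size_t)std::max(20000, 60 * n)) compact_heap();
    }
    t_cur = t_stop;
  }
};

}  // namespace

// [[Rcpp::export]]
List dmd_run_cpp(List sys, List run) {
  Engine E;
  NumericMatrix pos = sys["pos"], vel = sys["vel"];
  E.n = pos.nrow();
  E.box = as<double>(sys["box"]);
  E.mass = as<std::vector<double>>(sys["mass"]);
  E.rx.resize(E.n); E.ry.resize(E.n); E.rz.resize(E.n);
  E.vx.resize(E.n); E.vy.resize(E.n); E.vz.resize(E.n);
  for (int i = 0; i < E.n; ++i) {
    E.rx[i] = pos(i, 0); E.ry[i] = pos(i, 1); E.rz[i] = pos(i, 2);
    E.rx[i] = E.wrap(E.rx[i]); E.ry[i] = E.wrap(E.ry[i]);
    E.rz[i] = E.wrap(E.rz[i]);
    E.vx[i] = vel(i, 0); E.vy[i] = vel(i, 1); E.vz[i] = vel(i, 2);
  }
  E.tl.assign(E.n, 0.0);
  E.cnt.assign(E.n, 0u);

  IntegerVector bi = sys["bond_i"], bj = sys["bond_j"];
  NumericVector bmin = sys["bond_dmin"], bmax = sys["bond_dmax"];
  E.bonds.assign(E.n, {});
  E.excl_of.assign(E.n, {});
  for (int k = 0; k < bi.size(); ++k) {
    int a = bi[k], b = bj[k];
    E.bonds[a].push_back({b, bmin[k], bmax[k]});
    E.bonds[b].push_back({a, bmin[k], bmax[k]});
    E.excl_of[a].push_back(b);
    E.excl_of[b].push_back(a);
  }
  IntegerVector xi = sys["excl_i"], xj = sys["excl_j"];
  for (int k = 0; k < xi.size(); ++k) {
    E.excl_of[xi[k]].push_back(xj[k]);
    E.excl_of[xj[k]].push_back(xi[k]);
  }
  for (int i = 0; i < E.n; ++i) {
    std::sort(E.excl_of[i].begin(), E.excl_of[i].end());
    E.excl_of[i].erase(
        std::unique(E.excl_of[i].begin(), E.excl_of[i].end()),
        E.excl_of[i].end());
  }

  E.core = as<std::vector<double>>(sys["core"]);
  E.welltype = as<std::vector<int>>(sys["welltype"]);
  NumericMatrix eps = sys["eps"];
  E.nt = eps.nrow();
  E.eps.resize(E.nt * E.nt);
  for (int a = 0; a < E.nt; ++a)
    for (int b = 0; b < E.nt; ++b) E.eps[a * E.nt + b] = eps(a, b);
  E.hp_cutoff = as<double>(sys["hp_cutoff"]);

  E.hb_role = as<std::vector<int>>(sys["hb_role"]);
  E.fl1 = as<std::vector<int>>(sys["hb_flank1"]);
  E.fl2 = as<std::vector<int>>(sys["hb_flank2"]);
  E.pep = as<std::vector<int>>(sys["peptide"]);
  E.res = as<std::vector<int>>(sys["residue"]);
  E.hb_depth = as<double>(sys["hb_depth"]);
  NumericVector hw = sys["hb_window"], fw = sys["hb_flank_window"];
  E.hb_rmin = hw[0]; E.hb_rmax = hw[1];
  E.flank_lo = fw[0]; E.flank_hi = fw[1];
  E.hb_partner.assign(E.n, -1);
  IntegerMatrix hb0 = sys["hb_pairs"];
  for (int k = 0; k < hb0.nrow(); ++k) {
    E.hb_partner[hb0(k, 0)] = hb0(k, 1);
    E.hb_partner[hb0(k, 1)] = hb0(k, 0);
  }

  E.interactions_on = as<bool>(run["interactions_on"]);
  double t_end = as<double>(run["t_end"]);
  double frame_dt = as<double>(run["frame_dt"]);
  double thermo_dt = as<double>(run["thermo_dt"]);
  double thermo_tau = as<double>(run["thermo_tau"]);
  double T_target = as<double>(run["T_target"]);
  long long max_events = (long long)as<double>(run["max_events"]);
  if (run.containsElementNamed("debug_check"))
    E.debug_check = as<bool>(run["debug_check"]);

  // cells sized for the hard-core reach, with a long-range shell sized so
  // any pair outside it is beyond the largest cutoff
  E.longrange.assign(E.n, 0);
  for (int i = 0; i < E.n; ++i)
    E.longrange[i] = (E.welltype[i] >= 0 || E.hb_role[i] != 0) ? 1 : 0;
  double reach_core = 0.0, reach_lr = std::max(E.hp_cutoff, E.hb_rmax);
  for (int i = 0; i < E.n; ++i) reach_core = std::max(reach_core, E.core[i]);
  for (int k = 0; k < bmax.size(); ++k)
    reach_core = std::max(reach_core, bmax[k]);
  double wmin = reach_core + 0.2;
  int nc = (int)std::floor(E.box / wmin);
  E.ncell = nc >= 4 ? nc : 1;
  E.cellw = E.box / std::max(E.ncell, 1);
  E.cell_of.assign(E.n, 0);
  E.cell_next.assign(E.n, -1);
  E.cell_prev.assign(E.n, -1);
  E.cell_head.assign((size_t)std::max(E.ncell, 1) * std::max(E.ncell, 1) *
                         std::max(E.ncell, 1), -1);
  if (E.ncell > 1) {
    int shell = (int)std::ceil(reach_lr / E.cellw);
    if (shell < 1) shell = 1;
    if (2 * shell + 1 > E.ncell) {  // shell wraps onto itself: fall back
      E.ncell = 1;
      E.cellw = E.box;
      E.cell_head.assign(1, -1);
    } else {
      E.build_offsets(shell);
      for (int i = 0; i < E.n; ++i) E.cell_insert(i);
    }
  }

  E.t_cur = 0.0;
  E.U = 0.0;
  // initially engaged hydropathy wells and hydrogen bonds define U(0)
  if (E.interactions_on) {
    for (int i = 0; i < E.n; ++i) {
      if (E.welltype[i] < 0) continue;
      for (int j = i + 1; j < E.n; ++j) {
        if (E.welltype[j] < 0 || E.excluded(i, j)) continue;
        double dx = E.mind(E.rx[j] - E.rx[i]), dy = E.mind(E.ry[j] - E.ry[i]),
               dz = E.mind(E.rz[j] - E.rz[i]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < E.hp_cutoff * E.hp_cutoff)
          E.U += E.eps[E.welltype[i] * E.nt + E.welltype[j]];
      }
    }
    E.U -= E.hb_depth * E.hb_count();
  }
  E.KE = E.kinetic_exact();
  E.n_events = 0; E.n_checks = 0;

  E.rebuild_heap();

  int nframes = frame_dt > 0 ? (int)std::floor(t_end / frame_dt + 1e-9) + 1
                             : 2;
  NumericVector fr_t(nframes), fr_ke(nframes), fr_u(nframes);
  IntegerVector fr_hb(nframes);
  NumericVector frames(Dimension(E.n, 3, nframes));
  int fidx = 0;
  auto emit_frame = [&](double t) {
    if (fidx >= nframes) return;
    for (int i = 0; i < E.n; ++i) {
      double x, y, z;
      E.pos_at(i, t, x, y, z);
      frames[fidx * 3 * E.n + 0 * E.n + i] = E.wrap(x);
      frames[fidx * 3 * E.n + 1 * E.n + i] = E.wrap(y);
      frames[fidx * 3 * E.n + 2 * E.n + i] = E.wrap(z);
    }
    fr_t[fidx] = t;
    fr_ke[fidx] = E.kinetic_exact();
    fr_u[fidx] = E.U;
    fr_hb[fidx] = E.hb_count();
    ++fidx;
  };
  emit_frame(0.0);

  double next_frame = frame_dt > 0 ? frame_dt : t_end + 1.0;
  double next_th = thermo_dt > 0 ? thermo_dt : t_end + 1.0;
  double dof = 3.0 * E.n;
  const double tol = 1e-9;
  for (;;) {
    double t_stop = std::min(t_end, std::min(next_frame, next_th));
    E.integrate_to(t_stop, max_events);
    Rcpp::checkUserInterrupt();
    if (frame_dt > 0 && t_stop >= next_frame - tol) {
      emit_frame(t_stop);
      next_frame += frame_dt;
    }
    if (thermo_dt > 0 && t_stop >= next_th - tol) {
      for (int i = 0; i < E.n; ++i) E.advance(i, t_stop);
      double ke = E.kinetic_exact();
      double T_kin = 2.0 * ke / dof;
      if (T_kin > 0) {
        double lam2 = 1.0 + (thermo_dt / thermo_tau) * (T_target / T_kin - 1.0);
        double lam = std::sqrt(std::max(lam2, 0.0));
        lam = std::min(std::max(lam, 0.8), 1.25);
        for (int i = 0; i < E.n; ++i) {
          E.vx[i] *= lam; E.vy[i] *= lam; E.vz[i] *= lam;
        }
        E.KE = E.kinetic_exact();
        E.rebuild_heap();
      }
      next_th += thermo_dt;
    }
    if (t_stop >= t_end - tol) break;
  }
  // without periodic frame output, still record the final state
  if (frame_dt <= 0 && fidx < nframes) emit_frame(t_end);

  for (int i = 0; i < E.n; ++i) E.advance(i, t_end);
  NumericMatrix pos_out(E.n, 3), vel_out(E.n, 3);
  for (int i = 0; i < E.n; ++i) {
    pos_out(i, 0) = E.rx[i]; pos_out(i, 1) = E.ry[i]; pos_out(i, 2) = E.rz[i];
    vel_out(i, 0) = E.vx[i]; vel_out(i, 1) = E.vy[i]; vel_out(i, 2) = E.vz[i];
  }
  std::vector<int> hb_a, hb_b;
  for (int i = 0; i < E.n; ++i)
    if (E.hb_partner[i] > i) { hb_a.push_back(i); hb_b.push_back(E.hb_partner[i]); }
  IntegerMatrix hb_out(hb_a.size(), 2);
  for (size_t k = 0; k < hb_a.size(); ++k) {
    hb_out(k, 0) = hb_a[k]; hb_out(k, 1) = hb_b[k];
  }

  return List::create(
    _["frames"] = frames,
    _["frame_times"] = fr_t,
    _["frame_kinetic"] = fr_ke,
    _["frame_potential"] = fr_u,
    _["frame_hb"] = fr_hb,
    _["n_frames"] = fidx,
    _["pos"] = pos_out,
    _["vel"] = vel_out,
    _["hb_pairs"] = hb_out,
    _["n_events"] = (double)E.n_events,
    _["n_checks"] = (double)E.n_checks,
    _["event_types"] = NumericVector(E.type_count, E.type_count + 9),
    _["potential"] = E.U,
    _["kinetic"] = E.kinetic_exact()
  );
}
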