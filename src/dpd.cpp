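// DPD engine core: pair forces with Groot-Warren thermostat, harmonic bonds,
// cell-list neighbour search, modified velocity-Verlet integration, and
// Lees-Edwards sliding-brick imaging for bulk shear.  All quantities are in
// reduced DPD units (rc = m = kBT = 1 by convention, though rc is a parameter).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based pairwise RNG.
//
// The random force needs one symmetric draw per unordered pair per step
// (xi_ij == xi_ji).  A splitmix64 hash keyed on (seed, step, min(i,j),
// max(i,j)) gives draws that are independent of traversal order, so the
// cell-list and brute-force paths consume the identical stream, and restarting
// from a checkpoint at absolute step k reproduces the continuation bit-exactly.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t h) {
  // strictly inside (0,1): safe for log() in Box-Muller
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double pair_xi(uint64_t seed, uint64_t step, int i, int j,
                             bool gaussian) {
  int lo = i < j ? i : j, hi = i < j ? j : i;
  uint64_t h = splitmix64(seed ^ 0x8f1bbcdcULL);
  h = splitmix64(h ^ step);
  h = splitmix64(h ^ (uint64_t)(uint32_t)lo);
  h = splitmix64(h ^ (uint64_t)(uint32_t)hi);
  if (!gaussian) {
    // uniform on [-sqrt(3), sqrt(3)]: zero mean, unit variance
    return (2.0 * u01(h) - 1.0) * 1.7320508075688772;
  }
  uint64_t h2 = splitmix64(h ^ 0x243F6A8885A308D3ULL);
  return std::sqrt(-2.0 * std::log(u01(h))) *
         std::cos(6.283185307179586 * u01(h2));
}

// [[Rcpp::export]]
NumericVector cpp_pair_xi(double seed, double step, IntegerVector i,
                          IntegerVector j, bool gaussian) {
  int n = i.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = pair_xi((uint64_t)seed, (uint64_t)step, i[k], j[k], gaussian);
  return out;
}

// ---------------------------------------------------------------------------
// Periodic box with optional Lees-Edwards tilt.
// sd: shear (offset) axis, gd: gradient axis; images displaced by +-tilt along
// sd per image step along gd.  Box vectors: b_k = L[k] e_k, except
// b_gd = L[gd] e_gd + tilt e_sd.
// ---------------------------------------------------------------------------

struct BoxT {
  double L[3];
  double tilt;
  int sd, gd;
};

// Nearest-image wrap for the tilted cell using round-based image selection.
// For any pair at distance below cutoff <= min(L)/2 this recovers the exact
// image (any other gd-image is at least L[gd]/2 away), so it is what the
// pair search uses; the exhaustive variant below is kept for general
// displacement queries.
static inline void min_image_round(const BoxT &B, double *d, int *n) {
  int od = 3 - B.sd - B.gd;
  double f = std::floor(d[od] / B.L[od] + 0.5);
  d[od] -= f * B.L[od];
  n[od] = (int)f;
  double fg = std::floor(d[B.gd] / B.L[B.gd] + 0.5);
  d[B.gd] -= fg * B.L[B.gd];
  d[B.sd] -= fg * B.tilt;
  n[B.gd] = (int)fg;
  double fs = std::floor(d[B.sd] / B.L[B.sd] + 0.5);
  d[B.sd] -= fs * B.L[B.sd];
  n[B.sd] = (int)fs;
}

// Minimum image of displacement d; n[k] receives the integer image counts
// removed (d_min = d_raw - sum_k n[k] b_k).  Scans gd-image candidates so the
// result is the true minimum for |tilt| <= L[sd]/2 and near-cubic boxes.
static inline void min_image(const BoxT &B, double *d, int *n) {
  int od = 3 - B.sd - B.gd;
  double f = std::floor(d[od] / B.L[od] + 0.5);
  d[od] -= f * B.L[od];
  n[od] = (int)f;
  int n0 = (int)std::floor(d[B.gd] / B.L[B.gd] + 0.5);
  double best = 1e300, bds = 0, bdg = 0;
  int bng = n0, bns = 0;
  for (int ng = n0 - 1; ng <= n0 + 1; ++ng) {
    double dg = d[B.gd] - ng * B.L[B.gd];
    double ds = d[B.sd] - ng * B.tilt;
    double fs = std::floor(ds / B.L[B.sd] + 0.5);
    ds -= fs * B.L[B.sd];
    double d2 = ds * ds + dg * dg;
    if (d2 < best) { best = d2; bng = ng; bns = (int)fs; bds = ds; bdg = dg; }
  }
  d[B.gd] = bdg;
  d[B.sd] = bds;
  n[B.gd] = bng;
  n[B.sd] = bns;
}

// [[Rcpp::export]]
NumericMatrix cpp_min_image(NumericMatrix d, NumericVector boxL, double tilt,
                            int sd, int gd) {
  BoxT B;
  B.L[0] = boxL[0]; B.L[1] = boxL[1]; B.L[2] = boxL[2];
  B.tilt = tilt; B.sd = sd; B.gd = gd;
  int n = d.nrow();
  NumericMatrix out(n, 3);
  for (int k = 0; k < n; ++k) {
    double v[3] = {d(k, 0), d(k, 1), d(k, 2)};
    int im[3];
    min_image(B, v, im);
    out(k, 0) = v[0]; out(k, 1) = v[1]; out(k, 2) = v[2];
  }
  return out;
}

// Wrap a position into the primary cell.  With shear, crossing the gradient
// boundary shifts the sd coordinate by -+tilt and (for dynamics) the sd
// velocity by -+vshift = -+gdot*L[gd] (the sliding-brick rule).
static inline void wrap_one(const BoxT &B, double *x, double *v, double vshift) {
  int od = 3 - B.sd - B.gd;
  while (x[B.gd] < 0) {
    x[B.gd] += B.L[B.gd];
    x[B.sd] += B.tilt;
    if (v) v[B.sd] += vshift;
  }
  while (x[B.gd] >= B.L[B.gd]) {
    x[B.gd] -= B.L[B.gd];
    x[B.sd] -= B.tilt;
    if (v) v[B.sd] -= vshift;
  }
  x[B.sd] -= B.L[B.sd] * std::floor(x[B.sd] / B.L[B.sd]);
  x[od] -= B.L[od] * std::floor(x[od] / B.L[od]);
}

// [[Rcpp::export]]
List cpp_wrap_positions(NumericMatrix pos, NumericMatrix vel,
                        NumericVector boxL, double tilt, int sd, int gd,
                        double vshift) {
  BoxT B;
  B.L[0] = boxL[0]; B.L[1] = boxL[1]; B.L[2] = boxL[2];
  B.tilt = tilt; B.sd = sd; B.gd = gd;
  int n = pos.nrow();
  NumericMatrix p = clone(pos), v = clone(vel);
  bool hasv = v.nrow() == n;
  for (int k = 0; k < n; ++k) {
    double x[3] = {p(k, 0), p(k, 1), p(k, 2)};
    double vv[3] = {0, 0, 0};
    if (hasv) { vv[0] = v(k, 0); vv[1] = v(k, 1); vv[2] = v(k, 2); }
    wrap_one(B, x, hasv ? vv : (double *)0, vshift);
    p(k, 0) = x[0]; p(k, 1) = x[1]; p(k, 2) = x[2];
    if (hasv) { v(k, 0) = vv[0]; v(k, 1) = vv[1]; v(k, 2) = vv[2]; }
  }
  return List::create(_["positions"] = p, _["velocities"] = v);
}

// ---------------------------------------------------------------------------
// Cell list.  Positions must be wrapped.  Stencil widened along sd for
// image rows crossed along gd (tilt shifts the relevant columns); duplicate
// cell visits are suppressed with a stamp array, so small boxes degrade
// gracefully toward an all-pairs scan rather than double counting.
// ---------------------------------------------------------------------------

struct CellList {
  int nc[3];
  double cw[3];
  std::vector<int> head;   // first bead in cell, -1 if none
  std::vector<int> nxt;    // linked list
};

static void build_cells(const BoxT &B, int n, const double *pos, double cutoff,
                        CellList &cl) {
  for (int k = 0; k < 3; ++k) {
    cl.nc[k] = (int)std::floor(B.L[k] / cutoff);
    if (cl.nc[k] < 1) cl.nc[k] = 1;
    cl.cw[k] = B.L[k] / cl.nc[k];
  }
  cl.head.assign((size_t)cl.nc[0] * cl.nc[1] * cl.nc[2], -1);
  cl.nxt.assign(n, -1);
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      c[k] = (int)(pos[3 * i + k] / cl.cw[k]);
      if (c[k] >= cl.nc[k]) c[k] = cl.nc[k] - 1;
      if (c[k] < 0) c[k] = 0;
    }
    int id = (c[2] * cl.nc[1] + c[1]) * cl.nc[0] + c[0];
    cl.nxt[i] = cl.head[id];
    cl.head[id] = i;
  }
}

static inline int mod_pos(int a, int m) { int r = a % m; return r < 0 ? r + m : r; }

// Cheap minimum image for the untilted box: positions are wrapped, so every
// raw displacement lies within (-L, L) and a single conditional per axis
// suffices (and yields the image count directly).
static inline void min_image_fast(const BoxT &B, double *d, int *n) {
  for (int k = 0; k < 3; ++k) {
    double h = 0.5 * B.L[k];
    if (d[k] > h) { d[k] -= B.L[k]; n[k] = 1; }
    else if (d[k] < -h) { d[k] += B.L[k]; n[k] = -1; }
    else n[k] = 0;
  }
}

// Visit each unordered pair with min-image distance < cutoff exactly once.
template <typename F>
static void for_pairs(const BoxT &B, int n, const double *pos, double cutoff,
                      bool use_cells, F &&fn) {
  double c2 = cutoff * cutoff;
  bool tilted = B.tilt != 0.0;
  if (!use_cells) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d[3] = {pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                       pos[3 * i + 2] - pos[3 * j + 2]};
        int im[3];
        if (tilted) min_image_round(B, d, im); else min_image_fast(B, d, im);
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        if (r2 < c2) fn(i, j, d, r2, im);
      }
    return;
  }
  CellList cl;
  build_cells(B, n, pos, cutoff, cl);
  int od = 3 - B.sd - B.gd;
  if (!tilted && cl.nc[0] >= 3 && cl.nc[1] >= 3 && cl.nc[2] >= 3) {
    // half-stencil cell-pair sweep: each unordered cell pair visited once
    static const int HALF[13][3] = {
        {1, 0, 0},  {-1, 1, 0},  {0, 1, 0},  {1, 1, 0}, {-1, -1, 1},
        {0, -1, 1}, {1, -1, 1},  {-1, 0, 1}, {0, 0, 1}, {1, 0, 1},
        {-1, 1, 1}, {0, 1, 1},   {1, 1, 1}};
    for (int cz = 0; cz < cl.nc[2]; ++cz)
      for (int cy = 0; cy < cl.nc[1]; ++cy)
        for (int cx = 0; cx < cl.nc[0]; ++cx) {
          int id = (cz * cl.nc[1] + cy) * cl.nc[0] + cx;
          for (int i = cl.head[id]; i >= 0; i = cl.nxt[i])
            for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j]) {
              double d[3] = {pos[3 * i] - pos[3 * j],
                             pos[3 * i + 1] - pos[3 * j + 1],
                             pos[3 * i + 2] - pos[3 * j + 2]};
              int im[3];
              min_image_fast(B, d, im);
              double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
              if (r2 < c2) fn(i, j, d, r2, im);
            }
          for (int s = 0; s < 13; ++s) {
            int nx = mod_pos(cx + HALF[s][0], cl.nc[0]);
            int ny = mod_pos(cy + HALF[s][1], cl.nc[1]);
            int nz = mod_pos(cz + HALF[s][2], cl.nc[2]);
            int nid = (nz * cl.nc[1] + ny) * cl.nc[0] + nx;
            for (int i = cl.head[id]; i >= 0; i = cl.nxt[i])
              for (int j = cl.head[nid]; j >= 0; j = cl.nxt[j]) {
                double d[3] = {pos[3 * i] - pos[3 * j],
                               pos[3 * i + 1] - pos[3 * j + 1],
                               pos[3 * i + 2] - pos[3 * j + 2]};
                int im[3];
                min_image_fast(B, d, im);
                double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
                if (r2 < c2) fn(i, j, d, r2, im);
              }
          }
        }
    return;
  }
  std::vector<int> stamp(cl.head.size(), -1);
  for (int i = 0; i < n; ++i) {
    int ci[3];
    for (int k = 0; k < 3; ++k) {
      ci[k] = (int)(pos[3 * i + k] / cl.cw[k]);
      if (ci[k] >= cl.nc[k]) ci[k] = cl.nc[k] - 1;
      if (ci[k] < 0) ci[k] = 0;
    }
    for (int dg = -1; dg <= 1; ++dg) {
      int cg = ci[B.gd] + dg;
      int w = 0;
      if (cg < 0) { cg += cl.nc[B.gd]; w = -1; }
      else if (cg >= cl.nc[B.gd]) { cg -= cl.nc[B.gd]; w = 1; }
      // columns along sd shifted by the tilt when the row is an image row
      int s0, s1;
      if (w == 0) { s0 = -1; s1 = 1; }
      else {
        double s = -w * B.tilt / cl.cw[B.sd];
        s0 = (int)std::floor(s) - 1;
        s1 = (int)std::floor(s) + 2;
      }
      for (int ds = s0; ds <= s1; ++ds) {
        int cs = mod_pos(ci[B.sd] + ds, cl.nc[B.sd]);
        for (int do_ = -1; do_ <= 1; ++do_) {
          int co = mod_pos(ci[od] + do_, cl.nc[od]);
          int c[3];
          c[B.gd] = cg; c[B.sd] = cs; c[od] = co;
          int id = (c[2] * cl.nc[1] + c[1]) * cl.nc[0] + c[0];
          if (stamp[id] == i) continue;
          stamp[id] = i;
          for (int j = cl.head[id]; j >= 0; j = cl.nxt[j]) {
            if (j <= i) continue;
            double d[3] = {pos[3 * i] - pos[3 * j],
                           pos[3 * i + 1] - pos[3 * j + 1],
                           pos[3 * i + 2] - pos[3 * j + 2]};
            int im[3];
            if (tilted) min_image_round(B, d, im); else min_image_fast(B, d, im);
            double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
            if (r2 < c2) fn(i, j, d, r2, im);
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Force evaluation.
// Conservative:  a_ij (1 - r/rc) e          (soft repulsion, r < rc)
// Dissipative:  -gamma (1 - r/rc)^2 (v_ij . e) e
// Random:        sigma (1 - r/rc) xi dt^{-1/2} e,  xi symmetric per pair
// Bond:         -C (r - req) e  between bonded beads
// Conservative pair potential: a rc/2 (1 - r/rc)^2; bond: C/2 (r - req)^2.
// ---------------------------------------------------------------------------

struct PairRec {
  int i, j;
  double e[3];
  double wD;
  double vimg;  // sd-velocity of the j-image: n[gd] * gdot * L[gd]
};

struct ForceWork {
  std::vector<double> fcr;        // conservative + random + bond
  std::vector<double> fd;         // dissipative
  std::vector<PairRec> pairs;
  double epot;
  int n_zero;
};

static void eval_cr_forces(const BoxT &B, int n, const double *pos,
                           const int *spec, const double *A, int nspec,
                           const int *bonds, int nb, double rc, double sigma,
                           double dt, double Cspring, double req,
                           uint64_t seed, uint64_t stepkey, bool gaussian,
                           double gdot, bool use_cells, ForceWork &W) {
  W.fcr.assign(3 * n, 0.0);
  W.pairs.clear();
  W.epot = 0.0;
  W.n_zero = 0;
  double isqdt = 1.0 / std::sqrt(dt);
  for_pairs(B, n, pos, rc, use_cells,
            [&](int i, int j, const double *d, double r2, const int *im) {
    if (r2 <= 0) { W.n_zero++; return; }
    double r = std::sqrt(r2);
    double w = 1.0 - r / rc;
    double e[3] = {d[0] / r, d[1] / r, d[2] / r};
    double a = A[spec[i] + nspec * spec[j]];
    double f = a * w;
    if (sigma != 0.0)
      f += sigma * w * pair_xi(seed, stepkey, i, j, gaussian) * isqdt;
    for (int k = 0; k < 3; ++k) {
      W.fcr[3 * i + k] += f * e[k];
      W.fcr[3 * j + k] -= f * e[k];
    }
    W.epot += 0.5 * a * rc * w * w;
    PairRec pr;
    pr.i = i; pr.j = j;
    pr.e[0] = e[0]; pr.e[1] = e[1]; pr.e[2] = e[2];
    pr.wD = w * w;
    pr.vimg = im[B.gd] * gdot * B.L[B.gd];
    W.pairs.push_back(pr);
  });
  // bonds (no cutoff)
  for (int b = 0; b < nb; ++b) {
    int i = bonds[2 * b], j = bonds[2 * b + 1];
    double d[3] = {pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                   pos[3 * i + 2] - pos[3 * j + 2]};
    int im[3];
    min_image(B, d, im);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 <= 0) continue;  // req = 0: zero force at coincidence
    double r = std::sqrt(r2);
    double f = -Cspring * (r - req) / r;  // along d, negative = attraction
    for (int k = 0; k < 3; ++k) {
      W.fcr[3 * i + k] += f * d[k];
      W.fcr[3 * j + k] -= f * d[k];
    }
    W.epot += 0.5 * Cspring * (r - req) * (r - req);
  }
}

static void eval_d_forces(int n, const std::vector<PairRec> &pairs,
                          const double *vel, double gamma, int sd,
                          std::vector<double> &fd) {
  fd.assign(3 * n, 0.0);
  for (size_t p = 0; p < pairs.size(); ++p) {
    const PairRec &pr = pairs[p];
    double dv[3] = {vel[3 * pr.i] - vel[3 * pr.j],
                    vel[3 * pr.i + 1] - vel[3 * pr.j + 1],
                    vel[3 * pr.i + 2] - vel[3 * pr.j + 2]};
    dv[sd] -= pr.vimg;
    double vde = dv[0] * pr.e[0] + dv[1] * pr.e[1] + dv[2] * pr.e[2];
    double f = -gamma * pr.wD * vde;
    for (int k = 0; k < 3; ++k) {
      fd[3 * pr.i + k] += f * pr.e[k];
      fd[3 * pr.j + k] -= f * pr.e[k];
    }
  }
}

// One-shot force evaluation (the engine's oracle surface): returns total
// forces and conservative potential for the given state.
// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                NumericMatrix A, IntegerMatrix bonds, NumericVector boxL,
                double tilt, int sd, int gd, double rc, double gamma,
                double sigma, double dt, double Cspring, double req,
                double seed, double stepkey, bool gaussian, double gdot,
                bool use_cells) {
  int n = pos.nrow();
  BoxT B;
  B.L[0] = boxL[0]; B.L[1] = boxL[1]; B.L[2] = boxL[2];
  B.tilt = tilt; B.sd = sd; B.gd = gd;
  std::vector<double> P(3 * n), V(3 * n);
  std::vector<int> S(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      P[3 * i + k] = pos(i, k);
      V[3 * i + k] = vel(i, k);
    }
    S[i] = species[i];
  }
  int nb = bonds.nrow();
  std::vector<int> BD(2 * nb);
  for (int b = 0; b < nb; ++b) { BD[2 * b] = bonds(b, 0); BD[2 * b + 1] = bonds(b, 1); }
  ForceWork W;
  eval_cr_forces(B, n, P.data(), S.data(), REAL(A), A.nrow(), BD.data(), nb,
                 rc, sigma, dt, Cspring, req, (uint64_t)seed,
                 (uint64_t)stepkey, gaussian, gdot, use_cells, W);
  eval_d_forces(n, W.pairs, V.data(), gamma, B.sd, W.fd);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k)
      F(i, k) = W.fcr[3 * i + k] + W.fd[3 * i + k];
  return List::create(_["forces"] = F, _["epot"] = W.epot,
                      _["n_zero_dist"] = W.n_zero,
                      _["n_pairs"] = (int)W.pairs.size());
}

// ---------------------------------------------------------------------------
// Integrator: Groot-Warren modified velocity-Verlet (lambda = 0.5) with
// dissipative-force re-evaluation after the velocity correction, so that the
// force carried into the next step is a pure function of (x, v, step) and
// checkpoint restarts are bit-exact.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos0, NumericMatrix vel0, IntegerVector species,
             NumericMatrix A, IntegerMatrix bonds, NumericVector boxL,
             double tilt0, double strain0, int sd, int gd, double rc,
             double gamma, double sigma, double dt, double Cspring,
             double req, int n_steps, double step0, double seed,
             double shear_rate, int report_every, bool gaussian,
             double lambda, bool use_cells) {
  int n = pos0.nrow();
  BoxT B;
  B.L[0] = boxL[0]; B.L[1] = boxL[1]; B.L[2] = boxL[2];
  B.tilt = tilt0; B.sd = sd; B.gd = gd;
  std::vector<double> x(3 * n), v(3 * n), vt(3 * n), f(3 * n);
  std::vector<int> S(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) { x[3 * i + k] = pos0(i, k); v[3 * i + k] = vel0(i, k); }
    S[i] = species[i];
  }
  int nb = bonds.nrow();
  std::vector<int> BD(2 * nb);
  for (int b = 0; b < nb; ++b) { BD[2 * b] = bonds(b, 0); BD[2 * b + 1] = bonds(b, 1); }
  double strain = strain0;
  double vshift = shear_rate * B.L[gd];
  int dof = 3 * n - 3;
  if (dof < 1) dof = 1;
  uint64_t sd64 = (uint64_t)seed;
  ForceWork W;
  NumericVector temps(n_steps);
  List snaps;
  int total_zero = 0;

  // initial force from current state
  eval_cr_forces(B, n, x.data(), S.data(), REAL(A), A.nrow(), BD.data(), nb,
                 rc, sigma, dt, Cspring, req, sd64, (uint64_t)step0, gaussian,
                 shear_rate, use_cells, W);
  eval_d_forces(n, W.pairs, v.data(), gamma, sd, W.fd);
  for (int i = 0; i < 3 * n; ++i) f[i] = W.fcr[i] + W.fd[i];
  total_zero += W.n_zero;

  for (int s = 0; s < n_steps; ++s) {
    // advance the moving boundary
    if (shear_rate != 0.0) {
      B.tilt += shear_rate * B.L[gd] * dt;
      strain += shear_rate * dt;
      double half = 0.5 * B.L[sd];
      while (B.tilt > half) B.tilt -= B.L[sd];
      while (B.tilt < -half) B.tilt += B.L[sd];
    }
    // position update + velocity prediction
    for (int i = 0; i < 3 * n; ++i) {
      x[i] += dt * v[i] + 0.5 * dt * dt * f[i];
      vt[i] = v[i] + lambda * dt * f[i];
    }
    for (int i = 0; i < n; ++i)
      wrap_one(B, &x[3 * i], &v[3 * i], vshift);  // wrap also fixes vt below
    // (vt must see the same sliding-brick velocity shift as v)
    for (int i = 0; i < 3 * n; ++i) vt[i] = v[i] + lambda * dt * f[i];
    // new conservative + random forces; dissipative from predicted velocity
    eval_cr_forces(B, n, x.data(), S.data(), REAL(A), A.nrow(), BD.data(), nb,
                   rc, sigma, dt, Cspring, req, sd64,
                   (uint64_t)(step0 + s + 1), gaussian, shear_rate, use_cells,
                   W);
    eval_d_forces(n, W.pairs, vt.data(), gamma, sd, W.fd);
    total_zero += W.n_zero;
    // velocity correction
    for (int i = 0; i < 3 * n; ++i)
      v[i] += 0.5 * dt * (f[i] + W.fcr[i] + W.fd[i]);
    // re-evaluate dissipative force at the corrected velocity: the carried
    // force is then a function of the final state only (restartable)
    eval_d_forces(n, W.pairs, v.data(), gamma, sd, W.fd);
    for (int i = 0; i < 3 * n; ++i) f[i] = W.fcr[i] + W.fd[i];
    // kinetic temperature (momentum-free dof)
    double ke = 0;
    for (int i = 0; i < 3 * n; ++i) ke += v[i] * v[i];
    temps[s] = ke / dof;
    if (!std::isfinite(ke) || !std::isfinite(x[0]))
      stop("non-finite state at step %d", (int)(step0 + s + 1));
    if (report_every > 0 && ((s + 1) % report_every == 0)) {
      NumericMatrix sp(n, 3), sv(n, 3);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) { sp(i, k) = x[3 * i + k]; sv(i, k) = v[3 * i + k]; }
      snaps.push_back(List::create(
          _["step"] = step0 + s + 1, _["positions"] = sp, _["velocities"] = sv,
          _["tilt"] = B.tilt, _["strain"] = strain));
    }
  }
  NumericMatrix P(n, 3), V(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { P(i, k) = x[3 * i + k]; V(i, k) = v[3 * i + k]; }
  return List::create(_["positions"] = P, _["velocities"] = V,
                      _["tilt"] = B.tilt, _["strain"] = strain,
                      _["step"] = step0 + n_steps, _["temperature"] = temps,
                      _["snapshots"] = snaps, _["n_zero_dist"] = total_zero);
}

// ---------------------------------------------------------------------------
// Graph analyses: single-linkage clustering with periodic-wrap detection, on
// an index subset.  Wrap detection assigns integer image offsets along a BFS
// spanning tree; a closed loop with inconsistent offsets means the cluster is
// connected to its own periodic image (it percolates) in those dimensions.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_cluster(NumericMatrix pos, NumericVector boxL, double tilt, int sd,
                 int gd, IntegerVector idx, double cutoff,
                 IntegerMatrix edges, IntegerVector mol, int min_contacts) {
  BoxT B;
  B.L[0] = boxL[0]; B.L[1] = boxL[1]; B.L[2] = boxL[2];
  B.tilt = tilt; B.sd = sd; B.gd = gd;
  int m = idx.size();
  std::vector<double> P(3 * m);
  for (int i = 0; i < m; ++i) {
    double xx[3] = {pos(idx[i], 0), pos(idx[i], 1), pos(idx[i], 2)};
    wrap_one(B, xx, (double *)0, 0.0);
    P[3 * i] = xx[0]; P[3 * i + 1] = xx[1]; P[3 * i + 2] = xx[2];
  }
  bool has_mol = mol.size() == m && min_contacts > 1;
  std::map<int, int> molsize;
  if (has_mol) for (int i = 0; i < m; ++i) molsize[mol[i]]++;
  // contact candidates with image counts
  struct Cand { int i, j; int im[3]; };
  std::vector<Cand> cands;
  for_pairs(B, m, P.data(), cutoff, true,
            [&](int i, int j, const double *d, double r2, const int *im) {
    (void)d; (void)r2;
    Cand c;
    c.i = i; c.j = j;
    c.im[0] = im[0]; c.im[1] = im[1]; c.im[2] = im[2];
    cands.push_back(c);
  });
  // when molecules are given, a contact edge between two molecules only
  // counts if the pair shares at least min_contacts bead contacts (a single
  // grazing touch does not merge two chains into one aggregate)
  std::vector<char> keep(cands.size(), 1);
  if (has_mol) {
    std::map<std::pair<int, int>, int> npair;
    for (size_t k = 0; k < cands.size(); ++k) {
      int a = mol[cands[k].i], b = mol[cands[k].j];
      if (a == b) continue;
      npair[{std::min(a, b), std::max(a, b)}]++;
    }
    for (size_t k = 0; k < cands.size(); ++k) {
      int a = mol[cands[k].i], b = mol[cands[k].j];
      if (a == b) continue;
      // a molecule can never offer more contacts than it has beads, so the
      // threshold is capped by the smaller molecule
      int need = std::min(min_contacts,
                          std::min(molsize[a], molsize[b]));
      if (npair[{std::min(a, b), std::max(a, b)}] < need) keep[k] = 0;
    }
  }
  std::vector<std::vector<int>> adj(m);
  std::vector<std::vector<std::array<int, 3>>> aim(m);
  for (size_t k = 0; k < cands.size(); ++k) {
    if (!keep[k]) continue;
    const Cand &c = cands[k];
    adj[c.i].push_back(c.j);
    aim[c.i].push_back({c.im[0], c.im[1], c.im[2]});
    adj[c.j].push_back(c.i);
    aim[c.j].push_back({-c.im[0], -c.im[1], -c.im[2]});
  }
  // hard edges (bonds between subset members), whatever their length
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    double d[3] = {P[3 * i] - P[3 * j], P[3 * i + 1] - P[3 * j + 1],
                   P[3 * i + 2] - P[3 * j + 2]};
    int im[3];
    min_image(B, d, im);
    adj[i].push_back(j);
    aim[i].push_back({im[0], im[1], im[2]});
    adj[j].push_back(i);
    aim[j].push_back({-im[0], -im[1], -im[2]});
  }
  std::vector<int> lab(m, -1);
  std::vector<std::array<int, 3>> off(m);
  std::vector<int> queue;
  int ncl = 0;
  std::vector<std::array<bool, 3>> wraps;
  for (int s = 0; s < m; ++s) {
    if (lab[s] >= 0) continue;
    wraps.push_back({false, false, false});
    queue.clear();
    queue.push_back(s);
    lab[s] = ncl;
    off[s] = {0, 0, 0};
    size_t qi = 0;
    while (qi < queue.size()) {
      int i = queue[qi++];
      for (size_t e = 0; e < adj[i].size(); ++e) {
        int j = adj[i][e];
        // d_min = p_i - p_j - n.b  =>  consistent unwrap: O_j = O_i + n(i->j)
        std::array<int, 3> oj = {off[i][0] + aim[i][e][0],
                                 off[i][1] + aim[i][e][1],
                                 off[i][2] + aim[i][e][2]};
        if (lab[j] < 0) {
          lab[j] = ncl;
          off[j] = oj;
          queue.push_back(j);
        } else {
          for (int k = 0; k < 3; ++k)
            if (off[j][k] != oj[k]) wraps[ncl][k] = true;
        }
      }
    }
    ncl++;
  }
  IntegerVector labels(m);
  for (int i = 0; i < m; ++i) labels[i] = lab[i] + 1;
  LogicalMatrix wr(ncl, 3);
  IntegerMatrix offm(m, 3);
  for (int c = 0; c < ncl; ++c)
    for (int k = 0; k < 3; ++k) wr(c, k) = wraps[c][k];
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < 3; ++k) offm(i, k) = off[i][k];
  return List::create(_["labels"] = labels, _["wraps"] = wr,
                      _["offsets"] = offm, _["n_clusters"] = ncl);
}
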