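// Kinetic Monte Carlo engine for exciton hopping, inter-layer transfer and
// exciton-exciton annihilation on periodic rectangular grids wrapped on
// cylinders (one grid per tube wall).
//
// Conventions:
//  - layers are indexed 0 = inner, 1 = outer (R side uses "inner"/"outer")
//  - site indices are 0-based, periodic in both directions
//  - time unit fs; one call to step() advances dt and ends with an
//    annihilation sweep
//  - status codes: 0 alive, 1 decayed, 2 annihilated (deleted), 3 censored

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct LayerGeom {
  int nc = 0, na = 0;         // circumferential / axial site counts
  double H = 0.0;             // total per-step hop probability
  double R0 = 0.0;            // annihilation radius, lattice units
  double k = 0.0;             // inter-layer transfer rate, fs^-1
  std::vector<int> occ;       // per-site occupancy count
  int cell(int i, int j) const { return i * na + j; }
};

struct KmcState {
  std::vector<LayerGeom> layers;
  double dt = 1.0;            // fs
  double tau_fs = R_PosInf;   // one-exciton lifetime, fs
  long step_no = 0;
  bool finalized = false;
  std::mt19937_64 rng;

  // per-exciton bookkeeping
  std::vector<int> layer, ci, cj, origin;
  std::vector<signed char> status;
  std::vector<double> tterm;          // terminal time, fs (NA while alive)
  std::vector<int> lterm;             // terminal layer
  std::vector<int> nann_surv, nann_tot, nann_same;
  std::vector<double> ux, uy;         // unwrapped displacement, lattice units
  std::vector<int> alive;

  double now() const { return step_no * dt; }

  double runif() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
  }
  int rint(int n) {  // uniform on 0..n-1
    return std::uniform_int_distribution<int>(0, n - 1)(rng);
  }

  void add_exciton(int l, int i, int j) {
    layer.push_back(l); ci.push_back(i); cj.push_back(j);
    origin.push_back(l); status.push_back(0);
    tterm.push_back(NA_REAL); lterm.push_back(NA_INTEGER);
    nann_surv.push_back(0); nann_tot.push_back(0); nann_same.push_back(0);
    ux.push_back(0.0); uy.push_back(0.0);
    alive.push_back((int)layer.size() - 1);
    layers[l].occ[layers[l].cell(i, j)]++;
  }

  void kill(int e, signed char st, int at_layer) {
    LayerGeom& L = layers[layer[e]];
    L.occ[L.cell(ci[e], cj[e])]--;
    status[e] = st;
    tterm[e] = now();
    lterm[e] = at_layer;
  }

  void compact_alive() {
    alive.erase(std::remove_if(alive.begin(), alive.end(),
                               [&](int e) { return status[e] != 0; }),
                alive.end());
  }

  // ---- annihilation ----------------------------------------------------

  void collect_pairs_brute(const std::vector<int>& ids, const LayerGeom& L,
                           double R2, std::vector<std::pair<int,int>>& out) {
    for (size_t a = 0; a + 1 < ids.size(); ++a) {
      for (size_t b = a + 1; b < ids.size(); ++b) {
        int di = std::abs(ci[ids[a]] - ci[ids[b]]);
        di = std::min(di, L.nc - di);
        int dj = std::abs(cj[ids[a]] - cj[ids[b]]);
        dj = std::min(dj, L.na - dj);
        if ((double)(di * di + dj * dj) < R2)
          out.emplace_back(ids[a], ids[b]);
      }
    }
  }

  void collect_pairs_cells(const std::vector<int>& ids, const LayerGeom& L,
                           double R0v, double R2,
                           std::vector<std::pair<int,int>>& out) {
    // cell width >= R0 so violating pairs always sit in adjacent cells
    int ncx = std::max(1, (int)std::floor(L.nc / R0v));
    int ncy = std::max(1, (int)std::floor(L.na / R0v));
    double wx = (double)L.nc / ncx, wy = (double)L.na / ncy;
    std::vector<std::vector<int>> cells((size_t)ncx * ncy);
    for (int e : ids) {
      int cx = std::min(ncx - 1, (int)(ci[e] / wx));
      int cy = std::min(ncy - 1, (int)(cj[e] / wy));
      cells[(size_t)cx * ncy + cy].push_back(e);
    }
    for (int cx = 0; cx < ncx; ++cx) {
      for (int cy = 0; cy < ncy; ++cy) {
        const std::vector<int>& home = cells[(size_t)cx * ncy + cy];
        if (home.empty()) continue;
        // pairs within the home cell
        collect_pairs_brute(home, L, R2, out);
        // half of the 8 neighbour cells to avoid double counting
        static const int off[4][2] = {{1, 0}, {1, 1}, {0, 1}, {-1, 1}};
        for (auto& o : off) {
          int nx = (cx + o[0] + ncx) % ncx, ny = (cy + o[1] + ncy) % ncy;
          if (nx == cx && ny == cy) continue;
          const std::vector<int>& nb = cells[(size_t)nx * ncy + ny];
          for (int a : home) {
            for (int b : nb) {
              int di = std::abs(ci[a] - ci[b]); di = std::min(di, L.nc - di);
              int dj = std::abs(cj[a] - cj[b]); dj = std::min(dj, L.na - dj);
              if ((double)(di * di + dj * dj) < R2) out.emplace_back(a, b);
            }
          }
        }
      }
    }
  }

  // One sweep: find all same-layer pairs closer than R0, then resolve them
  // in random order, deleting one member of each still-alive pair uniformly.
  // Deletions cannot create new sub-R0 pairs, so one pass over the initial
  // pair list is equivalent to iterating until no violating pair remains.
  void sweep() {
    for (size_t l = 0; l < layers.size(); ++l) {
      LayerGeom& L = layers[l];
      if (L.R0 <= 0.0) continue;
      std::vector<int> ids;
      for (int e : alive)
        if (status[e] == 0 && layer[e] == (int)l) ids.push_back(e);
      if (ids.size() < 2) continue;
      double R2 = L.R0 * L.R0;
      std::vector<std::pair<int,int>> viol;
      bool small_grid = (L.nc < 3 * L.R0) || (L.na < 3 * L.R0);
      if (ids.size() <= 64 || small_grid)
        collect_pairs_brute(ids, L, R2, viol);
      else
        collect_pairs_cells(ids, L, L.R0, R2, viol);
      if (viol.empty()) continue;
      for (size_t a = viol.size(); a > 1; --a)
        std::swap(viol[a - 1], viol[rint((int)a)]);
      for (auto& pr : viol) {
        int a = pr.first, b = pr.second;
        if (status[a] != 0 || status[b] != 0) continue;
        int del = (runif() < 0.5) ? a : b;
        int sur = (del == a) ? b : a;
        kill(del, 2, (int)l);
        nann_tot[del]++; nann_tot[sur]++; nann_surv[sur]++;
        if (origin[a] == origin[b]) { nann_same[a]++; nann_same[b]++; }
      }
      compact_alive();
    }
  }

  // ---- one time step ---------------------------------------------------

  void step() {
    // fresh shuffle of the update order each step
    for (size_t a = alive.size(); a > 1; --a)
      std::swap(alive[a - 1], alive[rint((int)a)]);
    double pdec = R_finite(tau_fs) ? dt / tau_fs : 0.0;
    bool two = layers.size() == 2;
    for (int e : alive) {
      if (status[e] != 0) continue;
      double u = runif();
      if (u < pdec) { kill(e, 1, layer[e]); continue; }
      LayerGeom& L = layers[layer[e]];
      double v = runif();
      if (v < L.H) {
        int dir = rint(4);
        L.occ[L.cell(ci[e], cj[e])]--;
        switch (dir) {
          case 0: ci[e] = (ci[e] + 1) % L.nc;        ux[e] += 1.0; break;
          case 1: ci[e] = (ci[e] - 1 + L.nc) % L.nc; ux[e] -= 1.0; break;
          case 2: cj[e] = (cj[e] + 1) % L.na;        uy[e] += 1.0; break;
          default: cj[e] = (cj[e] - 1 + L.na) % L.na; uy[e] -= 1.0; break;
        }
        L.occ[L.cell(ci[e], cj[e])]++;
      } else if (two && v < L.H + L.k * dt) {
        // inter-layer transfer, only onto an unoccupied partner site
        int ol = 1 - layer[e];
        LayerGeom& O = layers[ol];
        int i2 = (int)std::floor(ci[e] * (double)O.nc / L.nc + 0.5) % O.nc;
        int c2 = O.cell(i2, cj[e]);
        if (O.occ[c2] == 0) {
          L.occ[L.cell(ci[e], cj[e])]--;
          O.occ[c2]++;
          layer[e] = ol; ci[e] = i2;
        }
      }  // else stay
    }
    compact_alive();
    step_no++;
    sweep();
  }

  void censor() {
    for (int e : alive) {
      status[e] = 3;
      tterm[e] = now();
      lterm[e] = layer[e];
    }
    // occupancy retained: censored excitons still sit on their sites
    finalized = true;
  }
};

static KmcState* get(SEXP xp) {
  Rcpp::XPtr<KmcState> p(xp);
  if (!p) stop("invalid KMC state pointer");
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_kmc_create(List layer_list, double dt, double tau_fs, int seed,
                    List init) {
  KmcState* s = new KmcState();
  s->dt = dt;
  s->tau_fs = tau_fs;
  s->rng.seed((uint64_t)seed);
  int nl = layer_list.size();
  if (nl < 1 || nl > 2) { delete s; stop("one or two layers required"); }
  for (int l = 0; l < nl; ++l) {
    List ll = layer_list[l];
    LayerGeom g;
    g.nc = as<int>(ll["n_circ"]);
    g.na = as<int>(ll["n_axial"]);
    g.H = as<double>(ll["hop_prob"]);
    g.R0 = as<double>(ll["ann_radius"]);
    g.k = as<double>(ll["k_transfer"]);
    if (g.nc < 1 || g.na < 1) { delete s; stop("lattice dimensions must be >= 1"); }
    double budget = (R_finite(tau_fs) ? dt / tau_fs : 0.0) ;
    if (g.H < 0 || g.H > 1 || budget > 1 || g.H + g.k * dt > 1) {
      delete s; stop("per-step probability budget exceeds 1");
    }
    g.occ.assign((size_t)g.nc * g.na, 0);
    s->layers.push_back(g);
  }
  // plant: either counts (uniform without double occupancy) or explicit
  // 0-based position matrices, one entry per layer
  for (int l = 0; l < nl; ++l) {
    SEXP el = init[l];
    LayerGeom& L = s->layers[l];
    if (Rf_isMatrix(el)) {
      IntegerMatrix pos(el);
      for (int r = 0; r < pos.nrow(); ++r) {
        int i = pos(r, 0), j = pos(r, 1);
        if (i < 0 || i >= L.nc || j < 0 || j >= L.na)
          { delete s; stop("initial position out of bounds"); }
        s->add_exciton(l, i, j);
      }
    } else {
      int ne = as<int>(el);
      long scount = (long)L.nc * L.na;
      if (ne < 0 || ne > scount) { delete s; stop("exciton count exceeds site count"); }
      std::vector<long> cells(scount);
      for (long c = 0; c < scount; ++c) cells[c] = c;
      for (int r = 0; r < ne; ++r) {  // partial Fisher-Yates
        long pick = r + (long)(s->runif() * (scount - r));
        if (pick >= scount) pick = scount - 1;
        std::swap(cells[r], cells[pick]);
        s->add_exciton(l, (int)(cells[r] / L.na), (int)(cells[r] % L.na));
      }
    }
  }
  Rcpp::XPtr<KmcState> p(s, true);
  return p;
}

// [[Rcpp::export]]
void cpp_kmc_sweep(SEXP xp) { get(xp)->sweep(); }

// [[Rcpp::export]]
void cpp_kmc_step(SEXP xp, int n) {
  KmcState* s = get(xp);
  if (s->finalized) stop("state already finalized");
  for (int i = 0; i < n; ++i) s->step();
}

// [[Rcpp::export]]
double cpp_kmc_time(SEXP xp) { return get(xp)->now(); }

// [[Rcpp::export]]
List cpp_kmc_snapshot(SEXP xp) {
  KmcState* s = get(xp);
  int n = (int)s->layer.size();
  IntegerVector layer(n), civ(n), cjv(n), orig(n), nsur(n), ntot(n), nsame(n);
  NumericVector uxv(n), uyv(n), tt(n);
  IntegerVector st(n), lt(n);
  for (int e = 0; e < n; ++e) {
    layer[e] = s->layer[e] + 1; civ[e] = s->ci[e]; cjv[e] = s->cj[e];
    orig[e] = s->origin[e] + 1; st[e] = s->status[e];
    tt[e] = s->tterm[e];
    lt[e] = (s->lterm[e] == NA_INTEGER) ? NA_INTEGER : s->lterm[e] + 1;
    nsur[e] = s->nann_surv[e]; ntot[e] = s->nann_tot[e];
    nsame[e] = s->nann_same[e];
    uxv[e] = s->ux[e]; uyv[e] = s->uy[e];
  }
  return List::create(
    _["time_fs"] = s->now(), _["layer"] = layer, _["i"] = civ, _["j"] = cjv,
    _["origin"] = orig, _["status"] = st, _["terminal_time_fs"] = tt,
    _["terminal_layer"] = lt, _["n_ann_survived"] = nsur,
    _["n_ann_total"] = ntot, _["n_ann_same_origin"] = nsame,
    _["ux"] = uxv, _["uy"] = uyv);
}

// Advance through sampling_steps (absolute step numbers, ascending; the
// current step may be included to sample the present state) and record the
// per-exciton state after each step's annihilation sweep.
// [[Rcpp::export]]
List cpp_kmc_run(SEXP xp, IntegerVector sampling_steps) {
  KmcState* s = get(xp);
  if (s->finalized) stop("state already finalized");
  int n = (int)s->layer.size(), nt = sampling_steps.size();
  IntegerMatrix aliveM(n, nt), layerM(n, nt), ntotM(n, nt), nsameM(n, nt);
  NumericMatrix disp2M(n, nt);
  NumericVector times(nt);
  for (int t = 0; t < nt; ++t) {
    long target = sampling_steps[t];
    if (target < s->step_no) stop("sampling steps must be ascending");
    while (s->step_no < target) {
      if (s->alive.empty()) { s->step_no = target; break; }  // nothing can happen
      s->step();
    }
    times[t] = s->now() ;
    for (int e = 0; e < n; ++e) {
      aliveM(e, t) = (s->status[e] == 0) ? 1 : 0;
      layerM(e, t) = s->layer[e] + 1;
      ntotM(e, t) = s->nann_tot[e];
      nsameM(e, t) = s->nann_same[e];
      disp2M(e, t) = s->ux[e] * s->ux[e] + s->uy[e] * s->uy[e];
    }
  }
  return List::create(
    _["times_fs"] = times, _["alive"] = aliveM, _["layer"] = layerM,
    _["n_ann_total"] = ntotM, _["n_ann_same_origin"] = nsameM,
    _["disp2"] = disp2M);
}

// [[Rcpp::export]]
List cpp_kmc_finalize(SEXP xp) {
  KmcState* s = get(xp);
  if (!s->finalized) s->censor();
  return cpp_kmc_snapshot(xp);
}

// [[Rcpp::export]]
IntegerVector cpp_kmc_occupancy(SEXP xp, int layer) {
  KmcState* s = get(xp);
  if (layer < 1 || layer > (int)s->layers.size()) stop("no such layer");
  LayerGeom& L = s->layers[layer - 1];
  IntegerMatrix m(L.nc, L.na);
  for (int i = 0; i < L.nc; ++i)
    for (int j = 0; j < L.na; ++j) m(i, j) = L.occ[L.cell(i, j)];
  return m;
}
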