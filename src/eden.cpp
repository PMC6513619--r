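#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Flat site index convention shared with the R side: idx = x * H + y
// (0-based internally), x = column in [0, L), y = row in [0, H).
// R matrices are nrow = H (y), ncol = L (x), column-major, so flat idx
// coincides with the R matrix offset.

namespace {

struct Lattice {
  int L, H;
  bool periodic_x;          // linear geometry wraps laterally
  inline int idx(int x, int y) const { return x * H + y; }
  // Writes up to 4 von-Neumann neighbour indices; returns count.
  inline int neighbours(int site, int *out) const {
    int x = site / H, y = site % H, n = 0;
    if (y > 0) out[n++] = site - 1;
    if (y < H - 1) out[n++] = site + 1;
    if (periodic_x) {
      out[n++] = ((x + 1) % L) * H + y;
      out[n++] = ((x + L - 1) % L) * H + y;
    } else {
      if (x < L - 1) out[n++] = site + H;
      if (x > 0) out[n++] = site - H;
    }
    return n;
  }
};

}  // namespace

// Core event loop of the generalized Eden model.
//
// state encoding: -1 empty, 0 wild type, >0 mutant clone id.
// disorder: logical mask, TRUE = disorder site (growth rate factor k).
// At k == 0 disorder sites are impassable: they can never be colonized.
//
// Mother selection: uniform draw from the active list, accepted with
// probability rate/rmax (rejection sampling); this leaves the embedded
// jump chain identical to exact rate-proportional selection and keeps the
// trajectory independent of the disorder mask when k == 1.
//
// Returns the final state, the division log (1 event per new site), the
// per-column max-height profile (linear geometry), optional global-width
// checkpoints, and the termination reason.
// [[Rcpp::export]]
List cpp_run_eden(int L, int H, bool radial, LogicalVector disorder,
                  double k, double s, double mu,
                  double n_target, double height_target,
                  double max_events, int edge_margin,
                  NumericVector wg_checkpoints, bool keep_log) {
  const int LH = L * H;
  if (disorder.size() != LH) stop("disorder mask has wrong length");
  Lattice lat{L, H, !radial};

  std::vector<int> state(LH, -1);
  const int *dis = LOGICAL(disorder);  // 0/1

  const double w_mt = 1.0 + s;
  if (w_mt <= 0) stop("1 + s must be positive");
  const double rmax = std::max(1.0, w_mt);
  const bool impassable = (k == 0.0);

  // class counts for the exact sum of eligible rates
  long n_nw = 0, n_nm = 0, n_dw = 0, n_dm = 0;

  std::vector<int> act;      // active (eligible) sites
  std::vector<int> apos(LH, -1);

  std::vector<double> hmax;  // per-column max occupied row (linear)
  double sumh = 0.0, sumh2 = 0.0;

  int nb[4];

  auto colonizable = [&](int j) {
    return state[j] == -1 && !(impassable && dis[j]);
  };
  auto has_open_nb = [&](int i) {
    int n = lat.neighbours(i, nb);
    for (int a = 0; a < n; ++a) if (colonizable(nb[a])) return true;
    return false;
  };
  auto class_of = [&](int i) {
    // 0 normal WT, 1 normal MT, 2 disorder WT, 3 disorder MT
    return (dis[i] ? 2 : 0) + (state[i] > 0 ? 1 : 0);
  };
  auto bump = [&](int cls, long d) {
    switch (cls) {
      case 0: n_nw += d; break;
      case 1: n_nm += d; break;
      case 2: n_dw += d; break;
      default: n_dm += d; break;
    }
  };
  auto add_active = [&](int i) {
    if (apos[i] >= 0) return;
    apos[i] = (int)act.size();
    act.push_back(i);
    bump(class_of(i), 1);
  };
  auto remove_active = [&](int i) {
    int p = apos[i];
    if (p < 0) return;
    int last = act.back();
    act[p] = last;
    apos[last] = p;
    act.pop_back();
    apos[i] = -1;
    bump(class_of(i), -1);
  };
  auto update_site = [&](int i) {
    if (state[i] >= 0 && has_open_nb(i)) add_active(i);
    else remove_active(i);
  };
  auto site_rate = [&](int i) {
    double r = dis[i] ? k : 1.0;
    if (state[i] > 0) r *= w_mt;
    return r;
  };

  // --- initial condition -------------------------------------------------
  int n_occupied = 0;
  if (radial) {
    int cx = L / 2, cy = H / 2;
    int f = lat.idx(cx, cy);
    state[f] = 0;
    n_occupied = 1;
    update_site(f);
  } else {
    hmax.assign(L, 0.0);
    for (int x = 0; x < L; ++x) state[lat.idx(x, 0)] = 0;
    n_occupied = L;
    for (int x = 0; x < L; ++x) update_site(lat.idx(x, 0));
  }
  const int n_initial = n_occupied;

  // --- log storage -------------------------------------------------------
  R_xlen_t cap = 0;
  {
    double c1 = n_target - n_initial;
    double c2 = max_events;
    double c3 = (double)LH;
    double c = std::min(std::min(c1, c2), c3);
    if (c < 0) c = 0;
    cap = (R_xlen_t)c + 8;
  }
  std::vector<double> log_t;
  std::vector<int> log_mx, log_my, log_dx, log_dy, log_clone;
  std::vector<int> log_mut;
  if (keep_log) {
    log_t.reserve(cap); log_mx.reserve(cap); log_my.reserve(cap);
    log_dx.reserve(cap); log_dy.reserve(cap);
    log_clone.reserve(cap); log_mut.reserve(cap);
  }

  std::vector<double> ck_hbar, ck_w, ck_t, ck_n;
  R_xlen_t next_ck = 0;

  double t_now = 0.0;
  double n_events = 0.0;
  int n_clones = 0;
  std::string term = "";

  // --- event loop --------------------------------------------------------
  while (true) {
    if (n_events >= max_events) { term = "max_events"; break; }
    if (act.empty()) { term = "pinned"; break; }

    double rtot = (double)n_nw + (double)n_nm * w_mt +
                  (double)n_dw * k + (double)n_dm * k * w_mt;

    // rejection sampling of the mother
    int mother;
    for (;;) {
      int j = (int)(unif_rand() * act.size());
      if (j >= (int)act.size()) j = (int)act.size() - 1;
      mother = act[j];
      double r = site_rate(mother);
      if (r >= rmax || unif_rand() * rmax < r) break;
    }

    // daughter: uniform over colonizable empty neighbours
    int n = lat.neighbours(mother, nb);
    int open[4], nopen = 0;
    for (int a = 0; a < n; ++a) if (colonizable(nb[a])) open[nopen++] = nb[a];
    int pick = (int)(unif_rand() * nopen);
    if (pick >= nopen) pick = nopen - 1;
    int daughter = open[pick];

    // genotype of the daughter; WT divisions draw one mutation uniform
    int cl = state[mother];
    int mutated = 0;
    if (cl == 0) {
      if (unif_rand() < mu) { cl = ++n_clones; mutated = 1; }
    }

    t_now += 1.0 / rtot;
    n_events += 1.0;
    state[daughter] = cl;
    ++n_occupied;

    if (keep_log) {
      log_t.push_back(t_now);
      log_mx.push_back(mother / H); log_my.push_back(mother % H);
      log_dx.push_back(daughter / H); log_dy.push_back(daughter % H);
      log_clone.push_back(cl); log_mut.push_back(mutated);
    }

    int dxc = daughter / H, dyc = daughter % H;
    if (!radial && (double)dyc > hmax[dxc]) {
      double h0 = hmax[dxc];
      sumh += dyc - h0;
      sumh2 += (double)dyc * dyc - h0 * h0;
      hmax[dxc] = dyc;
    }

    // eligibility updates are local to the daughter's neighbourhood
    update_site(daughter);
    int nn = lat.neighbours(daughter, nb);
    int nbs[4];
    for (int a = 0; a < nn; ++a) nbs[a] = nb[a];
    for (int a = 0; a < nn; ++a) if (state[nbs[a]] >= 0) update_site(nbs[a]);

    if (!radial && next_ck < wg_checkpoints.size()) {
      double hbar = sumh / L;
      while (next_ck < wg_checkpoints.size() &&
             hbar >= wg_checkpoints[next_ck]) {
        double m = sumh / L;
        double v = sumh2 / L - m * m;
        ck_hbar.push_back(m);
        ck_w.push_back(v > 0 ? std::sqrt(v) : 0.0);
        ck_t.push_back(t_now);
        ck_n.push_back((double)n_occupied);
        ++next_ck;
      }
    }

    // termination checks
    if (radial) {
      int bdist = std::min(std::min(dxc, L - 1 - dxc),
                           std::min(dyc, H - 1 - dyc));
      if (bdist < edge_margin) { term = "edge"; break; }
      if ((double)n_occupied >= n_target) { term = "reached_n"; break; }
    } else {
      if (dyc >= H - 1 - edge_margin) { term = "edge"; break; }
      if (sumh / L >= height_target) { term = "reached_n"; break; }
    }
  }

  IntegerVector st(LH);
  for (int i = 0; i < LH; ++i) st[i] = state[i];
  st.attr("dim") = IntegerVector::create(H, L);

  List out = List::create(
      _["state"] = st,
      _["t_now"] = t_now,
      _["n_occupied"] = n_occupied,
      _["n_initial"] = n_initial,
      _["n_clones"] = n_clones,
      _["terminated_by"] = term);
  if (keep_log) {
    out["log"] = DataFrame::create(
        _["time"] = NumericVector(log_t.begin(), log_t.end()),
        _["mother_x"] = IntegerVector(log_mx.begin(), log_mx.end()),
        _["mother_y"] = IntegerVector(log_my.begin(), log_my.end()),
        _["daughter_x"] = IntegerVector(log_dx.begin(), log_dx.end()),
        _["daughter_y"] = IntegerVector(log_dy.begin(), log_dy.end()),
        _["clone_id"] = IntegerVector(log_clone.begin(), log_clone.end()),
        _["mutated"] = LogicalVector(log_mut.begin(), log_mut.end()));
  }
  if (!radial) {
    out["height_profile"] = NumericVector(hmax.begin(), hmax.end());
    out["width_curve"] = DataFrame::create(
        _["hbar"] = NumericVector(ck_hbar.begin(), ck_hbar.end()),
        _["w_g"] = NumericVector(ck_w.begin(), ck_w.end()),
        _["time"] = NumericVector(ck_t.begin(), ck_t.end()),
        _["n_occupied"] = NumericVector(ck_n.begin(), ck_n.end()));
  }
  return out;
}

// Flood fill of the exterior empty region. Seeds: all border cells
// (radial) or the top row (linear, periodic in x). Barrier cells
// (impassable obstacles) block the fill without being occupied.
// [[Rcpp::export]]
LogicalVector cpp_exterior_mask(IntegerVector state, LogicalVector barrier,
                                int L, int H, bool periodic_x) {
  const int LH = L * H;
  if (state.size() != LH || barrier.size() != LH) stop("bad grid length");
  Lattice lat{L, H, periodic_x};
  std::vector<char> ext(LH, 0);
  std::vector<int> stack;
  auto open = [&](int j) {
    return state[j] == -1 && !barrier[j] && !ext[j];
  };
  if (periodic_x) {
    for (int x = 0; x < L; ++x) {
      int j = lat.idx(x, H - 1);
      if (open(j)) { ext[j] = 1; stack.push_back(j); }
    }
  } else {
    for (int x = 0; x < L; ++x) {
      int j1 = lat.idx(x, 0), j2 = lat.idx(x, H - 1);
      if (open(j1)) { ext[j1] = 1; stack.push_back(j1); }
      if (open(j2)) { ext[j2] = 1; stack.push_back(j2); }
    }
    for (int y = 0; y < H; ++y) {
      int j1 = lat.idx(0, y), j2 = lat.idx(L - 1, y);
      if (open(j1)) { ext[j1] = 1; stack.push_back(j1); }
      if (open(j2)) { ext[j2] = 1; stack.push_back(j2); }
    }
  }
  int nb[4];
  while (!stack.empty()) {
    int i = stack.back(); stack.pop_back();
    int n = lat.neighbours(i, nb);
    for (int a = 0; a < n; ++a) {
      int j = nb[a];
      if (open(j)) { ext[j] = 1; stack.push_back(j); }
    }
  }
  LogicalVector out(LH);
  for (int i = 0; i < LH; ++i) out[i] = ext[i] != 0;
  out.attr("dim") = IntegerVector::create(H, L);
  return out;
}

// Replays the daughter coordinates of a linear-geometry division log and
// records (mean height, global width) whenever the mean per-column max
// height crosses the next checkpoint.
// [[Rcpp::export]]
DataFrame cpp_height_curve(IntegerVector dx, IntegerVector dy, int L,
                           NumericVector checkpoints) {
  std::vector<double> hmax(L, 0.0);
  double sumh = 0.0, sumh2 = 0.0;
  std::vector<double> out_h, out_w;
  R_xlen_t next = 0;
  for (R_xlen_t e = 0; e < dx.size(); ++e) {
    int x = dx[e], y = dy[e];
    if ((double)y > hmax[x]) {
      double h0 = hmax[x];
      sumh += y - h0;
      sumh2 += (double)y * y - h0 * h0;
      hmax[x] = y;
    }
    double hbar = sumh / L;
    while (next < checkpoints.size() && hbar >= checkpoints[next]) {
      double v = sumh2 / L - hbar * hbar;
      out_h.push_back(hbar);
      out_w.push_back(v > 0 ? std::sqrt(v) : 0.0);
      ++next;
    }
  }
  return DataFrame::create(
      _["hbar"] = NumericVector(out_h.begin(), out_h.end()),
      _["w_g"] = NumericVector(out_w.begin(), out_w.end()));
}

// Path length to the founder for every logged site; events must be in
// chronological order so a mother's depth precedes her daughters'.
// [[Rcpp::export]]
IntegerVector cpp_depths(IntegerVector mothers, IntegerVector daughters,
                         int root, double n_sites) {
  IntegerVector depth((R_xlen_t)n_sites, NA_INTEGER);
  depth[root] = 0;
  for (R_xlen_t i = 0; i < mothers.size(); ++i) {
    if (depth[mothers[i]] == NA_INTEGER)
      stop("orphan site in the division log");
    depth[daughters[i]] = depth[mothers[i]] + 1;
  }
  return depth;
}

// Pooled transverse lineage fluctuations. parent maps flat site index to
// the mother's flat index (-1 for the founder); for each front leaf the
// reference ray runs from the colony center through that leaf, and at
// each integer radius bin t the recorded deviation is the perpendicular
// distance of the first path point (walking leaf -> root) with r <= t.
// Returns per-bin sums of squared deviations and counts (bins 1..tmax).
// ray_mode 0: ray through the lineage's own front leaf; ray_mode 1:
// origin-anchored least-squares ray (principal axis of the path's
// second-moment matrix about the center), which does not constrain the
// deviation to vanish at the leaf.
// If bridge is true, each squared deviation is standardized by the
// Brownian-bridge variance factor (1 - t / r_leaf) of its own lineage
// (the leaf-anchored ray forces d = 0 at r_leaf), and bins beyond
// 0.8 * r_leaf are dropped where the standardization becomes singular.
// [[Rcpp::export]]
List cpp_lineage_bins(IntegerVector parent, IntegerVector leaves,
                      double cx, double cy, int H, int tmax,
                      int ray_mode, bool bridge) {
  std::vector<double> sumsq(tmax, 0.0);
  std::vector<double> cnt(tmax, 0.0);
  for (R_xlen_t li = 0; li < leaves.size(); ++li) {
    int leaf = leaves[li];
    double lx = leaf / H - cx, ly = leaf % H - cy;
    double rl = std::sqrt(lx * lx + ly * ly);
    if (rl <= 0) continue;
    double ux = lx / rl, uy = ly / rl;
    if (ray_mode == 1) {
      double sxx = 0, sxy = 0, syy = 0;
      for (int node = leaf; node >= 0; node = parent[node]) {
        double vx = node / H - cx, vy = node % H - cy;
        sxx += vx * vx; sxy += vx * vy; syy += vy * vy;
      }
      // leading eigenvector of [[sxx, sxy], [sxy, syy]]
      double tr = sxx + syy;
      double det = sxx * syy - sxy * sxy;
      double lam = tr / 2 + std::sqrt(std::max(0.0, tr * tr / 4 - det));
      double ex = sxy, ey = lam - sxx;
      double ne = std::sqrt(ex * ex + ey * ey);
      if (ne < 1e-12) { ex = 1; ey = 0; ne = 1; }
      ex /= ne; ey /= ne;
      if (ex * ux + ey * uy < 0) { ex = -ex; ey = -ey; }
      ux = ex; uy = ey;
    }
    int tcur = (int)std::floor(bridge ? 0.8 * rl : rl);
    if (tcur > tmax) tcur = tmax;
    int node = leaf;
    while (node >= 0 && tcur >= 1) {
      double vx = node / H - cx, vy = node % H - cy;
      double r = std::sqrt(vx * vx + vy * vy);
      if (r <= (double)tcur) {
        double d = ux * vy - uy * vx;  // perpendicular offset from the ray
        int tlo = (int)std::ceil(r);
        if (tlo < 1) tlo = 1;
        for (int t = tcur; t >= tlo; --t) {
          double d2 = d * d;
          if (bridge) d2 /= 1.0 - (double)t / rl;
          sumsq[t - 1] += d2;
          cnt[t - 1] += 1.0;
        }
        tcur = tlo - 1;
      }
      node = parent[node];
    }
  }
  return List::create(
      _["sumsq"] = NumericVector(sumsq.begin(), sumsq.end()),
      _["count"] = NumericVector(cnt.begin(), cnt.end()));
}

// Same pooling as cpp_lineage_bins but binned by the path length from
// the founder (tree depth, i.e. divisions along the lineage), the
// intrinsic forward-time clock of a lineage. Depth decreases by
// exactly 1 per step toward the root, so every bin along a path holds
// exactly one point.
// [[Rcpp::export]]
List cpp_lineage_bins_depth(IntegerVector parent, IntegerVector depth,
                            IntegerVector leaves, double cx, double cy,
                            int H, int tmax, bool bridge) {
  std::vector<double> sumsq(tmax, 0.0), cnt(tmax, 0.0);
  for (R_xlen_t li = 0; li < leaves.size(); ++li) {
    int leaf = leaves[li];
    double lx = leaf / H - cx, ly = leaf % H - cy;
    double rl = std::sqrt(lx * lx + ly * ly);
    if (rl <= 0) continue;
    double ux = lx / rl, uy = ly / rl;
    double dl = depth[leaf];
    if (dl <= 0) continue;
    int tcap = bridge ? (int)(0.8 * dl) : (int)dl;
    if (tcap > tmax) tcap = tmax;
    for (int node = leaf; node >= 0; node = parent[node]) {
      int t = depth[node];
      if (t < 1) break;
      if (t > tcap) continue;
      double vx = node / H - cx, vy = node % H - cy;
      double d = ux * vy - uy * vx;
      double d2 = d * d;
      if (bridge) d2 /= 1.0 - (double)t / dl;
      sumsq[t - 1] += d2;
      cnt[t - 1] += 1.0;
    }
  }
  return List::create(
      _["sumsq"] = NumericVector(sumsq.begin(), sumsq.end()),
      _["count"] = NumericVector(cnt.begin(), cnt.end()));
}

// Same pooling as cpp_lineage_bins but binned by birth time of the
// path points: for each bin edge t (descending) the recorded deviation
// is that of the first path point (leaf -> root) born at or before t.
// Returns per-bin sums of squared deviations and counts for the
// supplied ascending bin times.
// [[Rcpp::export]]
List cpp_lineage_bins_time(IntegerVector parent, NumericVector btime,
                           IntegerVector leaves, double cx, double cy,
                           int H, NumericVector bins) {
  R_xlen_t nb = bins.size();
  std::vector<double> sumsq(nb, 0.0), cnt(nb, 0.0);
  for (R_xlen_t li = 0; li < leaves.size(); ++li) {
    int leaf = leaves[li];
    double lx = leaf / H - cx, ly = leaf % H - cy;
    double rl = std::sqrt(lx * lx + ly * ly);
    if (rl <= 0) continue;
    double ux = lx / rl, uy = ly / rl;
    R_xlen_t b = nb - 1;
    while (b >= 0 && bins[b] > btime[leaf]) --b;
    int node = leaf;
    while (node >= 0 && b >= 0) {
      if (btime[node] <= bins[b]) {
        double vx = node / H - cx, vy = node % H - cy;
        double d = ux * vy - uy * vx;
        while (b >= 0 && btime[node] <= bins[b]) {
          sumsq[b] += d * d;
          cnt[b] += 1.0;
          --b;
        }
      }
      node = parent[node];
    }
  }
  return List::create(
      _["sumsq"] = NumericVector(sumsq.begin(), sumsq.end()),
      _["count"] = NumericVector(cnt.begin(), cnt.end()));
}

// Pairwise MRCA over front leaves. depth[i] = path length to the founder.
// If the number of distinct pairs exceeds pair_budget, pairs are drawn at
// random (without replacement within a pair, with replacement across
// pairs). Returns (dx, t2) per pair, t2 measured back from t_total.
// [[Rcpp::export]]
DataFrame cpp_pair_coalescence(IntegerVector parent, IntegerVector depth,
                               NumericVector btime, IntegerVector leaves,
                               double t_total, int H, double pair_budget) {
  R_xlen_t nl = leaves.size();
  if (nl < 2) stop("need at least two front leaves");
  double npairs_all = (double)nl * (nl - 1) / 2.0;
  bool sample_pairs = npairs_all > pair_budget;
  R_xlen_t npairs = sample_pairs ? (R_xlen_t)pair_budget
                                 : (R_xlen_t)npairs_all;
  NumericVector out_dx(npairs), out_t2(npairs);
  R_xlen_t w = 0;
  auto emit = [&](int a, int b) {
    int la = leaves[a], lb = leaves[b];
    double ddx = (double)(la / H) - (lb / H);
    double ddy = (double)(la % H) - (lb % H);
    int u = la, v = lb;
    while (depth[u] > depth[v]) u = parent[u];
    while (depth[v] > depth[u]) v = parent[v];
    while (u != v) { u = parent[u]; v = parent[v]; }
    out_dx[w] = std::sqrt(ddx * ddx + ddy * ddy);
    out_t2[w] = t_total - btime[u];
    ++w;
  };
  if (sample_pairs) {
    for (R_xlen_t p = 0; p < npairs; ++p) {
      int a = (int)(unif_rand() * nl);
      int b = (int)(unif_rand() * (nl - 1));
      if (b >= a) ++b;
      if (a >= nl) a = (int)nl - 1;
      if (b >= nl) b = (int)nl - 1;
      emit(a, b);
    }
  } else {
    for (int a = 0; a < nl; ++a)
      for (int b = a + 1; b < nl; ++b) emit(a, b);
  }
  return DataFrame::create(_["dx"] = out_dx, _["t2"] = out_t2);
}
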