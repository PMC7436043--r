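#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Single-line DP over a cost matrix (rows = candidate boundary locations,
// cols = sequential positions).  Transition cost from row hp (previous column)
// to row h is C(h, w) * (1 + |h - hp| / gamma), |h - hp| <= delta_max.
//
// Ties are broken deterministically: smaller |delta| first, then smaller
// previous row.  fixed_start >= 0 restricts column 0 to that row;
// seam_center >= 0 restricts the final column to rows within delta_max of it.

static const double INF = std::numeric_limits<double>::infinity();

struct DPResult {
  std::vector<int> path;
  double cost;
};

// `bound`: since node costs are nonnegative, the per-column minimum of the
// cumulative cost never decreases; once it reaches `bound` no completion can
// beat the incumbent, so the run is abandoned (used by the closed-contour
// restarts; exactness is unaffected).
static DPResult dp_open_core(const NumericMatrix& cost, int delta_max,
                             double gamma, int fixed_start, int seam_center,
                             double bound = INF) {
  const int H = cost.nrow(), W = cost.ncol();
  const double* cp = REAL(cost);
  std::vector<double> prev(H), cur(H);
  std::vector<int> P(static_cast<size_t>(H) * W, -1);

  for (int h = 0; h < H; ++h)
    prev[h] = (fixed_start >= 0 && h != fixed_start) ? INF : cp[h];

  // delta iteration order: 0, +1, -1, +2, -2, ... so that strict improvement
  // prefers smaller |delta|, then the smaller previous row (prev = h - delta).
  std::vector<int> dorder;
  dorder.push_back(0);
  for (int a = 1; a <= delta_max; ++a) { dorder.push_back(a); dorder.push_back(-a); }
  std::vector<double> pen(dorder.size());
  for (size_t k = 0; k < dorder.size(); ++k)
    pen[k] = 1.0 + std::abs((double)dorder[k]) / gamma;

  DPResult res;
  res.cost = INF;
  for (int w = 1; w < W; ++w) {
    const double* colw = cp + static_cast<size_t>(w) * H;
    int* Pw = P.data() + static_cast<size_t>(w) * H;
    double colmin = INF;
    for (int h = 0; h < H; ++h) {
      double best = INF;
      int bestp = -1;
      for (size_t k = 0; k < dorder.size(); ++k) {
        const int hp = h - dorder[k];
        if (hp < 0 || hp >= H) continue;
        const double dpv = prev[hp];
        if (dpv == INF) continue;
        const double tot = dpv + colw[h] * pen[k];
        if (tot < best) { best = tot; bestp = hp; }
      }
      cur[h] = best;
      Pw[h] = bestp;
      if (best < colmin) colmin = best;
    }
    if (colmin >= bound) return res;  // pruned: cannot beat the incumbent
    std::swap(prev, cur);
  }

  int hbest = -1;
  for (int h = 0; h < H; ++h) {
    if (seam_center >= 0 && std::abs(h - seam_center) > delta_max) continue;
    if (prev[h] < res.cost) { res.cost = prev[h]; hbest = h; }
  }
  if (hbest < 0) return res;  // infeasible
  res.path.assign(W, 0);
  res.path[W - 1] = hbest;
  for (int w = W - 1; w > 0; --w)
    res.path[w - 1] = P[static_cast<size_t>(w) * H + res.path[w]];
  return res;
}

// [[Rcpp::export(name = ".dp_open_cpp")]]
List dp_open_cpp(NumericMatrix cost, int delta_max, double gamma) {
  DPResult r = dp_open_core(cost, delta_max, gamma, -1, -1, INF);
  return List::create(_["path"] = wrap(r.path), _["cost"] = r.cost);
}

// Closed contour: exact seam closure by solving the open problem once per
// start row (column 0 fixed) with the final column restricted to rows within
// delta_max of the start.  Keeps the feasible minimum; ties prefer the
// smaller start row.
// [[Rcpp::export(name = ".dp_closed_cpp")]]
List dp_closed_cpp(NumericMatrix cost, int delta_max, double gamma) {
  const int H = cost.nrow();
  // visit start rows by ascending first-column cost so a strong incumbent is
  // found early and later restarts are pruned; the result is independent of
  // the order (each restart is exact, ties resolved to the smaller start row).
  std::vector<int> order(H);
  for (int s = 0; s < H; ++s) order[s] = s;
  const double* c0 = REAL(cost);
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return c0[a] < c0[b]; });
  DPResult best;
  best.cost = INF;
  int best_s = -1;
  for (int i = 0; i < H; ++i) {
    const int s = order[i];
    DPResult r = dp_open_core(cost, delta_max, gamma, s, s, best.cost);
    if (r.path.empty()) continue;
    if (r.cost < best.cost || (r.cost == best.cost && s < best_s)) {
      best = r;
      best_s = s;
    }
  }
  if (best.path.empty()) stop("no feasible closed path");
  return List::create(_["path"] = wrap(best.path), _["cost"] = best.cost);
}

// Dual parallel-line DP.  cost_outer / cost_inner are crop-shaped matrices
// (rows = crop rows, cols = crop columns); the joint state per column is
// (y1, d) with inner row y2 = y1 + d and dmin_px <= d <= dmax_px.  Node cost
// is cost_outer(y1, x) + cost_inner(y2, x); moving a line by delta multiplies
// the node cost by (1+alpha)^|delta| and a separation change |dd| adds a
// factor (1 + alpha3*|dd|).  Exact over the restricted state space.
// [[Rcpp::export(name = ".mdp_dual_cpp")]]
List mdp_dual_cpp(NumericMatrix cost_outer, NumericMatrix cost_inner,
                  int delta1, int delta2, double alpha1, double alpha2,
                  double alpha3, int dmin_px, int dmax_px) {
  const int H = cost_outer.nrow(), W = cost_outer.ncol();
  if (cost_inner.nrow() != H || cost_inner.ncol() != W)
    stop("cost field shapes differ");
  const int ND = dmax_px - dmin_px + 1;
  if (ND <= 0 || H <= dmin_px) stop("no feasible dual-line state: crop too short for dmin/dmax");

  auto sidx = [&](int y1, int d) { return (d - dmin_px) * H + y1; };
  const int NS = ND * H;
  std::vector<double> cur(NS, INF), prev(NS, INF);
  std::vector<int> pred(static_cast<size_t>(NS) * W, -1);

  auto node = [&](int y1, int d, int x) {
    return cost_outer(y1, x) + cost_inner(y1 + d, x);
  };

  for (int d = dmin_px; d <= dmax_px; ++d)
    for (int y1 = 0; y1 + d < H; ++y1)
      prev[sidx(y1, d)] = node(y1, d, 0);

  for (int x = 1; x < W; ++x) {
    std::fill(cur.begin(), cur.end(), INF);
    for (int d = dmin_px; d <= dmax_px; ++d) {
      for (int y1 = 0; y1 + d < H; ++y1) {
        const int y2 = y1 + d;
        const double nc = node(y1, d, x);
        double best = INF;
        int bestp = -1;
        // previous-state iteration ordered by (prev y1, prev d) ascending so
        // strict improvement gives a deterministic tie-break.
        for (int d1 = delta1; d1 >= -delta1; --d1) {
          const int y1p = y1 - d1;
          if (y1p < 0 || y1p >= H) continue;
          for (int d2 = delta2; d2 >= -delta2; --d2) {
            const int y2p = y2 - d2;
            const int dp_ = y2p - y1p;
            if (dp_ < dmin_px || dp_ > dmax_px || y2p >= H) continue;
            const double pv = prev[sidx(y1p, dp_)];
            if (pv == INF) continue;
            const int dd = d - dp_;
            const double mult = std::pow(1.0 + alpha1, std::abs((double)d1)) *
                                std::pow(1.0 + alpha2, std::abs((double)d2)) *
                                (1.0 + alpha3 * std::abs((double)dd));
            const double tot = pv + nc * mult;
            if (tot < best) { best = tot; bestp = sidx(y1p, dp_); }
          }
        }
        cur[sidx(y1, d)] = best;
        pred[static_cast<size_t>(x) * NS + sidx(y1, d)] = bestp;
      }
    }
    std::swap(cur, prev);
  }

  // final state: minimal cumulative cost; ties prefer smaller outer row,
  // then smaller separation.
  double bestc = INF;
  int besty1 = -1, bestd = -1;
  for (int y1 = 0; y1 < H; ++y1)
    for (int d = dmin_px; d <= dmax_px; ++d)
      if (y1 + d < H && prev[sidx(y1, d)] < bestc) {
        bestc = prev[sidx(y1, d)]; besty1 = y1; bestd = d;
      }
  if (besty1 < 0) stop("no feasible dual-line path");

  IntegerVector outer(W), inner(W);
  int s = sidx(besty1, bestd);
  for (int x = W - 1; x >= 0; --x) {
    const int d = s / H + dmin_px, y1 = s % H;
    outer[x] = y1;
    inner[x] = y1 + d;
    if (x > 0) s = pred[static_cast<size_t>(x) * NS + s];
  }
  return List::create(_["outer"] = outer, _["inner"] = inner, _["cost"] = bestc);
}
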