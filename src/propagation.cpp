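#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Discrete-time constrained propagation from a single origin.
//
// speeds: list of dense N x N speed matrices, one per window step (element 1
//   is the window's first snapshot, whose edges are never used because the
//   process starts there); entry 0 means "no edge", +Inf means instantaneous.
// dists:  list of dense N x N distance matrices; length 1 for static
//   positions (reused every step), otherwise one per window step.
// tau:    snapshot duration in seconds.
// origin: 0-based node index.
// spatialTiebreak: when true, shortest-path DAG keeps only predecessors that
//   minimise spatial length among minimum-latency arrivals; when false all
//   recorded predecessors are kept (pure-temporal path counting).
// wantTrace: also return per-step reachability sets and progress matrices.
// wantCentrality: also return per-origin Brandes-style betweenness
//   accumulations (path betweenness and betweenness efficiency terms).
//
// Arrival rule: node w joins the reachability set at step s if some already
// reached v has accumulated progress P[v,w] >= D[v,w] (with a small relative
// tolerance for floating-point accumulation). Progress toward a reached node
// is frozen; progress resets to zero whenever the carrying edge is absent.
// [[Rcpp::export]]
List cpp_propagate(List speeds, List dists, double tau, int origin,
                   bool spatialTiebreak, bool wantTrace, bool wantCentrality) {
  int steps = speeds.size();
  NumericMatrix S0 = speeds[0];
  int n = S0.nrow();
  bool staticD = (dists.size() == 1);

  std::vector<char> reached(n, 0);
  std::vector<int> arrival(n, -1);  // step offset from window start
  reached[origin] = 1;
  arrival[origin] = 0;

  NumericMatrix P(n, n);
  std::vector<std::vector<int> > preds(n);
  std::vector<std::vector<double> > hops(n);

  List traceK, traceP;
  if (wantTrace) {
    traceK = List(steps);
    traceP = List(steps);
    LogicalVector k0(n);
    k0[origin] = true;
    traceK[0] = k0;
    traceP[0] = clone(P);
  }

  std::vector<int> newly;
  for (int s = 1; s < steps; ++s) {
    NumericMatrix Sm = speeds[s];
    NumericMatrix D = staticD ? as<NumericMatrix>(dists[0])
                              : as<NumericMatrix>(dists[s]);
    // progress update: only reached v -> unreached w pairs evolve
    for (int v = 0; v < n; ++v) {
      if (!reached[v]) continue;
      for (int w = 0; w < n; ++w) {
        if (reached[w] || w == v) continue;
        double sp = Sm(v, w);
        if (sp > 0.0) {
          double q = D(v, w) - P(v, w);
          if (q < 0.0) q = 0.0;
          double inc = tau * sp;  // +Inf speed => increment capped at q
          if (inc > q) inc = q;
          P(v, w) += inc;
        } else {
          P(v, w) = 0.0;  // edge absent: progress is lost
        }
      }
    }
    // arrivals are simultaneous: scan first, then mark
    newly.clear();
    for (int w = 0; w < n; ++w) {
      if (reached[w]) continue;
      bool hit = false;
      for (int v = 0; v < n; ++v) {
        if (!reached[v] || v == w) continue;
        double d = D(v, w);
        double tol = 1e-9 * (d > 1.0 ? d : 1.0);
        if (P(v, w) >= d - tol) {
          if (!hit) { newly.push_back(w); hit = true; }
          preds[w].push_back(v);
          hops[w].push_back(P(v, w));
        }
      }
    }
    for (size_t k = 0; k < newly.size(); ++k) {
      reached[newly[k]] = 1;
      arrival[newly[k]] = s;
    }
    if (wantTrace) {
      LogicalVector ks(n);
      for (int v = 0; v < n; ++v) ks[v] = reached[v] != 0;
      traceK[s] = ks;
      traceP[s] = clone(P);
    }
  }

  // nodes in non-decreasing arrival order (reached only)
  std::vector<int> order;
  order.reserve(n);
  for (int v = 0; v < n; ++v)
    if (reached[v]) order.push_back(v);
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return arrival[a] < arrival[b]; });

  // spatial-distance / path-count DP over the predecessor DAG
  std::vector<double> sdist(n, R_PosInf), sigma(n, 0.0);
  sdist[origin] = 0.0;
  sigma[origin] = 1.0;
  List dag(n), dagHops(n);
  for (size_t k = 0; k < order.size(); ++k) {
    int w = order[k];
    if (w == origin) continue;
    const std::vector<int> &pv = preds[w];
    const std::vector<double> &hv = hops[w];
    double best = R_PosInf;
    for (size_t j = 0; j < pv.size(); ++j) {
      double cand = sdist[pv[j]] + hv[j];
      if (cand < best) best = cand;
    }
    double tol = 1e-9 * (best > 1.0 ? best : 1.0);
    std::vector<int> opt;
    std::vector<double> optHop;
    double sig = 0.0;
    for (size_t j = 0; j < pv.size(); ++j) {
      double cand = sdist[pv[j]] + hv[j];
      if (!spatialTiebreak || cand <= best + tol) {
        opt.push_back(pv[j] + 1);  // 1-based for R
        optHop.push_back(hv[j]);
        sig += sigma[pv[j]];
      }
    }
    sdist[w] = best;
    sigma[w] = sig;
    dag[w] = IntegerVector(opt.begin(), opt.end());
    dagHops[w] = NumericVector(optHop.begin(), optHop.end());
  }
  dag[origin] = IntegerVector(0);
  dagHops[origin] = NumericVector(0);

  IntegerVector arrivalOut(n);
  for (int v = 0; v < n; ++v)
    arrivalOut[v] = reached[v] ? arrival[v] : NA_INTEGER;

  List predsAll(n), hopsAll(n);
  for (int v = 0; v < n; ++v) {
    IntegerVector pv(preds[v].size());
    for (size_t j = 0; j < preds[v].size(); ++j) pv[j] = preds[v][j] + 1;
    predsAll[v] = pv;
    hopsAll[v] = NumericVector(hops[v].begin(), hops[v].end());
  }

  List out = List::create(
      _["arrival"] = arrivalOut, _["sdist"] = NumericVector(sdist.begin(), sdist.end()),
      _["sigma"] = NumericVector(sigma.begin(), sigma.end()), _["dag"] = dag,
      _["hops"] = dagHops, _["predsAll"] = predsAll, _["hopsAll"] = hopsAll);

  if (wantCentrality) {
    // path betweenness: Brandes dependency accumulation over the DAG
    std::vector<double> delta(n, 0.0);
    for (size_t k = order.size(); k-- > 0;) {
      int u = order[k];
      if (u == origin) continue;
      IntegerVector pu = dag[u];
      for (int j = 0; j < pu.size(); ++j) {
        int v = pu[j] - 1;
        delta[v] += sigma[v] / sigma[u] * (1.0 + delta[u]);
      }
    }
    delta[origin] = 0.0;
    // betweenness efficiency: interior membership via DAG ancestor sets
    std::vector<std::vector<char> > anc(n, std::vector<char>(n, 0));
    std::vector<double> be(n, 0.0);
    for (size_t k = 0; k < order.size(); ++k) {
      int u = order[k];
      if (u == origin) continue;
      IntegerVector pu = dag[u];
      std::vector<char> &au = anc[u];
      for (int j = 0; j < pu.size(); ++j) {
        int v = pu[j] - 1;
        if (v != origin) au[v] = 1;
        const std::vector<char> &av = anc[v];
        for (int x = 0; x < n; ++x)
          if (av[x]) au[x] = 1;
      }
      double w = 1.0 / arrival[u];  // latency in timestep units
      for (int x = 0; x < n; ++x)
        if (au[x]) be[x] += w;
    }
    out["pb"] = NumericVector(delta.begin(), delta.end());
    out["be"] = NumericVector(be.begin(), be.end());
  }
  if (wantTrace) {
    out["traceK"] = traceK;
    out["traceP"] = traceP;
  }
  return out;
}
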