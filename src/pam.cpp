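#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Total cost of a medoid set: sum over points of dissimilarity to the nearest
// medoid. Medoids must be sorted ascending so that ties in "nearest" resolve
// to the lowest medoid index (strict < keeps the first minimum found).
static double medoid_cost(const NumericMatrix& d, const std::vector<int>& med,
                          std::vector<int>* assign = nullptr) {
  const int n = d.nrow();
  const int k = (int)med.size();
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < k; ++j) {
      const double v = d(i, med[j]);
      if (v < best) { best = v; bj = j; }
    }
    tot += best;
    if (assign) (*assign)[i] = bj;
  }
  return tot;
}

// Greedy BUILD phase: start from the point minimising total dissimilarity to
// all others, then repeatedly add the point giving the largest cost decrease.
// Ties break to the lowest point index.
static std::vector<int> build_phase(const NumericMatrix& d, int k) {
  const int n = d.nrow();
  std::vector<bool> is_med(n, false);
  std::vector<int> med;
  med.reserve(k);

  int first = 0;
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += d(i, j);
    if (s < best) { best = s; first = i; }
  }
  med.push_back(first);
  is_med[first] = true;

  std::vector<double> dmin(n);
  for (int i = 0; i < n; ++i) dmin[i] = d(i, first);

  while ((int)med.size() < k) {
    int pick = -1;
    double bestgain = -1.0;
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) continue;
      double gain = 0.0;
      for (int i = 0; i < n; ++i) {
        const double diff = dmin[i] - d(i, c);
        if (diff > 0) gain += diff;
      }
      if (gain > bestgain) { bestgain = gain; pick = c; }
    }
    med.push_back(pick);
    is_med[pick] = true;
    for (int i = 0; i < n; ++i)
      if (d(i, pick) < dmin[i]) dmin[i] = d(i, pick);
  }
  std::sort(med.begin(), med.end());
  return med;
}

// PAM: optional BUILD initialisation, then SWAP local search. Each accepted
// swap strictly decreases the objective; ties among candidate swaps keep the
// first one in scan order (lowest medoid slot, then lowest candidate index),
// so the result is deterministic given the initial medoids.
// [[Rcpp::export]]
List pam_fit(NumericMatrix d, int k, IntegerVector init_medoids, bool build,
             int max_iter = 1000) {
  const int n = d.nrow();
  if (k < 1 || k > n) stop("k must be in 1..n");

  std::vector<int> med;
  if (build) {
    med = build_phase(d, k);
  } else {
    if (init_medoids.size() != k) stop("init_medoids must have length k");
    med.resize(k);
    for (int j = 0; j < k; ++j) med[j] = init_medoids[j] - 1;  // to 0-based
    std::sort(med.begin(), med.end());
  }

  std::vector<int> assign(n);
  double cur = medoid_cost(d, med, &assign);
  int iter = 0;
  std::vector<double> trace;
  trace.push_back(cur);

  while (iter++ < max_iter) {
    double bestcost = cur;
    int best_slot = -1, best_h = -1;
    for (int slot = 0; slot < k; ++slot) {
      for (int h = 0; h < n; ++h) {
        bool ismed = false;
        for (int j = 0; j < k; ++j) if (med[j] == h) { ismed = true; break; }
        if (ismed) continue;
        std::vector<int> cand = med;
        cand[slot] = h;
        std::sort(cand.begin(), cand.end());
        const double c = medoid_cost(d, cand, nullptr);
        if (c < bestcost) { bestcost = c; best_slot = slot; best_h = h; }
      }
    }
    if (best_slot < 0) break;
    med[best_slot] = best_h;
    std::sort(med.begin(), med.end());
    cur = bestcost;
    trace.push_back(cur);
  }

  cur = medoid_cost(d, med, &assign);
  // a medoid always belongs to its own cluster, even when another medoid
  // sits at dissimilarity zero
  for (int j = 0; j < k; ++j) assign[med[j]] = j;

  IntegerVector med_out(k), asg_out(n);
  for (int j = 0; j < k; ++j) med_out[j] = med[j] + 1;
  for (int i = 0; i < n; ++i) asg_out[i] = assign[i] + 1;
  return List::create(_["medoids"] = med_out, _["assignment"] = asg_out,
                      _["objective"] = cur,
                      _["objective_trace"] = NumericVector(trace.begin(), trace.end()));
}
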