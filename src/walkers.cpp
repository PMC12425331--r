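#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Draw the next node from row `cur` of the transition matrix M, excluding up
// to two forbidden nodes (non-backtracking constraints). Returns -1 when the
// excluded set leaves no probability mass, so the caller can relax the
// constraint (deadlock escape at leaves).
static int draw_next(const NumericMatrix& M, int cur, int forbid1, int forbid2) {
  const int N = M.ncol();
  double tot = 0.0;
  for (int k = 0; k < N; ++k) {
    if (k == forbid1 || k == forbid2) continue;
    tot += M(cur, k);
  }
  if (tot <= 0.0) return -1;
  double u = unif_rand() * tot;
  double acc = 0.0;
  int last = -1;
  for (int k = 0; k < N; ++k) {
    if (k == forbid1 || k == forbid2) continue;
    double p = M(cur, k);
    if (p <= 0.0) continue;
    last = k;
    acc += p;
    if (u <= acc) return k;
  }
  return last; // guard against rounding at u ~ tot
}

static int step_walker(const NumericMatrix& M, int cur, int prev, int prev2,
                       int order) {
  int nxt = -1;
  if (order >= 3) nxt = draw_next(M, cur, prev, prev2);
  if (nxt < 0 && order >= 2) nxt = draw_next(M, cur, prev, -1);
  if (nxt < 0) nxt = draw_next(M, cur, -1, -1);
  return nxt;
}

// Per-row cumulative transition probabilities for fast order-1 stepping
// (binary search on the cumulative row).
static std::vector<double> row_cumsums(const NumericMatrix& M) {
  const int N = M.ncol();
  std::vector<double> cum((size_t)N * N);
  for (int i = 0; i < N; ++i) {
    double acc = 0.0;
    for (int k = 0; k < N; ++k) {
      acc += M(i, k);
      cum[(size_t)i * N + k] = acc;
    }
  }
  return cum;
}

static inline int step_order1(const std::vector<double>& cum, int N,
                              int cur) {
  const double* row = &cum[(size_t)cur * N];
  double u = unif_rand() * row[N - 1];
  int k = (int)(std::upper_bound(row, row + N, u) - row);
  if (k >= N) k = N - 1;
  return k;
}

// Simulate n_walks first-passage walks source -> target on the chain M.
// order 1: plain Markov chain; order 2: never immediately backtrack; order 3:
// additionally avoid the node visited two steps ago. Walks exceeding
// max_steps are returned as NA (capped), never silently truncated.
// [[Rcpp::export]]
NumericVector walk_hitting_cpp(NumericMatrix M, int source, int target,
                               int n_walks, int order, double max_steps) {
  NumericVector out(n_walks);
  const int N = M.ncol();
  std::vector<double> cum;
  if (order == 1) cum = row_cumsums(M);
  for (int w = 0; w < n_walks; ++w) {
    int cur = source, prev = -1, prev2 = -1;
    double steps = 0.0;
    bool capped = false;
    while (cur != target) {
      int nxt;
      if (order == 1) {
        nxt = step_order1(cum, N, cur);
      } else {
        nxt = step_walker(M, cur, prev, prev2, order);
        prev2 = prev;
        prev = cur;
      }
      cur = nxt;
      steps += 1.0;
      if (steps > max_steps) { capped = true; break; }
    }
    out[w] = capped ? NA_REAL : steps;
  }
  return out;
}

// Round-trip walks i -> j -> i; the walker's memory carries through the
// turnaround so higher-order constraints stay in force.
// [[Rcpp::export]]
NumericVector walk_commute_cpp(NumericMatrix M, int source, int target,
                               int n_walks, int order, double max_steps) {
  NumericVector out(n_walks);
  const int N = M.ncol();
  std::vector<double> cum;
  if (order == 1) cum = row_cumsums(M);
  for (int w = 0; w < n_walks; ++w) {
    int cur = source, prev = -1, prev2 = -1;
    int goal = target;
    double steps = 0.0;
    bool capped = false, returning = false;
    while (true) {
      if (cur == goal) {
        if (returning) break;
        returning = true;
        goal = source;
        continue;
      }
      int nxt;
      if (order == 1) {
        nxt = step_order1(cum, N, cur);
      } else {
        nxt = step_walker(M, cur, prev, prev2, order);
        prev2 = prev;
        prev = cur;
      }
      cur = nxt;
      steps += 1.0;
      if (steps > max_steps) { capped = true; break; }
    }
    out[w] = capped ? NA_REAL : steps;
  }
  return out;
}

// Mean-field Ising dynamics on a weighted adjacency A (zero diagonal).
// Energy convention E = -lambda * sum_ij A_ij s_i s_j (both orderings
// counted), so flipping spin i costs dE = 4 * lambda * s_i * h_i with local
// field h_i = sum_j A_ij s_j. Each timestep proposes ceil(flip_fraction * N)
// distinct spins and applies sequential single-flip Metropolis updates; one
// frame is recorded per timestep.
// [[Rcpp::export]]
List ising_run_cpp(NumericMatrix A, double lambda, int n_steps,
                   double flip_fraction) {
  const int N = A.ncol();
  std::vector<int> s(N);
  for (int i = 0; i < N; ++i) s[i] = (unif_rand() < 0.5) ? 1 : -1;

  std::vector<double> h(N, 0.0);
  for (int i = 0; i < N; ++i) {
    double acc = 0.0;
    for (int j = 0; j < N; ++j) acc += A(i, j) * s[j];
    h[i] = acc;
  }
  double E = 0.0;
  for (int i = 0; i < N; ++i) E -= lambda * s[i] * h[i];

  int m = (int)std::ceil(flip_fraction * N);
  if (m < 1) m = 1;
  if (m > N) m = N;

  IntegerMatrix spins(n_steps, N);
  NumericVector energy(n_steps);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  for (int t = 0; t < n_steps; ++t) {
    // partial Fisher-Yates: m distinct proposal sites
    for (int r = 0; r < m; ++r) {
      int j = r + (int)(unif_rand() * (N - r));
      if (j >= N) j = N - 1;
      std::swap(idx[r], idx[j]);
    }
    for (int r = 0; r < m; ++r) {
      int i = idx[r];
      double dE = 4.0 * lambda * s[i] * h[i];
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
        s[i] = -s[i];
        double delta = 2.0 * s[i]; // s_new - s_old
        for (int j = 0; j < N; ++j) h[j] += A(j, i) * delta;
        E += dE;
      }
    }
    for (int j = 0; j < N; ++j) spins(t, j) = s[j];
    energy[t] = E;
  }
  return List::create(_["spins"] = spins, _["energy"] = energy);
}
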