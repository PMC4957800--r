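// Exact stochastic simulation (Gillespie direct method) for mass-action
// networks up to bimolecular, with optional time-dependent rate modifiers
// handled by thinning against per-reaction upper bounds.
//
// Uses R's RNG so that set.seed() on the R side gives byte-for-byte
// reproducible trajectories.

#include <Rcpp.h>
using namespace Rcpp;

static inline double propensity(const std::vector<double>& n, int r,
                                const NumericVector& k,
                                const IntegerVector& order,
                                const IntegerVector& i1,
                                const IntegerVector& i2,
                                const NumericVector& omega_r) {
  switch (order[r]) {
  case 0:
    return k[r] * omega_r[r];
  case 1:
    return k[r] * n[i1[r]];
  default:
    if (i1[r] == i2[r]) {
      double x = n[i1[r]];
      return x > 1.0 ? k[r] * x * (x - 1.0) / omega_r[r] : 0.0;
    }
    return k[r] * n[i1[r]] * n[i2[r]] / omega_r[r];
  }
}

// Simulate one cell from (t0, n) to t_end in place. Returns false if the
// event cap was hit.
static bool advance(std::vector<double>& n, double& t, double t_end,
                    const IntegerMatrix& nu, const NumericVector& k,
                    const IntegerVector& order, const IntegerVector& i1,
                    const IntegerVector& i2, const NumericVector& omega_r,
                    bool has_input, const IntegerVector& input_idx,
                    const NumericVector& input_bound, Function input_eval,
                    long long& events, long long max_events) {
  const int R = k.size();
  const int M = nu.nrow();
  std::vector<double> a(R);
  while (t < t_end) {
    double atot = 0.0;
    for (int r = 0; r < R; ++r) {
      double ar = propensity(n, r, k, order, i1, i2, omega_r);
      // thinning: propose with the bounded rate a_r * B_r
      if (has_input && input_idx[r] > 0) ar *= input_bound[r];
      a[r] = ar;
      atot += ar;
    }
    if (atot <= 0.0) { t = t_end; break; }
    t += R::exp_rand() / atot;
    if (t >= t_end) { t = t_end; break; }
    double u = unif_rand() * atot;
    int r = 0;
    double acc = a[0];
    while (u > acc && r < R - 1) acc += a[++r];
    if (has_input && input_idx[r] > 0) {
      // accept with probability u_r(t) / bound_r
      NumericVector uval = input_eval(t);
      double p = uval[input_idx[r] - 1] / input_bound[r];
      if (unif_rand() >= p) {
        if (++events > max_events) return false;
        continue;
      }
    }
    for (int i = 0; i < M; ++i) n[i] += nu(i, r);
    if (++events > max_events) return false;
  }
  return true;
}

// [[Rcpp::export]]
List ssa_path_cpp(IntegerMatrix nu, NumericVector n0, double t0, double t_end,
                  NumericVector k, IntegerVector order, IntegerVector i1,
                  IntegerVector i2, NumericVector omega_r, bool has_input,
                  IntegerVector input_idx, NumericVector input_bound,
                  Function input_eval, double max_events) {
  const int R = k.size();
  const int M = nu.nrow();
  std::vector<double> n(n0.begin(), n0.end());
  std::vector<double> times;
  std::vector<double> states;
  double t = t0;
  times.push_back(t);
  for (int i = 0; i < M; ++i) states.push_back(n[i]);
  std::vector<double> a(R);
  long long events = 0;
  long long cap = (long long) max_events;
  while (t < t_end) {
    double atot = 0.0;
    for (int r = 0; r < R; ++r) {
      double ar = propensity(n, r, k, order, i1, i2, omega_r);
      if (has_input && input_idx[r] > 0) ar *= input_bound[r];
      a[r] = ar;
      atot += ar;
    }
    if (atot <= 0.0) break;
    double tnew = t + R::exp_rand() / atot;
    if (tnew >= t_end) break;
    t = tnew;
    double u = unif_rand() * atot;
    int r = 0;
    double acc = a[0];
    while (u > acc && r < R - 1) acc += a[++r];
    if (has_input && input_idx[r] > 0) {
      NumericVector uval = input_eval(t);
      double p = uval[input_idx[r] - 1] / input_bound[r];
      if (unif_rand() >= p) {
        if (++events > cap) stop("SSA event cap exceeded");
        continue;
      }
    }
    for (int i = 0; i < M; ++i) n[i] += nu(i, r);
    times.push_back(t);
    for (int i = 0; i < M; ++i) states.push_back(n[i]);
    if (++events > cap) stop("SSA event cap exceeded");
  }
  int T = times.size();
  NumericMatrix st(T, M);
  for (int q = 0; q < T; ++q)
    for (int i = 0; i < M; ++i) st(q, i) = states[(size_t) q * M + i];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = st);
}

// Snapshot ensemble: for each timepoint t_k, simulate n_cells[k] fresh,
// independent cells from t0 with initial counts drawn by init_draw (or the
// fixed counts n0) and record the state at t_k.
// [[Rcpp::export]]
List ssa_snapshot_cpp(IntegerMatrix nu, NumericVector n0, double t0,
                      NumericVector t_points, IntegerVector n_cells,
                      NumericVector k, IntegerVector order, IntegerVector i1,
                      IntegerVector i2, NumericVector omega_r, bool has_input,
                      IntegerVector input_idx, NumericVector input_bound,
                      Function input_eval, bool random_init,
                      Function init_draw, double max_events) {
  const int M = nu.nrow();
  const int K = t_points.size();
  List out(K);
  long long cap = (long long) max_events;
  for (int kk = 0; kk < K; ++kk) {
    int N = n_cells[kk];
    NumericMatrix snap(N, M);
    for (int j = 0; j < N; ++j) {
      std::vector<double> n(M);
      if (random_init) {
        NumericVector nd = init_draw();
        for (int i = 0; i < M; ++i) n[i] = nd[i];
      } else {
        for (int i = 0; i < M; ++i) n[i] = n0[i];
      }
      double t = t0;
      long long events = 0;
      if (!advance(n, t, t_points[kk], nu, k, order, i1, i2, omega_r,
                   has_input, input_idx, input_bound, input_eval, events,
                   cap)) {
        stop("SSA event cap exceeded at t=%f (cell %d)", t_points[kk], j + 1);
      }
      for (int i = 0; i < M; ++i) snap(j, i) = n[i];
    }
    out[kk] = snap;
  }
  return out;
}
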