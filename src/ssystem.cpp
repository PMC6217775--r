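// Core numerics for S-system models: power-law rate evaluation, an adaptive
// Cash-Karp Runge-Kutta integrator, and batched objective evaluation used by
// the optimizers. Kept in C++ because the metaheuristics evaluate the
// trajectory objective tens of thousands of times per fit.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// States are clipped to this floor inside rate evaluation only: power laws
// with fractional or negative kinetic orders are undefined at x <= 0, and
// optimizer exploration routinely visits parameter regions that would
// otherwise crash the integrator.
static const double STATE_FLOOR = 1e-9;

struct SSModel {
  int N;            // dependent states
  int m;            // independent inputs
  const double *alpha;  // length N
  const double *beta;   // length N
  const double *G;      // N x (N+m), column-major (R layout)
  const double *H;      // N x (N+m), column-major
};

// Sparse view of a model: per equation, only the variables with nonzero
// kinetic order. Rebuilt once per candidate, then reused across every
// integrator stage of that candidate's simulation.
struct SparseModel {
  int N, m;
  const double *alpha, *beta;
  std::vector<int> gj[32], hj[32];
  std::vector<double> gv[32], hv[32];
};

static void compile_model(const SSModel &mod, SparseModel &sp) {
  const int N = mod.N, M = mod.N + mod.m;
  sp.N = N;
  sp.m = mod.m;
  sp.alpha = mod.alpha;
  sp.beta = mod.beta;
  for (int i = 0; i < N; ++i) {
    sp.gj[i].clear(); sp.gv[i].clear();
    sp.hj[i].clear(); sp.hv[i].clear();
    for (int j = 0; j < M; ++j) {
      const double g = mod.G[i + j * N];
      if (g != 0.0) { sp.gj[i].push_back(j); sp.gv[i].push_back(g); }
      const double h = mod.H[i + j * N];
      if (h != 0.0) { sp.hj[i].push_back(j); sp.hv[i].push_back(h); }
    }
  }
}

static inline bool eval_rates_sparse(const SparseModel &sp, const double *state,
                                     const double *inputs, double *out) {
  const int N = sp.N;
  double xc[64];
  for (int j = 0; j < N; ++j) {
    double v = state[j];
    xc[j] = (v > STATE_FLOOR) ? v : STATE_FLOOR;
  }
  for (int j = 0; j < sp.m; ++j) {
    double v = inputs[j];
    xc[N + j] = (v > STATE_FLOOR) ? v : STATE_FLOOR;
  }
  bool ok = true;
  for (int i = 0; i < N; ++i) {
    double prod_g = 1.0, prod_h = 1.0;
    const size_t ng = sp.gj[i].size(), nh = sp.hj[i].size();
    for (size_t t = 0; t < ng; ++t) {
      const double e = sp.gv[i][t];
      const double x = xc[sp.gj[i][t]];
      prod_g *= (e == 1.0) ? x : std::pow(x, e);
    }
    for (size_t t = 0; t < nh; ++t) {
      const double e = sp.hv[i][t];
      const double x = xc[sp.hj[i][t]];
      prod_h *= (e == 1.0) ? x : std::pow(x, e);
    }
    const double d = sp.alpha[i] * prod_g - sp.beta[i] * prod_h;
    out[i] = d;
    if (!std::isfinite(d)) ok = false;
  }
  return ok;
}

// dx_i/dt = alpha_i * prod_j x_j^{g_ij} - beta_i * prod_j x_j^{h_ij},
// the product running over all N+m variables (states then constant inputs).
static inline bool eval_rates(const SSModel &mod, const double *state,
                              const double *inputs, double *out) {
  const int N = mod.N, M = mod.N + mod.m;
  double xc[64];
  for (int j = 0; j < N; ++j) {
    double v = state[j];
    xc[j] = (v > STATE_FLOOR) ? v : STATE_FLOOR;
  }
  for (int j = 0; j < mod.m; ++j) {
    double v = inputs[j];
    xc[N + j] = (v > STATE_FLOOR) ? v : STATE_FLOOR;
  }
  bool ok = true;
  for (int i = 0; i < N; ++i) {
    double prod_g = 1.0, prod_h = 1.0;
    for (int j = 0; j < M; ++j) {
      const double g = mod.G[i + j * N];
      if (g != 0.0) prod_g *= (g == 1.0) ? xc[j] : std::pow(xc[j], g);
      const double h = mod.H[i + j * N];
      if (h != 0.0) prod_h *= (h == 1.0) ? xc[j] : std::pow(xc[j], h);
    }
    const double d = mod.alpha[i] * prod_g - mod.beta[i] * prod_h;
    out[i] = d;
    if (!std::isfinite(d)) ok = false;
  }
  return ok;
}

// [[Rcpp::export(name = ".cpp_ss_rates")]]
NumericVector cpp_ss_rates(NumericVector alpha, NumericVector beta,
                           NumericMatrix G, NumericMatrix H,
                           NumericVector state, NumericVector inputs) {
  SSModel mod;
  mod.N = alpha.size();
  mod.m = inputs.size();
  mod.alpha = alpha.begin();
  mod.beta = beta.begin();
  mod.G = G.begin();
  mod.H = H.begin();
  NumericVector out(mod.N);
  eval_rates(mod, state.begin(), inputs.begin(), out.begin());
  return out;  // finiteness checked on the R side
}

// Cash-Karp embedded Runge-Kutta 4(5) coefficients.
static const double CK_A[6] = {0.0, 1.0 / 5, 3.0 / 10, 3.0 / 5, 1.0, 7.0 / 8};
static const double CK_B[6][5] = {
    {0, 0, 0, 0, 0},
    {1.0 / 5, 0, 0, 0, 0},
    {3.0 / 40, 9.0 / 40, 0, 0, 0},
    {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
    {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
    {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592,
     253.0 / 4096}};
static const double CK_C[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0,
                               512.0 / 1771};
static const double CK_DC[6] = {
    37.0 / 378 - 2825.0 / 27648,  0,
    250.0 / 621 - 18575.0 / 48384, 125.0 / 594 - 13525.0 / 55296,
    -277.0 / 14336,               512.0 / 1771 - 1.0 / 4};

// Integrate from t0 to t1 in place; returns false on step-size collapse or a
// non-finite rate. `h_guess` carries the step size across output intervals.
static bool advance(const SparseModel &mod, const double *inputs, double *x,
                    double t0, double t1, double rtol, double atol,
                    double &h_guess, long max_steps) {
  const int N = mod.N;
  double k[6][32], xt[32], xerr[32], xnew[32];
  double t = t0;
  const double span = t1 - t0;
  if (span <= 0) return true;
  double h = (h_guess > 0 && h_guess < span) ? h_guess : span;
  const double hmin = span * 1e-12 + 1e-14;
  long steps = 0;
  while (t < t1) {
    if (++steps > max_steps) return false;
    if (t + h > t1) h = t1 - t;
    // six stages
    if (!eval_rates_sparse(mod, x, inputs, k[0])) return false;
    bool stage_ok = true;
    for (int s = 1; s < 6 && stage_ok; ++s) {
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int p = 0; p < s; ++p) acc += CK_B[s][p] * k[p][i];
        xt[i] = x[i] + h * acc;
      }
      stage_ok = eval_rates_sparse(mod, xt, inputs, k[s]);
    }
    if (!stage_ok) return false;
    double errmax = 0.0;
    for (int i = 0; i < N; ++i) {
      double acc = 0.0, eacc = 0.0;
      for (int s = 0; s < 6; ++s) {
        acc += CK_C[s] * k[s][i];
        eacc += CK_DC[s] * k[s][i];
      }
      xnew[i] = x[i] + h * acc;
      xerr[i] = h * eacc;
      const double sk = atol + rtol * std::max(std::fabs(x[i]), std::fabs(xnew[i]));
      const double e = std::fabs(xerr[i]) / sk;
      if (e > errmax) errmax = e;
      if (!std::isfinite(xnew[i])) errmax = 1e10;
    }
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < N; ++i) x[i] = xnew[i];
      double fac = (errmax > 0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < hmin) return false;
    }
  }
  h_guess = h;
  return true;
}

// Integrate the model from x0 over `times` (strictly increasing, first entry
// is the initial time). Returns the sample matrix plus a success flag and the
// index of the last completed row (1-based) for the failure-tolerant callers.
// [[Rcpp::export(name = ".cpp_ss_simulate")]]
List cpp_ss_simulate(NumericVector alpha, NumericVector beta, NumericMatrix G,
                     NumericMatrix H, NumericVector x0, NumericVector inputs,
                     NumericVector times, double rtol, double atol,
                     long max_steps) {
  SSModel mod;
  mod.N = alpha.size();
  mod.m = inputs.size();
  mod.alpha = alpha.begin();
  mod.beta = beta.begin();
  mod.G = G.begin();
  mod.H = H.begin();
  SparseModel sp;
  compile_model(mod, sp);
  const int nt = times.size(), N = mod.N;
  NumericMatrix states(nt, N);
  std::fill(states.begin(), states.end(), NA_REAL);
  double x[32];
  for (int i = 0; i < N; ++i) {
    x[i] = x0[i];
    states(0, i) = x0[i];
  }
  double h_guess = -1.0;
  int last = 1;
  bool ok = true;
  for (int r = 1; r < nt; ++r) {
    if (!advance(sp, inputs.begin(), x, times[r - 1], times[r], rtol, atol,
                 h_guess, max_steps)) {
      ok = false;
      break;
    }
    for (int i = 0; i < N; ++i) states(r, i) = x[i];
    last = r + 1;
  }
  return List::create(_["states"] = states, _["success"] = ok,
                      _["last_row"] = last);
}

// Overwrite the flat template at free_idx (0-based, layout
// c(alpha, beta, G, H) column-major) with one candidate parameter vector.
static void decode_into(const NumericVector &tmpl, const IntegerVector &free_idx,
                        const double *cand, std::vector<double> &theta) {
  std::copy(tmpl.begin(), tmpl.end(), theta.begin());
  for (int j = 0; j < free_idx.size(); ++j) theta[free_idx[j]] = cand[j];
}

static SSModel model_view(const std::vector<double> &theta, int N, int m) {
  SSModel mod;
  mod.N = N;
  mod.m = m;
  mod.alpha = theta.data();
  mod.beta = theta.data() + N;
  mod.G = theta.data() + 2 * N;
  mod.H = theta.data() + 2 * N + N * (N + m);
  return mod;
}

// Trajectory RMSE objective for a batch of candidate parameter vectors
// (rows of P). Simulation failure maps to `penalty`. `normalized` selects
// sqrt(mean sq) over sqrt(sum sq).
// [[Rcpp::export(name = ".cpp_fitness_batch")]]
NumericVector cpp_fitness_batch(NumericMatrix P, IntegerVector free_idx,
                                NumericVector tmpl, int N, int m,
                                NumericMatrix data, NumericVector times,
                                NumericVector x0, NumericVector inputs,
                                double rtol, double atol, long max_steps,
                                double penalty, bool normalized) {
  const int n_cand = P.nrow(), nt = times.size();
  NumericVector out(n_cand);
  std::vector<double> theta(tmpl.size());
  std::vector<double> cand(P.ncol());
  SparseModel sp;
  double x[32];
  for (int c = 0; c < n_cand; ++c) {
    for (int j = 0; j < P.ncol(); ++j) cand[j] = P(c, j);
    decode_into(tmpl, free_idx, cand.data(), theta);
    SSModel mod = model_view(theta, N, m);
    compile_model(mod, sp);
    double sq = 0.0;
    bool ok = true;
    for (int i = 0; i < N; ++i) {
      x[i] = x0[i];
      const double d = x0[i] - data(0, i);
      sq += d * d;
    }
    double h_guess = -1.0;
    for (int r = 1; r < nt && ok; ++r) {
      ok = advance(sp, inputs.begin(), x, times[r - 1], times[r], rtol, atol,
                   h_guess, max_steps);
      if (ok) {
        for (int i = 0; i < N; ++i) {
          const double d = x[i] - data(r, i);
          sq += d * d;
          if (!std::isfinite(d)) ok = false;
        }
      }
    }
    if (!ok || !std::isfinite(sq)) {
      out[c] = penalty;
    } else {
      out[c] = normalized ? std::sqrt(sq / (double)(nt * N)) : std::sqrt(sq);
    }
  }
  return out;
}

// One-step-ahead state prediction for a batch of parameter vectors: start
// every candidate at x_from and integrate a single interval [t0, t1]. Used by
// the sigma-point measurement map of the UKF. Failed propagations return
// NA rows with ok = FALSE.
// [[Rcpp::export(name = ".cpp_predict_batch")]]
List cpp_predict_batch(NumericMatrix P, IntegerVector free_idx,
                       NumericVector tmpl, int N, int m, NumericVector x_from,
                       NumericVector inputs, double t0, double t1, double rtol,
                       double atol, long max_steps) {
  const int n_cand = P.nrow();
  NumericMatrix pred(n_cand, N);
  LogicalVector ok(n_cand);
  std::vector<double> theta(tmpl.size());
  std::vector<double> cand(P.ncol());
  SparseModel sp;
  double x[32];
  for (int c = 0; c < n_cand; ++c) {
    for (int j = 0; j < P.ncol(); ++j) cand[j] = P(c, j);
    decode_into(tmpl, free_idx, cand.data(), theta);
    SSModel mod = model_view(theta, N, m);
    compile_model(mod, sp);
    for (int i = 0; i < N; ++i) x[i] = x_from[i];
    double h_guess = -1.0;
    bool good = advance(sp, inputs.begin(), x, t0, t1, rtol, atol, h_guess,
                        max_steps);
    if (good) {
      for (int i = 0; i < N; ++i) {
        pred(c, i) = x[i];
        if (!std::isfinite(x[i])) good = false;
      }
    }
    if (!good)
      for (int i = 0; i < N; ++i) pred(c, i) = NA_REAL;
    ok[c] = good;
  }
  return List::create(_["pred"] = pred, _["ok"] = ok);
}
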