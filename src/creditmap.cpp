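#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Parameter layout (shared with R/model.R):
//   0-3  c_mf  [Common, Exclusive, Counterfactual, Absent]
//   4-7  c_mb  [Common, Exclusive, Counterfactual, Absent]
//   8    f_mf   9  f_mb   10  pr   11  f_p
// Persons and vegetables are 0-based indices; `grows` maps person -> 2 vegs.

namespace {

struct Roles {
  int common, exclusive, counter, absent;
};

// Classify the 4 vegetables given offered persons a, b and the chosen person.
inline Roles classify(const int grows[4][2], int a, int b, int chosen) {
  bool in_a[4] = {false, false, false, false};
  bool in_b[4] = {false, false, false, false};
  in_a[grows[a][0]] = in_a[grows[a][1]] = true;
  in_b[grows[b][0]] = in_b[grows[b][1]] = true;
  Roles r = {-1, -1, -1, -1};
  for (int v = 0; v < 4; ++v) {
    bool in_ch = (chosen == a) ? in_a[v] : in_b[v];
    bool in_un = (chosen == a) ? in_b[v] : in_a[v];
    if (in_ch && in_un) r.common = v;
    else if (in_ch) r.exclusive = v;
    else if (in_un) r.counter = v;
    else r.absent = v;
  }
  return r;
}

inline void zero(double* x, int n) { for (int i = 0; i < n; ++i) x[i] = 0.0; }

// One session (or stacked sessions) of trial data for likelihood evaluation.
struct TrialData {
  int n;
  int grows[4][2];
  const int *left, *right, *chosen, *reset;
  const int *rewards; // n x 4, column-major (+1/-1)
};

// log-likelihood of the hybrid agent (Eqs. of the model); fills grad12 with
// the analytic gradient when non-null
double loglik_core(const double par[12], const TrialData& d, double* grad12) {
  const double* cmf = par;
  const double* cmb = par + 4;
  const double fmf = par[8], fmb = par[9], pr = par[10], fp = par[11];
  double qmf[4], qmb[4], pers[4];
  double dqmf[4][12], dqmb[4][12], dpers[4][12];
  const bool wg = grad12 != nullptr;
  zero(qmf, 4); zero(qmb, 4); zero(pers, 4);
  if (wg) {
    zero(grad12, 12);
    for (int p = 0; p < 4; ++p) {
      zero(dqmf[p], 12); zero(dqmb[p], 12); zero(dpers[p], 12);
    }
  }
  double ll = 0.0;
  for (int t = 0; t < d.n; ++t) {
    if (d.reset[t]) {
      zero(qmf, 4); zero(qmb, 4); zero(pers, 4);
      if (wg) for (int p = 0; p < 4; ++p) {
        zero(dqmf[p], 12); zero(dqmb[p], 12); zero(dpers[p], 12);
      }
    }
    const int a = d.left[t], b = d.right[t], ch = d.chosen[t];
    const int un = (ch == a) ? b : a;
    const double qa = qmf[a] + qmb[d.grows[a][0]] + qmb[d.grows[a][1]] + pers[a];
    const double qb = qmf[b] + qmb[d.grows[b][0]] + qmb[d.grows[b][1]] + pers[b];
    const double diff = (ch == a) ? qa - qb : qb - qa;
    ll += (diff > 0) ? -log1p(std::exp(-diff)) : diff - log1p(std::exp(diff));

    Roles r = classify(d.grows, a, b, ch);
    const int veg_of_role[4] = {r.common, r.exclusive, r.counter, r.absent};
    double rw[4];
    for (int ty = 0; ty < 4; ++ty)
      rw[ty] = (double)d.rewards[veg_of_role[ty] * d.n + t];

    if (wg) {
      const double w = 1.0 / (1.0 + std::exp(diff)); // 1 - P(chosen)
      for (int k = 0; k < 12; ++k) {
        const double dch = dqmf[ch][k] + dqmb[d.grows[ch][0]][k] +
                           dqmb[d.grows[ch][1]][k] + dpers[ch][k];
        const double dun = dqmf[un][k] + dqmb[d.grows[un][0]][k] +
                           dqmb[d.grows[un][1]][k] + dpers[un][k];
        grad12[k] += w * (dch - dun);
      }
      for (int p = 0; p < 4; ++p) {
        const double qold = qmf[p], pold = pers[p];
        for (int k = 0; k < 12; ++k) {
          dqmf[p][k] *= (1.0 - fmf);
          dpers[p][k] *= (1.0 - fp);
        }
        dqmf[p][8] -= qold;
        dpers[p][11] -= pold;
        if (p == ch) {
          for (int ty = 0; ty < 4; ++ty) dqmf[p][ty] += rw[ty];
          dpers[p][10] += 1.0;
        }
      }
      for (int ty = 0; ty < 4; ++ty) {
        const int v = veg_of_role[ty];
        const double qold = qmb[v];
        for (int k = 0; k < 12; ++k) dqmb[v][k] *= (1.0 - fmb);
        dqmb[v][9] -= qold;
        dqmb[v][4 + ty] += rw[ty];
      }
    }

    double gain = 0.0;
    for (int ty = 0; ty < 4; ++ty) gain += cmf[ty] * rw[ty];
    for (int p = 0; p < 4; ++p) {
      qmf[p] *= (1.0 - fmf);
      pers[p] *= (1.0 - fp);
    }
    qmf[ch] += gain;
    pers[ch] += pr;
    for (int ty = 0; ty < 4; ++ty) {
      const int v = veg_of_role[ty];
      qmb[v] = (1.0 - fmb) * qmb[v] + cmb[ty] * rw[ty];
    }
  }
  return ll;
}

inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Objective over a model spec's free parameters, on the optimizer scale
// (forgetting coordinates logit-transformed): returns the negative
// log-likelihood; fills gfree (length k) when non-null.
struct SpecObjective {
  const TrialData* d;
  int k;
  const double* M;      // 12 x k, column-major embedding
  const int* islogit;   // k
  int nevals = 0;

  double eval(const double* x, double* gfree) {
    std::vector<double> nat(k), p12(12, 0.0);
    for (int j = 0; j < k; ++j)
      nat[j] = islogit[j] ? logistic(x[j]) : x[j];
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < 12; ++i) p12[i] += M[j * 12 + i] * nat[j];
    double g12[12];
    double ll = loglik_core(p12.data(), *d, gfree ? g12 : nullptr);
    if (gfree) {
      for (int j = 0; j < k; ++j) {
        double s = 0.0;
        for (int i = 0; i < 12; ++i) s += M[j * 12 + i] * g12[i];
        if (islogit[j]) s *= nat[j] * (1.0 - nat[j]);
        gfree[j] = -s;
      }
    }
    ++nevals;
    return -ll;
  }
};

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Projected L-BFGS (memory 6) with Armijo backtracking along the projected
// arc; falls back to projected steepest descent when the quasi-Newton
// direction fails. Box bounds via clamping.
struct OptResult {
  std::vector<double> x;
  double f;
  int converged;
};

OptResult lbfgs_box(SpecObjective& obj, const std::vector<double>& x0,
                    const double* lower, const double* upper,
                    int maxit = 300, double gtol = 1e-6, double ftol = 1e-9) {
  const int k = obj.k, m = 6;
  std::vector<double> x(x0), g(k), xn(k), gn(k), d(k);
  std::vector<std::vector<double>> S, Y;
  std::vector<double> rho;
  double f = obj.eval(x.data(), g.data());
  int converged = 0;

  for (int it = 0; it < maxit; ++it) {
    // projected gradient convergence check
    double pg = 0.0;
    for (int j = 0; j < k; ++j) {
      double step = clampd(x[j] - g[j], lower[j], upper[j]) - x[j];
      pg = std::max(pg, std::fabs(step));
    }
    if (pg < gtol) { converged = 1; break; }

    // two-loop recursion
    for (int j = 0; j < k; ++j) d[j] = -g[j];
    const int hm = (int)S.size();
    std::vector<double> alpha(hm);
    for (int i = hm - 1; i >= 0; --i) {
      double sd = 0.0;
      for (int j = 0; j < k; ++j) sd += S[i][j] * d[j];
      alpha[i] = rho[i] * sd;
      for (int j = 0; j < k; ++j) d[j] -= alpha[i] * Y[i][j];
    }
    if (hm > 0) {
      double yy = 0.0, sy = 0.0;
      for (int j = 0; j < k; ++j) {
        yy += Y[hm - 1][j] * Y[hm - 1][j];
        sy += S[hm - 1][j] * Y[hm - 1][j];
      }
      const double gamma = sy / std::max(yy, 1e-300);
      for (int j = 0; j < k; ++j) d[j] *= gamma;
    }
    for (int i = 0; i < hm; ++i) {
      double yd = 0.0;
      for (int j = 0; j < k; ++j) yd += Y[i][j] * d[j];
      const double beta = rho[i] * yd;
      for (int j = 0; j < k; ++j) d[j] += (alpha[i] - beta) * S[i][j];
    }

    bool ok = false;
    for (int attempt = 0; attempt < 2 && !ok; ++attempt) {
      if (attempt == 1)               // steepest-descent fallback
        for (int j = 0; j < k; ++j) d[j] = -g[j];
      double step = 1.0;
      for (int ls = 0; ls < 40; ++ls, step *= 0.5) {
        double gdx = 0.0;
        for (int j = 0; j < k; ++j) {
          xn[j] = clampd(x[j] + step * d[j], lower[j], upper[j]);
          gdx += g[j] * (xn[j] - x[j]);
        }
        if (gdx > -1e-16) continue;   // not a descent step after projection
        const double fn = obj.eval(xn.data(), gn.data());
        if (fn <= f + 1e-4 * gdx) {
          // curvature update
          std::vector<double> s(k), y(k);
          double sy = 0.0;
          for (int j = 0; j < k; ++j) {
            s[j] = xn[j] - x[j];
            y[j] = gn[j] - g[j];
            sy += s[j] * y[j];
          }
          if (sy > 1e-10) {
            if ((int)S.size() == m) {
              S.erase(S.begin()); Y.erase(Y.begin()); rho.erase(rho.begin());
            }
            S.push_back(s); Y.push_back(y); rho.push_back(1.0 / sy);
          }
          const double df = f - fn;
          x = xn; g = gn; f = fn;
          ok = true;
          if (df < ftol * (std::fabs(f) + 1.0)) { converged = 1; it = maxit; }
          break;
        }
      }
    }
    if (!ok) { converged = 1; break; }  // no further descent possible
  }
  return {x, f, converged};
}

TrialData make_trial_data(const IntegerMatrix& grows, const IntegerVector& left,
                          const IntegerVector& right, const IntegerVector& chosen,
                          const IntegerMatrix& rewards, const IntegerVector& reset) {
  TrialData d;
  d.n = left.size();
  for (int p = 0; p < 4; ++p) {
    d.grows[p][0] = grows(p, 0);
    d.grows[p][1] = grows(p, 1);
  }
  d.left = left.begin(); d.right = right.begin(); d.chosen = chosen.begin();
  d.reset = reset.begin(); d.rewards = rewards.begin();
  return d;
}

// simulate agent choices for trials [from, to) of a TrialData-like batch,
// writing chosen and p_left; rewards already laid out column-major
void simulate_core(const double par[12], const int grows[4][2], int n,
                   const int* left, const int* right, const int* rewards,
                   const int* reset, const double* u, int* chosen,
                   double* pleft) {
  const double* cmf = par;
  const double* cmb = par + 4;
  const double fmf = par[8], fmb = par[9], pr = par[10], fp = par[11];
  double qmf[4], qmb[4], pers[4];
  zero(qmf, 4); zero(qmb, 4); zero(pers, 4);
  for (int t = 0; t < n; ++t) {
    if (reset[t]) { zero(qmf, 4); zero(qmb, 4); zero(pers, 4); }
    const int a = left[t], b = right[t];
    const double qa = qmf[a] + qmb[grows[a][0]] + qmb[grows[a][1]] + pers[a];
    const double qb = qmf[b] + qmb[grows[b][0]] + qmb[grows[b][1]] + pers[b];
    const double pl = logistic(qa - qb);
    if (pleft) pleft[t] = pl;
    const int ch = (u[t] < pl) ? a : b;
    chosen[t] = ch;
    Roles r = classify(grows, a, b, ch);
    const int veg_of_role[4] = {r.common, r.exclusive, r.counter, r.absent};
    double rw[4];
    for (int ty = 0; ty < 4; ++ty) rw[ty] = (double)rewards[veg_of_role[ty] * n + t];
    double gain = 0.0;
    for (int ty = 0; ty < 4; ++ty) gain += cmf[ty] * rw[ty];
    for (int p = 0; p < 4; ++p) {
      qmf[p] *= (1.0 - fmf);
      pers[p] *= (1.0 - fp);
    }
    qmf[ch] += gain;
    pers[ch] += pr;
    for (int ty = 0; ty < 4; ++ty) {
      const int v = veg_of_role[ty];
      qmb[v] = (1.0 - fmb) * qmb[v] + cmb[ty] * rw[ty];
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_loglik(NumericVector par, IntegerMatrix grows, IntegerVector left,
                IntegerVector right, IntegerVector chosen,
                IntegerMatrix rewards, IntegerVector reset, bool want_grad) {
  TrialData d = make_trial_data(grows, left, right, chosen, rewards, reset);
  double g12[12];
  const double ll = loglik_core(par.begin(), d, want_grad ? g12 : nullptr);
  List out = List::create(_["loglik"] = ll);
  if (want_grad) out["grad"] = NumericVector(g12, g12 + 12);
  return out;
}

// Multi-start bounded fit of a model spec; starts are rows on the optimizer
// scale. Returns the best start's solution (ties by lowest start index).
// [[Rcpp::export]]
List cpp_fit(NumericMatrix starts, NumericMatrix M, IntegerVector islogit,
             NumericVector lower, NumericVector upper, IntegerMatrix grows,
             IntegerVector left, IntegerVector right, IntegerVector chosen,
             IntegerMatrix rewards, IntegerVector reset, int maxit = 300) {
  TrialData d = make_trial_data(grows, left, right, chosen, rewards, reset);
  const int k = M.ncol();
  SpecObjective obj{&d, k, M.begin(), islogit.begin()};
  double best_f = R_PosInf;
  std::vector<double> best_x(k, 0.0);
  int best_start = -1, best_conv = 0;
  for (int s = 0; s < starts.nrow(); ++s) {
    std::vector<double> x0(k);
    for (int j = 0; j < k; ++j) x0[j] = starts(s, j);
    const double f0 = obj.eval(x0.data(), nullptr);
    OptResult r = lbfgs_box(obj, x0, lower.begin(), upper.begin(), maxit);
    if (!std::isfinite(r.f) || r.f > f0) { r.x = x0; r.f = f0; r.converged = 0; }
    if (r.f < best_f - 1e-9) {
      best_f = r.f; best_x = r.x; best_start = s; best_conv = r.converged;
    }
  }
  return List::create(_["par"] = NumericVector(best_x.begin(), best_x.end()),
                      _["value"] = best_f, _["best_start"] = best_start + 1,
                      _["converged"] = best_conv, _["nevals"] = obj.nevals);
}

namespace {

// Fit sub and full models to one session with fixed shared start sets
// (rows of starts_sub / starts_full, optimizer scale); the full fit is
// additionally seeded at the embedded submodel optimum and floored at the
// submodel likelihood, so the returned 2*(LL_full - LL_sub) is >= 0.
double glrt_pair_core(const TrialData& d, const NumericMatrix& M_sub,
                      const int* islogit_sub, const double* lower_sub,
                      const double* upper_sub, const NumericMatrix& starts_sub,
                      const NumericMatrix& M_full, const int* islogit_full,
                      const double* lower_full, const double* upper_full,
                      const NumericMatrix& starts_full, int maxit,
                      double* sub_free_out) {
  const int k_sub = M_sub.ncol(), k_full = M_full.ncol();
  SpecObjective obj_sub{&d, k_sub, M_sub.begin(), islogit_sub};
  double f_sub = R_PosInf;
  std::vector<double> xs(k_sub), best_sub(k_sub, 0.0);
  for (int s = 0; s < starts_sub.nrow(); ++s) {
    for (int j = 0; j < k_sub; ++j) xs[j] = starts_sub(s, j);
    const double f0 = obj_sub.eval(xs.data(), nullptr);
    OptResult r = lbfgs_box(obj_sub, xs, lower_sub, upper_sub, maxit);
    if (!std::isfinite(r.f) || r.f > f0) { r.x = xs; r.f = f0; }
    if (r.f < f_sub - 1e-9) { f_sub = r.f; best_sub = r.x; }
  }
  if (sub_free_out)
    for (int j = 0; j < k_sub; ++j) sub_free_out[j] = best_sub[j];

  // embed the submodel optimum into the full model's free space
  std::vector<double> nat_sub(k_sub), p12hat(12, 0.0), emb(k_full);
  for (int j = 0; j < k_sub; ++j)
    nat_sub[j] = islogit_sub[j] ? logistic(best_sub[j]) : best_sub[j];
  for (int j = 0; j < k_sub; ++j)
    for (int i = 0; i < 12; ++i) p12hat[i] += M_sub(i, j) * nat_sub[j];
  for (int j = 0; j < k_full; ++j) {
    double num = 0.0, den = 0.0;
    for (int i = 0; i < 12; ++i) {
      num += M_full(i, j) * p12hat[i];
      den += M_full(i, j) * M_full(i, j);
    }
    double v = num / std::max(den, 1e-300);
    if (islogit_full[j]) {
      v = clampd(v, logistic(lower_full[j]) + 1e-12,
                 logistic(upper_full[j]) - 1e-12);
      v = std::log(v / (1.0 - v));
    }
    emb[j] = clampd(v, lower_full[j], upper_full[j]);
  }
  SpecObjective obj_full{&d, k_full, M_full.begin(), islogit_full};
  double f_full = obj_full.eval(emb.data(), nullptr);
  OptResult q = lbfgs_box(obj_full, emb, lower_full, upper_full, maxit);
  if (std::isfinite(q.f)) f_full = std::min(f_full, q.f);
  std::vector<double> xf(k_full);
  for (int s = 0; s < starts_full.nrow(); ++s) {
    for (int j = 0; j < k_full; ++j) xf[j] = starts_full(s, j);
    const double f0 = obj_full.eval(xf.data(), nullptr);
    OptResult r = lbfgs_box(obj_full, xf, lower_full, upper_full, maxit);
    const double fr = (std::isfinite(r.f) && r.f <= f0) ? r.f : f0;
    f_full = std::min(f_full, fr);
  }
  f_full = std::min(f_full, f_sub);     // exact nesting floor
  return 2.0 * (f_sub - f_full);
}

} // namespace

// GLRT statistic for observed sessions, using exactly the shared start sets.
// [[Rcpp::export]]
List cpp_glrt_observed(NumericMatrix M_sub, IntegerVector islogit_sub,
                       NumericVector lower_sub, NumericVector upper_sub,
                       NumericMatrix starts_sub, NumericMatrix M_full,
                       IntegerVector islogit_full, NumericVector lower_full,
                       NumericVector upper_full, NumericMatrix starts_full,
                       IntegerMatrix grows, IntegerVector left,
                       IntegerVector right, IntegerVector chosen,
                       IntegerMatrix rewards, IntegerVector reset,
                       int maxit = 300) {
  TrialData d = make_trial_data(grows, left, right, chosen, rewards, reset);
  NumericVector sub_free(M_sub.ncol());
  const double stat = glrt_pair_core(d, M_sub, islogit_sub.begin(),
                                     lower_sub.begin(), upper_sub.begin(),
                                     starts_sub, M_full, islogit_full.begin(),
                                     lower_full.begin(), upper_full.begin(),
                                     starts_full, maxit, sub_free.begin());
  return List::create(_["statistic"] = stat, _["sub_free"] = sub_free);
}

// Bootstrap-GLRT null statistics: for each stacked replicate session
// (delimited by `offsets`, with `subject` giving the generating-parameter
// row of gen_free, optimizer scale), simulate choices from the subject's
// fitted submodel parameters and compute the GLRT statistic with the same
// start sets used for the observed data.
// [[Rcpp::export]]
NumericVector cpp_glrt_stats(NumericMatrix gen_free, NumericMatrix M_sub,
                             IntegerVector islogit_sub, NumericVector lower_sub,
                             NumericVector upper_sub, NumericMatrix starts_sub,
                             NumericMatrix M_full, IntegerVector islogit_full,
                             NumericVector lower_full, NumericVector upper_full,
                             NumericMatrix starts_full, IntegerMatrix grows,
                             IntegerVector subject, IntegerVector offsets,
                             IntegerVector left, IntegerVector right,
                             IntegerMatrix rewards, IntegerVector reset,
                             NumericVector u, int maxit = 300) {
  const int nsess = subject.size();
  const int k_sub = M_sub.ncol();
  NumericVector stats(nsess);
  std::vector<int> chosen_buf;

  int gr4[4][2];
  for (int p = 0; p < 4; ++p) { gr4[p][0] = grows(p, 0); gr4[p][1] = grows(p, 1); }

  for (int s = 0; s < nsess; ++s) {
    const int from = offsets[s], to = offsets[s + 1];
    const int n = to - from;
    chosen_buf.assign(n, 0);

    // embed the generating free params into the 12-space and simulate
    std::vector<double> nat(k_sub), p12(12, 0.0);
    for (int j = 0; j < k_sub; ++j) {
      const double x = gen_free(subject[s], j);
      nat[j] = islogit_sub[j] ? logistic(x) : x;
    }
    for (int j = 0; j < k_sub; ++j)
      for (int i = 0; i < 12; ++i) p12[i] += M_sub(i, j) * nat[j];

    // column-major reward block for this session
    std::vector<int> rew(n * 4);
    for (int v = 0; v < 4; ++v)
      for (int t = 0; t < n; ++t) rew[v * n + t] = rewards(from + t, v);
    simulate_core(p12.data(), gr4, n, &left[from], &right[from], rew.data(),
                  &reset[from], &u[from], chosen_buf.data(), nullptr);

    TrialData d;
    d.n = n;
    for (int p = 0; p < 4; ++p) { d.grows[p][0] = gr4[p][0]; d.grows[p][1] = gr4[p][1]; }
    d.left = &left[from]; d.right = &right[from]; d.chosen = chosen_buf.data();
    d.reset = &reset[from]; d.rewards = rew.data();

    stats[s] = glrt_pair_core(d, M_sub, islogit_sub.begin(), lower_sub.begin(),
                              upper_sub.begin(), starts_sub, M_full,
                              islogit_full.begin(), lower_full.begin(),
                              upper_full.begin(), starts_full, maxit, nullptr);
  }
  return stats;
}

// Forward-simulate agent choices through (possibly many stacked) sessions.
// `u` holds pre-drawn Uniform(0,1) variates, one per trial; the left person
// is chosen when u < P(left). Rewards are pre-drawn (full feedback: outcomes
// do not depend on the choice). Returns 0-based chosen indices and P(left).
// [[Rcpp::export]]
List cpp_simulate_full(NumericVector par, IntegerMatrix grows,
                       IntegerVector left, IntegerVector right,
                       IntegerMatrix rewards, IntegerVector reset,
                       NumericVector u) {
  const int n = left.size();
  IntegerVector chosen(n);
  NumericVector pl(n);
  int gr4[4][2];
  for (int p = 0; p < 4; ++p) { gr4[p][0] = grows(p, 0); gr4[p][1] = grows(p, 1); }
  // rewards arrive column-major already (IntegerMatrix storage)
  simulate_core(par.begin(), gr4, n, left.begin(), right.begin(),
                rewards.begin(), reset.begin(), u.begin(), chosen.begin(),
                pl.begin());
  return List::create(_["chosen"] = chosen, _["p_left"] = pl);
}
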