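#include <Rcpp.h>
using namespace Rcpp;

// Marginal log-likelihood of a binomial (Bernoulli) GLMM with one random
// intercept per group, integrated by adaptive Gauss-Hermite quadrature.
// For each group the integrand is re-centred at the conditional mode
// (found by Newton steps on the 1-D joint log-density) and scaled by the
// curvature there; with a single node this is exactly the Laplace
// approximation. sigma <= 0 collapses to the plain logistic log-likelihood.

static inline double ll_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return log1p(exp(x));
}

// [[Rcpp::export]]
double glmm_marginal_loglik_cpp(NumericVector beta, double sigma,
                                NumericMatrix X, NumericVector y,
                                IntegerVector group, int ngroups,
                                NumericVector ghx, NumericVector ghw) {
  const int n = X.nrow(), p = X.ncol(), nq = ghx.size();
  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta0[i] = e;
  }

  if (sigma <= 0.0) {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) ll += y[i] * eta0[i] - ll_log1pexp(eta0[i]);
    return ll;
  }

  const double s2 = sigma * sigma;
  std::vector<double> mode(ngroups, 0.0), info(ngroups);

  // Per-group penalised log-density at the current modes.
  auto objective = [&](const std::vector<double>& m, std::vector<double>& f) {
    for (int g = 0; g < ngroups; ++g) f[g] = -0.5 * m[g] * m[g] / s2;
    for (int i = 0; i < n; ++i) {
      int g = group[i];
      double eta = eta0[i] + m[g];
      f[g] += y[i] * eta - ll_log1pexp(eta);
    }
  };

  // Newton with backtracking line search for the conditional modes, all
  // groups in parallel. The objective is strictly concave in each mode,
  // but a raw Newton step can overshoot and cycle where the logistic
  // curvature is flat; halving any non-improving step guarantees
  // monotone convergence.
  std::vector<double> f0(ngroups), f1(ngroups), trial(ngroups),
      step(ngroups);
  objective(mode, f0);
  for (int it = 0; it < 100; ++it) {
    std::vector<double> score(ngroups, 0.0), hess(ngroups, 0.0);
    for (int i = 0; i < n; ++i) {
      int g = group[i];
      double mu = 1.0 / (1.0 + exp(-(eta0[i] + mode[g])));
      score[g] += y[i] - mu;
      hess[g] += mu * (1.0 - mu);
    }
    for (int g = 0; g < ngroups; ++g) {
      double sc = score[g] - mode[g] / s2;
      double h = hess[g] + 1.0 / s2;
      step[g] = sc / h;
      if (step[g] > 10.0) step[g] = 10.0;
      if (step[g] < -10.0) step[g] = -10.0;
      info[g] = h;
    }
    for (int half = 0; half < 60; ++half) {
      for (int g = 0; g < ngroups; ++g) trial[g] = mode[g] + step[g];
      objective(trial, f1);
      bool all_ok = true;
      for (int g = 0; g < ngroups; ++g) {
        if (f1[g] < f0[g] - 1e-12) {
          step[g] *= 0.5;
          all_ok = false;
        }
      }
      if (all_ok) break;
    }
    double worst = 0.0;
    for (int g = 0; g < ngroups; ++g) {
      if (f1[g] >= f0[g] - 1e-12) {
        mode[g] += step[g];
        f0[g] = f1[g];
        worst = std::max(worst, std::fabs(step[g]));
      }
    }
    if (worst < 1e-10) break;
  }

  // Refresh curvature at the final modes.
  {
    std::vector<double> hess(ngroups, 0.0);
    for (int i = 0; i < n; ++i) {
      int g = group[i];
      double mu = 1.0 / (1.0 + exp(-(eta0[i] + mode[g])));
      hess[g] += mu * (1.0 - mu);
    }
    for (int g = 0; g < ngroups; ++g) info[g] = hess[g] + 1.0 / s2;
  }

  // Adaptive quadrature: nodes a_gk = mode_g + sqrt(2/info_g) * x_k.
  // log integrand h(a) = sum_i[y eta - log(1+e^eta)] + log phi(a; 0, s2).
  const double LOG_SQRT_2PI = 0.5 * log(2.0 * M_PI);
  std::vector<double> hval(ngroups * nq);
  for (int k = 0; k < nq; ++k) {
    for (int g = 0; g < ngroups; ++g) {
      double a = mode[g] + sqrt(2.0 / info[g]) * ghx[k];
      hval[g * nq + k] = -0.5 * a * a / s2 - log(sigma) - LOG_SQRT_2PI;
    }
    for (int i = 0; i < n; ++i) {
      int g = group[i];
      double a = mode[g] + sqrt(2.0 / info[g]) * ghx[k];
      double eta = eta0[i] + a;
      hval[g * nq + k] += y[i] * eta - ll_log1pexp(eta);
    }
  }

  double ll = 0.0;
  for (int g = 0; g < ngroups; ++g) {
    double m = -INFINITY;
    for (int k = 0; k < nq; ++k) {
      double v = log(ghw[k]) + ghx[k] * ghx[k] + hval[g * nq + k];
      if (v > m) m = v;
    }
    double s = 0.0;
    for (int k = 0; k < nq; ++k) {
      double v = log(ghw[k]) + ghx[k] * ghx[k] + hval[g * nq + k];
      s += exp(v - m);
    }
    ll += 0.5 * log(2.0 / info[g]) + m + log(s);
  }
  return ll;
}
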