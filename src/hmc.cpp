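// Hamiltonian Monte Carlo for the weighted Bernoulli-logit and
// cumulative-logit sub-models of the generalized SEM. Each sub-model has
// its own parameter block and the joint posterior factorizes, so sampling
// proceeds per sub-model. Static HMC with jittered leapfrog length,
// dual-averaging step-size adaptation (two warmup phases) and a diagonal
// metric estimated from early warmup draws.
//
// Parameter layout (sampling scale):
//   family 0 (Bernoulli-logit): beta[0..p-1], X includes any intercept
//     column; priors indexed per coefficient.
//   family 1 (cumulative-logit, latent shift): theta[0..K-2] raw
//     thresholds with alpha_1 = theta_0, alpha_c = alpha_{c-1} +
//     exp(theta_c); then slopes gamma[0..q-1]. logit P(y <= c) =
//     alpha_c - x'gamma. Priors apply to the natural thresholds alpha
//     (with the log-Jacobian of the ordered transform) and to the slopes.
//
// Prior codes: 0 Cauchy(loc, scale); 1 Student-t(df, loc, scale);
// 2 Normal(loc, scale); 3 flat on [-1000, 1000].

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double FLAT_BOUND = 1000.0;

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double log1pexp_(double x) {
  if (x > 0) return x + std::log1p(std::exp(-x));
  return std::log1p(std::exp(x));
}

// log prior density (unnormalized) and derivative at natural-scale value
static inline double prior_lp(double x, int type, double df, double loc,
                              double scale, double &grad) {
  double z = (x - loc) / scale;
  switch (type) {
  case 0: { // Cauchy
    double d = 1.0 + z * z;
    grad = -2.0 * z / (scale * d);
    return -std::log(d);
  }
  case 1: { // Student-t
    double d = 1.0 + z * z / df;
    grad = -(df + 1.0) * z / (scale * (df + z * z));
    return -0.5 * (df + 1.0) * std::log(d);
  }
  case 2: { // Normal
    grad = -z / scale;
    return -0.5 * z * z;
  }
  case 3: { // flat, bounded for propriety
    grad = 0.0;
    if (std::abs(x) > FLAT_BOUND) return -datum::inf;
    return 0.0;
  }
  }
  grad = 0.0;
  return 0.0;
}

struct Model {
  int family;      // 0 bernoulli, 1 cumulative
  int ncat;        // categories (2 for bernoulli)
  const mat &X;    // design (bernoulli: incl. intercept; cumulative: slopes)
  const ivec &y;
  const vec &w;
  const ivec &ptype;
  const vec &pdf_, &ploc, &pscale;

  int npar() const {
    return family == 0 ? (int)X.n_cols : (ncat - 1) + (int)X.n_cols;
  }

  // log posterior and gradient on the sampling scale
  double logpost(const vec &q, vec &grad, bool jacobian = true) const {
    grad.zeros(q.n_elem);
    double lp = 0.0;
    if (family == 0) {
      vec eta = X * q;
      vec mu(eta.n_elem);
      for (uword i = 0; i < eta.n_elem; ++i) {
        double e = eta[i];
        lp += w[i] * (y[i] * e - log1pexp_(e));
        mu[i] = w[i] * (y[i] - sigmoid(e));
      }
      grad = X.t() * mu;
      for (uword j = 0; j < q.n_elem; ++j) {
        double g;
        lp += prior_lp(q[j], ptype[j], pdf_[j], ploc[j], pscale[j], g);
        grad[j] += g;
      }
      return lp;
    }
    // cumulative logit
    int K = ncat, T = K - 1, Q = X.n_cols;
    vec alpha(T);
    alpha[0] = q[0];
    for (int c = 1; c < T; ++c) alpha[c] = alpha[c - 1] + std::exp(q[c]);
    vec gamma = q.subvec(T, T + Q - 1);
    vec eta = Q > 0 ? vec(X * gamma) : vec(y.n_elem, fill::zeros);
    vec galpha(T, fill::zeros);
    vec geta(eta.n_elem, fill::zeros);
    for (uword i = 0; i < eta.n_elem; ++i) {
      int c = y[i];
      double Fhi = 1.0, fhi = 0.0, Flo = 0.0, flo = 0.0;
      if (c <= K - 2) {
        Fhi = sigmoid(alpha[c] - eta[i]);
        fhi = Fhi * (1.0 - Fhi);
      }
      if (c >= 1) {
        Flo = sigmoid(alpha[c - 1] - eta[i]);
        flo = Flo * (1.0 - Flo);
      }
      double p = Fhi - Flo;
      if (!(p > 1e-300)) return -datum::inf;
      lp += w[i] * std::log(p);
      double inv = w[i] / p;
      if (c <= K - 2) galpha[c] += fhi * inv;
      if (c >= 1) galpha[c - 1] -= flo * inv;
      geta[i] = (flo - fhi) * inv;
    }
    if (Q > 0) grad.subvec(T, T + Q - 1) = X.t() * geta;
    // priors on natural thresholds and slopes
    for (int c = 0; c < T; ++c) {
      double g;
      lp += prior_lp(alpha[c], ptype[c], pdf_[c], ploc[c], pscale[c], g);
      galpha[c] += g;
    }
    for (int j = 0; j < Q; ++j) {
      double g;
      lp += prior_lp(gamma[j], ptype[T + j], pdf_[T + j], ploc[T + j],
                     pscale[T + j], g);
      grad[T + j] += g;
    }
    // chain rule alpha -> theta (suffix sums) + log-Jacobian
    double suffix = 0.0;
    for (int c = T - 1; c >= 0; --c) {
      suffix += galpha[c];
      if (c == 0) grad[0] = suffix;
      else {
        grad[c] = std::exp(q[c]) * suffix;
        if (jacobian) { grad[c] += 1.0; lp += q[c]; }
      }
    }
    return lp;
  }
};

// single leapfrog trajectory; returns new (q, grad, lp) by reference
static bool leapfrog(const Model &mod, vec &q, vec &r, vec &grad, double &lp,
                     const vec &invM, double eps, int L) {
  for (int l = 0; l < L; ++l) {
    r += 0.5 * eps * grad;
    q += eps * (invM % r);
    lp = mod.logpost(q, grad);
    if (!std::isfinite(lp)) return false;
    r += 0.5 * eps * grad;
  }
  return true;
}

static double kinetic(const vec &r, const vec &invM) {
  return 0.5 * dot(r % r, invM);
}

// [[Rcpp::export]]
Rcpp::List cpp_hmc(int family, const arma::mat &X, const arma::ivec &y,
                   const arma::vec &w, int ncat,
                   const arma::ivec &prior_type, const arma::vec &prior_df,
                   const arma::vec &prior_loc, const arma::vec &prior_scale,
                   const arma::vec &init, int iter, int warmup,
                   double target_accept, int max_leapfrog,
                   unsigned int seed) {
  Model mod{family, ncat, X, y, w, prior_type, prior_df, prior_loc,
            prior_scale};
  int p = mod.npar();
  if ((int)init.n_elem != p) Rcpp::stop("init length mismatch");
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> rnorm01(0.0, 1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);

  vec q = init, grad(p), invM(p, fill::ones);
  double lp = mod.logpost(q, grad);
  if (!std::isfinite(lp))
    Rcpp::stop("non-finite log density at initial values");

  // find a reasonable initial step size (Hoffman-Gelman heuristic)
  double eps = 0.1;
  {
    vec r(p);
    for (int j = 0; j < p; ++j) r[j] = rnorm01(rng);
    vec q1 = q, g1 = grad, r1 = r;
    double lp1 = lp;
    double H0 = lp - kinetic(r, invM);
    bool ok = leapfrog(mod, q1, r1, g1, lp1, invM, eps, 1);
    double a = ok ? std::exp(lp1 - kinetic(r1, invM) - H0) : 0.0;
    double dir = (a > 0.5) ? 1.0 : -1.0;
    for (int t = 0; t < 50; ++t) {
      eps *= (dir > 0) ? 2.0 : 0.5;
      q1 = q; g1 = grad; r1 = r; lp1 = lp;
      ok = leapfrog(mod, q1, r1, g1, lp1, invM, eps, 1);
      a = ok ? std::exp(lp1 - kinetic(r1, invM) - H0) : 0.0;
      if ((dir > 0 && a < 0.5) || (dir < 0 && a > 0.5)) break;
    }
    if (!(eps > 0) || !std::isfinite(eps)) eps = 0.01;
  }

  // dual averaging state
  const double da_gamma = 0.05, t0 = 10.0, kappa = 0.75;
  double mu = std::log(10.0 * eps), log_eps = std::log(eps),
         log_eps_bar = 0.0, Hbar = 0.0;
  int da_count = 0;
  auto da_restart = [&](double cur_eps) {
    mu = std::log(10.0 * cur_eps);
    log_eps = std::log(cur_eps);
    log_eps_bar = std::log(cur_eps);
    Hbar = 0.0;
    da_count = 0;
  };

  int half = warmup / 2;
  int var_from = warmup / 6;
  running_stat_vec<vec> rs;

  int keep = iter - warmup;
  mat draws(keep > 0 ? keep : 0, p);
  int divergent = 0, accepted = 0, total_post = 0;

  for (int it = 0; it < iter; ++it) {
    bool in_warmup = it < warmup;
    // metric switch at mid-warmup
    if (it == half && rs.count() > 10) {
      vec v = rs.var();
      double ns = (double)rs.count();
      for (int j = 0; j < p; ++j) {
        double reg = (ns / (ns + 5.0)) * v[j] + 1e-3 * (5.0 / (ns + 5.0));
        invM[j] = reg > 1e-10 ? reg : 1e-10;
      }
      da_restart(std::exp(log_eps));
    }

    double cur_eps = in_warmup ? std::exp(log_eps) : eps;
    // randomize the total integration time uniformly over (0, ~2pi]:
    // the trajectory-length range scales with the adapted step size so
    // every sub-model can cross its posterior in one trajectory, and the
    // +/-10% step-size jitter breaks periodic returns
    int L_hi = (int)std::ceil(6.283185307179586 / cur_eps);
    if (L_hi < 2) L_hi = 2;
    if (L_hi > 4 * max_leapfrog) L_hi = 4 * max_leapfrog;
    std::uniform_int_distribution<int> rL(1, L_hi);
    int L = rL(rng);
    cur_eps *= 0.9 + 0.2 * runif01(rng);

    vec r(p);
    for (int j = 0; j < p; ++j) r[j] = rnorm01(rng) / std::sqrt(invM[j]);
    double H0 = lp - kinetic(r, invM);
    vec q1 = q, g1 = grad, r1 = r;
    double lp1 = lp;
    bool ok = leapfrog(mod, q1, r1, g1, lp1, invM, cur_eps, L);
    double log_ratio = ok ? (lp1 - kinetic(r1, invM) - H0) : -datum::inf;
    double a = std::isfinite(log_ratio)
                   ? std::min(1.0, std::exp(log_ratio))
                   : 0.0;
    if (!ok || log_ratio < -1000.0) ++divergent;
    if (runif01(rng) < a) {
      q = q1; grad = g1; lp = lp1;
      if (!in_warmup) ++accepted;
    }
    if (!in_warmup) ++total_post;

    if (in_warmup) {
      // dual averaging update
      ++da_count;
      double frac = 1.0 / (da_count + t0);
      Hbar = (1.0 - frac) * Hbar + frac * (target_accept - a);
      log_eps = mu - std::sqrt((double)da_count) / da_gamma * Hbar;
      double eta_w = std::pow((double)da_count, -kappa);
      log_eps_bar = eta_w * log_eps + (1.0 - eta_w) * log_eps_bar;
      if (it >= var_from && it < half) rs(q);
      if (it == warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      // store on the natural scale
      if (family == 0) {
        draws.row(it - warmup) = q.t();
      } else {
        rowvec row(p);
        row[0] = q[0];
        for (int c = 1; c < ncat - 1; ++c)
          row[c] = row[c - 1] + std::exp(q[c]);
        for (uword j = ncat - 1; j < (uword)p; ++j) row[j] = q[j];
        draws.row(it - warmup) = row;
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("draws") = draws,
      Rcpp::Named("accept_rate") =
          total_post > 0 ? (double)accepted / total_post : NA_REAL,
      Rcpp::Named("divergent") = divergent,
      Rcpp::Named("step_size") = eps,
      Rcpp::Named("inv_metric") = invM);
}

// [[Rcpp::export]]
Rcpp::List cpp_logpost(int family, const arma::mat &X, const arma::ivec &y,
                       const arma::vec &w, int ncat,
                       const arma::ivec &prior_type,
                       const arma::vec &prior_df, const arma::vec &prior_loc,
                       const arma::vec &prior_scale, const arma::vec &q,
                       bool jacobian) {
  Model mod{family, ncat, X, y, w, prior_type, prior_df, prior_loc,
            prior_scale};
  vec grad;
  double lp = mod.logpost(q, grad, jacobian);
  return Rcpp::List::create(Rcpp::Named("lp") = lp,
                            Rcpp::Named("grad") = grad);
}

// Weighted log-likelihood of one sub-model at natural-scale parameters,
// summed over observations.
// [[Rcpp::export]]
double cpp_submodel_loglik(int family, const arma::mat &X,
                           const arma::ivec &y, const arma::vec &w, int ncat,
                           const arma::vec &params) {
  double ll = 0.0;
  if (family == 0) {
    vec eta = X * params;
    for (uword i = 0; i < eta.n_elem; ++i)
      ll += w[i] * (y[i] * eta[i] - log1pexp_(eta[i]));
    return ll;
  }
  int K = ncat, T = K - 1;
  vec alpha = params.subvec(0, T - 1);
  vec gamma = X.n_cols > 0 ? vec(params.subvec(T, T + X.n_cols - 1)) : vec();
  vec eta = X.n_cols > 0 ? vec(X * gamma) : vec(y.n_elem, fill::zeros);
  for (uword i = 0; i < eta.n_elem; ++i) {
    int c = y[i];
    double Fhi = (c <= K - 2) ? sigmoid(alpha[c] - eta[i]) : 1.0;
    double Flo = (c >= 1) ? sigmoid(alpha[c - 1] - eta[i]) : 0.0;
    double p = Fhi - Flo;
    ll += w[i] * std::log(p > 1e-300 ? p : 1e-300);
  }
  return ll;
}

// Weighted pointwise log-likelihood matrix (draw x observation) for one
// sub-model; draws are natural-scale rows.
// [[Rcpp::export]]
arma::mat cpp_pointwise_loglik(int family, const arma::mat &X,
                               const arma::ivec &y, const arma::vec &w,
                               int ncat, const arma::mat &draws) {
  uword n = y.n_elem, D = draws.n_rows;
  mat out(D, n);
  if (family == 0) {
    mat eta = X * draws.t(); // n x D
    for (uword d = 0; d < D; ++d)
      for (uword i = 0; i < n; ++i) {
        double e = eta(i, d);
        out(d, i) = w[i] * (y[i] * e - log1pexp_(e));
      }
    return out;
  }
  int K = ncat, T = K - 1;
  uword Q = X.n_cols;
  for (uword d = 0; d < D; ++d) {
    vec alpha = draws.row(d).subvec(0, T - 1).t();
    vec eta(n, fill::zeros);
    if (Q > 0) {
      vec gamma = draws.row(d).subvec(T, T + Q - 1).t();
      eta = X * gamma;
    }
    for (uword i = 0; i < n; ++i) {
      int c = y[i];
      double Fhi = (c <= K - 2) ? sigmoid(alpha[c] - eta[i]) : 1.0;
      double Flo = (c >= 1) ? sigmoid(alpha[c - 1] - eta[i]) : 0.0;
      double p = Fhi - Flo;
      out(d, i) = w[i] * std::log(p > 1e-300 ? p : 1e-300);
    }
  }
  return out;
}
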