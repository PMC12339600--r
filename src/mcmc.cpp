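// Adaptive random-walk Metropolis samplers for the intertemporal-choice
// models, on the unconstrained transformed parameter scale
// (log k, log m[, log s] / log u, log v, logit w).
//
// Model ids: 0 = direct_difference, 1 = hyperbolic,
// 2 = hyperboloid (normalized value, the canonical generative form),
// 3 = gaussian toy (y ~ N(theta, 1); used to validate the sampler
//     against the conjugate closed form),
// 4 = hyperboloid with payoff-scaled value.
//
// Prior rows (one per transformed parameter): {type, a, b} with
// type 0: z ~ Normal(a, b) on the transformed scale;
// type 1: exp(z) ~ Normal(a, b) truncated positive (Jacobian included);
// type 2: plogis(z) ~ Uniform(0, 1).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}
static inline double ncdf(double z) {
  return 0.5 * std::erfc(-z / 1.4142135623730951);
}
static inline double softplus(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

static void choice_probs_cpp(int model, const arma::mat& D,
                             const arma::vec& z, arma::vec& p) {
  const int T = D.n_rows;
  if (model == 1 || model == 2 || model == 4) {
    const double k = std::exp(std::min(z[0], 300.0));
    const double m = std::exp(std::min(z[1], 300.0));
    const double s = (model == 1) ? 1.0 : std::exp(std::min(z[2], 300.0));
    for (int i = 0; i < T; ++i) {
      double vll, vss;
      if (model == 1) {
        vll = D(i, 2) / (1.0 + k * D(i, 3));
        vss = D(i, 0) / (1.0 + k * D(i, 1));
      } else {
        const double gll = std::pow(k * D(i, 3), s);
        const double gss = std::pow(k * D(i, 1), s);
        const double nll = (model == 4) ? D(i, 2) : 1.0;
        const double nss = (model == 4) ? D(i, 0) : 1.0;
        vll = nll / (1.0 + gll);
        vss = nss / (1.0 + gss);
      }
      const double d = vll - vss;
      const double dm = d * m;
      if (std::isnan(dm))
        p[i] = (d > 0) ? 1.0 : ((d < 0) ? 0.0 : 0.5);
      else
        p[i] = sigmoid(dm);
    }
  } else if (model == 0) {
    const double u = std::exp(std::min(z[0], 300.0));
    const double v = std::exp(std::min(z[1], 300.0));
    const double w = sigmoid(z[2]);
    for (int i = 0; i < T; ++i) {
      const double a = std::pow(D(i, 2), u) - std::pow(D(i, 0), u);
      const double b = std::pow(D(i, 3), v) - std::pow(D(i, 1), v);
      if (!std::isfinite(a) || !std::isfinite(b)) {
        p[i] = std::numeric_limits<double>::quiet_NaN();
        continue;
      }
      const double d = w * a - (1.0 - w) * b;
      const double sg = std::sqrt(std::max(w * (1.0 - w), 0.0)) *
        std::fabs(a + b);
      p[i] = (sg > 0) ? ncdf(d / sg)
                      : ((d > 0) ? 1.0 : ((d < 0) ? 0.0 : 0.5));
    }
  } else {
    stop("unknown model id");
  }
}

// Bernoulli log-likelihood with probability clamping; optionally fills
// the pointwise per-trial log-likelihood vector.
static double loglik_cpp(int model, const arma::mat& D,
                         const arma::ivec& y, const arma::vec& z,
                         arma::vec* pw = nullptr) {
  const int T = D.n_rows;
  if (model == 3) {  // gaussian toy, unit observation SD
    double ll = 0.0;
    for (int i = 0; i < T; ++i) {
      const double r = D(i, 0) - z[0];
      const double li = -0.5 * r * r - 0.9189385332046727;
      ll += li;
      if (pw) (*pw)[i] = li;
    }
    return ll;
  }
  arma::vec p(T);
  choice_probs_cpp(model, D, z, p);
  double ll = 0.0;
  const double lo = 1e-12, hi = 1.0 - 1e-12;
  for (int i = 0; i < T; ++i) {
    double pi = p[i];
    if (!std::isfinite(pi)) return -std::numeric_limits<double>::infinity();
    pi = std::min(hi, std::max(lo, pi));
    const double li = (y[i] == 1) ? std::log(pi) : std::log1p(-pi);
    ll += li;
    if (pw) (*pw)[i] = li;
  }
  return ll;
}

static double logprior_cpp(const arma::mat& prior, const arma::vec& z) {
  double lp = 0.0;
  for (arma::uword j = 0; j < prior.n_rows; ++j) {
    const int type = (int)prior(j, 0);
    const double a = prior(j, 1), b = prior(j, 2);
    if (type == 0) {
      const double r = (z[j] - a) / b;
      lp += -0.5 * r * r - std::log(b);
    } else if (type == 1) {
      const double th = std::exp(z[j]);
      const double r = (th - a) / b;
      lp += -0.5 * r * r - std::log(b) + z[j];
    } else if (type == 2) {
      lp += -softplus(z[j]) - softplus(-z[j]);
    } else {
      stop("unknown prior type");
    }
  }
  return lp;
}

static arma::vec prior_draw_cpp(const arma::mat& prior, std::mt19937& rng) {
  std::normal_distribution<double> N(0.0, 1.0);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  arma::vec z(prior.n_rows);
  for (arma::uword j = 0; j < prior.n_rows; ++j) {
    const int type = (int)prior(j, 0);
    const double a = prior(j, 1), b = prior(j, 2);
    if (type == 0) {
      z[j] = a + b * N(rng);
    } else if (type == 1) {
      double th = a + b * N(rng);
      int tries = 0;
      while (th <= 0 && ++tries < 10000) th = a + b * N(rng);
      z[j] = std::log(std::max(th, 1e-8));
    } else {
      double w = U(rng);
      w = std::min(std::max(w, 1e-10), 1.0 - 1e-10);
      z[j] = std::log(w) - std::log1p(-w);
    }
  }
  return z;
}

// [[Rcpp::export]]
List rwm_fit_cpp(int model, const arma::mat& design, const arma::ivec& resp,
                 const arma::mat& prior, int n_chains, int n_iter,
                 int n_burn, int thin, int seed, bool keep_pointwise) {
  const int P = prior.n_rows;
  const int T = design.n_rows;
  const int n_keep = (n_iter - n_burn) / thin;
  const int total = n_keep * n_chains;
  arma::mat draws(total, P);
  arma::vec lp_out(total), ll_out(total);
  arma::ivec chain_id(total);
  arma::mat pw_out;
  if (keep_pointwise) pw_out.set_size(total, T);
  arma::vec accept(n_chains, arma::fill::zeros);
  arma::vec pw(T);

  int row = 0;
  for (int c = 0; c < n_chains; ++c) {
    std::seed_seq ss{seed, c};
    std::mt19937 rng(ss);
    std::normal_distribution<double> N(0.0, 1.0);
    std::uniform_real_distribution<double> U(0.0, 1.0);

    arma::vec z = prior_draw_cpp(prior, rng);
    double ll = loglik_cpp(model, design, resp, z);
    int tries = 0;
    while (!std::isfinite(ll) && ++tries < 100) {
      z = prior_draw_cpp(prior, rng);
      ll = loglik_cpp(model, design, resp, z);
    }
    if (!std::isfinite(ll))
      stop("could not initialize chain at a finite likelihood");
    double lp = logprior_cpp(prior, z);

    arma::vec scale(P, arma::fill::value(0.5));
    arma::vec win_acc(P, arma::fill::zeros);
    int win_n = 0;
    long acc_count = 0, prop_count = 0;

    for (int it = 0; it < n_iter; ++it) {
      for (int j = 0; j < P; ++j) {
        arma::vec zp = z;
        zp[j] += scale[j] * N(rng);
        const double llp = loglik_cpp(model, design, resp, zp);
        double a = -std::numeric_limits<double>::infinity();
        double lpp = 0.0;
        if (std::isfinite(llp)) {
          lpp = logprior_cpp(prior, zp);
          a = (llp + lpp) - (ll + lp);
        }
        ++prop_count;
        if (std::log(U(rng)) < a) {
          z = zp; ll = llp; lp = lpp;
          ++acc_count;
          if (it < n_burn) win_acc[j] += 1.0;
        }
      }
      if (it < n_burn) {
        ++win_n;
        if (win_n == 50) {  // stochastic-approximation step toward ~30%
          for (int j = 0; j < P; ++j) {
            const double r = win_acc[j] / 50.0;
            scale[j] *= std::exp(r - 0.3);
            scale[j] = std::min(std::max(scale[j], 1e-3), 50.0);
          }
          win_acc.zeros();
          win_n = 0;
        }
      }
      if (it >= n_burn && ((it - n_burn) % thin == 0)) {
        draws.row(row) = z.t();
        ll_out[row] = ll;
        lp_out[row] = ll + lp;
        chain_id[row] = c + 1;
        if (keep_pointwise) {
          loglik_cpp(model, design, resp, z, &pw);
          pw_out.row(row) = pw.t();
        }
        ++row;
      }
    }
    accept[c] = (double)acc_count / (double)prop_count;
  }

  List out = List::create(
    _["draws"] = draws, _["logpost"] = lp_out, _["loglik"] = ll_out,
    _["chain"] = chain_id, _["accept_rate"] = accept,
    _["n_keep_per_chain"] = n_keep);
  if (keep_pointwise) out["pointwise"] = pw_out;
  return out;
}

// [[Rcpp::export]]
double loglik_point_cpp(int model, const arma::mat& design,
                        const arma::ivec& resp, const arma::vec& z) {
  return loglik_cpp(model, design, resp, z);
}

// [[Rcpp::export]]
arma::vec pointwise_loglik_cpp(int model, const arma::mat& design,
                               const arma::ivec& resp, const arma::vec& z) {
  arma::vec pw(design.n_rows);
  loglik_cpp(model, design, resp, z, &pw);
  return pw;
}

// Hierarchical sampler: individual transformed parameters z_ij are
// normal around group locations mu_j with scales sigma_j; hyperpriors
// mu_j ~ Normal(0, loc_sd^2), sigma_j ~ Uniform(0, scale_upper).
// Metropolis-within-Gibbs: random-walk updates for each z_ij and for
// log sigma_j, conjugate normal draw for mu_j.
// [[Rcpp::export]]
List hier_fit_cpp(int model, const List& designs, const List& resps,
                  int P, int n_chains, int n_iter, int n_burn, int thin,
                  int seed, double loc_sd, double scale_upper,
                  int keep_individual) {
  const int N = resps.size();
  const bool shared = (designs.size() == 1);
  std::vector<arma::mat> D(shared ? 1 : N);
  std::vector<arma::ivec> Y(N);
  for (int i = 0; i < (shared ? 1 : N); ++i)
    D[i] = as<arma::mat>(designs[i]);
  for (int i = 0; i < N; ++i) Y[i] = as<arma::ivec>(resps[i]);

  const int n_keep = (n_iter - n_burn) / thin;
  const int total = n_keep * n_chains;
  arma::mat group(total, 2 * P);       // mu then sigma
  arma::vec joint_lp(total);
  arma::ivec chain_id(total);
  arma::mat ind_mean(N, P, arma::fill::zeros);
  arma::mat ind_map(N, P, arma::fill::zeros);
  double best_lp = -std::numeric_limits<double>::infinity();
  const int K = std::min(keep_individual, N);
  arma::cube ind_draws;
  if (K > 0) ind_draws.set_size(total, P, K);

  int row = 0;
  for (int c = 0; c < n_chains; ++c) {
    std::seed_seq ss{seed, 7919 + c};
    std::mt19937 rng(ss);
    std::normal_distribution<double> Nd(0.0, 1.0);
    std::uniform_real_distribution<double> U(0.0, 1.0);

    arma::vec mu(P, arma::fill::zeros), sig(P, arma::fill::ones);
    arma::mat Z(P, N);
    arma::vec ll(N);
    for (int i = 0; i < N; ++i) {
      const arma::mat& Di = D[shared ? 0 : i];
      for (int j = 0; j < P; ++j) Z(j, i) = mu[j] + sig[j] * Nd(rng);
      ll[i] = loglik_cpp(model, Di, Y[i], Z.col(i));
      int tries = 0;
      while (!std::isfinite(ll[i]) && ++tries < 100) {
        for (int j = 0; j < P; ++j) Z(j, i) = mu[j] + sig[j] * Nd(rng);
        ll[i] = loglik_cpp(model, Di, Y[i], Z.col(i));
      }
      if (!std::isfinite(ll[i]))
        stop("could not initialize participant %d at a finite likelihood",
             i + 1);
    }

    arma::mat scale(P, N, arma::fill::value(0.5));
    arma::mat win_acc(P, N, arma::fill::zeros);
    arma::vec sig_scale(P, arma::fill::value(0.3));
    int win_n = 0;

    for (int it = 0; it < n_iter; ++it) {
      // individual-level updates
      for (int i = 0; i < N; ++i) {
        const arma::mat& Di = D[shared ? 0 : i];
        for (int j = 0; j < P; ++j) {
          arma::vec zp = Z.col(i);
          zp[j] += scale(j, i) * Nd(rng);
          const double llp = loglik_cpp(model, Di, Y[i], zp);
          if (!std::isfinite(llp)) continue;
          const double dz_new = (zp[j] - mu[j]) / sig[j];
          const double dz_old = (Z(j, i) - mu[j]) / sig[j];
          const double a = (llp - 0.5 * dz_new * dz_new) -
                           (ll[i] - 0.5 * dz_old * dz_old);
          if (std::log(U(rng)) < a) {
            Z(j, i) = zp[j];
            ll[i] = llp;
            if (it < n_burn) win_acc(j, i) += 1.0;
          }
        }
      }
      // group locations: conjugate normal
      for (int j = 0; j < P; ++j) {
        const double prec = N / (sig[j] * sig[j]) + 1.0 / (loc_sd * loc_sd);
        const double mean = arma::accu(Z.row(j)) / (sig[j] * sig[j]) / prec;
        mu[j] = mean + Nd(rng) / std::sqrt(prec);
      }
      // group scales: random walk on log sigma, uniform prior support
      for (int j = 0; j < P; ++j) {
        const double ls = std::log(sig[j]);
        const double lsp = ls + sig_scale[j] * Nd(rng);
        const double sp = std::exp(lsp);
        if (sp >= scale_upper) continue;
        double a = 0.0;
        for (int i = 0; i < N; ++i) {
          const double rn = (Z(j, i) - mu[j]) / sp;
          const double ro = (Z(j, i) - mu[j]) / sig[j];
          a += -0.5 * rn * rn + 0.5 * ro * ro;
        }
        a += N * (ls - lsp) + (lsp - ls);  // likelihood normalizer + Jacobian
        if (std::log(U(rng)) < a) sig[j] = sp;
      }
      if (it < n_burn) {
        ++win_n;
        if (win_n == 50) {
          for (int i = 0; i < N; ++i)
            for (int j = 0; j < P; ++j) {
              const double r = win_acc(j, i) / 50.0;
              scale(j, i) *= std::exp(r - 0.3);
              scale(j, i) = std::min(std::max(scale(j, i), 1e-3), 50.0);
            }
          win_acc.zeros();
          win_n = 0;
        }
      }
      if (it >= n_burn && ((it - n_burn) % thin == 0)) {
        for (int j = 0; j < P; ++j) {
          group(row, j) = mu[j];
          group(row, P + j) = sig[j];
        }
        double jlp = 0.0;
        for (int i = 0; i < N; ++i) {
          jlp += ll[i];
          for (int j = 0; j < P; ++j) {
            const double r = (Z(j, i) - mu[j]) / sig[j];
            jlp += -0.5 * r * r - std::log(sig[j]);
          }
        }
        for (int j = 0; j < P; ++j) {
          const double rm = mu[j] / loc_sd;
          jlp += -0.5 * rm * rm;
        }
        joint_lp[row] = jlp;
        ind_mean += Z.t();
        if (jlp > best_lp) { best_lp = jlp; ind_map = Z.t(); }
        for (int q = 0; q < K; ++q)
          for (int j = 0; j < P; ++j) ind_draws(row, j, q) = Z(j, q);
        chain_id[row] = c + 1;
        ++row;
      }
    }
  }
  ind_mean /= (double)total;

  List out = List::create(
    _["group"] = group, _["joint_logpost"] = joint_lp,
    _["chain"] = chain_id, _["individual_mean"] = ind_mean,
    _["individual_map"] = ind_map, _["n_keep_per_chain"] = n_keep);
  if (K > 0) out["individual_draws"] = ind_draws;
  return out;
}
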