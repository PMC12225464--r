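#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log(sigmoid(x)), stable on both tails
static inline double log_sigmoid(double x) {
  if (x > 0.0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

// log(1 - exp(x)) for x < 0, stable near 0
static inline double log1m_expc(double x) {
  if (x > -M_LN2) return std::log(-std::expm1(x));
  return std::log1p(-std::exp(x));
}

// per-record log-likelihood of the marginalised two-stage Bernoulli model
static inline double ll_record(double eta_p, double eta_v, int y) {
  double lvp = log_sigmoid(eta_p) + log_sigmoid(eta_v);
  return y == 1 ? lvp : log1m_expc(lvp);
}

// One chain of componentwise adaptive random-walk Metropolis over the
// box-uniform prior [-bound, bound]. The flat prior cancels in the
// acceptance ratio; proposals leaving the box are rejected outright.
// Columns of the design matrices are stored sparsely so a proposal for a
// dummy coefficient only revisits the records in that category. An extra
// antithetic joint move on (mu_p, mu_v) each sweep handles the weakly
// identified intercept ridge created by the product likelihood.
// Proposal scales adapt by Robbins-Monro toward 0.44 acceptance during
// warmup and are frozen afterwards. Uses R's RNG: seed from R.
// [[Rcpp::export]]
List sample_chain_cpp(NumericMatrix Xp, NumericMatrix Xv, IntegerVector y,
                      NumericVector theta0, int n_warmup, int n_iter,
                      double bound, bool save_loglik, int loglik_thin) {
  const int n = Xp.nrow();
  const int kp = Xp.ncol();
  const int kv = Xv.ncol();
  const int k = kp + kv;

  // sparse column storage: row indices + values of non-zero entries
  std::vector< std::vector<int> > rows(k);
  std::vector< std::vector<double> > vals(k);
  for (int j = 0; j < k; ++j) {
    const bool det = j < kp;
    for (int i = 0; i < n; ++i) {
      double x = det ? Xp(i, j) : Xv(i, j - kp);
      if (x != 0.0) { rows[j].push_back(i); vals[j].push_back(x); }
    }
  }

  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> eta_p(n, 0.0), eta_v(n, 0.0), llvec(n);
  for (int j = 0; j < k; ++j) {
    std::vector<double> &eta = j < kp ? eta_p : eta_v;
    for (size_t m = 0; m < rows[j].size(); ++m)
      eta[rows[j][m]] += theta[j] * vals[j][m];
  }
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    llvec[i] = ll_record(eta_p[i], eta_v[i], y[i]);
    ll += llvec[i];
  }

  std::vector<double> log_s(k, std::log(0.1));
  double log_s_ridge = std::log(0.1);
  std::vector<double> acc(k, 0.0);
  double acc_ridge = 0.0;
  const double target = 0.44;

  const int n_total = n_warmup + n_iter;
  NumericMatrix draws(n_iter, k);
  int n_saved = save_loglik ? (n_iter + loglik_thin - 1) / loglik_thin : 0;
  NumericMatrix loglik(n_saved, save_loglik ? n : 0);
  int saved = 0;

  std::vector<double> new_eta, new_ll;
  for (int t = 1; t <= n_total; ++t) {
    const bool adapt = t <= n_warmup;
    const double gamma = adapt ? 1.0 / std::pow((double)t, 0.6) : 0.0;

    // refresh the total from the per-record terms (cheap, kills drift)
    ll = 0.0;
    for (int i = 0; i < n; ++i) ll += llvec[i];

    for (int j = 0; j < k; ++j) {
      double delta = R::rnorm(0.0, std::exp(log_s[j]));
      double cand = theta[j] + delta;
      double alpha = 0.0;
      if (std::fabs(cand) <= bound) {
        std::vector<double> &eta = j < kp ? eta_p : eta_v;
        const std::vector<int> &rj = rows[j];
        const std::vector<double> &vj = vals[j];
        const size_t nz = rj.size();
        new_eta.resize(nz); new_ll.resize(nz);
        double diff = 0.0;
        for (size_t m = 0; m < nz; ++m) {
          const int i = rj[m];
          new_eta[m] = eta[i] + delta * vj[m];
          new_ll[m] = j < kp ? ll_record(new_eta[m], eta_v[i], y[i])
                             : ll_record(eta_p[i], new_eta[m], y[i]);
          diff += new_ll[m] - llvec[i];
        }
        alpha = diff >= 0.0 ? 1.0 : std::exp(diff);
        if (unif_rand() < alpha) {
          theta[j] = cand;
          for (size_t m = 0; m < nz; ++m) {
            eta[rj[m]] = new_eta[m];
            llvec[rj[m]] = new_ll[m];
          }
          ll += diff;
        }
      }
      if (adapt) log_s[j] += gamma * (alpha - target);
      if (!adapt) acc[j] += alpha;
    }

    // joint ridge move: mu_p up, mu_v down (and vice versa)
    {
      double delta = R::rnorm(0.0, std::exp(log_s_ridge));
      double cp = theta[0] + delta, cv = theta[kp] - delta;
      double alpha = 0.0;
      if (std::fabs(cp) <= bound && std::fabs(cv) <= bound) {
        double diff = 0.0;
        for (int i = 0; i < n; ++i)
          diff += ll_record(eta_p[i] + delta, eta_v[i] - delta, y[i]) -
                  llvec[i];
        alpha = diff >= 0.0 ? 1.0 : std::exp(diff);
        if (unif_rand() < alpha) {
          theta[0] = cp; theta[kp] = cv;
          for (int i = 0; i < n; ++i) {
            eta_p[i] += delta; eta_v[i] -= delta;
            llvec[i] = ll_record(eta_p[i], eta_v[i], y[i]);
          }
        }
      }
      if (adapt) log_s_ridge += gamma * (alpha - target);
      if (!adapt) acc_ridge += alpha;
    }

    if (t > n_warmup) {
      const int it = t - n_warmup - 1;
      for (int j = 0; j < k; ++j) draws(it, j) = theta[j];
      if (save_loglik && it % loglik_thin == 0) {
        for (int i = 0; i < n; ++i) loglik(saved, i) = llvec[i];
        ++saved;
      }
    }
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_out(k);
  for (int j = 0; j < k; ++j) acc_out[j] = acc[j] / n_iter;
  NumericVector sd_out(k);
  for (int j = 0; j < k; ++j) sd_out[j] = std::exp(log_s[j]);

  return List::create(
    _["draws"] = draws,
    _["loglik"] = loglik,
    _["accept_rate"] = acc_out,
    _["accept_rate_ridge"] = acc_ridge / n_iter,
    _["proposal_sd"] = sd_out
  );
}
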