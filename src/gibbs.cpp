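// Gibbs sweep for the folded-normal / shifted-gamma mixture with
// SC-modulated shape and logistic prior. Conjugate draws for beta and
// sigma0^2, multiple-try Metropolis (MTM) with symmetric multivariate-t
// proposals for the alpha and gamma coefficient blocks, Bernoulli latent
// membership updates. All randomness comes from R's RNG so chains are
// reproducible under set.seed().

#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

static const double LA_CAP = 600.0;  // cap on log-shape before exp()

struct ModelData {
  const NumericVector &tF, &tS;
  double mu1;
  // per-link log(tF - mu1), NaN where tF <= mu1
  std::vector<double> log_dF;
  ModelData(const NumericVector &tF_, const NumericVector &tS_, double mu1_)
      : tF(tF_), tS(tS_), mu1(mu1_), log_dF(tF_.size()) {
    for (int i = 0; i < tF_.size(); ++i)
      log_dF[i] = tF_[i] > mu1_ ? std::log(tF_[i] - mu1_) : NA_REAL;
  }
};

// -0.5 * x' P x for a 2x2 precision matrix P
static inline double neg_half_quad(const NumericMatrix &P, double x0,
                                   double x1) {
  return -0.5 * (P(0, 0) * x0 * x0 + 2.0 * P(0, 1) * x0 * x1 +
                 P(1, 1) * x1 * x1);
}

// log target of the alpha block given w, beta (prior x likelihood terms
// that involve the gamma shape)
static double log_target_alpha(double a0, double a1, const ModelData &md,
                               const std::vector<int> &alt, double log_beta,
                               const NumericMatrix &P_alpha) {
  double lp = neg_half_quad(P_alpha, a0, a1);
  for (size_t j = 0; j < alt.size(); ++j) {
    int i = alt[j];
    double la = a0 + a1 * md.tS[i];
    if (la > LA_CAP) return R_NegInf;
    double a = std::exp(la);
    lp += a * log_beta - R::lgammafn(a) + a * md.log_dF[i];
  }
  return std::isfinite(lp) ? lp : R_NegInf;
}

// log target of the gamma block given w (prior x logistic likelihood)
static double log_target_gamma(double g0, double g1, const ModelData &md,
                               const std::vector<int> &w,
                               const NumericMatrix &P_gamma) {
  double lp = neg_half_quad(P_gamma, g0, g1);
  int m = md.tF.size();
  for (int i = 0; i < m; ++i) {
    double eta = g0 + g1 * md.tS[i];
    lp += w[i] * eta - Rf_log1pexp(eta);
  }
  return std::isfinite(lp) ? lp : R_NegInf;
}

static inline double log_sum_exp(const std::vector<double> &v) {
  double mx = R_NegInf;
  for (double x : v) if (x > mx) mx = x;
  if (!std::isfinite(mx)) return R_NegInf;
  double s = 0.0;
  for (double x : v) s += std::exp(x - mx);
  return mx + std::log(s);
}

// One multiple-try Metropolis step with k symmetric bivariate-t(nu)
// proposals; candidate weights equal the target density. Returns true on
// acceptance, updating (x0, x1).
static bool mtm_step(double &x0, double &x1, double scale, int k, double nu,
                     const std::function<double(double, double)> &logpost,
                     double &lp_cur) {
  std::vector<double> y0(k), y1(k), lw(k);
  for (int j = 0; j < k; ++j) {
    double s = std::sqrt(R::rchisq(nu) / nu);
    y0[j] = x0 + scale * norm_rand() / s;
    y1[j] = x1 + scale * norm_rand() / s;
    lw[j] = logpost(y0[j], y1[j]);
  }
  double lse_y = log_sum_exp(lw);
  if (!std::isfinite(lse_y)) return false;
  // select a candidate with probability proportional to its weight
  double u = unif_rand(), acc = 0.0;
  int J = k - 1;
  for (int j = 0; j < k; ++j) {
    acc += std::exp(lw[j] - lse_y);
    if (u <= acc) { J = j; break; }
  }
  // reference set: k-1 draws around the selected candidate, plus current
  std::vector<double> lv(k);
  for (int j = 0; j < k - 1; ++j) {
    double s = std::sqrt(R::rchisq(nu) / nu);
    double r0 = y0[J] + scale * norm_rand() / s;
    double r1 = y1[J] + scale * norm_rand() / s;
    lv[j] = logpost(r0, r1);
  }
  lv[k - 1] = lp_cur;
  double log_ratio = lse_y - log_sum_exp(lv);
  if (std::log(unif_rand()) < log_ratio) {
    x0 = y0[J]; x1 = y1[J]; lp_cur = lw[J];
    return true;
  }
  return false;
}

// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
List gibbs_chain_cpp(NumericVector t_f, NumericVector t_s, List hyper,
                     List init, List ctrl) {
  const int m = t_f.size();
  const double mu1 = as<double>(hyper["mu1"]);
  const double a_beta = as<double>(hyper["a_beta"]);
  const double b_beta = as<double>(hyper["b_beta"]);
  const double a_sigma = as<double>(hyper["a_sigma"]);
  const double b_sigma = as<double>(hyper["b_sigma"]);
  const NumericMatrix P_alpha = as<NumericMatrix>(hyper["P_alpha"]);
  const NumericMatrix P_gamma = as<NumericMatrix>(hyper["P_gamma"]);
  const double nu = as<double>(hyper["nu"]);

  const int n_iter = as<int>(ctrl["n_iter"]);
  const int burn_in = as<int>(ctrl["burn_in"]);
  const int thin = as<int>(ctrl["thin"]);
  const int k_try = as<int>(ctrl["mtm_tries"]);
  const bool adapt = as<bool>(ctrl["adapt"]);
  const bool up_w = as<bool>(ctrl["update_w"]);
  const bool up_a = as<bool>(ctrl["update_alpha"]);
  const bool up_g = as<bool>(ctrl["update_gamma"]);
  const bool up_b = as<bool>(ctrl["update_beta"]);
  const bool up_s = as<bool>(ctrl["update_sigma"]);
  double scale_a = as<double>(ctrl["mtm_scale_alpha"]);
  double scale_g = as<double>(ctrl["mtm_scale_gamma"]);

  double a0 = as<NumericVector>(init["alpha"])[0];
  double a1 = as<NumericVector>(init["alpha"])[1];
  double g0 = as<NumericVector>(init["gamma"])[0];
  double g1 = as<NumericVector>(init["gamma"])[1];
  double beta = as<double>(init["beta"]);
  double sigma2 = as<double>(init["sigma0_sq"]);
  IntegerVector w_init = as<IntegerVector>(init["w"]);
  std::vector<int> w(w_init.begin(), w_init.end());

  ModelData md(t_f, t_s, mu1);
  std::vector<int> alt;                       // indices with w = 1
  auto refresh_alt = [&]() {
    alt.clear();
    for (int i = 0; i < m; ++i) if (w[i]) alt.push_back(i);
  };
  refresh_alt();

  const int n_ret = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_ret, 6);
  colnames(draws) = CharacterVector::create("alpha0", "alpha1", "gamma0",
                                            "gamma1", "beta", "sigma0_sq");
  NumericVector p_mean(m);                    // posterior-mean membership
  int row = 0;

  long acc_a = 0, acc_g = 0, try_a = 0, try_g = 0;   // post burn-in
  int bacc_a = 0, bacc_g = 0, batch = 0;             // adaptation window
  const int batch_len = 50;
  const double target_rate = 0.3;

  double lp_a = log_target_alpha(a0, a1, md, alt, std::log(beta), P_alpha);
  double lp_g = log_target_gamma(g0, g1, md, w, P_gamma);

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    // ---- latent membership w (Bernoulli with Eq-15 probabilities) ----
    if (up_w) {
      const double log_sig = std::log(sigma2);
      const double lf0_c = M_LN2 - 0.5 * (std::log(2.0 * M_PI) + log_sig);
      const double log_beta = std::log(beta);
      for (int i = 0; i < m; ++i) {
        if (!(t_f[i] > mu1)) { w[i] = 0; continue; }
        double eta = g0 + g1 * t_s[i];
        double l0 = -Rf_log1pexp(eta) + lf0_c -
                    t_f[i] * t_f[i] / (2.0 * sigma2);
        double la = a0 + a1 * t_s[i];
        double l1;
        if (la > LA_CAP) l1 = R_NegInf;
        else {
          double a = std::exp(la);
          l1 = eta - Rf_log1pexp(eta) + a * log_beta - R::lgammafn(a) +
               (a - 1.0) * md.log_dF[i] - beta * (t_f[i] - mu1);
        }
        double p = std::isfinite(l1) ? 1.0 / (1.0 + std::exp(l0 - l1)) : 0.0;
        w[i] = unif_rand() < p ? 1 : 0;
        if (it > burn_in) p_mean[i] += p;  // running sum, normalised later
      }
      refresh_alt();
      lp_a = log_target_alpha(a0, a1, md, alt, std::log(beta), P_alpha);
      lp_g = log_target_gamma(g0, g1, md, w, P_gamma);
    }

    // ---- alpha block: MTM ----
    if (up_a) {
      double log_beta = std::log(beta);
      auto tgt = [&](double x0, double x1) {
        return log_target_alpha(x0, x1, md, alt, log_beta, P_alpha);
      };
      bool ok = mtm_step(a0, a1, scale_a, k_try, nu, tgt, lp_a);
      if (it > burn_in) { try_a++; acc_a += ok; }
      else if (adapt) bacc_a += ok;
    }

    // ---- gamma block: MTM ----
    if (up_g) {
      auto tgt = [&](double x0, double x1) {
        return log_target_gamma(x0, x1, md, w, P_gamma);
      };
      bool ok = mtm_step(g0, g1, scale_g, k_try, nu, tgt, lp_g);
      if (it > burn_in) { try_g++; acc_g += ok; }
      else if (adapt) bacc_g += ok;
    }

    // ---- beta: conjugate Gamma draw ----
    if (up_b) {
      double shp = a_beta, rate = b_beta;
      for (size_t j = 0; j < alt.size(); ++j) {
        int i = alt[j];
        double la = a0 + a1 * t_s[i];
        shp += std::exp(std::min(la, LA_CAP));
        rate += t_f[i] - mu1;
      }
      beta = R::rgamma(shp, 1.0 / rate);
      lp_a = log_target_alpha(a0, a1, md, alt, std::log(beta), P_alpha);
    }

    // ---- sigma0^2: conjugate Inverse-Gamma draw ----
    if (up_s) {
      double shp = a_sigma, scl = b_sigma;
      for (int i = 0; i < m; ++i)
        if (!w[i]) { shp += 0.5; scl += 0.5 * t_f[i] * t_f[i]; }
      sigma2 = scl / R::rgamma(shp, 1.0);
    }

    // ---- proposal-scale adaptation during burn-in only ----
    if (adapt && it <= burn_in && it % batch_len == 0) {
      batch++;
      double step = 1.0 / std::sqrt((double)batch);
      if (up_a) {
        scale_a *= std::exp(step * ((double)bacc_a / batch_len - target_rate));
        bacc_a = 0;
      }
      if (up_g) {
        scale_g *= std::exp(step * ((double)bacc_g / batch_len - target_rate));
        bacc_g = 0;
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && row < n_ret) {
      draws(row, 0) = a0; draws(row, 1) = a1;
      draws(row, 2) = g0; draws(row, 3) = g1;
      draws(row, 4) = beta; draws(row, 5) = sigma2;
      row++;
    }
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  if (up_w && n_iter > burn_in)
    for (int i = 0; i < m; ++i) p_mean[i] /= (n_iter - burn_in);

  return List::create(
      _["draws"] = draws,
      _["accept_alpha"] = try_a > 0 ? (double)acc_a / try_a : NA_REAL,
      _["accept_gamma"] = try_g > 0 ? (double)acc_g / try_g : NA_REAL,
      _["scale_alpha"] = scale_a, _["scale_gamma"] = scale_g,
      _["p_mean"] = p_mean,
      _["w_final"] = IntegerVector(w.begin(), w.end()));
}
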