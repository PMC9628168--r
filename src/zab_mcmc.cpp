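// Metropolis-within-Gibbs sampler for the zero-augmented beta-prime / gamma
// three-level two-part mixed model.
//
// Update blocks per iteration:
//   (a) Part I coefficients alpha: componentwise random-walk MH
//       (constant-tau mode instead draws tau from its conjugate Beta)
//   (b) Part II coefficients beta: componentwise random-walk MH
//   (c) psi: random-walk MH on log scale (with Jacobian)
//   (d) random effects: per-cluster MH, bivariate (p1,p2)/(c1,c2) in
//       correlated mode, scalar Part-II effects in the reduced mode
//   (e) level covariances: conjugate inverse-Wishart Gibbs (correlated) or
//       inverse-gamma Gibbs (independent)
// Proposal scales are adapted by Robbins-Monro toward a target acceptance
// rate during burn-in and frozen afterwards.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double ETA_CAP = 40.0;

static inline double clamp_eta(double x) {
  if (x > ETA_CAP) return ETA_CAP;
  if (x < -ETA_CAP) return -ETA_CAP;
  return x;
}

static inline double safe_apr(double dll) {
  if (std::isnan(dll)) return 0.0;   // out-of-support proposal
  return std::min(1.0, std::exp(dll));
}

static inline double softplus(double x) {
  return (x > 0.0) ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// log density of the positive-part family at positive subject t given linear
// predictor eta (log mean) and dispersion psi; family 0 = BP, 1 = gamma
struct ContData {
  arma::vec y, ly, l1py;
  int family;
};

static inline double cont_ll_one(const ContData& d, int t, double eta, double psi) {
  eta = clamp_eta(eta);
  if (d.family == 0) {
    double a = std::exp(eta) * (psi + 1.0);
    double b = psi + 2.0;
    return (a - 1.0) * d.ly[t] - (a + b) * d.l1py[t]
         - std::lgamma(a) - std::lgamma(b) + std::lgamma(a + b);
  }
  return psi * (std::log(psi) - eta) + (psi - 1.0) * d.ly[t]
       - psi * d.y[t] * std::exp(-eta) - std::lgamma(psi);
}

static double cont_ll_all(const ContData& d, const arma::vec& eta_pos, double psi) {
  double s = 0.0;
  for (arma::uword t = 0; t < eta_pos.n_elem; ++t)
    s += cont_ll_one(d, (int)t, eta_pos[t], psi);
  return s;
}

static inline double bern_ll_one(int omega, double eta) {
  return omega * eta - softplus(eta);
}

// Robbins-Monro log-scale update toward target acceptance
static inline void rm_adapt(double& lscale, double apr, double target, int t) {
  lscale += std::pow((double)t + 1.0, -0.6) * (apr - target);
  if (lscale > 8.0) lscale = 8.0;
  if (lscale < -12.0) lscale = -12.0;
}

// one draw Sigma ~ InverseWishart(Omega, nu), p = 2, via Bartlett
static arma::mat riw2(const arma::mat& Omega, double nu) {
  arma::mat V = arma::inv_sympd(arma::symmatu(Omega));
  double l11 = std::sqrt(V(0, 0));
  double l21 = V(1, 0) / l11;
  double l22 = std::sqrt(V(1, 1) - l21 * l21);
  double a11 = std::sqrt(R::rchisq(nu));
  double a22 = std::sqrt(R::rchisq(nu - 1.0));
  double a21 = R::rnorm(0.0, 1.0);
  double b11 = l11 * a11;
  double b21 = l21 * a11 + l22 * a21;
  double b22 = l22 * a22;
  // W = B B', Sigma = W^{-1}
  double w11 = b11 * b11;
  double w12 = b11 * b21;
  double w22 = b21 * b21 + b22 * b22;
  double det = w11 * w22 - w12 * w12;
  arma::mat S(2, 2);
  S(0, 0) = w22 / det;  S(0, 1) = -w12 / det;
  S(1, 0) = -w12 / det; S(1, 1) = w11 / det;
  return S;
}

// [[Rcpp::export]]
arma::mat rinvwishart2(arma::mat Omega, double nu) {
  if (nu <= 1.0) stop("nu must exceed p - 1 = 1");
  return riw2(Omega, nu);
}

static inline double mvn2_q(const arma::mat& P, double u1, double u2) {
  // quadratic form u' P u for 2-vector
  return P(0, 0) * u1 * u1 + 2.0 * P(0, 1) * u1 * u2 + P(1, 1) * u2 * u2;
}

// [[Rcpp::export]]
List zab_mcmc_cpp(arma::vec y, arma::ivec omega,
                  arma::mat X1, arma::mat X2,
                  arma::ivec prov, arma::ivec city, arma::ivec city_prov,
                  int n_prov, int n_city,
                  int family, bool constant_tau, bool correlated_re,
                  bool has_p, bool has_c,
                  List priors, List init, List control) {
  const int N = y.n_elem;
  const int q1 = X2.n_cols;
  const int r1 = constant_tau ? 0 : (int)X1.n_cols;

  // ---- positive subjects --------------------------------------------------
  std::vector<int> posIdx;
  for (int k = 0; k < N; ++k) if (omega[k] == 1) posIdx.push_back(k);
  const int Npos = (int)posIdx.size();
  ContData cd;
  cd.family = family;
  cd.y.set_size(Npos); cd.ly.set_size(Npos); cd.l1py.set_size(Npos);
  arma::mat X2pos(Npos, q1);
  arma::ivec prov_pos(Npos), city_pos(Npos);
  for (int t = 0; t < Npos; ++t) {
    int k = posIdx[t];
    cd.y[t] = y[k];
    cd.ly[t] = std::log(y[k]);
    cd.l1py[t] = std::log1p(y[k]);
    X2pos.row(t) = X2.row(k);
    prov_pos[t] = prov[k];
    city_pos[t] = city[k];
  }
  // cluster membership lists
  std::vector< std::vector<int> > prov_all(n_prov), city_all(n_city);
  for (int k = 0; k < N; ++k) {
    if (n_prov > 0) prov_all[prov[k]].push_back(k);
    if (n_city > 0) city_all[city[k]].push_back(k);
  }
  std::vector< std::vector<int> > prov_posl(n_prov), city_posl(n_city);
  for (int t = 0; t < Npos; ++t) {
    if (n_prov > 0) prov_posl[prov_pos[t]].push_back(t);
    if (n_city > 0) city_posl[city_pos[t]].push_back(t);
  }

  // ---- priors -------------------------------------------------------------
  const double alpha_var = as<double>(priors["alpha_var"]);
  const double beta_var = as<double>(priors["beta_var"]);
  const bool psi_gamma = as<bool>(priors["psi_gamma"]);
  const double psi_a = as<double>(priors["psi_a"]);
  const double psi_b = as<double>(priors["psi_b"]);
  const arma::mat Omega1 = as<arma::mat>(priors["Omega1"]);
  const arma::mat Omega2 = as<arma::mat>(priors["Omega2"]);
  const double nu1 = as<double>(priors["nu1"]);
  const double nu2 = as<double>(priors["nu2"]);
  const double sig_a = as<double>(priors["sigma2_a"]);
  const double sig_b = as<double>(priors["sigma2_b"]);
  const double tau_a = as<double>(priors["tau_a"]);
  const double tau_b = as<double>(priors["tau_b"]);

  // ---- state --------------------------------------------------------------
  arma::vec alpha = as<arma::vec>(init["alpha"]);  // length r1 (may be 0)
  arma::vec beta = as<arma::vec>(init["beta"]);
  double psi = as<double>(init["psi"]);
  double tau = as<double>(init["tau"]);
  arma::vec p1 = as<arma::vec>(init["p1"]), p2 = as<arma::vec>(init["p2"]);
  arma::vec c1 = as<arma::vec>(init["c1"]), c2 = as<arma::vec>(init["c2"]);
  arma::mat Sigma1 = as<arma::mat>(init["Sigma1"]);
  arma::mat Sigma2 = as<arma::mat>(init["Sigma2"]);
  double sigma2_p = as<double>(init["sigma2_p"]);
  double sigma2_c = as<double>(init["sigma2_c"]);

  const bool re1_p = correlated_re && has_p;   // Part I province effect present
  const bool re1_c = correlated_re && has_c;

  // linear predictors
  arma::vec eta1(N, arma::fill::zeros);
  if (!constant_tau) {
    eta1 = X1 * alpha;
    for (int k = 0; k < N; ++k) {
      if (re1_p) eta1[k] += p1[prov[k]];
      if (re1_c) eta1[k] += c1[city[k]];
    }
  }
  arma::vec eta2_pos = X2pos * beta;
  for (int t = 0; t < Npos; ++t) {
    if (has_p) eta2_pos[t] += p2[prov_pos[t]];
    if (has_c) eta2_pos[t] += c2[city_pos[t]];
  }

  double cur_cll = cont_ll_all(cd, eta2_pos, psi);
  double cur_bll = 0.0;
  if (!constant_tau) for (int k = 0; k < N; ++k) cur_bll += bern_ll_one(omega[k], eta1[k]);
  if (!std::isfinite(cur_cll) || !std::isfinite(cur_bll))
    stop("log-likelihood non-finite at initial values");

  const int sum_omega = Npos;

  // ---- control ------------------------------------------------------------
  const int n_iter = as<int>(control["n_iter"]);
  const int burnin = as<int>(control["n_burnin"]);
  const int thin = as<int>(control["thin"]);
  const bool adapt = as<bool>(control["adapt"]);
  const double target = as<double>(control["target"]);
  arma::vec ls_alpha(std::max(r1, 1), arma::fill::value(std::log(as<double>(control["s_alpha"]))));
  arma::vec ls_beta(q1, arma::fill::value(std::log(as<double>(control["s_beta"]))));
  double ls_psi = std::log(as<double>(control["s_psi"]));
  arma::vec ls_p(std::max(n_prov, 1), arma::fill::value(std::log(as<double>(control["s_p"]))));
  arma::vec ls_c(std::max(n_city, 1), arma::fill::value(std::log(as<double>(control["s_c"]))));

  const int n_keep = (n_iter - burnin) / thin;
  arma::mat alpha_d(n_keep, std::max(r1, 0)), beta_d(n_keep, q1);
  arma::vec psi_d(n_keep), tau_d(n_keep);
  arma::mat p1_d, p2_d, c1_d, c2_d;
  if (has_p) { p2_d.set_size(n_keep, n_prov); if (re1_p) p1_d.set_size(n_keep, n_prov); }
  if (has_c) { c2_d.set_size(n_keep, n_city); if (re1_c) c1_d.set_size(n_keep, n_city); }
  arma::mat Sig1_d(n_keep, 3), Sig2_d(n_keep, 3);
  arma::vec sig2p_d(n_keep), sig2c_d(n_keep);

  // acceptance tracking (post burn-in)
  double acc_alpha = 0, try_alpha = 0, acc_beta = 0, try_beta = 0;
  double acc_psi = 0, try_psi = 0, acc_p = 0, try_p = 0, acc_c = 0, try_c = 0;

  arma::mat P1inv(2, 2), P2inv(2, 2);
  if (re1_p) P1inv = arma::inv_sympd(arma::symmatu(Sigma1));
  if (re1_c) P2inv = arma::inv_sympd(arma::symmatu(Sigma2));

  int keep_i = 0;
  for (int it = 0; it < n_iter; ++it) {
    const bool in_burn = it < burnin;
    const bool do_adapt = adapt && in_burn;

    // (a) Part I --------------------------------------------------------
    if (constant_tau) {
      tau = R::rbeta(tau_a + sum_omega, tau_b + (N - sum_omega));
    } else {
      for (int l = 0; l < r1; ++l) {
        double s = std::exp(ls_alpha[l]);
        double delta = s * R::rnorm(0.0, 1.0);
        double dll = 0.0;
        for (int k = 0; k < N; ++k)
          dll += bern_ll_one(omega[k], eta1[k] + delta * X1(k, l))
               - bern_ll_one(omega[k], eta1[k]);
        double anew = alpha[l] + delta;
        dll += (alpha[l] * alpha[l] - anew * anew) / (2.0 * alpha_var);
        double apr = safe_apr(dll);
        if (!in_burn) { try_alpha += 1; }
        if (R::runif(0.0, 1.0) < apr) {
          alpha[l] = anew;
          eta1 += delta * X1.col(l);
          if (!in_burn) acc_alpha += 1;
        }
        if (do_adapt) rm_adapt(ls_alpha[l], apr, target, it);
      }
    }

    // (b) beta ----------------------------------------------------------
    for (int l = 0; l < q1; ++l) {
      double s = std::exp(ls_beta[l]);
      double delta = s * R::rnorm(0.0, 1.0);
      arma::vec eta_prop = eta2_pos + delta * X2pos.col(l);
      double new_cll = cont_ll_all(cd, eta_prop, psi);
      double bnew = beta[l] + delta;
      double dll = new_cll - cur_cll
                 + (beta[l] * beta[l] - bnew * bnew) / (2.0 * beta_var);
      double apr = safe_apr(dll);
      if (!in_burn) try_beta += 1;
      if (R::runif(0.0, 1.0) < apr) {
        beta[l] = bnew;
        eta2_pos = eta_prop;
        cur_cll = new_cll;
        if (!in_burn) acc_beta += 1;
      }
      if (do_adapt) rm_adapt(ls_beta[l], apr, target, it);
    }

    // (c) psi (log-scale RW with Jacobian) -------------------------------
    // support truncated to log psi in [-300, 300]: beyond that exp()
    // under/overflows, and under the near-flat small-psi tail of a
    // Gamma(0.01, 0.01)-type prior the truncation is numerically negligible
    {
      double s = std::exp(ls_psi);
      double lpsi = std::log(psi);
      double lpsi_new = lpsi + s * R::rnorm(0.0, 1.0);
      double apr = 0.0;
      if (lpsi_new > -300.0 && lpsi_new < 300.0) {
        double psi_new = std::exp(lpsi_new);
        double new_cll = cont_ll_all(cd, eta2_pos, psi_new);
        double dprior;
        if (psi_gamma)
          dprior = (psi_a - 1.0) * (lpsi_new - lpsi) - psi_b * (psi_new - psi);
        else
          dprior = -(psi_a + 1.0) * (lpsi_new - lpsi) - psi_b * (1.0 / psi_new - 1.0 / psi);
        double dll = new_cll - cur_cll + dprior + (lpsi_new - lpsi); // Jacobian
        apr = safe_apr(dll);
        if (R::runif(0.0, 1.0) < apr) {
          psi = psi_new;
          cur_cll = new_cll;
          if (!in_burn) acc_psi += 1;
        }
      }
      if (!in_burn) try_psi += 1;
      if (do_adapt) rm_adapt(ls_psi, apr, target, it);
    }

    // (d) random effects -------------------------------------------------
    if (has_p) {
      for (int i = 0; i < n_prov; ++i) {
        double s = std::exp(ls_p[i]);
        double d2 = s * R::rnorm(0.0, 1.0);
        double d1 = re1_p ? s * R::rnorm(0.0, 1.0) : 0.0;
        double dll = 0.0;
        for (size_t u = 0; u < prov_posl[i].size(); ++u) {
          int t = prov_posl[i][u];
          dll += cont_ll_one(cd, t, eta2_pos[t] + d2, psi)
               - cont_ll_one(cd, t, eta2_pos[t], psi);
        }
        if (re1_p) {
          for (size_t u = 0; u < prov_all[i].size(); ++u) {
            int k = prov_all[i][u];
            dll += bern_ll_one(omega[k], eta1[k] + d1) - bern_ll_one(omega[k], eta1[k]);
          }
          dll += -0.5 * mvn2_q(P1inv, p1[i] + d1, p2[i] + d2)
               + 0.5 * mvn2_q(P1inv, p1[i], p2[i]);
        } else {
          double pn = p2[i] + d2;
          dll += (p2[i] * p2[i] - pn * pn) / (2.0 * sigma2_p);
        }
        double apr = safe_apr(dll);
        if (!in_burn) try_p += 1;
        if (R::runif(0.0, 1.0) < apr) {
          p2[i] += d2;
          for (size_t u = 0; u < prov_posl[i].size(); ++u) eta2_pos[prov_posl[i][u]] += d2;
          if (re1_p) {
            p1[i] += d1;
            for (size_t u = 0; u < prov_all[i].size(); ++u) eta1[prov_all[i][u]] += d1;
          }
          if (!in_burn) acc_p += 1;
        }
        if (do_adapt) rm_adapt(ls_p[i], apr, target, it);
      }
    }
    if (has_c) {
      for (int j = 0; j < n_city; ++j) {
        double s = std::exp(ls_c[j]);
        double d2 = s * R::rnorm(0.0, 1.0);
        double d1 = re1_c ? s * R::rnorm(0.0, 1.0) : 0.0;
        double dll = 0.0;
        for (size_t u = 0; u < city_posl[j].size(); ++u) {
          int t = city_posl[j][u];
          dll += cont_ll_one(cd, t, eta2_pos[t] + d2, psi)
               - cont_ll_one(cd, t, eta2_pos[t], psi);
        }
        if (re1_c) {
          for (size_t u = 0; u < city_all[j].size(); ++u) {
            int k = city_all[j][u];
            dll += bern_ll_one(omega[k], eta1[k] + d1) - bern_ll_one(omega[k], eta1[k]);
          }
          dll += -0.5 * mvn2_q(P2inv, c1[j] + d1, c2[j] + d2)
               + 0.5 * mvn2_q(P2inv, c1[j], c2[j]);
        } else {
          double cn = c2[j] + d2;
          dll += (c2[j] * c2[j] - cn * cn) / (2.0 * sigma2_c);
        }
        double apr = safe_apr(dll);
        if (!in_burn) try_c += 1;
        if (R::runif(0.0, 1.0) < apr) {
          c2[j] += d2;
          for (size_t u = 0; u < city_posl[j].size(); ++u) eta2_pos[city_posl[j][u]] += d2;
          if (re1_c) {
            c1[j] += d1;
            for (size_t u = 0; u < city_all[j].size(); ++u) eta1[city_all[j][u]] += d1;
          }
          if (!in_burn) acc_c += 1;
        }
        if (do_adapt) rm_adapt(ls_c[j], apr, target, it);
      }
    }

    // psi-dependent cached loglik must track RE moves: cur_cll was updated
    // incrementally only for beta/psi; recompute after RE sweeps
    if (has_p || has_c) cur_cll = cont_ll_all(cd, eta2_pos, psi);

    // (e) variance components (conjugate Gibbs) --------------------------
    if (has_p) {
      if (correlated_re) {
        arma::mat S(2, 2, arma::fill::zeros);
        for (int i = 0; i < n_prov; ++i) {
          S(0, 0) += p1[i] * p1[i]; S(0, 1) += p1[i] * p2[i]; S(1, 1) += p2[i] * p2[i];
        }
        S(1, 0) = S(0, 1);
        Sigma1 = riw2(Omega1 + S, nu1 + n_prov);
        P1inv = arma::inv_sympd(arma::symmatu(Sigma1));
      } else {
        double ssq = arma::dot(p2, p2);
        sigma2_p = 1.0 / R::rgamma(sig_a + 0.5 * n_prov, 1.0 / (sig_b + 0.5 * ssq));
      }
    }
    if (has_c) {
      if (correlated_re) {
        arma::mat S(2, 2, arma::fill::zeros);
        for (int j = 0; j < n_city; ++j) {
          S(0, 0) += c1[j] * c1[j]; S(0, 1) += c1[j] * c2[j]; S(1, 1) += c2[j] * c2[j];
        }
        S(1, 0) = S(0, 1);
        Sigma2 = riw2(Omega2 + S, nu2 + n_city);
        P2inv = arma::inv_sympd(arma::symmatu(Sigma2));
      } else {
        double ssq = arma::dot(c2, c2);
        sigma2_c = 1.0 / R::rgamma(sig_a + 0.5 * n_city, 1.0 / (sig_b + 0.5 * ssq));
      }
    }

    // ---- store --------------------------------------------------------
    if (!in_burn && ((it - burnin + 1) % thin == 0) && keep_i < n_keep) {
      for (int l = 0; l < r1; ++l) alpha_d(keep_i, l) = alpha[l];
      for (int l = 0; l < q1; ++l) beta_d(keep_i, l) = beta[l];
      psi_d[keep_i] = psi;
      tau_d[keep_i] = tau;
      if (has_p) {
        p2_d.row(keep_i) = p2.t();
        if (re1_p) p1_d.row(keep_i) = p1.t();
        if (correlated_re) {
          Sig1_d(keep_i, 0) = Sigma1(0, 0); Sig1_d(keep_i, 1) = Sigma1(0, 1);
          Sig1_d(keep_i, 2) = Sigma1(1, 1);
        } else sig2p_d[keep_i] = sigma2_p;
      }
      if (has_c) {
        c2_d.row(keep_i) = c2.t();
        if (re1_c) c1_d.row(keep_i) = c1.t();
        if (correlated_re) {
          Sig2_d(keep_i, 0) = Sigma2(0, 0); Sig2_d(keep_i, 1) = Sigma2(0, 1);
          Sig2_d(keep_i, 2) = Sigma2(1, 1);
        } else sig2c_d[keep_i] = sigma2_c;
      }
      ++keep_i;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  List acc = List::create(
    _["alpha"] = try_alpha > 0 ? acc_alpha / try_alpha : NA_REAL,
    _["beta"] = try_beta > 0 ? acc_beta / try_beta : NA_REAL,
    _["psi"] = try_psi > 0 ? acc_psi / try_psi : NA_REAL,
    _["p"] = try_p > 0 ? acc_p / try_p : NA_REAL,
    _["c"] = try_c > 0 ? acc_c / try_c : NA_REAL);

  return List::create(
    _["alpha"] = alpha_d, _["beta"] = beta_d, _["psi"] = psi_d,
    _["tau"] = tau_d,
    _["p1"] = p1_d, _["p2"] = p2_d, _["c1"] = c1_d, _["c2"] = c2_d,
    _["Sigma1"] = Sig1_d, _["Sigma2"] = Sig2_d,
    _["sigma2_p"] = sig2p_d, _["sigma2_c"] = sig2c_d,
    _["accept"] = acc,
    _["scales"] = List::create(
      _["alpha"] = arma::exp(ls_alpha), _["beta"] = arma::exp(ls_beta),
      _["psi"] = std::exp(ls_psi), _["p"] = arma::exp(ls_p),
      _["c"] = arma::exp(ls_c)));
}
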