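// MCMC cores for latent-normal joint-model imputation (homoscedastic and
// heteroscedastic) and for substantive-model-compatible imputation, where
// covariate proposals are accepted against the substantive-model likelihood.
//
// Conventions shared with the R wrappers:
//  * Y is the n x p matrix of current values for the joint-model variables
//    (binary variables coded 0/1, already initialised: no NA).
//  * obs is the n x p observed mask (1 = observed in the source data).
//  * Z is the n x p working matrix: equal to Y for continuous columns and
//    holding the latent normal for binary columns; level-2 columns are
//    replicated across the rows of each cluster.
//  * U is J x p: random effects for level-1 columns, and the whole cluster
//    deviation (value - alpha) for level-2 columns; Omega2 is p x p over all
//    columns, Omega1 is p1 x p1 over level-1 columns only.
//  * Latent-binary rows of Omega1 (level 1) and Omega2 (level 2) carry a
//    unit-diagonal probit identifiability constraint; those matrices are
//    updated by random-walk Metropolis-Hastings on a log-Cholesky
//    parametrisation of the constrained space, with the exact Jacobian.

#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// low-level draws
// ---------------------------------------------------------------------------

// N(mu, sd^2) truncated to [0, inf) when positive, (-inf, 0) otherwise.
static double rtnorm_one(double mu, double sd, int positive) {
  if (!positive) return -rtnorm_one(-mu, sd, 1);
  double b  = -mu / sd;                          // standardised lower bound
  double lp = R::pnorm(b, 0.0, 1.0, 0, 1);       // log P(Z > b)
  double q  = std::log(R::unif_rand()) + lp;     // log of uniform tail mass
  double z  = R::qnorm(q, 0.0, 1.0, 0, 1);       // upper-tail quantile
  return mu + sd * z;
}

static arma::vec rmvnorm_chol(const arma::vec& mu, const arma::mat& Sigma) {
  arma::mat Ssym = 0.5 * (Sigma + Sigma.t());
  arma::mat L;
  if (!arma::chol(L, Ssym, "lower")) {
    Ssym.diag() += 1e-10 * (1.0 + arma::trace(Ssym));
    L = arma::chol(Ssym, "lower");
  }
  arma::vec e(mu.n_elem);
  for (arma::uword i = 0; i < mu.n_elem; ++i) e(i) = R::norm_rand();
  return mu + L * e;
}

static arma::mat rwish(double nu, const arma::mat& S) {
  int p = S.n_rows;
  arma::mat L = arma::chol(0.5 * (S + S.t()), "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

static arma::mat riwish(double nu, const arma::mat& S) {
  return arma::inv_sympd(rwish(nu, arma::inv_sympd(0.5 * (S + S.t()))));
}

static arma::mat safe_inv(const arma::mat& S) {
  arma::mat Ssym = 0.5 * (S + S.t());
  arma::mat out;
  if (!arma::inv_sympd(out, Ssym)) {
    Ssym.diag() += 1e-10 * (1.0 + arma::trace(Ssym));
    out = arma::inv_sympd(Ssym);
  }
  return out;
}

// ---------------------------------------------------------------------------
// constrained covariance MH update (log-Cholesky parametrisation)
// ---------------------------------------------------------------------------

// Build lower Cholesky factor from free parameters; rows listed in conrow
// have their diagonal determined by the unit-variance constraint.
static bool theta_to_chol(const arma::vec& theta, const std::vector<int>& conrow,
                          int p, arma::mat& L) {
  L.zeros(p, p);
  int idx = 0;
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < i; ++j) L(i, j) = theta(idx++);
    if (conrow[i]) {
      double s = 1.0;
      for (int j = 0; j < i; ++j) s -= L(i, j) * L(i, j);
      if (s <= 1e-10) return false;
      L(i, i) = std::sqrt(s);
    } else {
      L(i, i) = std::exp(theta(idx++));
    }
  }
  return true;
}

static arma::vec chol_to_theta(const arma::mat& L, const std::vector<int>& conrow) {
  int p = L.n_rows, nfree = 0;
  for (int i = 0; i < p; ++i) nfree += i + (conrow[i] ? 0 : 1);
  arma::vec theta(nfree);
  int idx = 0;
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < i; ++j) theta(idx++) = L(i, j);
    if (!conrow[i]) theta(idx++) = std::log(L(i, i));
  }
  return theta;
}

// log |d Omega / d theta| for the parametrisation above
static double log_jac(const arma::mat& L, const std::vector<int>& conrow) {
  int p = L.n_rows;
  double lj = 0.0;
  for (int j = 0; j < p; ++j) lj += (p - 1 - j) * std::log(L(j, j));
  for (int i = 0; i < p; ++i)
    if (!conrow[i]) lj += std::log(2.0) + 2.0 * std::log(L(i, i));
  return lj;
}

// inverse-Wishart-form log target: -(nu+p+1)/2 log|Om| - tr(S Om^-1)/2
static double log_target_iw(const arma::mat& Om, double nu_post, const arma::mat& S_post) {
  double ld, sign;
  arma::log_det(ld, sign, Om);
  if (sign <= 0) return -std::numeric_limits<double>::infinity();
  return -0.5 * (nu_post + Om.n_rows + 1) * ld
         - 0.5 * arma::trace(arma::solve(Om, S_post));
}

// Random-walk MH on the constrained space; returns updated Omega.
static arma::mat mh_cov_update(const arma::mat& Om, const std::vector<int>& conrow,
                               double nu_post, const arma::mat& S_post,
                               double step, int inner, int& n_acc, int& n_try) {
  arma::mat L = arma::chol(0.5 * (Om + Om.t()), "lower");
  arma::vec theta = chol_to_theta(L, conrow);
  double lt_cur = log_target_iw(L * L.t(), nu_post, S_post) + log_jac(L, conrow);
  for (int it = 0; it < inner; ++it) {
    arma::vec prop = theta;
    for (arma::uword k = 0; k < prop.n_elem; ++k) prop(k) += step * R::norm_rand();
    arma::mat Lp;
    ++n_try;
    if (!theta_to_chol(prop, conrow, Om.n_rows, Lp)) continue;
    double lt_prop = log_target_iw(Lp * Lp.t(), nu_post, S_post) + log_jac(Lp, conrow);
    if (std::log(R::unif_rand()) < lt_prop - lt_cur) {
      theta = prop; L = Lp; lt_cur = lt_prop; ++n_acc;
    }
  }
  arma::mat out = L * L.t();
  for (int i = 0; i < (int)out.n_rows; ++i)
    if (conrow[i]) out(i, i) = 1.0;   // exact unit diagonal on latent rows
  return out;
}

// ---------------------------------------------------------------------------
// joint covariate/outcome model state
// ---------------------------------------------------------------------------

struct JointModel {
  int n, p, J, p1, p2;
  arma::mat Y;
  arma::imat obs;
  arma::ivec isbin, lev2, clus;
  arma::uvec idx1, idx2;          // level-1 / level-2 column indices
  arma::ivec pos1;                // column -> position within idx1 (-1 if level 2)
  std::vector<arma::uvec> crows;  // rows of each cluster
  arma::uvec firstrow;            // representative row per cluster

  arma::vec alpha;
  arma::mat U;                    // J x p
  arma::mat Om1;                  // p1 x p1 (homoscedastic)
  std::vector<arma::mat> Om1j;    // heteroscedastic
  arma::mat Om2;                  // p x p
  arma::mat Z;                    // n x p

  bool het;
  double iw_a;                    // het: IW degrees of freedom
  arma::mat A;                    // het: IW scale
  double nuA0; arma::mat VA0inv;  // Wishart hyperprior for A

  double nu1_0, nu2_0;
  arma::mat S1_0, S2_0;
  std::vector<int> con1, con2;    // constrained rows of Om1 / Om2
  bool any_con1 = false, any_con2 = false;

  double step1, step2;            // MH step sizes
  int mh_inner;
  int acc_cov = 0, try_cov = 0;

  // missingness bookkeeping
  std::vector<int> miss_rows;                  // rows with >=1 missing level-1 cell
  std::vector<arma::uvec> miss_pos, obs_pos;   // positions within idx1 per such row
  std::vector<std::pair<int,int>> miss2;       // (cluster, column) level-2 missing

  const arma::mat& om1_of(int j) const { return het ? Om1j[j] : Om1; }

  double eres(int i, int a) const {            // level-1 residual, position a
    int k = idx1(a);
    return Z(i, k) - alpha(k) - U(clus(i), k);
  }

  void setup(bool smc_mode) {
    p1 = 0; p2 = 0;
    std::vector<arma::uword> i1, i2;
    pos1.set_size(p); pos1.fill(-1);
    for (int k = 0; k < p; ++k) {
      if (lev2(k)) { i2.push_back(k); }
      else { pos1(k) = p1; i1.push_back(k); ++p1; }
    }
    p2 = (int)i2.size();
    idx1 = arma::uvec(i1); idx2 = arma::uvec(i2);
    crows.resize(J); firstrow.set_size(J);
    std::vector<std::vector<arma::uword>> tmp(J);
    for (int i = 0; i < n; ++i) tmp[clus(i)].push_back(i);
    for (int j = 0; j < J; ++j) { crows[j] = arma::uvec(tmp[j]); firstrow(j) = crows[j](0); }

    con1.assign(p1, 0); con2.assign(p, 0);
    for (int a = 0; a < p1; ++a)
      if (isbin(idx1(a))) { con1[a] = 1; any_con1 = true; }
    for (int b = 0; b < p2; ++b)
      if (isbin(idx2(b))) { con2[idx2(b)] = 1; any_con2 = true; }

    nu1_0 = p1 + 1; S1_0 = arma::eye(p1, p1);
    nu2_0 = p + 1;  S2_0 = arma::eye(p, p);

    // missingness lists
    for (int i = 0; i < n; ++i) {
      std::vector<arma::uword> m, o;
      for (int a = 0; a < p1; ++a) {
        if (obs(i, idx1(a))) o.push_back(a); else m.push_back(a);
      }
      if (!m.empty()) {
        miss_rows.push_back(i);
        miss_pos.push_back(arma::uvec(m));
        obs_pos.push_back(arma::uvec(o));
      }
    }
    for (int b = 0; b < p2; ++b) {
      int k = idx2(b);
      for (int j = 0; j < J; ++j)
        if (!obs(firstrow(j), k)) miss2.push_back(std::make_pair(j, k));
    }
    (void)smc_mode;
  }

  // --- latent refresh for binary columns -----------------------------------
  // include_missing: also refresh latents of imputed cells, truncated to the
  // current imputed value (used in SMC mode to keep the chain mixing).
  void refresh_latents(bool include_missing) {
    // level-1 binary columns
    for (int a = 0; a < p1; ++a) {
      int k = idx1(a);
      if (!isbin(k)) continue;
      for (int j = 0; j < J; ++j) {
        const arma::mat& Om = om1_of(j);
        arma::vec bcoef; double s2 = Om(a, a);
        if (p1 > 1) {
          arma::uvec rest(p1 - 1); int c = 0;
          for (int t = 0; t < p1; ++t) if (t != a) rest(c++) = t;
          arma::mat Orr = Om.submat(rest, rest);
          arma::vec ora = Om.submat(rest, arma::uvec{(arma::uword)a});
          bcoef = arma::solve(Orr, ora);
          s2 = Om(a, a) - arma::dot(ora, bcoef);
          const arma::uvec& rows = crows[j];
          for (arma::uword ridx = 0; ridx < rows.n_elem; ++ridx) {
            int i = rows(ridx);
            if (!obs(i, k) && !include_missing) continue;
            double adj = 0.0; int c2 = 0;
            for (int t = 0; t < p1; ++t) if (t != a) adj += bcoef(c2++) * eres(i, t);
            double mu = alpha(k) + U(j, k) + adj;
            Z(i, k) = rtnorm_one(mu, std::sqrt(std::max(s2, 1e-12)), (int)(Y(i, k) >= 0.5));
          }
        } else {
          const arma::uvec& rows = crows[j];
          for (arma::uword ridx = 0; ridx < rows.n_elem; ++ridx) {
            int i = rows(ridx);
            if (!obs(i, k) && !include_missing) continue;
            double mu = alpha(k) + U(j, k);
            Z(i, k) = rtnorm_one(mu, std::sqrt(std::max(s2, 1e-12)), (int)(Y(i, k) >= 0.5));
          }
        }
      }
    }
    // level-2 binary columns: cluster-level truncated draw from Omega2
    for (int b = 0; b < p2; ++b) {
      int k = idx2(b);
      if (!isbin(k)) continue;
      arma::uvec rest(p - 1); int c = 0;
      for (int t = 0; t < p; ++t) if (t != k) rest(c++) = t;
      arma::mat Orr = Om2.submat(rest, rest);
      arma::vec ora = Om2.submat(rest, arma::uvec{(arma::uword)k});
      arma::vec bcoef = arma::solve(Orr, ora);
      double s2 = Om2(k, k) - arma::dot(ora, bcoef);
      for (int j = 0; j < J; ++j) {
        if (!obs(firstrow(j), k) && !include_missing) continue;
        double mu = alpha(k) + arma::dot(bcoef, U.submat(arma::uvec{(arma::uword)j}, rest).t());
        double z = rtnorm_one(mu, std::sqrt(std::max(s2, 1e-12)),
                              (int)(Y(firstrow(j), k) >= 0.5));
        U(j, k) = z - alpha(k);
        const arma::uvec& rows = crows[j];
        for (arma::uword r = 0; r < rows.n_elem; ++r) Z(rows(r), k) = z;
      }
    }
  }

  // conditional (mean, cov) of missing level-1 residuals of one row
  void cond_level1(int which, arma::vec& mu, arma::mat& Sig) const {
    int i = miss_rows[which];
    const arma::uvec& m = miss_pos[which];
    const arma::uvec& o = obs_pos[which];
    const arma::mat& Om = om1_of(clus(i));
    if (o.n_elem == 0) { mu = arma::zeros(m.n_elem); Sig = Om.submat(m, m); return; }
    arma::vec eo(o.n_elem);
    for (arma::uword t = 0; t < o.n_elem; ++t) eo(t) = eres(i, o(t));
    arma::mat Ooo = Om.submat(o, o);
    arma::mat Omo = Om.submat(m, o);
    arma::mat W = arma::solve(Ooo, Omo.t()).t();   // m x o
    mu  = W * eo;
    Sig = Om.submat(m, m) - W * Omo.t();
  }

  void set_level1_cell(int i, int a, double znew) {
    int k = idx1(a);
    Z(i, k) = znew;
    Y(i, k) = isbin(k) ? (znew >= 0.0 ? 1.0 : 0.0) : znew;
  }

  // Gibbs draw of all missing cells (standard JM imputation)
  void draw_missing_gibbs() {
    for (size_t w = 0; w < miss_rows.size(); ++w) {
      arma::vec mu; arma::mat Sig;
      cond_level1((int)w, mu, Sig);
      arma::vec e = rmvnorm_chol(mu, Sig);
      int i = miss_rows[w];
      const arma::uvec& m = miss_pos[w];
      for (arma::uword t = 0; t < m.n_elem; ++t) {
        int k = idx1(m(t));
        set_level1_cell(i, m(t), alpha(k) + U(clus(i), k) + e(t));
      }
    }
    for (size_t w = 0; w < miss2.size(); ++w) {
      int j = miss2[w].first, k = miss2[w].second;
      double mu, s2;
      cond_level2(j, k, mu, s2);
      double u = mu + std::sqrt(std::max(s2, 1e-12)) * R::norm_rand();
      set_level2_value(j, k, u);
    }
  }

  // conditional of U(j,k) given the other components of U(j,.) under Omega2
  void cond_level2(int j, int k, double& mu, double& s2) const {
    arma::uvec rest(p - 1); int c = 0;
    for (int t = 0; t < p; ++t) if (t != k) rest(c++) = t;
    arma::mat Orr = Om2.submat(rest, rest);
    arma::vec ora = Om2.submat(rest, arma::uvec{(arma::uword)k});
    arma::vec bcoef = arma::solve(Orr, ora);
    mu = arma::dot(bcoef, U.submat(arma::uvec{(arma::uword)j}, rest).t());
    s2 = Om2(k, k) - arma::dot(ora, bcoef);
  }

  void set_level2_value(int j, int k, double u) {
    U(j, k) = u;
    double z = alpha(k) + u;
    double val = isbin(k) ? (z >= 0.0 ? 1.0 : 0.0) : z;
    const arma::uvec& rows = crows[j];
    for (arma::uword r = 0; r < rows.n_elem; ++r) { Z(rows(r), k) = z; Y(rows(r), k) = val; }
  }

  // --- parameter updates ----------------------------------------------------
  void update_u() {
    arma::mat B12; arma::mat Scond;
    arma::uvec u1 = idx1, u2 = idx2;
    if (p2 > 0) {
      arma::mat O11 = Om2.submat(u1, u1), O12 = Om2.submat(u1, u2), O22 = Om2.submat(u2, u2);
      B12 = arma::solve(O22, O12.t()).t();         // p1 x p2
      Scond = O11 - B12 * O12.t();
    } else {
      Scond = Om2.submat(u1, u1);
    }
    arma::mat Sci = safe_inv(Scond);
    for (int j = 0; j < J; ++j) {
      arma::mat O1i = safe_inv(om1_of(j));
      const arma::uvec& rows = crows[j];
      arma::vec sumz = arma::zeros(p1);
      for (arma::uword r = 0; r < rows.n_elem; ++r) {
        int i = rows(r);
        for (int a = 0; a < p1; ++a) sumz(a) += Z(i, idx1(a)) - alpha(idx1(a));
      }
      arma::vec mprior = arma::zeros(p1);
      if (p2 > 0) {
        arma::vec u2j(p2);
        for (int b = 0; b < p2; ++b) u2j(b) = U(j, idx2(b));
        mprior = B12 * u2j;
      }
      arma::mat prec = Sci + (double)rows.n_elem * O1i;
      arma::mat cov = safe_inv(prec);
      arma::vec mean = cov * (Sci * mprior + O1i * sumz);
      arma::vec unew = rmvnorm_chol(mean, cov);
      for (int a = 0; a < p1; ++a) U(j, idx1(a)) = unew(a);
    }
  }

  arma::mat resid1() const {
    arma::mat E(n, p1);
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < p1; ++a) E(i, a) = eres(i, a);
    return E;
  }

  void update_om1() {
    if (!het) {
      arma::mat E = resid1();
      arma::mat SSE = E.t() * E;
      if (!any_con1) {
        Om1 = riwish(nu1_0 + n, S1_0 + SSE);
      } else {
        Om1 = mh_cov_update(Om1, con1, nu1_0 + n, S1_0 + SSE,
                            step1, mh_inner, acc_cov, try_cov);
      }
    } else {
      arma::mat sum_inv = arma::zeros(p1, p1);
      for (int j = 0; j < J; ++j) {
        const arma::uvec& rows = crows[j];
        arma::mat SSE = arma::zeros(p1, p1);
        arma::vec e(p1);
        for (arma::uword r = 0; r < rows.n_elem; ++r) {
          int i = rows(r);
          for (int a = 0; a < p1; ++a) e(a) = eres(i, a);
          SSE += e * e.t();
        }
        if (!any_con1) {
          Om1j[j] = riwish(iw_a + rows.n_elem, A + SSE);
        } else {
          Om1j[j] = mh_cov_update(Om1j[j], con1, iw_a + rows.n_elem, A + SSE,
                                  step1, mh_inner, acc_cov, try_cov);
        }
        sum_inv += safe_inv(Om1j[j]);
      }
      // conjugate Wishart update of the scale hyperparameter A
      A = rwish(nuA0 + J * iw_a, safe_inv(VA0inv + sum_inv));
    }
  }

  void update_om2() {
    arma::mat UU = U.t() * U;
    if (!any_con2) {
      Om2 = riwish(nu2_0 + J, S2_0 + UU);
    } else {
      Om2 = mh_cov_update(Om2, con2, nu2_0 + J, S2_0 + UU,
                          step2, mh_inner, acc_cov, try_cov);
    }
  }

  void update_alpha() {
    // level-1 intercepts: flat prior, conjugate normal (GLS across clusters)
    if (p1 > 0) {
      arma::mat prec = arma::zeros(p1, p1);
      arma::vec lin = arma::zeros(p1);
      for (int j = 0; j < J; ++j) {
        arma::mat O1i = safe_inv(om1_of(j));
        const arma::uvec& rows = crows[j];
        arma::vec sumr = arma::zeros(p1);
        for (arma::uword r = 0; r < rows.n_elem; ++r) {
          int i = rows(r);
          for (int a = 0; a < p1; ++a) sumr(a) += Z(i, idx1(a)) - U(j, idx1(a));
        }
        prec += (double)rows.n_elem * O1i;
        lin += O1i * sumr;
      }
      arma::mat cov = safe_inv(prec);
      arma::vec anew = rmvnorm_chol(cov * lin, cov);
      for (int a = 0; a < p1; ++a) alpha(idx1(a)) = anew(a);
    }
    // level-2 intercepts given the level-1 random effects
    if (p2 > 0) {
      arma::uvec u1 = idx1, u2 = idx2;
      arma::mat O11 = Om2.submat(u1, u1), O21 = Om2.submat(u2, u1), O22 = Om2.submat(u2, u2);
      arma::mat B21 = arma::solve(O11, O21.t()).t();   // p2 x p1
      arma::mat C = O22 - B21 * O21.t();
      arma::vec msum = arma::zeros(p2);
      for (int j = 0; j < J; ++j) {
        arma::vec u1j(p1);
        for (int a = 0; a < p1; ++a) u1j(a) = U(j, idx1(a));
        arma::vec pred = (p1 > 0) ? arma::vec(B21 * u1j) : arma::zeros(p2);
        for (int b = 0; b < p2; ++b) msum(b) += Z(firstrow(j), idx2(b)) - pred(b);
      }
      arma::vec anew = rmvnorm_chol(msum / (double)J, C / (double)J);
      for (int b = 0; b < p2; ++b) {
        int k = idx2(b);
        alpha(k) = anew(b);
        for (int j = 0; j < J; ++j) U(j, k) = Z(firstrow(j), k) - alpha(k);
      }
    }
  }
};

// ---------------------------------------------------------------------------
// substantive model
// ---------------------------------------------------------------------------

struct SubModel {
  int family;        // 0 gaussian, 1 binomial logit, 2 ordinal cumulative logit
  arma::imat terms;  // q x 4: (v1, pow1, v2, pow2); v = -1 means constant 1
  arma::ivec rcols;  // random-effect design: -1 intercept, else column index
  int q, r, K;
  arma::vec beta;
  arma::mat usub;    // J x r
  arma::mat omu;     // r x r
  double sig2e;
  arma::vec cut;     // K-1 ordinal cutpoints
  double nu_u0; arma::mat S_u0;

  double xterm(const arma::mat& Y, int i, int t) const {
    double v = 1.0;
    int v1 = terms(t, 0), p1 = terms(t, 1), v2 = terms(t, 2), p2 = terms(t, 3);
    if (v1 >= 0) v *= std::pow(Y(i, v1), (double)p1);
    if (v2 >= 0) v *= std::pow(Y(i, v2), (double)p2);
    return v;
  }

  double eta(const arma::mat& Y, int i, int j) const {
    double e = 0.0;
    for (int t = 0; t < q; ++t) e += beta(t) * xterm(Y, i, t);
    for (int s = 0; s < r; ++s)
      e += usub(j, s) * (rcols(s) < 0 ? 1.0 : Y(i, rcols(s)));
    return e;
  }

  double loglik_row(const arma::mat& Y, const arma::vec& yout, int i, int j) const {
    double e = eta(Y, i, j);
    if (family == 0) {
      double d = yout(i) - e;
      return -0.5 * std::log(2.0 * M_PI * sig2e) - d * d / (2.0 * sig2e);
    } else if (family == 1) {
      double lse = (e > 30.0) ? e : std::log1p(std::exp(e));
      return yout(i) * e - lse;
    } else {
      int k = (int)yout(i);
      double up = (k < K) ? R::plogis(cut(k - 1) - e, 0.0, 1.0, 1, 0) : 1.0;
      double lo = (k > 1) ? R::plogis(cut(k - 2) - e, 0.0, 1.0, 1, 0) : 0.0;
      return std::log(std::max(up - lo, 1e-300));
    }
  }

  double loglik_all(const arma::mat& Y, const arma::vec& yout, const arma::ivec& clus) const {
    double s = 0.0;
    for (arma::uword i = 0; i < yout.n_elem; ++i) s += loglik_row(Y, yout, i, clus(i));
    return s;
  }

  arma::mat design(const arma::mat& Y) const {
    arma::mat X(Y.n_rows, q);
    for (arma::uword i = 0; i < Y.n_rows; ++i)
      for (int t = 0; t < q; ++t) X(i, t) = xterm(Y, i, t);
    return X;
  }

  arma::mat rdesign(const arma::mat& Y) const {
    arma::mat Zr(Y.n_rows, r);
    for (arma::uword i = 0; i < Y.n_rows; ++i)
      for (int s = 0; s < r; ++s) Zr(i, s) = (rcols(s) < 0 ? 1.0 : Y(i, rcols(s)));
    return Zr;
  }

  // one Bayesian update sweep of the substantive parameters
  void update(const arma::mat& Y, const arma::vec& yout, const arma::ivec& clus,
              const std::vector<arma::uvec>& crows) {
    int n = (int)yout.n_elem, J = (int)crows.size();
    arma::mat X = design(Y), Zr = rdesign(Y);
    if (family == 0) {
      // beta | rest
      arma::vec resid_u(n);
      for (int i = 0; i < n; ++i)
        resid_u(i) = yout(i) - arma::dot(Zr.row(i), usub.row(clus(i)));
      arma::mat XtX = X.t() * X;
      arma::mat XtXi = safe_inv(XtX);
      arma::vec bhat = XtXi * (X.t() * resid_u);
      beta = rmvnorm_chol(bhat, sig2e * XtXi);
      // u_j | rest
      arma::mat Omui = safe_inv(omu);
      for (int j = 0; j < J; ++j) {
        const arma::uvec& rows = crows[j];
        arma::mat ZtZ = arma::zeros(r, r);
        arma::vec Ztr = arma::zeros(r);
        for (arma::uword rr = 0; rr < rows.n_elem; ++rr) {
          int i = rows(rr);
          arma::vec z = Zr.row(i).t();
          ZtZ += z * z.t();
          Ztr += z * (yout(i) - arma::dot(X.row(i), beta));
        }
        arma::mat prec = ZtZ / sig2e + Omui;
        arma::mat cov = safe_inv(prec);
        arma::vec mean = cov * (Ztr / sig2e);
        usub.row(j) = rmvnorm_chol(mean, cov).t();
      }
      // omega_u and sigma2_e
      omu = riwish(nu_u0 + J, S_u0 + usub.t() * usub);
      double sse = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = yout(i) - arma::dot(X.row(i), beta) - arma::dot(Zr.row(i), usub.row(clus(i)));
        sse += d * d;
      }
      sig2e = 1.0 / R::rgamma(0.001 + 0.5 * n, 1.0 / (0.001 + 0.5 * sse));
    } else {
      // random-walk MH for beta (joint proposal scaled by the logistic
      // information approximation), then per-cluster random effects
      arma::mat XtX = X.t() * X * 0.25;
      XtX.diag() += 1e-8;
      arma::mat Lprop = arma::chol(safe_inv(XtX), "lower");
      double ll_cur = loglik_all(Y, yout, clus);
      for (int rep = 0; rep < 3; ++rep) {
        arma::vec eps(q);
        for (int t = 0; t < q; ++t) eps(t) = R::norm_rand();
        arma::vec bold = beta;
        beta = bold + 0.8 * (Lprop * eps);
        double ll_prop = loglik_all(Y, yout, clus);
        if (std::log(R::unif_rand()) < ll_prop - ll_cur) ll_cur = ll_prop;
        else beta = bold;
      }
      arma::mat Omui = safe_inv(omu);
      for (int j = 0; j < J; ++j) {
        const arma::uvec& rows = crows[j];
        arma::vec uold = usub.row(j).t();
        arma::vec uprop = uold;
        for (int s = 0; s < r; ++s) uprop(s) += 0.3 * R::norm_rand();
        double d = 0.0;
        d -= 0.5 * arma::as_scalar(uprop.t() * Omui * uprop - uold.t() * Omui * uold);
        usub.row(j) = uprop.t();
        for (arma::uword rr = 0; rr < rows.n_elem; ++rr) d += loglik_row(Y, yout, rows(rr), j);
        usub.row(j) = uold.t();
        for (arma::uword rr = 0; rr < rows.n_elem; ++rr) d -= loglik_row(Y, yout, rows(rr), j);
        if (std::log(R::unif_rand()) < d) usub.row(j) = uprop.t();
      }
      omu = riwish(nu_u0 + J, S_u0 + usub.t() * usub);
      if (family == 2) {
        for (int k = 0; k < K - 1; ++k) {
          double prop = cut(k) + 0.1 * R::norm_rand();
          if ((k > 0 && prop <= cut(k - 1)) || (k < K - 2 && prop >= cut(k + 1))) continue;
          double old = cut(k);
          double ll0 = loglik_all(Y, yout, clus);
          cut(k) = prop;
          double ll1 = loglik_all(Y, yout, clus);
          if (std::log(R::unif_rand()) >= ll1 - ll0) cut(k) = old;
        }
      }
    }
  }
};

// ---------------------------------------------------------------------------
// shared plumbing
// ---------------------------------------------------------------------------

static void init_joint(JointModel& jm, const arma::mat& Y, const arma::imat& obs,
                       const arma::ivec& isbin, const arma::ivec& lev2,
                       const arma::ivec& clus, int J, double mh_step, int mh_inner,
                       bool het, double iw_a, const List& init, bool smc_mode) {
  jm.n = Y.n_rows; jm.p = Y.n_cols; jm.J = J;
  jm.Y = Y; jm.obs = obs; jm.isbin = isbin; jm.lev2 = lev2; jm.clus = clus;
  jm.het = het; jm.iw_a = iw_a; jm.mh_inner = mh_inner;
  jm.setup(smc_mode);
  jm.alpha = as<arma::vec>(init["alpha"]);
  jm.U = as<arma::mat>(init["u"]);
  jm.Om1 = as<arma::mat>(init["omega1"]);
  jm.Om2 = as<arma::mat>(init["omega2"]);
  jm.Z = as<arma::mat>(init["z"]);
  // proposal sd scales with posterior concentration (~1/sqrt(rows)) and
  // with the dimension of the free parametrisation (random-walk optimal
  // scaling), so the default mh_step behaves across problem sizes
  int ncon1 = 0, ncon2 = 0;
  for (int a = 0; a < jm.p1; ++a) ncon1 += jm.con1[a];
  for (int k = 0; k < jm.p; ++k) ncon2 += jm.con2[k];
  double d1 = std::max(jm.p1 * (jm.p1 + 1) / 2 - ncon1, 1);
  double d2 = std::max(jm.p * (jm.p + 1) / 2 - ncon2, 1);
  jm.step1 = mh_step * 10.0 / std::sqrt((double)std::max(jm.n, 2) * d1);
  jm.step2 = mh_step * 10.0 / std::sqrt((double)std::max(jm.J, 2) * d2);
  if (het) {
    jm.Om1j.assign(J, jm.Om1);
    if (init.containsElementNamed("omega1_by_cluster")) {
      List ol = init["omega1_by_cluster"];
      if (ol.size() == J)
        for (int j = 0; j < J; ++j) jm.Om1j[j] = as<arma::mat>(ol[j]);
    }
    if (init.containsElementNamed("iw_scale") && !Rf_isNull(init["iw_scale"])) {
      jm.A = as<arma::mat>(init["iw_scale"]);
    } else {
      jm.A = (iw_a - jm.p1 - 1) * jm.Om1;
    }
    jm.nuA0 = jm.p1 + 1;
    jm.VA0inv = safe_inv(jm.A / jm.nuA0);
    // per-cluster updates see few rows; widen the proposal accordingly
    jm.step1 = mh_step * 10.0 /
      std::sqrt((double)std::max(jm.n / std::max(J, 1), 2) * d1);
  }
}

static List state_list(const JointModel& jm) {
  List st = List::create(_["alpha"] = jm.alpha, _["u"] = jm.U,
                         _["omega1"] = jm.Om1, _["omega2"] = jm.Om2,
                         _["z"] = jm.Z, _["values"] = jm.Y);
  if (jm.het) {
    List ol(jm.J);
    for (int j = 0; j < jm.J; ++j) ol[j] = jm.Om1j[j];
    st["omega1_by_cluster"] = ol;
    st["iw_scale"] = jm.A;
    st["iw_df"] = jm.iw_a;
  }
  return st;
}

static int tri_len(int p) { return p * (p + 1) / 2; }

static void record_tri(arma::rowvec& row, int& pos, const arma::mat& M) {
  int p = M.n_rows;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j <= i; ++j) row(pos++) = M(i, j);
}

// ---------------------------------------------------------------------------
// exported samplers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_rtnorm(IntegerVector value, NumericVector mean, NumericVector sd) {
  int n = value.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm_one(mean[i], sd[i], value[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_jm_mcmc(arma::mat Y, arma::imat obs, arma::ivec isbin, arma::ivec lev2,
                 arma::ivec clus, int J, int n_iter, arma::ivec register_iters,
                 double mh_step, int mh_inner, bool het, double iw_a,
                 List init, bool record_cells) {
  JointModel jm;
  init_joint(jm, Y, obs, isbin, lev2, clus, J, mh_step, mh_inner, het, iw_a, init, false);

  int nchain = jm.p + tri_len(jm.p1) + tri_len(jm.p) + (het ? tri_len(jm.p1) : 0);
  arma::mat chains(n_iter, nchain);
  List imps(register_iters.n_elem);
  int next_reg = 0;
  int ncells = 0;
  for (size_t w = 0; w < jm.miss_rows.size(); ++w) ncells += jm.miss_pos[w].n_elem;
  ncells += (int)jm.miss2.size();
  arma::mat cell_trace;
  if (record_cells) cell_trace.set_size(n_iter, ncells);

  for (int it = 0; it < n_iter; ++it) {
    jm.refresh_latents(false);
    jm.draw_missing_gibbs();
    jm.update_u();
    jm.update_om1();
    jm.update_om2();
    jm.update_alpha();

    arma::rowvec row(nchain); int pos = 0;
    for (int k = 0; k < jm.p; ++k) row(pos++) = jm.alpha(k);
    if (jm.het) {
      // summarise the cluster-specific covariances by their mean
      arma::mat Om1bar = arma::zeros(jm.p1, jm.p1);
      for (int j = 0; j < jm.J; ++j) Om1bar += jm.Om1j[j];
      record_tri(row, pos, Om1bar / jm.J);
    } else {
      record_tri(row, pos, jm.Om1);
    }
    record_tri(row, pos, jm.Om2);
    if (het) record_tri(row, pos, jm.A);
    chains.row(it) = row;

    if (record_cells) {
      int cpos = 0;
      for (size_t w = 0; w < jm.miss_rows.size(); ++w)
        for (arma::uword t = 0; t < jm.miss_pos[w].n_elem; ++t)
          cell_trace(it, cpos++) = jm.Y(jm.miss_rows[w], jm.idx1(jm.miss_pos[w](t)));
      for (size_t w = 0; w < jm.miss2.size(); ++w)
        cell_trace(it, cpos++) = jm.Y(jm.firstrow(jm.miss2[w].first), jm.miss2[w].second);
    }
    if (next_reg < (int)register_iters.n_elem && it + 1 == register_iters(next_reg)) {
      imps[next_reg] = jm.Y;
      ++next_reg;
    }
  }

  List out = List::create(_["imputations"] = imps, _["chains"] = chains,
                          _["state"] = state_list(jm),
                          _["accept_cov"] = (jm.try_cov > 0 ? (double)jm.acc_cov / jm.try_cov : NA_REAL));
  if (record_cells) out["cell_trace"] = cell_trace;
  return out;
}

// [[Rcpp::export]]
List cpp_smc_mcmc(arma::mat Y, arma::imat obs, arma::ivec isbin, arma::ivec lev2,
                  arma::ivec clus, int J,
                  arma::vec yout, int family, arma::imat terms, arma::ivec rcols, int n_cat,
                  int n_iter, arma::ivec register_iters,
                  double mh_step, int mh_inner, bool het, double iw_a,
                  List init_cov, List init_sub,
                  bool freeze_cov, bool freeze_sub, bool record_cells) {
  JointModel jm;
  init_joint(jm, Y, obs, isbin, lev2, clus, J, mh_step, mh_inner, het, iw_a, init_cov, true);

  SubModel sm;
  sm.family = family; sm.terms = terms; sm.rcols = rcols;
  sm.q = terms.n_rows; sm.r = rcols.n_elem; sm.K = n_cat;
  sm.beta = as<arma::vec>(init_sub["beta"]);
  sm.usub = as<arma::mat>(init_sub["u_sub"]);
  sm.omu = as<arma::mat>(init_sub["omega_u"]);
  sm.sig2e = as<double>(init_sub["sigma2_e"]);
  sm.cut = init_sub.containsElementNamed("cutpoints") && !Rf_isNull(init_sub["cutpoints"])
             ? as<arma::vec>(init_sub["cutpoints"]) : arma::vec();
  sm.nu_u0 = sm.r + 2;
  sm.S_u0 = 0.01 * arma::eye(sm.r, sm.r);

  int nsub = sm.q + tri_len(sm.r) + (family == 0 ? 1 : 0) + (family == 2 ? sm.K - 1 : 0);
  int nchain = jm.p + tri_len(jm.p1) + tri_len(jm.p) + nsub;
  arma::mat chains(n_iter, nchain);
  List imps(register_iters.n_elem);
  int next_reg = 0;

  int ncells = 0;
  for (size_t w = 0; w < jm.miss_rows.size(); ++w) ncells += jm.miss_pos[w].n_elem;
  ncells += (int)jm.miss2.size();
  arma::mat cell_trace;
  if (record_cells) cell_trace.set_size(n_iter, ncells);
  long acc_cell = 0, try_cell = 0;

  for (int it = 0; it < n_iter; ++it) {
    jm.refresh_latents(true);

    // Metropolis-Hastings imputation of the missing covariate cells: one
    // proposal per cell from the covariate-model conditional; the covariate
    // factor cancels, leaving the substantive-likelihood ratio.
    for (size_t w = 0; w < jm.miss_rows.size(); ++w) {
      int i = jm.miss_rows[w];
      int j = jm.clus(i);
      const arma::uvec& m = jm.miss_pos[w];
      const arma::mat& Om = jm.om1_of(j);
      for (arma::uword t = 0; t < m.n_elem; ++t) {
        int a = m(t), k = jm.idx1(a);
        // conditional on all other level-1 components at current values
        arma::vec bcoef; double s2 = Om(a, a), adj = 0.0;
        if (jm.p1 > 1) {
          arma::uvec rest(jm.p1 - 1); int c = 0;
          for (int tt = 0; tt < jm.p1; ++tt) if (tt != a) rest(c++) = tt;
          arma::mat Orr = Om.submat(rest, rest);
          arma::vec ora = Om.submat(rest, arma::uvec{(arma::uword)a});
          bcoef = arma::solve(Orr, ora);
          s2 = Om(a, a) - arma::dot(ora, bcoef);
          int c2 = 0;
          for (int tt = 0; tt < jm.p1; ++tt) if (tt != a) adj += bcoef(c2++) * jm.eres(i, tt);
        }
        double mu = jm.alpha(k) + jm.U(j, k) + adj;
        double zprop = mu + std::sqrt(std::max(s2, 1e-12)) * R::norm_rand();
        double vprop = jm.isbin(k) ? (zprop >= 0.0 ? 1.0 : 0.0) : zprop;
        double zold = jm.Z(i, k), vold = jm.Y(i, k);
        ++try_cell;
        double ll0 = sm.loglik_row(jm.Y, yout, i, j);
        jm.Y(i, k) = vprop;
        double ll1 = sm.loglik_row(jm.Y, yout, i, j);
        if (std::log(R::unif_rand()) < ll1 - ll0) {
          jm.Z(i, k) = zprop; ++acc_cell;
        } else {
          jm.Y(i, k) = vold; jm.Z(i, k) = zold;
        }
      }
    }
    // level-2 cells: acceptance on the cluster's summed log-likelihood
    for (size_t w = 0; w < jm.miss2.size(); ++w) {
      int j = jm.miss2[w].first, k = jm.miss2[w].second;
      double mu, s2;
      jm.cond_level2(j, k, mu, s2);
      double uprop = mu + std::sqrt(std::max(s2, 1e-12)) * R::norm_rand();
      double zprop = jm.alpha(k) + uprop;
      double vprop = jm.isbin(k) ? (zprop >= 0.0 ? 1.0 : 0.0) : zprop;
      double uold = jm.U(j, k);
      double vold = jm.Y(jm.firstrow(j), k);
      double zold = jm.Z(jm.firstrow(j), k);
      const arma::uvec& rows = jm.crows[j];
      ++try_cell;
      double d = 0.0;
      for (arma::uword rr = 0; rr < rows.n_elem; ++rr)
        d -= sm.loglik_row(jm.Y, yout, rows(rr), j);
      for (arma::uword rr = 0; rr < rows.n_elem; ++rr) jm.Y(rows(rr), k) = vprop;
      for (arma::uword rr = 0; rr < rows.n_elem; ++rr)
        d += sm.loglik_row(jm.Y, yout, rows(rr), j);
      if (std::log(R::unif_rand()) < d) {
        jm.U(j, k) = uprop; ++acc_cell;
        for (arma::uword rr = 0; rr < rows.n_elem; ++rr) jm.Z(rows(rr), k) = zprop;
      } else {
        jm.U(j, k) = uold;
        for (arma::uword rr = 0; rr < rows.n_elem; ++rr) {
          jm.Y(rows(rr), k) = vold; jm.Z(rows(rr), k) = zold;
        }
      }
    }

    if (!freeze_cov) {
      jm.update_u();
      jm.update_om1();
      jm.update_om2();
      jm.update_alpha();
    }
    if (!freeze_sub) sm.update(jm.Y, yout, jm.clus, jm.crows);

    arma::rowvec row(nchain); int pos = 0;
    for (int k = 0; k < jm.p; ++k) row(pos++) = jm.alpha(k);
    if (jm.het) {
      // summarise the cluster-specific covariances by their mean
      arma::mat Om1bar = arma::zeros(jm.p1, jm.p1);
      for (int j = 0; j < jm.J; ++j) Om1bar += jm.Om1j[j];
      record_tri(row, pos, Om1bar / jm.J);
    } else {
      record_tri(row, pos, jm.Om1);
    }
    record_tri(row, pos, jm.Om2);
    for (int t = 0; t < sm.q; ++t) row(pos++) = sm.beta(t);
    record_tri(row, pos, sm.omu);
    if (family == 0) row(pos++) = sm.sig2e;
    if (family == 2) for (int k = 0; k < sm.K - 1; ++k) row(pos++) = sm.cut(k);
    chains.row(it) = row;

    if (record_cells) {
      int cpos = 0;
      for (size_t w = 0; w < jm.miss_rows.size(); ++w)
        for (arma::uword t = 0; t < jm.miss_pos[w].n_elem; ++t)
          cell_trace(it, cpos++) = jm.Y(jm.miss_rows[w], jm.idx1(jm.miss_pos[w](t)));
      for (size_t w = 0; w < jm.miss2.size(); ++w)
        cell_trace(it, cpos++) = jm.Y(jm.firstrow(jm.miss2[w].first), jm.miss2[w].second);
    }
    if (next_reg < (int)register_iters.n_elem && it + 1 == register_iters(next_reg)) {
      imps[next_reg] = jm.Y;
      ++next_reg;
    }
  }

  List sub = List::create(_["beta"] = sm.beta, _["u_sub"] = sm.usub,
                          _["omega_u"] = sm.omu, _["sigma2_e"] = sm.sig2e,
                          _["cutpoints"] = sm.cut);
  List out = List::create(_["imputations"] = imps, _["chains"] = chains,
                          _["state"] = state_list(jm), _["substantive"] = sub,
                          _["accept_cell"] = (try_cell > 0 ? (double)acc_cell / try_cell : NA_REAL),
                          _["accept_cov"] = (jm.try_cov > 0 ? (double)jm.acc_cov / jm.try_cov : NA_REAL));
  if (record_cells) out["cell_trace"] = cell_trace;
  return out;
}
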