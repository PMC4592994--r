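// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "samplers.h"
using namespace Rcpp;

// One draw of beta | ELSE ~ N(mean, P^{-1}) with
//   P    = Sigma0inv / sigma2_beta + X' D_omega X
//   mean = P^{-1} (Sigma0inv beta0 / sigma2_beta + X' D_omega resid)
// resid is the liability net of the polygenic part (l - Zb).
//
// Two exact routes: the direct p x p factorization, and an n-dimensional
// auxiliary-variable draw (Bhattacharya-Chakraborty-Mallick) for the ridge
// prior beta ~ N(0, v I sigma2_beta) when p >> n. Both sample the identical
// distribution.
static arma::vec draw_beta(const arma::mat& X, const arma::vec& omega,
                           const arma::vec& resid, const arma::vec& beta0,
                           const arma::mat& Sigma0inv, double sigma2_beta,
                           bool improper, double sigma0_scalar,
                           bool use_woodbury) {
  int n = X.n_rows, p = X.n_cols;
  if (use_woodbury) {
    double tau2 = sigma0_scalar * sigma2_beta; // prior variance of each beta_j
    arma::vec sqw = arma::sqrt(omega);
    arma::mat Phi = X.each_col() % sqw;    // n x p
    arma::vec alpha = sqw % resid;
    arma::vec u(p), delta(n);
    for (int j = 0; j < p; ++j) u[j] = std::sqrt(tau2) * norm_rand();
    for (int i = 0; i < n; ++i) delta[i] = norm_rand();
    arma::vec v = Phi * u + delta;
    arma::mat M = tau2 * (Phi * Phi.t());
    M.diag() += 1.0;
    arma::vec w = arma::solve(M, alpha - v, arma::solve_opts::likely_sympd);
    return u + tau2 * (Phi.t() * w);
  }
  arma::mat P = X.t() * (X.each_col() % omega);
  arma::vec rhs = X.t() * (omega % resid);
  if (!improper) {
    P += Sigma0inv / sigma2_beta;
    rhs += Sigma0inv * beta0 / sigma2_beta;
  }
  arma::mat R;
  if (!arma::chol(R, P))
    stop("posterior precision of beta is not positive definite (rank-deficient X'DX under an improper prior?)");
  arma::vec mean = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), rhs));
  arma::vec z(p);
  for (int j = 0; j < p; ++j) z[j] = norm_rand();
  return mean + arma::solve(arma::trimatu(R), z);
}

// Exposed for conjugate-oracle and ridge-equivalence tests
// [[Rcpp::export]]
arma::mat cpp_beta_draws(int ndraws, const arma::mat& X,
                         const arma::vec& omega, const arma::vec& resid,
                         const arma::vec& beta0, const arma::mat& Sigma0inv,
                         double sigma2_beta, bool improper,
                         double sigma0_scalar, bool use_woodbury) {
  arma::mat out(ndraws, X.n_cols);
  for (int s = 0; s < ndraws; ++s)
    out.row(s) = draw_beta(X, omega, resid, beta0, Sigma0inv, sigma2_beta,
                           improper, sigma0_scalar, use_woodbury).t();
  return out;
}

// Full Gibbs sweep for the latent-liability cumulative-link model.
// y in 1..C; line in 1..I (empty -> no polygenic term); Ginv is the inverse
// relationship matrix (I x I, ignored when no polygenic term).
// [[Rcpp::export]]
List cpp_gibbs(const IntegerVector& y, const arma::mat& X,
               const IntegerVector& line, const arma::mat& Ginv,
               int C, const List& prior, const List& config) {
  int n = X.n_rows, p = X.n_cols;
  bool polygenic = line.size() > 0;
  int I = 0;
  if (polygenic) I = Rcpp::max(line);

  arma::vec beta0 = prior["beta0"];
  arma::mat Sigma0inv = prior["Sigma0inv"];
  bool improper = prior["improper"];
  double sigma0_scalar = prior["sigma0_scalar"]; // NA when Sigma0 is not v*I
  double nu_beta = prior["nu_beta"], S_beta = prior["S_beta"];
  bool fix_sigma_beta = prior["fix_sigma_beta"];
  double nu_b = prior["nu_b"], S_b = prior["S_b"];
  double gmin = prior["gamma_min"], gmax = prior["gamma_max"];

  int n_iter = config["n_iter"], burn_in = config["burn_in"];
  bool probit = config["probit"], pin_omega = config["pin_omega"];
  int ridge_method = config["ridge_method"]; // 0 auto, 1 direct, 2 woodbury
  bool store_liab = config["store_liabilities"];
  bool verbose = config["verbose"];

  bool scalar_prior = R_finite(sigma0_scalar) && !improper &&
                      arma::all(beta0 == 0.0);
  bool use_woodbury =
      (ridge_method == 2) || (ridge_method == 0 && p > 2 * n && scalar_prior);
  if (use_woodbury && !scalar_prior)
    stop("the n-dimensional ridge draw requires a zero-mean scalar prior v*I");

  // --- initialization -----------------------------------------------------
  arma::vec gam(C - 1);
  {
    arma::vec cnt(C, arma::fill::zeros);
    for (int i = 0; i < n; ++i) cnt[y[i] - 1] += 1.0;
    double cum = 0.0;
    for (int c = 0; c < C - 1; ++c) {
      cum += cnt[c];
      gam[c] = R::qnorm(cum / n, 0.0, 1.0, 1, 0);
      gam[c] = std::min(std::max(gam[c], gmin + 1e-6), gmax - 1e-6);
      if (c > 0 && gam[c] <= gam[c - 1]) gam[c] = gam[c - 1] + 1e-6;
    }
  }
  arma::vec beta(p, arma::fill::zeros), b;
  if (polygenic) b.zeros(I);
  double sigma2_b = polygenic ? S_b : 0.0, sigma2_beta = 1.0;
  arma::vec l(n), omega(n, arma::fill::ones), eta(n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    int c = y[i];
    if (c == 1)            l[i] = gam[0] - 0.5;
    else if (c == C)       l[i] = gam[C - 2] + 0.5;
    else                   l[i] = 0.5 * (gam[c - 2] + gam[c - 1]);
  }

  arma::mat XtX; // reusable when D_omega is constant (probit / pinned omega)
  bool const_omega = probit || pin_omega;
  if (const_omega && !use_woodbury) XtX = X.t() * X;

  int kept = n_iter - burn_in;
  arma::mat S_beta_draws(kept, p), S_gamma(kept, C - 1);
  arma::vec S_s2beta(kept), S_s2b(polygenic ? kept : 0);
  arma::mat S_b_draws(polygenic ? kept : 0, polygenic ? I : 0);
  arma::mat S_liab(store_liab ? kept : 0, store_liab ? n : 0);

  arma::vec maxl(C), minl(C), sumw, rhs_b;
  if (polygenic) { sumw.zeros(I); rhs_b.zeros(I); }

  for (int iter = 0; iter < n_iter; ++iter) {
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();

    // (1) liabilities: truncated normal within the category interval
    for (int i = 0; i < n; ++i) {
      int c = y[i];
      double lo = (c == 1) ? R_NegInf : gam[c - 2];
      double up = (c == C) ? R_PosInf : gam[c - 1];
      l[i] = rtnorm1(eta[i], 1.0 / std::sqrt(omega[i]), lo, up);
    }

    // (2) Polya-Gamma augmentation (identity with omega = 1 under probit)
    if (!const_omega)
      for (int i = 0; i < n; ++i) omega[i] = rpg_int(2, eta[i] - l[i]);

    // (3) regression coefficients
    {
      arma::vec resid = l;
      if (polygenic)
        for (int i = 0; i < n; ++i) resid[i] -= b[line[i] - 1];
      if (const_omega && !use_woodbury) {
        arma::mat P = XtX;
        arma::vec rhs = X.t() * resid;
        if (!improper) {
          P += Sigma0inv / sigma2_beta;
          rhs += Sigma0inv * beta0 / sigma2_beta;
        }
        arma::mat R = arma::chol(P);
        arma::vec mean = arma::solve(arma::trimatu(R),
                                     arma::solve(arma::trimatl(R.t()), rhs));
        arma::vec z(p);
        for (int j = 0; j < p; ++j) z[j] = norm_rand();
        beta = mean + arma::solve(arma::trimatu(R), z);
      } else {
        beta = draw_beta(X, omega, resid, beta0, Sigma0inv, sigma2_beta,
                         improper, sigma0_scalar, use_woodbury);
      }
    }

    // (4) polygenic effects
    if (polygenic) {
      sumw.zeros();
      rhs_b.zeros();
      arma::vec xb = X * beta;
      for (int i = 0; i < n; ++i) {
        int g = line[i] - 1;
        sumw[g] += omega[i];
        rhs_b[g] += omega[i] * (l[i] - xb[i]);
      }
      arma::mat A = Ginv / sigma2_b;
      A.diag() += sumw;
      arma::mat R;
      if (!arma::chol(R, A))
        stop("polygenic precision matrix is not positive definite (iteration %d)",
             iter + 1);
      arma::vec mean = arma::solve(arma::trimatu(R),
                                   arma::solve(arma::trimatl(R.t()), rhs_b));
      arma::vec z(I);
      for (int g = 0; g < I; ++g) z[g] = norm_rand();
      b = mean + arma::solve(arma::trimatu(R), z);

      // (5) polygenic variance: scaled inverse chi-square
      double quad = arma::as_scalar(b.t() * Ginv * b);
      sigma2_b = (quad + nu_b * S_b) / R::rchisq(nu_b + I);
    }

    // refresh the linear predictor used by (1)-(2) next sweep and (6) now
    eta = X * beta;
    if (polygenic)
      for (int i = 0; i < n; ++i) eta[i] += b[line[i] - 1];

    // (6) thresholds: uniform on the interval pinched by the liabilities
    maxl.fill(R_NegInf);
    minl.fill(R_PosInf);
    for (int i = 0; i < n; ++i) {
      int c = y[i] - 1;
      if (l[i] > maxl[c]) maxl[c] = l[i];
      if (l[i] < minl[c]) minl[c] = l[i];
    }
    for (int j = 0; j < C - 1; ++j) {
      double lo = std::max(maxl[j], (j > 0) ? gam[j - 1] : gmin);
      lo = std::max(lo, gmin);
      double up = std::min(minl[j + 1], (j < C - 2) ? gam[j + 1] : gmax);
      up = std::min(up, gmax);
      if (!(up > lo))
        stop("degenerate threshold interval for category %d at iteration %d",
             j + 1, iter + 1);
      gam[j] = lo + (up - lo) * unif_rand();
    }

    // (7) coefficient variance: scaled inverse chi-square
    if (!fix_sigma_beta && !improper) {
      arma::vec d = beta - beta0;
      double quad = arma::as_scalar(d.t() * Sigma0inv * d);
      sigma2_beta = (quad + nu_beta * S_beta) / R::rchisq(nu_beta + p);
    }

    if (iter >= burn_in) {
      int s = iter - burn_in;
      S_beta_draws.row(s) = beta.t();
      S_gamma.row(s) = gam.t();
      S_s2beta[s] = sigma2_beta;
      if (polygenic) {
        S_s2b[s] = sigma2_b;
        S_b_draws.row(s) = b.t();
      }
      if (store_liab) S_liab.row(s) = l.t();
    }
    if (verbose && (iter + 1) % 1000 == 0)
      Rcout << "iteration " << iter + 1 << " / " << n_iter << "\n";
  }

  return List::create(_["beta"] = S_beta_draws, _["gamma"] = S_gamma,
                      _["sigma2_beta"] = S_s2beta, _["sigma2_b"] = S_s2b,
                      _["b"] = S_b_draws, _["liabilities"] = S_liab,
                      _["used_woodbury"] = use_woodbury);
}
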