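// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Single-chain Gibbs sampler for the four-component mixture model of SNP
// effects (class variances gamma * sigma2_g, first class a point mass at 0)
// with an optional residual polygenic effect whose covariance is the
// pedigree relationship matrix A (supplied via its eigen-decomposition over
// the phenotyped animals: A = U diag(lambda) U').
//
// The polygenic block is sampled jointly: with one record per animal the
// conditional precision is diagonal in the eigenbasis of A, so the draw
// costs two matrix-vector products per iteration.
//
// Uses R's RNG throughout, so set.seed() in R makes chains reproducible.
// [[Rcpp::export(name = ".bayesrGibbs")]]
List bayesrGibbs(NumericMatrix Zr, NumericVector yr, NumericVector gamma,
                 NumericVector alpha, int niter, int burnin, int thin,
                 bool usePoly, NumericMatrix Ur, NumericVector lambdar,
                 double nu0, double s2g0, double s2e0, double s2u0) {
  int n = Zr.nrow(), m = Zr.ncol(), K = gamma.size();
  arma::mat Z(Zr.begin(), n, m, false);
  arma::vec y(yr.begin(), n, false);
  arma::mat U;
  arma::vec lambda;
  if (usePoly) {
    U = arma::mat(Ur.begin(), n, n, false);
    lambda = arma::vec(lambdar.begin(), n, false);
  }

  double vary = arma::var(y);
  arma::vec zz(m);
  for (int j = 0; j < m; ++j) zz[j] = arma::dot(Z.col(j), Z.col(j));

  arma::vec beta(m, arma::fill::zeros);
  arma::ivec cls(m, arma::fill::zeros);
  arma::vec u(n, arma::fill::zeros);
  arma::vec e = y; // residual y - Z beta - u
  double s2g = s2g0, s2e = s2e0, s2u = s2u0;
  arma::vec pi(K);
  pi.fill(1.0 / K);

  int nkeep = niter - burnin;
  arma::vec sumBeta(m, arma::fill::zeros);
  arma::mat clsCount(m, K, arma::fill::zeros);
  int ntr = nkeep / thin + 1;
  arma::mat traces(ntr, 4, arma::fill::zeros);
  int tr = 0;

  arma::vec logl(K), nk(K);

  for (int it = 0; it < niter; ++it) {
    // --- SNP effects: class membership, then effect draw ---
    nk.zeros();
    for (int j = 0; j < m; ++j) {
      double bOld = beta[j];
      double rhs = arma::dot(Z.col(j), e) + zz[j] * bOld; // z_j' (e + z_j b_old)
      // marginal log-likelihood per class (effect integrated out)
      for (int k = 0; k < K; ++k) {
        double vk = gamma[k] * s2g;
        if (vk <= 0.0) {
          logl[k] = std::log(pi[k] + 1e-300);
        } else {
          double t = zz[j] * vk + s2e;
          logl[k] = std::log(pi[k] + 1e-300)
                  - 0.5 * std::log(t / s2e)
                  + 0.5 * rhs * rhs * vk / (s2e * t);
        }
      }
      double mx = logl.max();
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { logl[k] = std::exp(logl[k] - mx); tot += logl[k]; }
      double uu = R::unif_rand() * tot, acc = 0.0;
      int k = K - 1;
      for (int kk = 0; kk < K; ++kk) { acc += logl[kk]; if (uu <= acc) { k = kk; break; } }
      cls[j] = k;
      nk[k] += 1.0;
      double bNew = 0.0;
      if (k > 0) {
        double vk = gamma[k] * s2g;
        double prec = zz[j] / s2e + 1.0 / vk;
        double mean = (rhs / s2e) / prec;
        bNew = mean + R::norm_rand() / std::sqrt(prec);
      }
      if (bNew != bOld) e += Z.col(j) * (bOld - bNew);
      beta[j] = bNew;
    }

    // --- mixture proportions: Dirichlet update ---
    double psum = 0.0;
    for (int k = 0; k < K; ++k) { pi[k] = R::rgamma(alpha[k] + nk[k], 1.0); psum += pi[k]; }
    pi /= psum;

    // --- genetic variance level (class variances re-tied to it) ---
    double S = 0.0; int nnz = 0;
    for (int j = 0; j < m; ++j)
      if (cls[j] > 0) { S += beta[j] * beta[j] / gamma[cls[j]]; ++nnz; }
    s2g = (S + nu0 * s2g0) / R::rchisq(nu0 + nnz);

    // --- residual polygenic effect in the eigenbasis of A ---
    if (usePoly) {
      arma::vec ewo = e + u;
      arma::vec r = U.t() * ewo;
      arma::vec v(n);
      double Su = 0.0; int npos = 0;
      for (int i = 0; i < n; ++i) {
        if (lambda[i] < 1e-10) { v[i] = 0.0; continue; }
        double d = 1.0 / s2e + 1.0 / (s2u * lambda[i]);
        double mean = (r[i] / s2e) / d;
        v[i] = mean + R::norm_rand() / std::sqrt(d);
        Su += v[i] * v[i] / lambda[i];
        ++npos;
      }
      u = U * v;
      e = ewo - u;
      s2u = (Su + nu0 * s2u0) / R::rchisq(nu0 + npos);
    }

    // --- residual variance ---
    s2e = (arma::dot(e, e) + nu0 * s2e0) / R::rchisq(nu0 + n);

    if (s2e > 1e6 * vary || s2g > 1e6 * vary)
      stop("divergent variance draw (sigma2 > 1e6 * phenotypic variance) at iteration %d", it + 1);

    if (it >= burnin) {
      sumBeta += beta;
      for (int j = 0; j < m; ++j) clsCount(j, cls[j]) += 1.0;
      if ((it - burnin) % thin == 0 && tr < ntr) {
        traces(tr, 0) = s2g; traces(tr, 1) = s2e; traces(tr, 2) = s2u;
        traces(tr, 3) = nnz;
        ++tr;
      }
    }
  }

  return List::create(
    _["effMean"] = wrap(sumBeta / nkeep),
    _["classProb"] = wrap(clsCount / nkeep),
    _["traces"] = wrap(traces.rows(0, tr - 1)),
    _["piMean"] = wrap(pi));
}
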