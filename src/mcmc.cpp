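#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Truncated squared-exponential kernel k(d) = exp(-d^2 / sigma) on marker
// index distance; weights below eps are dropped. cum[d] = k(0) + ... + k(d).
static void kernel_build(double sigma, double eps, int maxlen,
                         std::vector<double> &k, std::vector<double> &cum,
                         int &h) {
  h = (int)std::floor(std::sqrt(std::max(0.0, sigma * std::log(1.0 / eps))));
  if (h > maxlen - 1) h = maxlen - 1;
  k.assign(h + 1, 0.0);
  cum.assign(h + 1, 0.0);
  for (int d = 0; d <= h; ++d) {
    k[d] = std::exp(-(double)d * d / sigma);
    cum[d] = (d == 0) ? k[0] : cum[d - 1] + k[d];
  }
}

// Kernel-weighted ancestry counts a[x] = sum_i zsum[i] k(|x-i|) and total
// kernel mass K[x], never crossing chromosome boundaries.
static void kernel_sums(const std::vector<double> &zsum,
                        const std::vector<int> &cs, const std::vector<int> &ce,
                        const std::vector<double> &k,
                        const std::vector<double> &cum, int h,
                        std::vector<double> &a, std::vector<double> &K) {
  for (size_t c = 0; c < cs.size(); ++c) {
    int lo = cs[c], hi = ce[c];
    for (int x = lo; x <= hi; ++x) {
      int dl = std::min(h, x - lo), dr = std::min(h, hi - x);
      double s = zsum[x];
      for (int d = 1; d <= dl; ++d) s += zsum[x - d] * k[d];
      for (int d = 1; d <= dr; ++d) s += zsum[x + d] * k[d];
      a[x] = s;
      K[x] = cum[dl] + cum[dr] - 1.0; // k(0)=1 counted once
    }
  }
}

static inline double log_beta_pdf(double logq, double log1q, double la,
                                  double lb, double alpha, double beta) {
  return (alpha - 1.0) * logq + (beta - 1.0) * log1q - la - lb +
         std::lgamma(alpha + beta);
}

// One MCMC chain for the correlated beta process model. lik is the 3 x n_adm
// x L likelihood grid; chromosomes are contiguous locus ranges [cs, ce]
// (0-based, inclusive). Sweep order per iteration: all z, kernel sums (kernel
// rebuilt if sigma changed), all q, then a Metropolis update of sigma on the
// log scale with the beta-likelihood ratio.
// [[Rcpp::export]]
List cpp_run_chain(NumericVector lik, int L, int nadm, IntegerVector cs_in,
                   IntegerVector ce_in, double alpha0, double beta0,
                   double sigma_min, double sigma_max, double sigma_step,
                   int iters, int burnin, int thin, double eps,
                   IntegerVector z_init, NumericVector q_init,
                   double sigma_init) {
  std::vector<int> cs(cs_in.begin(), cs_in.end()),
      ce(ce_in.begin(), ce_in.end());
  int maxclen = 0;
  for (size_t c = 0; c < cs.size(); ++c)
    maxclen = std::max(maxclen, ce[c] - cs[c] + 1);

  std::vector<int> z(z_init.begin(), z_init.end()); // L*nadm, ind fastest? no:
  // layout matches lik: z[j + nadm*x]
  std::vector<double> q(q_init.begin(), q_init.end());
  double sigma = sigma_init;

  std::vector<double> k, cum, kp, cump;
  int h, hp;
  kernel_build(sigma, eps, maxclen, k, cum, h);

  std::vector<double> zsum(L), a(L), K(L), ap(L), Kp(L), logq(L), log1q(L);
  const double *likp = REAL(lik);

  int nkeep = (iters - burnin) / thin;
  NumericMatrix q_draws(L, nkeep);
  IntegerMatrix zsum_draws(L, nkeep);
  NumericVector sigma_draws(nkeep);
  NumericMatrix dos(L, nadm);
  int kept = 0;
  long accept = 0, nprop = 0, under = 0;
  const double qlo = 1e-12, qhi = 1.0 - 1e-12;

  for (int it = 1; it <= iters; ++it) {
    // --- z | q, data ---
    for (int x = 0; x < L; ++x) {
      double qx = q[x];
      double p0 = (1.0 - qx) * (1.0 - qx);
      double p1 = 2.0 * qx * (1.0 - qx);
      double p2 = qx * qx;
      const double *lx = likp + (size_t)3 * nadm * x;
      int *zx = z.data() + (size_t)nadm * x;
      double s = 0.0;
      for (int j = 0; j < nadm; ++j) {
        double w0 = lx[3 * j] * p0;
        double w1 = lx[3 * j + 1] * p1;
        double w2 = lx[3 * j + 2] * p2;
        double tot = w0 + w1 + w2;
        int zv;
        if (tot <= 0.0 || !std::isfinite(tot)) { // underflow: fall back to prior
          ++under;
          double u = R::unif_rand();
          zv = (u < p0) ? 0 : (u < p0 + p1 ? 1 : 2);
        } else {
          double u = R::unif_rand() * tot;
          zv = (u < w0) ? 0 : (u < w0 + w1 ? 1 : 2);
        }
        zx[j] = zv;
        s += zv;
      }
      zsum[x] = s;
    }

    // --- q | z, sigma ---
    kernel_sums(zsum, cs, ce, k, cum, h, a, K);
    double twon = 2.0 * nadm;
    for (int x = 0; x < L; ++x) {
      double alpha = alpha0 + a[x];
      double beta = beta0 + twon * K[x] - a[x];
      double d = R::rbeta(alpha, beta);
      if (d < qlo) d = qlo;
      if (d > qhi) d = qhi;
      q[x] = d;
    }

    // --- sigma | q, z (Metropolis, log-scale random walk) ---
    double prop = std::exp(std::log(sigma) + R::norm_rand() * sigma_step);
    ++nprop;
    if (prop >= sigma_min && prop <= sigma_max) {
      kernel_build(prop, eps, maxclen, kp, cump, hp);
      kernel_sums(zsum, cs, ce, kp, cump, hp, ap, Kp);
      for (int x = 0; x < L; ++x) {
        logq[x] = std::log(q[x]);
        log1q[x] = std::log1p(-q[x]);
      }
      double lr = 0.0;
      for (int x = 0; x < L; ++x) {
        double al = alpha0 + a[x], be = beta0 + twon * K[x] - a[x];
        double alp = alpha0 + ap[x], bep = beta0 + twon * Kp[x] - ap[x];
        lr += log_beta_pdf(logq[x], log1q[x], std::lgamma(alp),
                           std::lgamma(bep), alp, bep) -
              log_beta_pdf(logq[x], log1q[x], std::lgamma(al), std::lgamma(be),
                           al, be);
      }
      if (std::log(R::unif_rand()) < lr) {
        sigma = prop;
        k.swap(kp);
        cum.swap(cump);
        h = hp;
        ++accept;
      }
    }

    if (it > burnin && (it - burnin) % thin == 0) {
      for (int x = 0; x < L; ++x) {
        q_draws(x, kept) = q[x];
        zsum_draws(x, kept) = (int)zsum[x];
      }
      sigma_draws[kept] = sigma;
      for (int x = 0; x < L; ++x) {
        const int *zx = z.data() + (size_t)nadm * x;
        for (int j = 0; j < nadm; ++j) dos(x, j) += zx[j];
      }
      ++kept;
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }
  if (kept > 0)
    for (int x = 0; x < L; ++x)
      for (int j = 0; j < nadm; ++j) dos(x, j) /= kept;

  return List::create(_["q"] = q_draws, _["zsum"] = zsum_draws,
                      _["sigma"] = sigma_draws, _["dosage"] = dos,
                      _["accept_rate"] = nprop ? (double)accept / nprop : 0.0,
                      _["n_underflow"] = (double)under);
}
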