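// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fit the three-group linear discriminant for one SNP window.
// X: n_ref x p (individuals x window SNPs), grp in {0,1,2}.
// Pooled within-group covariance (divisor sum(n_g) - 3) with ridge,
// between-group scatter (1/3) sum (mu_g - mu)(mu_g - mu)^T, leading
// eigenvector of solve(Sw) %*% SB, sign-fixed so group-2 scores exceed
// group-0 scores on average.
static int fit_window(const arma::mat &X, const arma::ivec &grp,
                      double ridge_scale, double var_floor_scale,
                      arma::vec &coef, arma::rowvec &offset, arma::vec &means,
                      arma::vec &vars) {
  const int n = X.n_rows, p = X.n_cols;
  offset = arma::mean(X, 0);
  arma::mat Xc = X.each_row() - offset;

  arma::mat Sw(p, p, arma::fill::zeros);
  arma::mat mug(3, p);
  arma::ivec ng(3, arma::fill::zeros);
  for (int g = 0; g < 3; ++g) {
    arma::uvec id = arma::find(grp == g);
    ng[g] = id.n_elem;
    arma::mat Xg = Xc.rows(id);
    mug.row(g) = arma::mean(Xg, 0);
    arma::mat Gg = Xg.each_row() - mug.row(g);
    Sw += Gg.t() * Gg;
  }
  Sw /= (double)(n - 3);
  double ridge = ridge_scale * arma::mean(Sw.diag());
  if (!(ridge > 0)) ridge = ridge_scale;
  Sw.diag() += ridge;

  arma::mat SB(p, p, arma::fill::zeros);
  for (int g = 0; g < 3; ++g)
    SB += mug.row(g).t() * mug.row(g); // grand mean is zero after centering
  SB /= 3.0;

  arma::mat M;
  if (!arma::solve(M, Sw, SB, arma::solve_opts::no_approx))
    return -1; // singular within-group covariance
  arma::cx_vec eval;
  arma::cx_mat evec;
  if (!arma::eig_gen(eval, evec, M)) return -1;
  arma::uword imax = arma::real(eval).index_max();
  coef = arma::real(evec.col(imax));
  double nrm = arma::norm(coef);
  if (nrm > 0) coef /= nrm;

  arma::vec sc = Xc * coef;
  means.set_size(3);
  vars.set_size(3);
  for (int g = 0; g < 3; ++g) {
    arma::uvec id = arma::find(grp == g);
    arma::vec sg = sc.elem(id);
    means[g] = arma::mean(sg);
    vars[g] = (ng[g] > 1) ? arma::var(sg) : 0.0;
  }
  if (means[2] < means[0]) { // sign convention
    coef = -coef;
    sc = -sc;
    means = -means;
  }
  double pooled = arma::var(sc);
  double floorv = std::max(var_floor_scale * pooled, 1e-12);
  int nfloored = 0;
  for (int g = 0; g < 3; ++g)
    if (vars[g] < floorv) {
      vars[g] = floorv;
      ++nfloored;
    }
  return nfloored;
}

// [[Rcpp::export]]
List cpp_fit_da_window(const arma::mat &X, const arma::ivec &grp,
                       double ridge_scale, double var_floor_scale) {
  arma::vec coef, means, vars;
  arma::rowvec offset;
  int nf = fit_window(X, grp, ridge_scale, var_floor_scale, coef, offset,
                      means, vars);
  if (nf < 0) stop("within-group covariance is singular after ridge");
  return List::create(_["coef"] = coef, _["offset"] = offset,
                      _["means"] = means, _["vars"] = vars,
                      _["n_floored"] = nf);
}

// Fit all per-locus windows and evaluate the 3-state ancestry likelihood for
// every admixed individual. Gref: L x n_ref, Gadm: L x n_adm; win: L x 2
// matrix of 0-based window bounds (inclusive, same chromosome as the focal
// locus). Returns likelihood array (3 x n_adm x L), scores (L x n_adm), and
// optionally the per-locus models.
// [[Rcpp::export]]
List cpp_fit_da_all(const arma::mat &Gref, const arma::ivec &grp,
                    const IntegerMatrix &win, const arma::mat &Gadm,
                    double ridge_scale, double var_floor_scale,
                    double lik_floor, bool keep_models) {
  const int L = Gref.n_rows, nadm = Gadm.n_cols;
  NumericVector lik(Dimension(3, nadm, L));
  NumericMatrix scores(L, nadm);
  List models = keep_models ? List(L) : List(0);
  int tot_floored = 0;

  arma::vec coef, means, vars;
  arma::rowvec offset;
  for (int x = 0; x < L; ++x) {
    int a = win(x, 0), b = win(x, 1);
    arma::mat X = Gref.rows(a, b).t();
    int nf = fit_window(X, grp, ridge_scale, var_floor_scale, coef, offset,
                        means, vars);
    if (nf < 0)
      stop("within-group covariance singular after ridge at locus %d", x + 1);
    tot_floored += nf;
    arma::mat A = Gadm.rows(a, b).t(); // nadm x p
    A.each_row() -= offset;
    arma::vec d = A * coef;
    double *lx = &lik[3 * nadm * x];
    for (int j = 0; j < nadm; ++j) {
      if (!std::isfinite(d[j]))
        stop("non-finite discriminant score at locus %d, individual %d", x + 1,
             j + 1);
      scores(x, j) = d[j];
      for (int g = 0; g < 3; ++g) {
        double v = vars[g];
        double e = d[j] - means[g];
        double f = std::exp(-0.5 * e * e / v) / std::sqrt(2.0 * M_PI * v);
        lx[3 * j + g] = (f < lik_floor) ? lik_floor : f;
      }
    }
    if (keep_models)
      models[x] = List::create(_["coef"] = coef, _["offset"] = offset,
                               _["means"] = means, _["vars"] = vars);
    if (x % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["lik"] = lik, _["scores"] = scores,
                      _["models"] = models, _["n_floored"] = tot_floored);
}
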