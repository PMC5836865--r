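#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Log multivariate normal density for all rows of X, via lower Cholesky.
// Returns false when Sigma is not positive definite.
static bool log_dmvnorm(const arma::mat& X, const arma::rowvec& mu,
                        const arma::mat& Sigma, arma::vec& out) {
  arma::mat L;
  if (!arma::chol(L, Sigma, "lower")) return false;
  arma::mat D = X.each_row() - mu;
  arma::mat Z = arma::solve(arma::trimatl(L), D.t());
  arma::vec q = arma::sum(arma::square(Z), 0).t();
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  double d = static_cast<double>(X.n_cols);
  out = -0.5 * (d * std::log(2.0 * M_PI) + logdet + q);
  return true;
}

// One EM run on a full-covariance Gaussian mixture from the supplied
// initialization. Convergence: relative log-likelihood change < tol.
// `reg` is an absolute ridge added to every covariance diagonal each M-step.
// [[Rcpp::export]]
List gmm_em_cpp(const arma::mat& X, arma::mat means, arma::cube covs,
                arma::vec weights, int max_iter, double tol, double reg) {
  const int n = X.n_rows, k = means.n_rows;
  arma::mat logp(n, k), resp(n, k);
  arma::vec tmp(n);
  double ll = R_NegInf;
  bool converged = false, ok = true;
  int iter = 0;

  auto e_step = [&](double& ll_out) -> bool {
    for (int j = 0; j < k; ++j) {
      if (!log_dmvnorm(X, means.row(j), covs.slice(j), tmp)) return false;
      logp.col(j) = tmp + std::log(weights(j));
    }
    arma::vec m = arma::max(logp, 1);
    arma::mat ex = arma::exp(logp.each_col() - m);
    arma::vec s = arma::sum(ex, 1);
    ll_out = arma::accu(m + arma::log(s));
    resp = ex.each_col() / s;
    return true;
  };

  for (iter = 1; iter <= max_iter; ++iter) {
    double ll_new;
    if (!e_step(ll_new)) { ok = false; break; }
    if (std::isfinite(ll) &&
        std::abs(ll_new - ll) < tol * std::abs(ll_new)) {
      ll = ll_new;
      converged = true;
      break;  // params used in this E-step are returned: resp/ll consistent
    }
    ll = ll_new;
    // M-step
    arma::rowvec nk = arma::sum(resp, 0);
    if (nk.min() < 1e-10) { ok = false; break; }
    weights = nk.t() / static_cast<double>(n);
    means = resp.t() * X;
    means.each_col() /= nk.t();
    for (int j = 0; j < k; ++j) {
      arma::mat D = X.each_row() - means.row(j);
      arma::mat Dw = D.each_col() % resp.col(j);
      arma::mat S = (Dw.t() * D) / nk(j);
      S.diag() += reg;
      covs.slice(j) = S;
    }
  }
  if (ok && !converged) {
    // max_iter hit after an M-step: refresh ll/resp for the final params
    double ll_new;
    if (e_step(ll_new)) ll = ll_new; else ok = false;
  }

  return List::create(
    _["ok"] = ok, _["converged"] = converged, _["iter"] = iter,
    _["loglik"] = ll, _["means"] = means, _["covs"] = covs,
    _["weights"] = weights, _["resp"] = resp);
}

// Number of 26-connected components summed over all positive labels of a 3D
// integer volume (iterative flood fill).
// [[Rcpp::export]]
int count_connected_cpp(const IntegerVector& vol, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ntot = nx * ny * nz;
  if (vol.size() != ntot) stop("volume/dims mismatch");
  std::vector<char> visited(ntot, 0);
  std::vector<int> stack;
  int count = 0;
  for (int s = 0; s < ntot; ++s) {
    if (vol[s] == NA_INTEGER || vol[s] <= 0 || visited[s]) continue;
    ++count;
    const int target = vol[s];
    visited[s] = 1;
    stack.push_back(s);
    while (!stack.empty()) {
      const int idx = stack.back();
      stack.pop_back();
      const int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            const int j = xx + nx * (yy + ny * zz);
            if (!visited[j] && vol[j] != NA_INTEGER && vol[j] == target) {
              visited[j] = 1;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  return count;
}
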