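#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double INV_SQRT_2PI = 0.3989422804014327;

// Gaussian kernel density estimate evaluated at arbitrary points.
// [[Rcpp::export]]
arma::vec kde1_eval_cpp(const arma::vec& xe, const arma::vec& xt, double h) {
  const arma::uword ne = xe.n_elem, nt = xt.n_elem;
  arma::vec out(ne);
  const double inv_h = 1.0 / h;
  for (arma::uword i = 0; i < ne; ++i) {
    double s = 0.0;
    const double xi = xe[i];
    for (arma::uword j = 0; j < nt; ++j) {
      const double d = (xi - xt[j]) * inv_h;
      s += std::exp(-0.5 * d * d);
    }
    out[i] = s * INV_SQRT_2PI * inv_h / (double)nt;
  }
  return out;
}

// Held-out densities for one CV fold of the GCC fit.
// scales holds per-dimension bandwidth scale factors; every (sx, sy) pair
// from the grid is evaluated. Returns ne x (2 + m*m):
//   col 0: marginal KDE of x at the held-out points
//   col 1: marginal KDE of y
//   col 2 + (k*m + l): joint product-kernel KDE at (hx*scales[k],
//                      hy*scales[l])
// The exponential factors are computed once per dimension and scale and
// shared across the m*m grid combinations.
// [[Rcpp::export]]
arma::mat gcc_fold_density_cpp(const arma::vec& xe, const arma::vec& ye,
                               const arma::vec& xt, const arma::vec& yt,
                               double hx, double hy, const arma::vec& scales) {
  const arma::uword ne = xe.n_elem, nt = xt.n_elem, m = scales.n_elem;
  arma::mat out(ne, 2 + m * m);

  // squared standardized distances, ne x nt
  arma::mat QX(ne, nt), QY(ne, nt);
  const double inv_hx = 1.0 / hx, inv_hy = 1.0 / hy;
  for (arma::uword j = 0; j < nt; ++j) {
    const double xj = xt[j], yj = yt[j];
    for (arma::uword i = 0; i < ne; ++i) {
      const double dx = (xe[i] - xj) * inv_hx;
      const double dy = (ye[i] - yj) * inv_hy;
      QX(i, j) = dx * dx;
      QY(i, j) = dy * dy;
    }
  }

  std::vector<arma::mat> EX(m), EY(m);
  int base_idx = -1;
  for (arma::uword s = 0; s < m; ++s)
    if (scales[s] == 1.0) base_idx = (int)s;
  arma::mat EX0, EY0;
  if (base_idx >= 0) {
    EX[base_idx] = arma::exp(-0.5 * QX);
    EY[base_idx] = arma::exp(-0.5 * QY);
    EX0 = EX[base_idx];
    EY0 = EY[base_idx];
  } else {
    EX0 = arma::exp(-0.5 * QX);
    EY0 = arma::exp(-0.5 * QY);
  }
  for (arma::uword s = 0; s < m; ++s) {
    if ((int)s == base_idx) continue;
    const double c = 0.5 / (scales[s] * scales[s]);
    EX[s] = arma::exp(-c * QX);
    EY[s] = arma::exp(-c * QY);
  }

  out.col(0) = arma::sum(EX0, 1) * (INV_SQRT_2PI * inv_hx / (double)nt);
  out.col(1) = arma::sum(EY0, 1) * (INV_SQRT_2PI * inv_hy / (double)nt);
  for (arma::uword k = 0; k < m; ++k)
    for (arma::uword l = 0; l < m; ++l)
      out.col(2 + k * m + l) = arma::sum(EX[k] % EY[l], 1) *
        (INV_SQRT_2PI * INV_SQRT_2PI * inv_hx * inv_hy /
         (scales[k] * scales[l] * (double)nt));
  return out;
}
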