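#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Dominant eigenvector of sum_m w_m v_m v_m^T for unit-norm zero-mean columns
// of M. Computed through the smaller Gram matrix side. Columns of M are
// zero-mean, so the returned vector (a combination of them) is zero-mean too.
static vec dominant_template(const mat& M, const vec& sw) {
  mat X = M;
  X.each_row() %= sw.t(); // scale column m by sqrt(w_m)
  vec t;
  if (X.n_cols <= X.n_rows) {
    mat G = X.t() * X;
    vec eval;
    mat evec;
    eig_sym(eval, evec, G);
    t = X * evec.col(G.n_cols - 1);
  } else {
    mat G = X * X.t();
    vec eval;
    mat evec;
    eig_sym(eval, evec, G);
    t = evec.col(G.n_rows - 1);
  }
  double n = norm(t);
  if (n > 0) t /= n;
  return t;
}

// Modified (polarity-invariant) k-means over topographic maps.
//
// V:     C x N matrix of unit-norm, zero-mean maps (columns)
// w:     length-N nonnegative weights (GFP^2) entering GEV and the update
// inits: k x R matrix of 0-based column indices initializing each restart
//
// Assignment maximizes squared spatial correlation (|t' v|) per map; the
// update replaces each template by the dominant eigenvector of the weighted
// scatter of its members, so each sweep is coordinate ascent on GEV.
// Empty clusters are re-seeded from the currently worst-fit map.
// warm: optional C x k template matrix evaluated as one extra restart
// (hierarchical warm start from the k-1 solution); pass a 0 x 0 matrix to
// disable.
// [[Rcpp::export]]
Rcpp::List mk_kmeans_engine(const arma::mat& V, const arma::vec& w,
                            const arma::umat& inits, int max_iter,
                            double tol, const arma::mat& warm) {
  const uword C = V.n_rows, N = V.n_cols;
  const uword k = inits.n_rows, R = inits.n_cols;
  const bool has_warm = warm.n_cols == k && warm.n_rows == C;
  const double wtot = accu(w);
  const vec sw = sqrt(w);

  double best_gev = -1.0;
  mat best_T;
  urowvec best_L;
  int best_iter = 0;

  for (uword r = 0; r < R + (has_warm ? 1 : 0); ++r) {
    mat T(C, k);
    if (r == R)
      T = warm;
    else
      for (uword j = 0; j < k; ++j) T.col(j) = V.col(inits(j, r));

    double gev_prev = -1.0, gev = 0.0;
    urowvec labels(N);
    int it = 0;
    for (it = 1; it <= max_iter; ++it) {
      mat A = abs(T.t() * V); // k x N absolute spatial correlations
      labels = index_max(A, 0);
      rowvec rbest = max(A, 0);
      gev = dot(w, square(rbest.t())) / wtot;
      if (it > 1 && gev - gev_prev <= tol * std::max(gev_prev, 1e-12)) break;
      gev_prev = gev;
      for (uword j = 0; j < k; ++j) {
        uvec idx = find(labels == j);
        if (idx.n_elem == 0) {
          T.col(j) = V.col(rbest.index_min());
        } else {
          T.col(j) = dominant_template(V.cols(idx), sw(idx));
        }
      }
    }
    // re-assign so labels/GEV are consistent with the final templates
    mat A = abs(T.t() * V);
    labels = index_max(A, 0);
    gev = dot(w, square(max(A, 0).t())) / wtot;

    if (gev > best_gev) {
      best_gev = gev;
      best_T = T;
      best_L = labels;
      best_iter = std::min(it, max_iter);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("templates") = best_T,
      Rcpp::Named("labels") = conv_to<ivec>::from(best_L.t()) + 1,
      Rcpp::Named("gev") = best_gev, Rcpp::Named("n_iter") = best_iter);
}
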