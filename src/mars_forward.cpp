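// Forward pass of the MARS basis search: greedy addition of reflected-pair
// hinge bases max(0, x - t), max(0, t - x) multiplied onto an existing basis
// function, choosing at each step the (parent, variable, knot) triple that
// most reduces the residual sum of squares. Orthonormal bookkeeping (a
// running Gram-Schmidt Q of the basis) makes each candidate evaluation
// O(n * m). Interactions are limited to `max_degree` factors and a variable
// never appears twice in one basis function.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// b(i) * max(0, x(i) - t)  (pos) or  b(i) * max(0, t - x(i))
static inline vec hinge(const vec& b, const vec& x, double t, bool pos) {
  vec out(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) {
    double d = pos ? (x[i] - t) : (t - x[i]);
    out[i] = d > 0 ? b[i] * d : 0.0;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List mars_forward_cpp(const arma::mat& X, const arma::vec& y,
                            const Rcpp::List& knots, int max_terms,
                            int max_degree) {
  const uword n = X.n_rows, p = X.n_cols;
  const double tol = 1e-10;

  std::vector<vec> bcols;            // basis columns
  std::vector<int> parent, var, sign, degree;
  std::vector<double> knot;
  std::vector<std::vector<int>> vars_used;

  bcols.push_back(vec(n, fill::ones));
  parent.push_back(-1); var.push_back(-1); sign.push_back(0);
  knot.push_back(0.0); degree.push_back(0);
  vars_used.push_back(std::vector<int>());

  mat Q(n, 1);
  Q.col(0) = bcols[0] / norm(bcols[0]);
  vec r = y - Q * (Q.t() * y);
  double rss = dot(r, r);
  const double rss0 = std::max(rss, 1e-12);

  while ((int)bcols.size() + 1 < max_terms) {
    double best_red = 0.0;
    int best_j = -1, best_v = -1;
    double best_t = 0.0;

    for (size_t j = 0; j < bcols.size(); ++j) {
      if (degree[j] >= max_degree) continue;
      const vec& b = bcols[j];
      for (uword v = 0; v < p; ++v) {
        bool used = false;
        for (int uv : vars_used[j]) if (uv == (int)v) { used = true; break; }
        if (used) continue;
        Rcpp::NumericVector kv = knots[v];
        const vec xv = X.col(v);
        for (int ki = 0; ki < kv.size(); ++ki) {
          double t = kv[ki];
          vec c1 = hinge(b, xv, t, true);
          vec u1 = c1 - Q * (Q.t() * c1);
          double n1 = dot(u1, u1);
          double red = 0.0;
          vec u1n;
          bool have1 = n1 > tol;
          if (have1) {
            double pr = dot(u1, r);
            red += pr * pr / n1;
            u1n = u1 / std::sqrt(n1);
          }
          vec c2 = hinge(b, xv, t, false);
          vec u2 = c2 - Q * (Q.t() * c2);
          if (have1) u2 -= u1n * dot(u1n, c2);
          double n2 = dot(u2, u2);
          if (n2 > tol) {
            double pr2 = dot(u2, r);
            red += pr2 * pr2 / n2;
          }
          if (red > best_red) {
            best_red = red; best_j = (int)j; best_v = (int)v; best_t = t;
          }
        }
      }
    }

    if (best_j < 0 || best_red < 1e-8 * rss0) break;

    const vec& b = bcols[best_j];
    const vec xv = X.col(best_v);
    std::vector<int> vu = vars_used[best_j];
    vu.push_back(best_v);
    int sgns[2] = {1, -1};
    for (int s = 0; s < 2; ++s) {
      vec c = hinge(b, xv, best_t, s == 0);
      vec u = c - Q * (Q.t() * c);
      double nu = dot(u, u);
      if (nu <= tol) continue;
      u /= std::sqrt(nu);
      Q = join_rows(Q, u);
      r -= u * dot(u, r);
      bcols.push_back(c);
      parent.push_back(best_j); var.push_back(best_v);
      sign.push_back(sgns[s]); knot.push_back(best_t);
      degree.push_back(degree[best_j] + 1);
      vars_used.push_back(vu);
      if ((int)bcols.size() >= max_terms) break;
    }
    rss = dot(r, r);
  }

  mat B(n, bcols.size());
  for (size_t j = 0; j < bcols.size(); ++j) B.col(j) = bcols[j];
  return Rcpp::List::create(
    Rcpp::Named("B") = B,
    Rcpp::Named("parent") = Rcpp::IntegerVector(parent.begin(), parent.end()),
    Rcpp::Named("var") = Rcpp::IntegerVector(var.begin(), var.end()),
    Rcpp::Named("sign") = Rcpp::IntegerVector(sign.begin(), sign.end()),
    Rcpp::Named("knot") = Rcpp::NumericVector(knot.begin(), knot.end()),
    Rcpp::Named("degree") = Rcpp::IntegerVector(degree.begin(), degree.end()));
}
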