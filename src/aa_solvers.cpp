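// Simplex-constrained least squares and the alternating archetypal-analysis
// fit. The inner solver is an exact primal active-set method for
//   min_w  0.5 w' G w - f' w   s.t.  sum(w) = 1, w >= 0,
// where G = M'M and f = M'b for a least-squares problem min ||M w - b||.
// Supports stay small (at most d + 1 vertices are ever needed to represent a
// point of a d-dimensional convex hull), so the KKT systems remain tiny even
// when the number of variables is the number of data points.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve the equality-constrained subproblem on the passive set P:
//   [ G_PP  1 ] [w]   [f_P]
//   [ 1'    0 ] [l] = [ 1 ]
static vec solve_kkt(const mat& G, const vec& f, const uvec& P, double& lambda) {
  const uword p = P.n_elem;
  mat K(p + 1, p + 1, fill::zeros);
  K.submat(0, 0, p - 1, p - 1) = G.submat(P, P);
  // tiny ridge keeps degenerate (duplicated-point) systems solvable
  double d0 = trace(K.submat(0, 0, p - 1, p - 1)) / p;
  K.submat(0, 0, p - 1, p - 1).diag() += 1e-12 * (1.0 + d0);
  K.col(p).head(p).ones();
  K.row(p).head(p).ones();
  vec rhs(p + 1, fill::zeros);
  rhs.head(p) = f(P);
  rhs(p) = 1.0;
  vec sol;
  if (!solve(sol, K, rhs, solve_opts::no_approx)) {
    sol = pinv(K) * rhs;
  }
  lambda = sol(p);
  return sol.head(p);
}

// Active-set solver. w0 may supply a feasible warm start (sum 1, nonneg);
// pass an empty vector to start from the best single vertex.
static vec simplex_ls_gram(const mat& G, const vec& f, const vec& w0) {
  const uword k = f.n_elem;
  vec w(k, fill::zeros);
  if (k == 1) { w(0) = 1.0; return w; }

  uvec inP(k, fill::zeros);
  if (w0.n_elem == k && w0.min() >= 0 && std::abs(accu(w0) - 1.0) < 1e-8) {
    w = w0;
    for (uword j = 0; j < k; ++j) if (w(j) > 0) inP(j) = 1;
  } else {
    // start at the vertex with the smallest objective 0.5*G_jj - f_j
    vec obj = 0.5 * G.diag() - f;
    uword j0 = obj.index_min();
    w(j0) = 1.0;
    inP(j0) = 1;
  }

  const double tol = 1e-9 * std::max(1.0, G.diag().max());
  const int max_outer = 30 * static_cast<int>(k) + 200;

  for (int it = 0; it < max_outer; ++it) {
    uvec P = find(inP == 1);
    double lambda = 0.0;
    vec wp = solve_kkt(G, f, P, lambda);

    if (wp.min() >= -1e-12) {
      vec wnew(k, fill::zeros);
      for (uword i = 0; i < P.n_elem; ++i) wnew(P(i)) = std::max(wp(i), 0.0);
      w = wnew;
      uvec Acts = find(inP == 0);
      if (Acts.n_elem == 0) break;
      // KKT: multiplier of an active bound is mu_j = (G w - f)_j + lambda >= 0
      vec g = G * w - f;
      vec r = g(Acts) + lambda;
      uword jm = r.index_min();
      if (r(jm) >= -tol) break;
      inP(Acts(jm)) = 1;
    } else {
      // step from the current feasible point toward wp up to the boundary
      double alpha = 1.0;
      uword blk = k;  // invalid sentinel
      for (uword i = 0; i < P.n_elem; ++i) {
        if (wp(i) < 0) {
          double wi = w(P(i));
          double a = wi / (wi - wp(i));
          if (a < alpha) { alpha = a; blk = P(i); }
        }
      }
      vec wnew(k, fill::zeros);
      for (uword i = 0; i < P.n_elem; ++i) {
        double v = w(P(i)) + alpha * (wp(i) - w(P(i)));
        wnew(P(i)) = std::max(v, 0.0);
      }
      if (blk < k) { wnew(blk) = 0.0; inP(blk) = 0; }
      double s = accu(wnew);
      if (s > 0) wnew /= s;
      w = wnew;
    }
  }

  w.transform([](double v) { return v < 0 ? 0.0 : v; });
  double s = accu(w);
  if (s > 0) w /= s; else w.fill(1.0 / k);
  return w;
}

// [[Rcpp::export]]
arma::vec cpp_simplex_ls(const arma::mat& M, const arma::vec& b) {
  mat G = M.t() * M;
  vec f = M.t() * b;
  return simplex_ls_gram(G, f, vec());
}

// Decompose each row of X (n x d) onto archetypes Z (k x d) under simplex
// constraints; returns the n x k weight matrix.
// [[Rcpp::export]]
arma::mat cpp_simplex_decompose(const arma::mat& X, const arma::mat& Z) {
  mat G = Z * Z.t();
  mat F = Z * X.t();  // k x n
  mat A(X.n_rows, Z.n_rows);
  for (uword i = 0; i < X.n_rows; ++i) {
    A.row(i) = simplex_ls_gram(G, F.col(i), vec()).t();
  }
  return A;
}

// Alternating fit: A-step is an exact per-row simplex LS given Z = B X;
// B-step is per-archetype Gauss-Seidel coordinate descent. For archetype j
// the objective restricted to z_j is ||a_j||^2 ||z_j - z*_j||^2 + const with
// z*_j = R_j' a_j / ||a_j||^2, so projecting z*_j onto conv(X) under simplex
// weights is the exact minimizer over B_j; every step is therefore
// non-increasing in RSS.
// [[Rcpp::export]]
Rcpp::List cpp_fit_aa(const arma::mat& X, int k, const arma::uvec& init_idx,
                      double tol, int max_iter) {
  const uword n = X.n_rows;
  mat B(k, n, fill::zeros);
  for (uword j = 0; j < static_cast<uword>(k); ++j) B(j, init_idx(j)) = 1.0;
  mat Z = B * X;
  mat XXt = X * X.t();

  mat A;
  std::vector<double> rss_hist;
  double rss = datum::inf, rss_prev = datum::inf;
  bool converged = false;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    // A-step
    A = cpp_simplex_decompose(X, Z);
    mat R = X - A * Z;
    rss = accu(R % R);
    rss_hist.push_back(rss);
    if (std::isfinite(rss_prev) &&
        (rss_prev - rss) <= tol * std::max(rss_prev, 1e-12)) {
      converged = true;
      break;
    }
    rss_prev = rss;

    // B-step (Gauss-Seidel over archetypes, warm-started)
    for (uword j = 0; j < static_cast<uword>(k); ++j) {
      vec aj = A.col(j);
      double na = dot(aj, aj);
      if (na < 1e-12) continue;  // unused archetype: leave as is
      // ideal archetype: z*_j = (R + a_j z_j)' a_j / ||a_j||^2
      rowvec zstar = (aj.t() * R) / na + Z.row(j);
      vec fj = X * zstar.t();
      vec bj = simplex_ls_gram(XXt, fj, B.row(j).t());
      rowvec znew = bj.t() * X;
      R += aj * (Z.row(j) - znew);
      Z.row(j) = znew;
      B.row(j) = bj.t();
    }
  }
  if (it > max_iter) it = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("archetypes") = Z,
      Rcpp::Named("A") = A,
      Rcpp::Named("B") = B,
      Rcpp::Named("rss") = rss,
      Rcpp::Named("rss_history") = rss_hist,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iter") = it);
}
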