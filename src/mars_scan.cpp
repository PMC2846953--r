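// Exact candidate search for the spline forward pass.
//
// For every allowed (parent basis function, variable) pair, scans all
// candidate knots c of the variable (observed values, thinned by
// min_span) and computes the residual-sum-of-squares reduction obtained
// by adding the reflected hinge pair
//     b1 = parent * max(0, x - c),   b2 = parent * max(0, c - x)
// to the current design. The scan is O(n * m) per (parent, variable)
// via prefix sums over the sorted variable, plus O(m^2) per knot for the
// projection against the current design.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List scan_hinge_pairs(const arma::mat& X, const arma::mat& Ginv,
                            const arma::vec& r, const arma::mat& Z,
                            const arma::mat& P,
                            const arma::imat& allowed,
                            const int min_span, const double eps) {
  const uword p = Z.n_cols, q = P.n_cols;

  mat best_drss(q, p); best_drss.fill(-1.0);
  mat best_knot(q, p); best_knot.fill(datum::nan);
  imat best_kind(q, p, fill::zeros);  // 2 = pair, 1 = upper, -1 = lower

  for (uword qi = 0; qi < q; ++qi) {
    uvec act = find(P.col(qi) != 0.0);
    const uword na = act.n_elem;
    if (na < (uword)(2 * min_span)) continue;

    vec pa = P(act, uvec{qi});
    vec ra = r(act);
    mat Xa = X.rows(act);

    for (uword j = 0; j < p; ++j) {
      if (!allowed(qi, j)) continue;
      vec xa = Z(act, uvec{j});
      uvec ord = stable_sort_index(xa);
      vec xs = xa(ord);
      if (xs(na - 1) <= xs(0)) continue;  // constant on active rows

      vec ps = pa(ord), rs = ra(ord);
      mat Xs = Xa.rows(ord);

      // prefix cumulative sums (ascending in x)
      vec p2 = square(ps);
      vec c_pr = cumsum(ps % rs);
      vec c_pxr = cumsum(ps % xs % rs);
      vec c_p2 = cumsum(p2);
      vec c_p2x = cumsum(p2 % xs);
      vec c_p2x2 = cumsum(p2 % square(xs));
      mat c_pX = cumsum(Xs.each_col() % ps, 0);
      mat c_pxX = cumsum(Xs.each_col() % (ps % xs), 0);

      const double t_pr = c_pr(na - 1), t_pxr = c_pxr(na - 1);
      const double t_p2 = c_p2(na - 1), t_p2x = c_p2x(na - 1),
                   t_p2x2 = c_p2x2(na - 1);
      rowvec t_pX = c_pX.row(na - 1), t_pxX = c_pxX.row(na - 1);

      double prev_knot = datum::nan;
      for (uword k = (uword)min_span; k + (uword)min_span <= na;
           k += (uword)min_span) {
        const double c = xs(k - 1);  // k-th order statistic (1-based)
        if (std::isfinite(prev_knot) && c == prev_knot) continue;
        prev_knot = c;
        const uword i = k - 1;

        // b1 = p * (x - c) over x > c  (suffix sums)
        double b1b1 = (t_p2x2 - c_p2x2(i)) - 2.0 * c * (t_p2x - c_p2x(i)) +
                      c * c * (t_p2 - c_p2(i));
        double c1 = (t_pxr - c_pxr(i)) - c * (t_pr - c_pr(i));
        // b2 = p * (c - x) over x < c  (prefix sums)
        double b2b2 = c * c * c_p2(i) - 2.0 * c * c_p2x(i) + c_p2x2(i);
        double c2 = c * c_pr(i) - c_pxr(i);

        vec v1 = ((t_pxX - c_pxX.row(i)) - c * (t_pX - c_pX.row(i))).t();
        vec v2 = (c * c_pX.row(i) - c_pxX.row(i)).t();
        vec u1 = Ginv * v1;
        double M11 = b1b1 - dot(v1, u1);
        double M22 = b2b2 - dot(v2, Ginv * v2);
        double M12 = -dot(v2, u1);  // b1'b2 = 0 pointwise

        bool ok1 = b1b1 > 0.0 && M11 > eps * b1b1;
        bool ok2 = b2b2 > 0.0 && M22 > eps * b2b2;

        double drss = -1.0;
        int kind = 0;
        if (ok1 && ok2) {
          double det = M11 * M22 - M12 * M12;
          if (det > eps * M11 * M22) {
            drss = (M22 * c1 * c1 - 2.0 * M12 * c1 * c2 + M11 * c2 * c2) /
                   det;
            kind = 2;
          }
        }
        if (kind == 0) {
          double d1 = ok1 ? c1 * c1 / M11 : -1.0;
          double d2 = ok2 ? c2 * c2 / M22 : -1.0;
          if (d1 >= d2 && d1 > 0.0) { drss = d1; kind = 1; }
          else if (d2 > 0.0) { drss = d2; kind = -1; }
        }
        if (kind != 0 && drss > best_drss(qi, j)) {
          best_drss(qi, j) = drss;
          best_knot(qi, j) = c;
          best_kind(qi, j) = kind;
        }
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("drss") = best_drss,
                            Rcpp::Named("knot") = best_knot,
                            Rcpp::Named("kind") = best_kind);
}
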