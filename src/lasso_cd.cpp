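#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent LASSO path on pre-standardized inputs.
//
// Solves, for each lambda in decreasing order with warm starts,
//   min_beta  (1/2) beta' C beta - b' beta + lambda * ||beta||_1
// where C = X'X/n (Gram of standardized predictors) and b = X'y_c/n.
// This is the normal-equation form of (1/(2n))||y_c - X beta||^2 +
// lambda ||beta||_1 up to a constant, the objective used throughout
// the regression stage.  Covariance updates make each coordinate step
// O(p), independent of the sample count.
//
// [[Rcpp::export(name = ".cd_lasso_path")]]
NumericMatrix cd_lasso_path(NumericMatrix C, NumericVector b,
                            NumericVector lambda,
                            double tol, int maxit) {
  const int p = b.size();
  const int nl = lambda.size();
  NumericMatrix B(p, nl);
  std::vector<double> beta(p, 0.0);

  for (int l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    for (int it = 0; it < maxit; ++it) {
      double dmax = 0.0;
      for (int j = 0; j < p; ++j) {
        double cjj = C(j, j);
        if (cjj <= 0.0) { beta[j] = 0.0; continue; }
        double r = b[j] + cjj * beta[j];
        for (int k = 0; k < p; ++k) r -= C(j, k) * beta[k];
        double bj = 0.0;
        if (r > lam) bj = (r - lam) / cjj;
        else if (r < -lam) bj = (r + lam) / cjj;
        double d = bj - beta[j];
        if (d != 0.0) {
          beta[j] = bj;
          double ad = d < 0 ? -d : d;
          if (ad > dmax) dmax = ad;
        }
      }
      if (dmax < tol) break;
    }
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
  }
  return B;
}

// Fitch small parsimony for one binary character on a rooted tree.
//
// Nodes are numbered 1..n_node; children are given per internal node in
// postorder.  Leaf states are 1 (absent), 2 (present) or 3 (missing /
// either).  Returns the minimum number of state changes.
//
// [[Rcpp::export(name = ".fitch_count")]]
int fitch_count(IntegerVector postorder, IntegerVector child_ptr,
                IntegerVector child_idx, IntegerVector leaf_state,
                int n_node) {
  std::vector<int> state(n_node + 1, 0);
  for (int i = 0; i < leaf_state.size(); ++i) state[i + 1] = leaf_state[i];
  int changes = 0;
  for (int i = 0; i < postorder.size(); ++i) {
    int v = postorder[i];
    int from = child_ptr[v - 1], to = child_ptr[v];
    int inter = 3, uni = 0;
    bool any = false;
    for (int c = from; c < to; ++c) {
      int s = state[child_idx[c]];
      if (s == 0 || s == 3) continue;  // missing children are skipped
      any = true;
      inter &= s;
      uni |= s;
    }
    if (!any) { state[v] = 3; continue; }
    if (inter != 0) state[v] = inter;
    else { state[v] = uni; ++changes; }
  }
  return changes;
}
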