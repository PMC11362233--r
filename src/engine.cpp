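#include <Rcpp.h>
using namespace Rcpp;

// Numerically stable log(exp(a) + exp(b)).
static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = (a > b) ? a : b;
  return m + log1p(exp(-fabs(a - b)));
}

// Pointwise log-likelihood of decomposed tree responses.
//
// theta : N x T matrix of person parameters (one column per latent trait)
// ipar  : I x P matrix of item parameters (expanded, estimation scale)
// X     : N x (I*H) integer matrix of pseudo-responses, column (i-1)*H + h;
//         values 0..K_h, any negative value is skipped (missing by design or
//         respondent missing)
// nodes : list of H node descriptions, each a list with elements
//         K (int), tau_cols (0-based int vector, length K),
//         kind (int vector, 1 = dominance, 0 = ideal point),
//         trait (0-based cols of theta), disc (0-based cols of ipar),
//         loc_type (0 none, 1 column, 2 ratio num/den),
//         loc1, loc2 (0-based cols of ipar),
//         weights (R x (K+1) matrix of scoring weights)
// which_nodes : 1-based node indices to include (others contribute 0)
// reduce : 0 = N x I matrix, 1 = per person, 2 = per item, 3 = scalar
//
// Each pseudo-item follows the two-exponential divide-by-total form: for
// category y the two linear predictors share the category intercept cumsum
// and differ only in ideal-point scoring weights (s_y vs M - s_y, M = 2K+1).
// [[Rcpp::export]]
SEXP ll_tree_engine(NumericMatrix theta, NumericMatrix ipar, IntegerMatrix X,
                    List nodes, IntegerVector which_nodes, int reduce) {
  const int N = theta.nrow();
  const int H = nodes.size();
  const int I = X.ncol() / H;

  std::vector<bool> use(H, false);
  for (int j = 0; j < which_nodes.size(); ++j) use[which_nodes[j] - 1] = true;

  NumericMatrix outM;
  NumericVector outV;
  double outS = 0.0;
  if (reduce == 0) outM = NumericMatrix(N, I);
  else if (reduce == 1) outV = NumericVector(N);
  else if (reduce == 2) outV = NumericVector(I);

  std::vector<double> ct, lw, a, b;

  for (int h = 0; h < H; ++h) {
    if (!use[h]) continue;
    List nd = nodes[h];
    const int K = as<int>(nd["K"]);
    IntegerVector tau_cols = nd["tau_cols"];
    IntegerVector kind = nd["kind"];
    IntegerVector trait = nd["trait"];
    IntegerVector disc = nd["disc"];
    IntegerVector loc_type = nd["loc_type"];
    IntegerVector loc1 = nd["loc1"];
    IntegerVector loc2 = nd["loc2"];
    NumericMatrix w = nd["weights"];
    const int R = kind.size();
    const double M = 2.0 * K + 1.0;

    ct.assign(K + 1, 0.0);
    lw.assign(K + 1, 0.0);
    a.assign(K + 1, 0.0);
    b.assign(K + 1, 0.0);
    std::vector<double> dsc(R), loc(R);

    for (int i = 0; i < I; ++i) {
      // cumulative category intercepts, tau_0 = 0
      for (int y = 1; y <= K; ++y) ct[y] = ct[y - 1] + ipar(i, tau_cols[y - 1]);
      for (int r = 0; r < R; ++r) {
        dsc[r] = ipar(i, disc[r]);
        if (loc_type[r] == 1) loc[r] = ipar(i, loc1[r]);
        else if (loc_type[r] == 2) loc[r] = ipar(i, loc1[r]) / ipar(i, loc2[r]);
        else loc[r] = 0.0;
      }
      const int col = i * H + h;
      for (int v = 0; v < N; ++v) {
        const int x = X(v, col);
        if (x < 0) continue;
        for (int y = 0; y <= K; ++y) { a[y] = -ct[y]; b[y] = -ct[y]; }
        for (int r = 0; r < R; ++r) {
          const double tv = theta(v, trait[r]);
          if (kind[r] == 1) {
            for (int y = 0; y <= K; ++y) {
              const double t = dsc[r] * w(r, y) * tv;
              a[y] += t; b[y] += t;
            }
          } else {
            const double d = tv - loc[r];
            for (int y = 0; y <= K; ++y) {
              a[y] += dsc[r] * w(r, y) * d;
              b[y] += dsc[r] * (M - w(r, y)) * d;
            }
          }
        }
        double mx = R_NegInf;
        for (int y = 0; y <= K; ++y) {
          lw[y] = logadd(a[y], b[y]);
          if (lw[y] > mx) mx = lw[y];
        }
        double s = 0.0;
        for (int y = 0; y <= K; ++y) s += exp(lw[y] - mx);
        const double ll = lw[x] - mx - log(s);
        if (reduce == 0) outM(v, i) += ll;
        else if (reduce == 1) outV[v] += ll;
        else if (reduce == 2) outV[i] += ll;
        else outS += ll;
      }
    }
  }
  if (reduce == 0) return outM;
  if (reduce == 3) return wrap(outS);
  return outV;
}
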