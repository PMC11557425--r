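#include <Rcpp.h>
using namespace Rcpp;

// Sequence-order-preserving alignment (Needleman-Wunsch, gap penalty 0)
// maximizing the summed pair weights in W (query rows x reference columns).
// Returns the matched index pairs, 1-based, in chain order.
// [[Rcpp::export]]
IntegerMatrix dp_align_cpp(NumericMatrix W) {
  const int n = W.nrow(), m = W.ncol();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix T(n + 1, m + 1); // 0 = diagonal, 1 = up (gap in ref), 2 = left
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double diag = H(i - 1, j - 1) + W(i - 1, j - 1);
      const double up = H(i - 1, j);
      const double left = H(i, j - 1);
      if (diag >= up && diag >= left) {
        H(i, j) = diag; T(i, j) = 0;
      } else if (up >= left) {
        H(i, j) = up; T(i, j) = 1;
      } else {
        H(i, j) = left; T(i, j) = 2;
      }
    }
  }
  std::vector<int> qi, rj;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    if (T(i, j) == 0) {
      qi.push_back(i); rj.push_back(j); --i; --j;
    } else if (T(i, j) == 1) {
      --i;
    } else {
      --j;
    }
  }
  const int k = static_cast<int>(qi.size());
  IntegerMatrix out(k, 2);
  for (int t = 0; t < k; ++t) {
    out(k - 1 - t, 0) = qi[t];
    out(k - 1 - t, 1) = rj[t];
  }
  return out;
}
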