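#include <Rcpp.h>
using namespace Rcpp;

// Pairwise L1 (Manhattan) distance between the rows of a non-negative sparse
// matrix in dgCMatrix layout. Uses |a - b| = a + b - 2 * min(a, b), which for
// non-negative entries lets the all-zero pairs be covered by the row sums and
// only co-nonzero pairs within a column need explicit work, so the cost is
// sum over columns of nnz(column)^2 rather than nrow^2 * ncol.
// [[Rcpp::export]]
NumericMatrix pairwise_l1_sparse(S4 mat) {
  IntegerVector dim = mat.slot("Dim");
  IntegerVector p = mat.slot("p");
  IntegerVector i = mat.slot("i");
  NumericVector x = mat.slot("x");
  const int n = dim[0], ncol = dim[1];

  NumericVector rowsum(n);
  NumericMatrix smin(n, n); // lower triangle holds sum over columns of min()

  for (int c = 0; c < ncol; ++c) {
    const int s = p[c], e = p[c + 1];
    for (int a = s; a < e; ++a) {
      const int ra = i[a];
      const double xa = x[a];
      if (xa < 0) stop("pairwise_l1_sparse requires non-negative entries");
      rowsum[ra] += xa;
      for (int b = a + 1; b < e; ++b) {
        const int rb = i[b];
        const double m = xa < x[b] ? xa : x[b];
        if (ra > rb) smin(ra, rb) += m; else smin(rb, ra) += m;
      }
    }
  }

  NumericMatrix D(n, n);
  for (int r = 0; r < n; ++r) {
    D(r, r) = 0.0;
    for (int c2 = 0; c2 < r; ++c2) {
      double d = rowsum[r] + rowsum[c2] - 2.0 * smin(r, c2);
      if (d < 0) d = 0; // guard against rounding
      D(r, c2) = d;
      D(c2, r) = d;
    }
  }
  return D;
}
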