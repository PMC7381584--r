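#include <Rcpp.h>
using namespace Rcpp;

// Sequential conditional sampling of integer contingency tables with fixed
// marginal totals, from the multiple hypergeometric distribution (the
// conditional law of independent cells given both margins).  Cells are filled
// row by row; cell (i, j) given everything placed so far is hypergeometric:
// of the rowrem items left for row i, the number landing in column j when the
// remaining column capacities are colrem[j..c-1].
//
// Uses R's RNG so draws are reproducible under set.seed().

// [[Rcpp::export]]
IntegerVector patefield_cpp(IntegerVector row_sums, IntegerVector col_sums,
                            int nrep) {
  const int r = row_sums.size(), c = col_sums.size();
  if (nrep < 1) stop("nrep must be >= 1");
  long total_r = 0, total_c = 0;
  for (int i = 0; i < r; ++i) {
    if (row_sums[i] < 0) stop("negative row total");
    total_r += row_sums[i];
  }
  for (int j = 0; j < c; ++j) {
    if (col_sums[j] < 0) stop("negative column total");
    total_c += col_sums[j];
  }
  if (total_r != total_c) stop("row and column totals must agree");

  IntegerVector out(Dimension(r, c, nrep));
  std::vector<long> colrem(c);

  for (int k = 0; k < nrep; ++k) {
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
    for (int j = 0; j < c; ++j) colrem[j] = col_sums[j];
    long totrem = total_r;
    const int base = k * r * c;
    for (int i = 0; i < r; ++i) {
      long rowrem = row_sums[i];
      long rest = totrem;  // sum of colrem[j..c-1] as j advances
      for (int j = 0; j < c; ++j) {
        long nij;
        if (j == c - 1) {
          nij = rowrem;
        } else if (rowrem == 0) {
          nij = 0;
        } else {
          nij = (long)::Rf_rhyper((double)colrem[j],
                                  (double)(rest - colrem[j]),
                                  (double)rowrem);
        }
        out[base + j * r + i] = (int)nij;
        rowrem -= nij;
        rest -= colrem[j];
        colrem[j] -= nij;
      }
      totrem -= row_sums[i];
    }
  }
  return out;
}
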