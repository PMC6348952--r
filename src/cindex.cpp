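#include <Rcpp.h>
using namespace Rcpp;

// Pairwise tally for Harrell's concordance index.
// A pair (i, j) is comparable iff one member is an observed event with a
// strictly earlier time than the other's follow-up time. Scores are
// survival-oriented (higher = longer predicted survival), so concordance
// means the earlier failure has the lower score. Tied scores tally as ties.
// [[Rcpp::export]]
NumericVector cindex_tally(NumericVector time, IntegerVector event,
                           NumericVector score) {
  const R_xlen_t n = time.size();
  double concordant = 0.0, tied = 0.0, comparable = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (event[i] != 1) continue;
    for (R_xlen_t j = 0; j < n; ++j) {
      if (j == i) continue;
      if (time[i] < time[j]) {
        comparable += 1.0;
        if (score[i] < score[j]) concordant += 1.0;
        else if (score[i] == score[j]) tied += 1.0;
      }
    }
  }
  // each unordered pair with two events and distinct times is seen once
  // (from the earlier failure); event/censored pairs likewise.
  return NumericVector::create(concordant, tied, comparable);
}
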