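#include <Rcpp.h>
using namespace Rcpp;

// Pairwise counts for Harrell's C on right-censored data.
// A pair (i, j) is comparable iff time[i] < time[j] and event[i] == 1;
// tied times are never comparable. Concordant when score[i] > score[j]
// (higher score = higher risk = earlier event); equal scores count as ties.
// Returns c(concordant, tied_score, comparable).
// [[Rcpp::export(name = ".concordance_counts")]]
NumericVector concordance_counts(NumericVector score, NumericVector time,
                                 IntegerVector event) {
  const int n = score.size();
  double conc = 0.0, tied = 0.0, comp = 0.0;
  for (int i = 0; i < n; ++i) {
    if (event[i] != 1) continue;
    const double ti = time[i], si = score[i];
    for (int j = 0; j < n; ++j) {
      if (ti < time[j]) {
        comp += 1.0;
        if (si > score[j]) conc += 1.0;
        else if (si == score[j]) tied += 1.0;
      }
    }
  }
  return NumericVector::create(conc, tied, comp);
}
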