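#include <Rcpp.h>
using namespace Rcpp;

// Pairwise scan for Harrell's concordance under right censoring.
// A pair is usable when the ordering of death times is determinable:
// the earlier observed time must be an event; ties in time are usable
// only when exactly one of the pair is an event (the censored subject
// is known to have survived past the tied death). Score ties count 0.5.
// Scores are risk-oriented: higher score should mean earlier death.
// [[Rcpp::export(name = ".cindex_counts")]]
NumericVector cindex_counts(NumericVector score, NumericVector time,
                            IntegerVector event) {
  const R_xlen_t n = score.size();
  double concordant = 0.0, usable = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double ti = time[i], tj = time[j];
      int di = event[i], dj = event[j];
      R_xlen_t first;  // the pair member known to die first
      if (ti < tj) {
        if (di != 1) continue;
        first = i;
      } else if (tj < ti) {
        if (dj != 1) continue;
        first = j;
      } else {
        if (di + dj != 1) continue;  // tie: need exactly one event
        first = (di == 1) ? i : j;
      }
      usable += 1.0;
      double s_first = (first == i) ? score[i] : score[j];
      double s_other = (first == i) ? score[j] : score[i];
      if (s_first > s_other) concordant += 1.0;
      else if (s_first == s_other) concordant += 0.5;
    }
  }
  return NumericVector::create(concordant, usable);
}
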