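#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ungapped scan: every 0-based start where `pattern` matches
// `subject` with at most `max_mm` mismatches. An N in the pattern matches
// nothing (always a mismatch). Early exit once max_mm is exceeded keeps the
// scan effectively O(subject length) for small mismatch budgets.
// [[Rcpp::export]]
List scan_ungapped(const std::string& subject, const std::string& pattern,
                   int max_mm) {
  const int L = subject.size();
  const int w = pattern.size();
  std::vector<int> starts;
  std::vector<int> mms;
  if (w > 0 && w <= L) {
    for (int i = 0; i + w <= L; ++i) {
      int mm = 0;
      for (int j = 0; j < w; ++j) {
        const char p = pattern[j];
        if (p == 'N' || p != subject[i + j]) {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) {
        starts.push_back(i);
        mms.push_back(mm);
      }
    }
  }
  return List::create(_["start"] = wrap(starts),
                      _["mismatches"] = wrap(mms));
}
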