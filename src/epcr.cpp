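#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ungapped scan of a primer-length pattern over one target strand.
// Positions outside the 5' window must match exactly (this includes the 3'
// terminus); mismatches inside the window are counted and capped by both the
// window cap and the overall identity floor. `window_on_left` is true when
// the pattern's 5' end is its leftmost base (plus-strand orientation); for a
// reverse-complemented pattern the 5' window sits at the right end.
// [[Rcpp::export]]
DataFrame cpp_scan_primer(std::string target, std::string pattern,
                          int window, int max_mm, double min_identity,
                          bool window_on_left) {
  const int n = (int)target.size();
  const int L = (int)pattern.size();
  std::vector<int> starts;
  std::vector<int> mms;
  if (n >= L && L > 0) {
    int cap = (int)std::floor(L * (1.0 - min_identity) + 1e-9);
    if (cap > max_mm) cap = max_mm;
    if (cap < 0) cap = 0;
    const char *t = target.c_str();
    const char *p = pattern.c_str();
    for (int i = 0; i + L <= n; ++i) {
      bool ok = true;
      int mm = 0;
      if (window_on_left) {
        for (int j = window; j < L; ++j)
          if (t[i + j] != p[j]) { ok = false; break; }
        if (!ok) continue;
        for (int j = 0; j < window && mm <= cap; ++j)
          if (t[i + j] != p[j]) ++mm;
      } else {
        for (int j = 0; j < L - window; ++j)
          if (t[i + j] != p[j]) { ok = false; break; }
        if (!ok) continue;
        for (int j = L - window; j < L && mm <= cap; ++j)
          if (t[i + j] != p[j]) ++mm;
      }
      if (mm <= cap) {
        starts.push_back(i + 1);  // 1-based
        mms.push_back(mm);
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["mismatches"] = mms);
}
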