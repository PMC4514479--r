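#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Score every window of one encoded sequence (codes 1..4, 0 = ambiguous)
// against a PWM's exact (bits) and discretized (integer) log-odds tables.
// Windows containing an ambiguous base are skipped. Reverse-strand windows
// score the reverse complement; their reported offset is the site's
// position on the forward strand.
// [[Rcpp::export]]
List scan_windows_cpp(IntegerVector code, IntegerMatrix icell,
                      NumericMatrix lo, bool both_strands) {
  const int n = code.size(), W = icell.ncol();
  const int nw = n - W + 1;
  std::vector<int> off, istrand, ints;
  std::vector<double> bits;
  if (nw > 0) {
    off.reserve(2 * nw);
    for (int i = 0; i < nw; ++i) {
      double b = 0;
      int s = 0;
      bool ok = true;
      for (int w = 0; w < W; ++w) {
        const int c = code[i + w];
        if (c == 0) { ok = false; break; }
        b += lo(c - 1, w);
        s += icell(c - 1, w);
      }
      if (!ok) continue;
      off.push_back(i);
      istrand.push_back(1);
      bits.push_back(b);
      ints.push_back(s);
    }
    if (both_strands) {
      for (int i = 0; i < nw; ++i) {
        // reverse complement of the window starting at i
        double b = 0;
        int s = 0;
        bool ok = true;
        for (int w = 0; w < W; ++w) {
          const int c = code[i + W - 1 - w];
          if (c == 0) { ok = false; break; }
          const int rc = 5 - c;
          b += lo(rc - 1, w);
          s += icell(rc - 1, w);
        }
        if (!ok) continue;
        off.push_back(i);
        istrand.push_back(2);
        bits.push_back(b);
        ints.push_back(s);
      }
    }
  }
  return List::create(
      _["offset"] = IntegerVector(off.begin(), off.end()),
      _["istrand"] = IntegerVector(istrand.begin(), istrand.end()),
      _["bits"] = NumericVector(bits.begin(), bits.end()),
      _["int"] = IntegerVector(ints.begin(), ints.end()));
}
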