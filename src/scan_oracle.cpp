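#include <Rcpp.h>
#include <string>
#include <vector>
#include <cctype>
using namespace Rcpp;

// Reference scanner: for every position and every allowed period, extend the
// maximal perfect run by direct character comparison, then apply the
// left-to-right greedy selection policy (longest qualifying run, smallest
// period on ties, resume after the chosen run's end).  Deliberately naive:
// it trades speed for transparency and is used to validate the vectorised
// scanner and to build ground-truth locus tables for synthetic genomes.

static bool motif_primitive(const std::string &s, int start, int p) {
  for (int d = 1; d < p; ++d) {
    if (p % d != 0) continue;
    bool periodic = true;
    for (int i = 0; i < p - d; ++i) {
      if (s[start + i] != s[start + i + d]) { periodic = false; break; }
    }
    if (periodic) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".scan_oracle_cpp")]]
DataFrame scan_oracle_cpp(std::string seq, IntegerVector periods,
                          IntegerVector min_copies) {
  const int n = (int) seq.size();
  std::vector<bool> valid(n);
  for (int i = 0; i < n; ++i) {
    char c = (char) std::toupper((unsigned char) seq[i]);
    seq[i] = c;
    valid[i] = (c == 'A' || c == 'C' || c == 'G' || c == 'T');
  }
  const int np = periods.size();

  std::vector<int> out_start, out_end, out_period, out_copies;

  int pos = 0;
  while (pos < n) {
    int best_len = -1, best_p = 0;
    for (int k = 0; k < np; ++k) {
      const int p = periods[k];
      if (pos + p > n) continue;
      // maximal run at pos: every char pairs with the one a period later
      int len = p;
      while (pos + len < n && valid[pos + len] && valid[pos + len - p] &&
             seq[pos + len] == seq[pos + len - p]) ++len;
      bool ok = true;
      for (int i = pos; i < pos + p; ++i) if (!valid[i]) { ok = false; break; }
      if (!ok) continue;
      const int copies = len / p;
      if (copies < min_copies[k]) continue;
      if (!motif_primitive(seq, pos, p)) continue;
      if (len > best_len || (len == best_len && p < best_p)) {
        best_len = len; best_p = p;
      }
    }
    if (best_len > 0) {
      out_start.push_back(pos);
      out_end.push_back(pos + best_len);
      out_period.push_back(best_p);
      out_copies.push_back(best_len / best_p);
      pos += best_len;
    } else {
      ++pos;
    }
  }

  return DataFrame::create(
    Named("start") = wrap(out_start),
    Named("end") = wrap(out_end),
    Named("period") = wrap(out_period),
    Named("copies") = wrap(out_copies));
}
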