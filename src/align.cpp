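#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Global Needleman-Wunsch alignment with unit costs (match 0, mismatch 1,
// gap 1), so the alignment cost equals the Levenshtein edit distance.
// Traceback tie-breaking is deterministic: prefer the diagonal move
// (match/substitution) over gaps, then a gap in the read (deletion of a
// reference base) over a gap in the reference (insertion).
// [[Rcpp::export(name = ".nw_align_batch")]]
List nw_align_batch(CharacterVector reads, std::string ref) {
  const int m = ref.size();
  const int n_reads = reads.size();
  CharacterVector read_aln(n_reads), ref_aln(n_reads);
  IntegerVector cost(n_reads);

  std::vector<int> dp;
  for (int r = 0; r < n_reads; ++r) {
    const std::string read = as<std::string>(reads[r]);
    const int n = read.size();
    dp.assign((size_t)(n + 1) * (m + 1), 0);
    const int W = m + 1;
    for (int j = 0; j <= m; ++j) dp[j] = j;
    for (int i = 1; i <= n; ++i) {
      dp[(size_t)i * W] = i;
      const char a = read[i - 1];
      for (int j = 1; j <= m; ++j) {
        const int sub = dp[(size_t)(i - 1) * W + (j - 1)] + (a != ref[j - 1]);
        const int del = dp[(size_t)i * W + (j - 1)] + 1;  // gap in read
        const int ins = dp[(size_t)(i - 1) * W + j] + 1;  // gap in ref
        dp[(size_t)i * W + j] = std::min(sub, std::min(del, ins));
      }
    }
    cost[r] = dp[(size_t)n * W + m];

    std::string ra, sa;  // built backwards
    ra.reserve(n + m);
    sa.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
      const int cur = dp[(size_t)i * W + j];
      if (i > 0 && j > 0 &&
          cur == dp[(size_t)(i - 1) * W + (j - 1)] +
                     (read[i - 1] != ref[j - 1])) {
        ra.push_back(read[i - 1]);
        sa.push_back(ref[j - 1]);
        --i; --j;
      } else if (j > 0 && cur == dp[(size_t)i * W + (j - 1)] + 1) {
        ra.push_back('-');
        sa.push_back(ref[j - 1]);
        --j;
      } else {
        ra.push_back(read[i - 1]);
        sa.push_back('-');
        --i;
      }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(sa.begin(), sa.end());
    read_aln[r] = ra;
    ref_aln[r] = sa;
  }
  return List::create(_["read"] = read_aln, _["ref"] = ref_aln,
                      _["cost"] = cost);
}
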