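#include <Rcpp.h>
#include <algorithm>

using namespace Rcpp;

// Quality trimming, mirroring the cited trimmer's semantics:
//  1. clip leading/trailing bases with phred <= end_clip_max
//  2. slide a window of `window` bases 5'->3'; at the first window whose mean
//     phred < win_min_mean, keep bases from the window start while their
//     individual phred >= win_min_mean, cut there
//  3. results shorter than min_length are discarded (keep = FALSE)

// [[Rcpp::export]]
List cpp_trim_reads(CharacterVector seqs, CharacterVector quals, int window,
                    double win_min_mean, int end_clip_max, int min_length) {
    int n = seqs.size();
    CharacterVector oseq(n), oqual(n);
    LogicalVector keep(n);
    for (int r = 0; r < n; ++r) {
        std::string s = as<std::string>(seqs[r]);
        std::string q = as<std::string>(quals[r]);
        if (s.size() != q.size())
            stop("sequence/quality length mismatch in read %d", r + 1);
        int lo = 0, hi = (int)s.size();
        while (lo < hi && (int)q[lo] - 33 <= end_clip_max) ++lo;
        while (hi > lo && (int)q[hi - 1] - 33 <= end_clip_max) --hi;
        // sliding window over the clipped read
        int cut = hi;
        if (hi - lo >= window) {
            int wsum = 0;
            for (int i = lo; i < lo + window; ++i) wsum += (int)q[i] - 33;
            for (int i = lo;; ++i) {
                if ((double)wsum / window < win_min_mean) {
                    cut = i;
                    while (cut < hi && (int)q[cut] - 33 >= win_min_mean) ++cut;
                    break;
                }
                if (i + window >= hi) break;
                wsum += ((int)q[i + window] - 33) - ((int)q[i] - 33);
            }
        }
        int len = cut - lo;
        if (len < min_length) {
            keep[r] = false;
            oseq[r] = ""; oqual[r] = "";
        } else {
            keep[r] = true;
            oseq[r] = s.substr(lo, len);
            oqual[r] = q.substr(lo, len);
        }
    }
    return List::create(_["sequence"] = oseq, _["quality"] = oqual,
                        _["keep"] = keep);
}
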