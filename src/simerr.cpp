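#include <Rcpp.h>
#include "dna_utils.h"

using namespace Rcpp;

// Per-base substitution errors using R's RNG so results are reproducible
// under set.seed(). Each base is replaced, with probability `rate`, by a
// uniformly chosen different base.
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector seqs, double rate) {
    if (rate < 0 || rate >= 1) stop("error rate must be in [0, 1)");
    RNGScope scope;
    CharacterVector out(seqs.size());
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        if (rate > 0) {
            for (size_t j = 0; j < s.size(); ++j) {
                if (unif_rand() < rate) {
                    int cur = base_code(s[j]);
                    if (cur < 0) continue;
                    int shift = 1 + (int)(unif_rand() * 3.0);
                    if (shift > 3) shift = 3;
                    s[j] = bases[(cur + shift) & 3];
                }
            }
        }
        out[i] = s;
    }
    return out;
}
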