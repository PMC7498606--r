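#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include "dna_utils.h"

using namespace Rcpp;

// Affine-gap local alignment (Gotoh). A gap of length L scores
// gap_open + L * gap_extend (both negative), i.e. the first gapped base
// costs gap_open + gap_extend.

namespace {

inline double subst(char a, char b, double match, double mismatch) {
    int ca = base_code(a), cb = base_code(b);
    if (ca < 0 || cb < 0) return mismatch;  // N never matches
    return (ca == cb) ? match : mismatch;
}

// score-only, O(n) memory
double sw_score(const std::string& q, const std::string& s,
                double match, double mismatch, double go, double ge) {
    size_t m = q.size(), n = s.size();
    double open_cost = go + ge;  // score delta for starting a gap
    std::vector<double> H(n + 1, 0.0), E(n + 1, R_NegInf);
    double best = 0.0;
    for (size_t i = 1; i <= m; ++i) {
        double Hdiag = H[0];  // H[i-1][0]
        double F = R_NegInf;
        H[0] = 0.0;
        for (size_t j = 1; j <= n; ++j) {
            E[j] = std::max(H[j] + open_cost, E[j] + ge);        // gap in query (vertical in s)
            F = std::max(H[j - 1] + open_cost, F + ge);          // gap in subject
            double h = Hdiag + subst(q[i - 1], s[j - 1], match, mismatch);
            h = std::max(h, std::max(E[j], F));
            h = std::max(h, 0.0);
            Hdiag = H[j];
            H[j] = h;
            if (h > best) best = h;
        }
    }
    return best;
}

struct AlnResult {
    double score;
    int qstart, qend, sstart, send;  // 0-based half-open
    int matches, aln_len;
};

// full DP with traceback
AlnResult sw_traceback(const std::string& q, const std::string& s,
                       double match, double mismatch, double go, double ge) {
    size_t m = q.size(), n = s.size();
    if ((double)m * (double)n > 6.4e7)
        stop("sequences too long for full-traceback local alignment");
    double open_cost = go + ge;
    size_t W = n + 1;
    std::vector<double> H((m + 1) * W, 0.0), E((m + 1) * W, R_NegInf),
        F((m + 1) * W, R_NegInf);
    // direction codes for H: 0 stop, 1 diag, 2 E (gap in s-direction), 3 F
    std::vector<unsigned char> dH((m + 1) * W, 0), dE((m + 1) * W, 0), dF((m + 1) * W, 0);
    double best = 0.0;
    size_t bi = 0, bj = 0;
    for (size_t i = 1; i <= m; ++i) {
        for (size_t j = 1; j <= n; ++j) {
            size_t c = i * W + j, up = (i - 1) * W + j, left = c - 1,
                   diag = up - 1;
            double e_open = H[left] + open_cost, e_ext = E[left] + ge;
            E[c] = std::max(e_open, e_ext);
            dE[c] = (e_open >= e_ext) ? 1 : 0;
            double f_open = H[up] + open_cost, f_ext = F[up] + ge;
            F[c] = std::max(f_open, f_ext);
            dF[c] = (f_open >= f_ext) ? 1 : 0;
            double hd = H[diag] + subst(q[i - 1], s[j - 1], match, mismatch);
            double h = 0.0;
            unsigned char d = 0;
            if (hd > h) { h = hd; d = 1; }
            if (E[c] > h) { h = E[c]; d = 2; }
            if (F[c] > h) { h = F[c]; d = 3; }
            H[c] = h;
            dH[c] = d;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    AlnResult r;
    r.score = best;
    r.matches = 0;
    r.aln_len = 0;
    if (best <= 0.0) {
        r.qstart = r.qend = r.sstart = r.send = 0;
        return r;
    }
    size_t i = bi, j = bj;
    int state = 0;  // 0 = in H, 2 = in E, 3 = in F
    for (;;) {
        size_t c = i * W + j;
        if (state == 0) {
            unsigned char d = dH[c];
            if (d == 0) break;
            if (d == 1) {
                ++r.aln_len;
                if (subst(q[i - 1], s[j - 1], 1.0, -1.0) > 0) ++r.matches;
                --i; --j;
            } else state = (int)d;
        } else if (state == 2) {  // gap: consume subject base
            ++r.aln_len;
            int opened = dE[c];
            --j;
            if (opened) state = 0;
        } else {  // state == 3, gap: consume query base
            ++r.aln_len;
            int opened = dF[c];
            --i;
            if (opened) state = 0;
        }
    }
    r.qstart = (int)i;
    r.qend = (int)bi;
    r.sstart = (int)j;
    r.send = (int)bj;
    return r;
}

}  // namespace

// [[Rcpp::export]]
List cpp_sw_align(std::string query, std::string subject, double match,
                  double mismatch, double gap_open, double gap_extend) {
    AlnResult r = sw_traceback(query, subject, match, mismatch, gap_open, gap_extend);
    return List::create(
        _["score"] = r.score, _["qstart"] = r.qstart, _["qend"] = r.qend,
        _["sstart"] = r.sstart, _["send"] = r.send, _["matches"] = r.matches,
        _["aln_len"] = r.aln_len);
}

// best local score of each query against any subject, both query strands
// [[Rcpp::export]]
NumericVector cpp_best_db_scores(CharacterVector queries, CharacterVector db,
                                 double match, double mismatch,
                                 double gap_open, double gap_extend) {
    NumericVector out(queries.size());
    for (R_xlen_t i = 0; i < queries.size(); ++i) {
        std::string q = as<std::string>(queries[i]);
        std::string qr = revcomp_str(q);
        double best = 0.0;
        for (R_xlen_t j = 0; j < db.size(); ++j) {
            std::string s = as<std::string>(db[j]);
            best = std::max(best, sw_score(q, s, match, mismatch, gap_open, gap_extend));
            best = std::max(best, sw_score(qr, s, match, mismatch, gap_open, gap_extend));
        }
        out[i] = best;
    }
    return out;
}
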