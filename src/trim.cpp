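#include <Rcpp.h>
#include <cctype>
#include "dna_utils.h"

using namespace Rcpp;

// Quality-trimming operators. Qualities arrive as Phred+33 strings; every
// operator returns the trimmed (seq, qual) pair, always substrings of the
// input with equal lengths.

static List make_pair(std::vector<std::string>& s, std::vector<std::string>& q) {
    return List::create(_["seq"] = wrap(s), _["qual"] = wrap(q));
}

// [[Rcpp::export]]
List cpp_headcrop(CharacterVector seq, CharacterVector qual, int n) {
    if (n < 0) stop("n must be >= 0");
    R_xlen_t m = seq.size();
    std::vector<std::string> s(m), q(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        std::string si = as<std::string>(seq[i]), qi = as<std::string>(qual[i]);
        size_t cut = std::min((size_t)n, si.size());
        s[i] = si.substr(cut);
        q[i] = qi.substr(cut);
    }
    return make_pair(s, q);
}

// [[Rcpp::export]]
List cpp_leading(CharacterVector seq, CharacterVector qual, int minq) {
    R_xlen_t m = seq.size();
    std::vector<std::string> s(m), q(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        std::string si = as<std::string>(seq[i]), qi = as<std::string>(qual[i]);
        size_t j = 0;
        while (j < qi.size() && (qi[j] - 33) < minq) ++j;
        s[i] = si.substr(j);
        q[i] = qi.substr(j);
    }
    return make_pair(s, q);
}

// [[Rcpp::export]]
List cpp_trailing(CharacterVector seq, CharacterVector qual, int minq) {
    R_xlen_t m = seq.size();
    std::vector<std::string> s(m), q(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        std::string si = as<std::string>(seq[i]), qi = as<std::string>(qual[i]);
        size_t end = qi.size();
        while (end > 0 && (qi[end - 1] - 33) < minq) --end;
        s[i] = si.substr(0, end);
        q[i] = qi.substr(0, end);
    }
    return make_pair(s, q);
}

// Keep the prefix before the first full window (start s = 0,1,...,len-w)
// whose mean quality drops below q. Only complete windows are scanned, so
// the operator is idempotent; reads shorter than w pass unchanged.
// [[Rcpp::export]]
List cpp_sliding_window(CharacterVector seq, CharacterVector qual, int w, double minq) {
    if (w < 1) stop("w must be >= 1");
    R_xlen_t m = seq.size();
    std::vector<std::string> s(m), q(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        std::string si = as<std::string>(seq[i]), qi = as<std::string>(qual[i]);
        size_t len = qi.size(), cut = len;
        if (len >= (size_t)w) {
            double sum = 0.0;
            for (int j = 0; j < w; ++j) sum += (double)(qi[j] - 33);
            for (size_t start = 0; ; ++start) {
                if (sum / (double)w < minq) { cut = start; break; }
                if (start + (size_t)w >= len) break;
                sum += (double)(qi[start + w] - 33) - (double)(qi[start] - 33);
            }
        }
        s[i] = si.substr(0, cut);
        q[i] = qi.substr(0, cut);
    }
    return make_pair(s, q);
}

// Clip when a prefix of an adapter (length >= min_overlap) exactly matches a
// suffix of the read; longest match over all adapters wins. N never matches.
// [[Rcpp::export]]
List cpp_adapter_clip(CharacterVector seq, CharacterVector qual,
                      CharacterVector adapters, int min_overlap) {
    if (adapters.size() == 0) stop("adapters must be non-empty");
    if (min_overlap < 1) stop("min_overlap must be >= 1");
    std::vector<std::string> ads(adapters.size());
    for (R_xlen_t a = 0; a < adapters.size(); ++a)
        ads[a] = as<std::string>(adapters[a]);
    R_xlen_t m = seq.size();
    std::vector<std::string> s(m), q(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        std::string si = as<std::string>(seq[i]), qi = as<std::string>(qual[i]);
        size_t best = 0;  // longest matching overlap
        for (size_t a = 0; a < ads.size(); ++a) {
            size_t maxo = std::min(si.size(), ads[a].size());
            for (size_t o = maxo; o >= (size_t)min_overlap && o > best; --o) {
                bool ok = true;
                size_t off = si.size() - o;
                for (size_t j = 0; j < o; ++j) {
                    char rb = si[off + j], ab = ads[a][j];
                    if (base_code(rb) < 0 || base_code(ab) < 0 ||
                        toupper(rb) != toupper(ab)) { ok = false; break; }
                }
                if (ok) { best = o; break; }
            }
        }
        size_t keep = si.size() - best;
        s[i] = si.substr(0, keep);
        q[i] = qi.substr(0, keep);
    }
    return make_pair(s, q);
}

// keep iff (#bases with quality < q_min) / len <= max_frac; empty -> discard
// [[Rcpp::export]]
LogicalVector cpp_quality_fraction_keep(CharacterVector qual, int q_min, double max_frac) {
    R_xlen_t m = qual.size();
    LogicalVector out(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        std::string qi = as<std::string>(qual[i]);
        if (qi.empty()) { out[i] = false; continue; }
        size_t low = 0;
        for (size_t j = 0; j < qi.size(); ++j)
            if ((qi[j] - 33) < q_min) ++low;
        out[i] = ((double)low / (double)qi.size()) <= max_frac;
    }
    return out;
}
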