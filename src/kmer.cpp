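#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include "dna_utils.h"

using namespace Rcpp;

// Rolling scan over one sequence; calls f(canonical_kmer) for every
// N-free window of length k.
template <typename F>
static void scan_canonical(const char* s, int len, int k, F f) {
    if (len < k) return;
    kmer_t mask = (k == 64) ? (kmer_t)-1 : (((kmer_t)1 << (2 * k)) - 1);
    kmer_t fwd = 0, rc = 0;
    int valid = 0;  // number of consecutive valid bases ending here
    int shift = 2 * (k - 1);
    for (int i = 0; i < len; ++i) {
        int c = base_code(s[i]);
        if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (kmer_t)c) & mask;
        rc = (rc >> 2) | ((kmer_t)(3 - c) << shift);
        if (++valid >= k) f(fwd < rc ? fwd : rc);
    }
}

typedef std::unordered_map<kmer_t, int, KmerHash> kmer_map;

// [[Rcpp::export]]
List cpp_build_catalog(CharacterVector seqs, int k) {
    if (k < 1 || k > 63) stop("k must be in [1, 63]");
    kmer_map counts;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        int len = (int)LENGTH(STRING_ELT(seqs, i));
        scan_canonical(s, len, k, [&](kmer_t km) { counts[km]++; });
    }
    std::vector<std::pair<kmer_t, int> > v(counts.begin(), counts.end());
    std::sort(v.begin(), v.end());
    CharacterVector km(v.size());
    IntegerVector ct(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
        km[i] = unpack_kmer(v[i].first, k);
        ct[i] = v[i].second;
    }
    return List::create(_["kmer"] = km, _["count"] = ct);
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector kmers) {
    CharacterVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        std::string s = as<std::string>(kmers[i]);
        std::string r = revcomp_str(s);
        out[i] = (s < r) ? s : r;
    }
    return out;
}

// mask over kmers_a: count >= min_count and absent from kmers_b.
// Inputs are assumed canonical (as produced by cpp_build_catalog).
// [[Rcpp::export]]
LogicalVector cpp_subtract_mask(CharacterVector kmers_a, IntegerVector counts_a,
                                CharacterVector kmers_b, int k, int min_count) {
    std::unordered_set<kmer_t, KmerHash> bset;
    bset.reserve(kmers_b.size() * 2 + 16);
    for (R_xlen_t i = 0; i < kmers_b.size(); ++i) {
        kmer_t x;
        if (!pack_kmer(CHAR(STRING_ELT(kmers_b, i)), k, x))
            stop("invalid base in catalog k-mer");
        bset.insert(x);
    }
    LogicalVector out(kmers_a.size());
    for (R_xlen_t i = 0; i < kmers_a.size(); ++i) {
        kmer_t x;
        if (!pack_kmer(CHAR(STRING_ELT(kmers_a, i)), k, x))
            stop("invalid base in catalog k-mer");
        out[i] = counts_a[i] >= min_count && bset.find(x) == bset.end();
    }
    return out;
}

// TRUE for every read containing >= 1 canonical k-mer from `specific`.
// [[Rcpp::export]]
LogicalVector cpp_recruit(CharacterVector seqs, CharacterVector specific, int k) {
    std::unordered_set<kmer_t, KmerHash> sset;
    sset.reserve(specific.size() * 2 + 16);
    for (R_xlen_t i = 0; i < specific.size(); ++i) {
        kmer_t x;
        if (!pack_kmer(CHAR(STRING_ELT(specific, i)), k, x))
            stop("invalid base in specific k-mer");
        sset.insert(x);
    }
    LogicalVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        bool hit = false;
        if (!sset.empty()) {
            const char* s = CHAR(STRING_ELT(seqs, i));
            int len = (int)LENGTH(STRING_ELT(seqs, i));
            scan_canonical(s, len, k, [&](kmer_t km) {
                if (!hit && sset.count(km)) hit = true;
            });
        }
        out[i] = hit;
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i)
        out[i] = revcomp_str(as<std::string>(seqs[i]));
    return out;
}
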