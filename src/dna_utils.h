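#ifndef KSUBMAP_DNA_UTILS_H
#define KSUBMAP_DNA_UTILS_H

#include <cstdint>
#include <string>
#include <stdexcept>

// 2-bit DNA packing shared by the k-mer counter, assembler and mapper.
// A=0, C=1, G=2, T=3 so numeric order of packed k-mers equals
// lexicographic order of their strings. k up to 63 via 128-bit words.

typedef unsigned __int128 kmer_t;

inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or anything else: invalid
    }
}

inline char code_base(int code) {
    static const char b[4] = {'A', 'C', 'G', 'T'};
    return b[code & 3];
}

inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
    }
}

inline std::string revcomp_str(const std::string& s) {
    std::string r(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i)
        r[s.size() - 1 - i] = comp_base(s[i]);
    return r;
}

inline std::string unpack_kmer(kmer_t x, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = code_base((int)(x & 3));
        x >>= 2;
    }
    return s;
}

// pack, returns false if any invalid base
inline bool pack_kmer(const char* s, int k, kmer_t& out) {
    kmer_t x = 0;
    for (int i = 0; i < k; ++i) {
        int c = base_code(s[i]);
        if (c < 0) return false;
        x = (x << 2) | (kmer_t)c;
    }
    out = x;
    return true;
}

inline kmer_t revcomp_kmer(kmer_t x, int k) {
    kmer_t r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (kmer_t)(3 - (int)(x & 3));
        x >>= 2;
    }
    return r;
}

struct KmerHash {
    size_t operator()(kmer_t x) const {
        uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
        uint64_t h = lo * 0x9e3779b97f4a7c15ULL;
        h ^= hi + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
        return (size_t)h;
    }
};

#endif
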