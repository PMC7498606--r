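#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include "dna_utils.h"

using namespace Rcpp;

// Node-centric canonical de Bruijn graph. A node is a canonical k-mer; an
// oriented node is the packed value of the k-mer as read on one strand.
// Unitigs (maximal unbranched paths) are emitted as contigs after a
// coverage cutoff on node counts and iterative clipping of short tips.

namespace {

struct Graph {
    int k;
    kmer_t mask;
    int shift;
    std::unordered_map<kmer_t, int, KmerHash> nodes;  // canonical -> count

    kmer_t canon(kmer_t x) const {
        kmer_t r = revcomp_kmer(x, k);
        return x < r ? x : r;
    }
    bool has(kmer_t oriented) const { return nodes.count(canon(oriented)) > 0; }

    int successors(kmer_t x, kmer_t out[4]) const {
        int n = 0;
        for (int b = 0; b < 4; ++b) {
            kmer_t y = ((x << 2) | (kmer_t)b) & mask;
            if (has(y)) out[n++] = y;
        }
        return n;
    }
    int predecessors(kmer_t x, kmer_t out[4]) const {
        int n = 0;
        for (int b = 0; b < 4; ++b) {
            kmer_t y = (x >> 2) | ((kmer_t)b << shift);
            if (has(y)) out[n++] = y;
        }
        return n;
    }
    int outdeg(kmer_t x) const { kmer_t t[4]; return successors(x, t); }
    int indeg(kmer_t x) const { kmer_t t[4]; return predecessors(x, t); }
};

struct Unitig {
    std::vector<kmer_t> path;  // oriented nodes
    bool front_open;           // has predecessors outside the path start
    bool back_open;            // has successors past the path end
};

// walk forward from an oriented start node through unbranched nodes
static void walk(const Graph& g, kmer_t start,
                 std::unordered_set<kmer_t, KmerHash>& visited,
                 std::vector<kmer_t>& path) {
    path.clear();
    path.push_back(start);
    visited.insert(g.canon(start));
    kmer_t cur = start;
    for (;;) {
        kmer_t succ[4];
        if (g.successors(cur, succ) != 1) break;
        kmer_t nxt = succ[0];
        if (g.indeg(nxt) != 1) break;
        if (visited.count(g.canon(nxt))) break;  // cycle closure
        path.push_back(nxt);
        visited.insert(g.canon(nxt));
        cur = nxt;
    }
}

static bool is_path_start(const Graph& g, kmer_t x) {
    kmer_t pred[4];
    int nin = g.predecessors(x, pred);
    if (nin != 1) return true;
    return g.outdeg(pred[0]) != 1;
}

static std::vector<Unitig> build_unitigs(const Graph& g) {
    std::vector<kmer_t> order;
    order.reserve(g.nodes.size());
    for (std::unordered_map<kmer_t, int, KmerHash>::const_iterator it = g.nodes.begin();
         it != g.nodes.end(); ++it)
        order.push_back(it->first);
    std::sort(order.begin(), order.end());

    std::unordered_set<kmer_t, KmerHash> visited;
    std::vector<Unitig> out;
    for (size_t i = 0; i < order.size(); ++i) {
        kmer_t c = order[i];
        if (visited.count(c)) continue;
        kmer_t orients[2] = {c, revcomp_kmer(c, g.k)};
        bool placed = false;
        for (int o = 0; o < 2 && !placed; ++o) {
            if (!is_path_start(g, orients[o])) continue;
            Unitig u;
            walk(g, orients[o], visited, u.path);
            u.front_open = g.indeg(u.path.front()) > 0;
            u.back_open = g.outdeg(u.path.back()) > 0;
            out.push_back(u);
            placed = true;
        }
    }
    // leftovers are pure cycles
    for (size_t i = 0; i < order.size(); ++i) {
        kmer_t c = order[i];
        if (visited.count(c)) continue;
        Unitig u;
        walk(g, c, visited, u.path);
        u.front_open = true;
        u.back_open = true;
        out.push_back(u);
    }
    return out;
}

static std::string path_seq(const std::vector<kmer_t>& path, int k) {
    std::string s = unpack_kmer(path[0], k);
    for (size_t i = 1; i < path.size(); ++i)
        s.push_back(code_base((int)(path[i] & 3)));
    return s;
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_assemble(CharacterVector seqs, int k, int cov_cutoff, int tip_max_len) {
    if (k < 3 || k > 63 || k % 2 == 0) stop("k_asm must be odd and in [3, 63]");
    if (cov_cutoff < 1) stop("cov_cutoff must be >= 1");

    Graph g;
    g.k = k;
    g.mask = (((kmer_t)1 << (2 * k)) - 1);
    g.shift = 2 * (k - 1);

    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        int len = (int)LENGTH(STRING_ELT(seqs, i));
        if (len < k) continue;
        kmer_t fwd = 0, rc = 0;
        int valid = 0;
        for (int j = 0; j < len; ++j) {
            int c = base_code(s[j]);
            if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
            fwd = ((fwd << 2) | (kmer_t)c) & g.mask;
            rc = (rc >> 2) | ((kmer_t)(3 - c) << g.shift);
            if (++valid >= k) g.nodes[fwd < rc ? fwd : rc]++;
        }
    }
    // coverage cutoff
    for (std::unordered_map<kmer_t, int, KmerHash>::iterator it = g.nodes.begin();
         it != g.nodes.end();) {
        if (it->second < cov_cutoff) it = g.nodes.erase(it);
        else ++it;
    }

    // iterative tip clipping: a tip is a unitig with exactly one dead end
    // shorter than tip_max_len bases
    for (int round = 0; round < 10; ++round) {
        std::vector<Unitig> us = build_unitigs(g);
        bool changed = false;
        for (size_t i = 0; i < us.size(); ++i) {
            const Unitig& u = us[i];
            bool dead_front = !u.front_open, dead_back = !u.back_open;
            if (dead_front == dead_back) continue;  // internal or isolated
            int len_bases = (int)u.path.size() + k - 1;
            if (len_bases >= tip_max_len) continue;
            for (size_t j = 0; j < u.path.size(); ++j)
                g.nodes.erase(g.canon(u.path[j]));
            changed = true;
        }
        if (!changed) break;
    }

    std::vector<Unitig> us = build_unitigs(g);
    std::vector<std::string> seq_out;
    std::vector<double> cov_out;
    for (size_t i = 0; i < us.size(); ++i) {
        std::string s = path_seq(us[i].path, k);
        std::string r = revcomp_str(s);
        double cov = 0.0;
        for (size_t j = 0; j < us[i].path.size(); ++j)
            cov += g.nodes.find(g.canon(us[i].path[j]))->second;
        cov /= (double)us[i].path.size();
        seq_out.push_back(s < r ? s : r);
        cov_out.push_back(cov);
    }
    // deterministic report order: longest first, then lexicographic
    std::vector<size_t> idx(seq_out.size());
    for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
        if (seq_out[a].size() != seq_out[b].size())
            return seq_out[a].size() > seq_out[b].size();
        return seq_out[a] < seq_out[b];
    });
    CharacterVector seq_col(idx.size());
    NumericVector cov_col(idx.size());
    IntegerVector len_col(idx.size());
    for (size_t i = 0; i < idx.size(); ++i) {
        seq_col[i] = seq_out[idx[i]];
        cov_col[i] = cov_out[idx[i]];
        len_col[i] = (int)seq_out[idx[i]].size();
    }
    return DataFrame::create(_["sequence"] = seq_col, _["length"] = len_col,
                             _["coverage"] = cov_col,
                             _["stringsAsFactors"] = false);
}
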