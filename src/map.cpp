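#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <set>
#include <algorithm>
#include "dna_utils.h"

using namespace Rcpp;

// Ungapped read placement with at most `max_mm` mismatches and a
// unique-best requirement (a mismatch-count tie between distinct loci is
// reported as ambiguous). Placements are found exactly via pigeonhole
// seeding: a read with <= m mismatches split into m+1 segments has one
// exact segment, so indexing fixed-length seeds at segment starts finds
// every valid placement; short reads fall back to a full scan.

namespace {

const int SEED_LEN = 16;

struct SeedIndex {
    std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > idx;  // seed -> (contig, pos)

    void build(const std::vector<std::string>& contigs) {
        for (size_t c = 0; c < contigs.size(); ++c) {
            const std::string& s = contigs[c];
            if ((int)s.size() < SEED_LEN) continue;
            uint64_t x = 0, mask = (1ULL << (2 * SEED_LEN)) - 1;
            int valid = 0;
            for (size_t i = 0; i < s.size(); ++i) {
                int b = base_code(s[i]);
                if (b < 0) { valid = 0; x = 0; continue; }
                x = ((x << 2) | (uint64_t)b) & mask;
                if (++valid >= SEED_LEN)
                    idx[x].push_back(std::make_pair((int)c, (int)(i + 1 - SEED_LEN)));
            }
        }
    }
};

// mismatches of read placed at contig[start..start+len), early exit
int count_mm(const std::string& read, const std::string& contig, int start, int limit) {
    int mm = 0;
    for (size_t i = 0; i < read.size(); ++i) {
        char a = read[i], b = contig[start + i];
        int ca = base_code(a), cb = base_code(b);
        if (ca < 0 || cb < 0 || ca != cb) {
            if (++mm > limit) return mm;
        }
    }
    return mm;
}

struct Placement {
    int contig, start, strand, mm;
    bool operator<(const Placement& o) const {
        if (contig != o.contig) return contig < o.contig;
        if (start != o.start) return start < o.start;
        return strand < o.strand;
    }
};

void collect_seeded(const std::string& oriented, int strand, int max_mm,
                    const SeedIndex& index, const std::vector<std::string>& contigs,
                    std::set<Placement>& placements) {
    int L = (int)oriented.size();
    int nseg = max_mm + 1;
    for (int s = 0; s < nseg; ++s) {
        int off = (int)((long long)s * L / nseg);
        if (off + SEED_LEN > L) continue;
        uint64_t x = 0;
        bool ok = true;
        for (int j = 0; j < SEED_LEN; ++j) {
            int b = base_code(oriented[off + j]);
            if (b < 0) { ok = false; break; }
            x = (x << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::const_iterator
            it = index.idx.find(x);
        if (it == index.idx.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
            int c = it->second[h].first;
            int start = it->second[h].second - off;
            if (start < 0 || start + L > (int)contigs[c].size()) continue;
            Placement p;
            p.contig = c; p.start = start; p.strand = strand;
            if (placements.count(p)) continue;
            p.mm = count_mm(oriented, contigs[c], start, max_mm);
            if (p.mm <= max_mm) placements.insert(p);
        }
    }
}

void collect_scan(const std::string& oriented, int strand, int max_mm,
                  const std::vector<std::string>& contigs,
                  std::set<Placement>& placements) {
    int L = (int)oriented.size();
    for (size_t c = 0; c < contigs.size(); ++c) {
        int n = (int)contigs[c].size();
        for (int start = 0; start + L <= n; ++start) {
            int mm = count_mm(oriented, contigs[c], start, max_mm);
            if (mm <= max_mm) {
                Placement p;
                p.contig = (int)c; p.start = start; p.strand = strand; p.mm = mm;
                placements.insert(p);
            }
        }
    }
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector contigs, int max_mm) {
    if (max_mm < 0) stop("max_mm must be >= 0");
    std::vector<std::string> ctg(contigs.size());
    for (R_xlen_t i = 0; i < contigs.size(); ++i)
        ctg[i] = as<std::string>(contigs[i]);
    SeedIndex index;
    index.build(ctg);

    R_xlen_t nr = reads.size();
    IntegerVector contig_col(nr), start_col(nr), strand_col(nr), mm_col(nr);
    CharacterVector status_col(nr);

    for (R_xlen_t i = 0; i < nr; ++i) {
        std::string fwd = as<std::string>(reads[i]);
        std::string rev = revcomp_str(fwd);
        int L = (int)fwd.size();
        std::set<Placement> placements;
        if (L >= SEED_LEN * (max_mm + 1)) {
            collect_seeded(fwd, 1, max_mm, index, ctg, placements);
            collect_seeded(rev, -1, max_mm, index, ctg, placements);
        } else {
            collect_scan(fwd, 1, max_mm, ctg, placements);
            collect_scan(rev, -1, max_mm, ctg, placements);
        }
        int best = max_mm + 1, nbest = 0;
        const Placement* bp = 0;
        for (std::set<Placement>::const_iterator it = placements.begin();
             it != placements.end(); ++it) {
            if (it->mm < best) { best = it->mm; nbest = 1; bp = &(*it); }
            else if (it->mm == best) ++nbest;
        }
        if (nbest == 0) {
            contig_col[i] = NA_INTEGER; start_col[i] = NA_INTEGER;
            strand_col[i] = NA_INTEGER; mm_col[i] = NA_INTEGER;
            status_col[i] = "unmapped";
        } else if (nbest > 1) {
            contig_col[i] = NA_INTEGER; start_col[i] = NA_INTEGER;
            strand_col[i] = NA_INTEGER; mm_col[i] = NA_INTEGER;
            status_col[i] = "ambiguous";
        } else {
            contig_col[i] = bp->contig + 1;
            start_col[i] = bp->start;
            strand_col[i] = bp->strand;
            mm_col[i] = bp->mm;
            status_col[i] = "mapped";
        }
    }
    return DataFrame::create(
        _["read"] = seq_len(nr), _["contig"] = contig_col, _["start0"] = start_col,
        _["strand"] = strand_col, _["mismatches"] = mm_col, _["status"] = status_col,
        _["stringsAsFactors"] = false);
}

// per-contig 4 x length base counts (rows A,C,G,T); minus-strand reads are
// complemented back to the forward strand before tallying
// [[Rcpp::export]]
List cpp_pileup(CharacterVector reads, IntegerVector contig_idx, IntegerVector start0,
                IntegerVector strand, IntegerVector contig_lengths) {
    int nc = contig_lengths.size();
    std::vector<IntegerMatrix> mats;
    for (int c = 0; c < nc; ++c) {
        IntegerMatrix m(4, contig_lengths[c]);
        rownames(m) = CharacterVector::create("A", "C", "G", "T");
        mats.push_back(m);
    }
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        if (contig_idx[i] == NA_INTEGER) continue;
        int c = contig_idx[i] - 1;
        if (c < 0 || c >= nc) stop("contig index out of range");
        std::string s = as<std::string>(reads[i]);
        if (strand[i] < 0) s = revcomp_str(s);
        int start = start0[i];
        if (start < 0 || start + (int)s.size() > contig_lengths[c])
            stop("mapped read exceeds contig bounds");
        for (size_t j = 0; j < s.size(); ++j) {
            int b = base_code(s[j]);
            if (b >= 0) mats[c](b, start + (int)j)++;
        }
    }
    List out(nc);
    for (int c = 0; c < nc; ++c) out[c] = mats[c];
    return out;
}
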