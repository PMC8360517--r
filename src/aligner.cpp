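#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Seed-and-extend read aligner used by align().
//
// Seeding follows the pigeonhole principle: a read split into (max_mm + 1)
// disjoint segments must contain at least one segment free of mismatches
// whenever the placement carries at most max_mm mismatches, so indexing
// exact seeds of length <= floor(read_len / (max_mm + 1)) guarantees that
// every qualifying ungapped placement is recovered.  Reference positions
// holding 'N' (uncharacterized sequence) match any read base at zero
// penalty; seeds containing non-ACGT characters are skipped, so the
// guarantee holds only across fully characterized reference windows.

static inline int base2bits(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
    return r;
}

struct Hit {
    int ref;
    int pos;
    int strand;
    int nmis;
};

// [[Rcpp::export]]
DataFrame cpp_align(CharacterVector reads, CharacterVector refs,
                    int max_mm, int seed_len, bool exhaustive,
                    bool both_strands) {
    const int nref = refs.size();
    std::vector<std::string> R(nref);
    for (int i = 0; i < nref; ++i) R[i] = as<std::string>(refs[i]);

    // index every seed_len-mer of every reference (2-bit encoded)
    std::unordered_map<uint64_t, std::vector<uint64_t> > idx;
    idx.reserve(1 << 20);
    const uint64_t mask = (seed_len >= 32) ? ~0ULL
        : ((1ULL << (2 * seed_len)) - 1ULL);
    for (int r = 0; r < nref; ++r) {
        const std::string& s = R[r];
        if ((int)s.size() < seed_len) continue;
        uint64_t key = 0;
        int run = 0; // valid bases accumulated
        for (size_t p = 0; p < s.size(); ++p) {
            int b = base2bits(s[p]);
            if (b < 0) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t)b) & mask;
            if (++run >= seed_len) {
                uint64_t packed = ((uint64_t)r << 32) |
                    (uint64_t)(p - seed_len + 1);
                idx[key].push_back(packed);
            }
        }
    }

    std::vector<int> out_read, out_ref, out_pos, out_strand, out_nmis;
    std::vector<uint64_t> cand;

    const int nreads = reads.size();
    for (int q = 0; q < nreads; ++q) {
        std::string fwd = as<std::string>(reads[q]);
        const int len = (int)fwd.size();
        if (len < seed_len) continue;
        std::vector<Hit> hits;
        int best = max_mm + 1;
        const int nseg = max_mm + 1;
        const int seg = len / nseg;

        for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
            std::string s = (strand == 0) ? fwd : revcomp(fwd);
            cand.clear();
            for (int i = 0; i < nseg; ++i) {
                int off = i * seg;
                if (seg < seed_len) off = i * (len - seed_len) /
                    std::max(1, nseg - 1); // degenerate short reads
                if (off + seed_len > len) break;
                uint64_t key = 0;
                bool ok = true;
                for (int j = 0; j < seed_len; ++j) {
                    int b = base2bits(s[off + j]);
                    if (b < 0) { ok = false; break; }
                    key = (key << 2) | (uint64_t)b;
                }
                if (!ok) continue;
                auto it = idx.find(key & mask);
                if (it == idx.end()) continue;
                for (uint64_t packed : it->second) {
                    int r = (int)(packed >> 32);
                    int hp = (int)(packed & 0xffffffffULL);
                    int start = hp - off;
                    if (start < 0 || start + len > (int)R[r].size())
                        continue;
                    cand.push_back(((uint64_t)r << 32) | (uint64_t)start);
                }
            }
            std::sort(cand.begin(), cand.end());
            cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
            for (uint64_t c : cand) {
                int r = (int)(c >> 32);
                int start = (int)(c & 0xffffffffULL);
                const std::string& ref = R[r];
                int mm = 0;
                for (int j = 0; j < len; ++j) {
                    char rb = ref[start + j];
                    if (rb == 'N') continue; // uncharacterized matches free
                    if (rb != s[j] && ++mm > max_mm) break;
                }
                if (mm > max_mm) continue;
                hits.push_back({r, start, strand, mm});
                if (mm < best) best = mm;
            }
        }
        for (const Hit& h : hits) {
            if (!exhaustive && h.nmis != best) continue;
            out_read.push_back(q + 1);
            out_ref.push_back(h.ref + 1);
            out_pos.push_back(h.pos);
            out_strand.push_back(h.strand);
            out_nmis.push_back(h.nmis);
        }
    }

    return DataFrame::create(
        _["read"] = out_read, _["ref"] = out_ref, _["pos"] = out_pos,
        _["strand"] = out_strand, _["nmis"] = out_nmis);
}

// Accumulate per-position base depth for reads placed on one reference
// frame.  `pos` is 0-based placement start, `seqs` are reference-oriented
// read sequences.  Returns a 4 x frame_len matrix (rows A, C, G, T).
// [[Rcpp::export]]
IntegerMatrix cpp_depth(int frame_len, IntegerVector pos,
                        CharacterVector seqs) {
    IntegerMatrix out(4, frame_len);
    const int n = pos.size();
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        int start = pos[i];
        for (size_t j = 0; j < s.size(); ++j) {
            int p = start + (int)j;
            if (p < 0 || p >= frame_len) continue;
            int b = base2bits(s[j]);
            if (b < 0) continue;
            out(b, p) += 1;
        }
    }
    return out;
}

// Hamming mismatch count between equal-length strings, 'N' ignored.
// [[Rcpp::export]]
IntegerVector cpp_pair_mismatch(CharacterVector a, CharacterVector b) {
    int n = a.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string x = as<std::string>(a[i]);
        std::string y = as<std::string>(b[i]);
        int mm = 0;
        size_t L = std::min(x.size(), y.size());
        for (size_t j = 0; j < L; ++j) {
            if (x[j] == 'N' || y[j] == 'N') continue;
            if (x[j] != y[j]) ++mm;
        }
        out[i] = mm;
    }
    return out;
}
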