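#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Seed-and-verify read mapper with a pigeonhole completeness guarantee:
// a read aligned with <= k mismatches, split into k+1 non-overlapping seeds,
// must contain at least one exact seed (each mismatch spoils at most one
// seed), so exact lookup of all k+1 seeds followed by full Hamming
// verification of every candidate window enumerates every <= k alignment.

struct SeedIndexData {
    int seed_len;
    std::vector<uint8_t>  seq;     // concatenated genomes; 0..3 = ACGT, 4 = N/other
    std::vector<uint64_t> keys;    // 2-bit seed keys, sorted
    std::vector<uint32_t> pos;     // global seed start, parallel to keys
    std::vector<uint64_t> gstart;  // genome offsets, length n_genomes + 1
};

static inline uint8_t base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default:            return 4;
    }
}

// [[Rcpp::export]]
SEXP afs_build_index(CharacterVector genomes, int seed_len) {
    if (seed_len < 10 || seed_len > 31)
        stop("seed_len must be between 10 and 31");
    SeedIndexData* idx = new SeedIndexData();
    idx->seed_len = seed_len;

    uint64_t total = 0;
    idx->gstart.push_back(0);
    for (R_xlen_t g = 0; g < genomes.size(); ++g) {
        total += LENGTH(STRING_ELT(genomes, g));
        idx->gstart.push_back(total);
    }
    idx->seq.resize(total);

    std::vector<std::pair<uint64_t, uint32_t> > entries;
    entries.reserve(total);
    const uint64_t mask = (seed_len == 32) ? ~0ULL
        : ((1ULL << (2 * seed_len)) - 1ULL);

    for (R_xlen_t g = 0; g < genomes.size(); ++g) {
        const char* s = CHAR(STRING_ELT(genomes, g));
        const uint64_t off = idx->gstart[g];
        const uint64_t len = idx->gstart[g + 1] - off;
        uint64_t key = 0;
        int64_t run = 0;  // length of current N-free suffix
        for (uint64_t i = 0; i < len; ++i) {
            uint8_t c = base_code(s[i]);
            idx->seq[off + i] = c;
            if (c > 3) { run = 0; key = 0; continue; }
            key = ((key << 2) | c) & mask;
            if (++run >= seed_len)
                entries.push_back(std::make_pair(
                    key, (uint32_t)(off + i - seed_len + 1)));
        }
    }
    std::sort(entries.begin(), entries.end());
    idx->keys.resize(entries.size());
    idx->pos.resize(entries.size());
    for (size_t i = 0; i < entries.size(); ++i) {
        idx->keys[i] = entries[i].first;
        idx->pos[i]  = entries[i].second;
    }
    XPtr<SeedIndexData> ptr(idx, true);
    return ptr;
}

// [[Rcpp::export]]
double afs_index_size(SEXP xp) {
    XPtr<SeedIndexData> idx(xp);
    return (double)idx->keys.size();
}

// [[Rcpp::export]]
IntegerVector afs_index_lookup(SEXP xp, std::string seed) {
    // positions (global, 1-based) of one exact seed; for tests/introspection
    XPtr<SeedIndexData> idx(xp);
    if ((int)seed.size() != idx->seed_len) stop("seed length mismatch");
    uint64_t key = 0;
    for (size_t i = 0; i < seed.size(); ++i) {
        uint8_t c = base_code(seed[i]);
        if (c > 3) return IntegerVector(0);
        key = (key << 2) | c;
    }
    std::vector<int> out;
    std::pair<std::vector<uint64_t>::const_iterator,
              std::vector<uint64_t>::const_iterator> rng =
        std::equal_range(idx->keys.begin(), idx->keys.end(), key);
    for (size_t i = rng.first - idx->keys.begin();
         i < (size_t)(rng.second - idx->keys.begin()); ++i)
        out.push_back((int)idx->pos[i] + 1);
    std::sort(out.begin(), out.end());
    return wrap(out);
}

struct Hit {
    uint32_t g;
    uint32_t start;   // local, 0-based
    int8_t strand;    // +1 / -1
    uint8_t mm;
};

// [[Rcpp::export]]
List afs_map_reads(SEXP xp, CharacterVector reads, int k) {
    XPtr<SeedIndexData> idx(xp);
    const int seed_len = idx->seed_len;
    const int n_genomes = (int)idx->gstart.size() - 1;
    if (k < 0) stop("k must be >= 0");

    std::vector<int> o_read, o_genome, o_pos, o_strand, o_mm;
    std::vector<int> too_short;
    std::vector<uint8_t> fwd, rev;
    std::vector<Hit> hits;
    std::vector<std::pair<uint64_t, int8_t> > seen;  // (global start, strand)

    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char* s = CHAR(STRING_ELT(reads, r));
        const int L = LENGTH(STRING_ELT(reads, r));
        if (L < (k + 1) * seed_len) { too_short.push_back((int)r + 1); continue; }
        fwd.resize(L); rev.resize(L);
        for (int i = 0; i < L; ++i) {
            uint8_t c = base_code(s[i]);
            fwd[i] = c;
            rev[L - 1 - i] = (c > 3) ? 4 : (uint8_t)(3 - c);
        }
        hits.clear(); seen.clear();

        for (int ori = 0; ori < 2; ++ori) {
            const std::vector<uint8_t>& q = ori == 0 ? fwd : rev;
            for (int j = 0; j <= k; ++j) {
                const int off = j * seed_len;
                uint64_t key = 0;
                bool ok = true;
                for (int i = 0; i < seed_len; ++i) {
                    uint8_t c = q[off + i];
                    if (c > 3) { ok = false; break; }
                    key = (key << 2) | c;
                }
                if (!ok) continue;
                std::pair<std::vector<uint64_t>::const_iterator,
                          std::vector<uint64_t>::const_iterator> rng =
                    std::equal_range(idx->keys.begin(), idx->keys.end(), key);
                for (std::vector<uint64_t>::const_iterator it = rng.first;
                     it != rng.second; ++it) {
                    const uint32_t p = idx->pos[it - idx->keys.begin()];
                    if ((int64_t)p - off < 0) continue;
                    const uint64_t start = (uint64_t)p - off;
                    const int8_t strand = ori == 0 ? 1 : -1;
                    bool dup = false;
                    for (size_t d = 0; d < seen.size(); ++d)
                        if (seen[d].first == start && seen[d].second == strand) {
                            dup = true; break;
                        }
                    if (dup) continue;
                    seen.push_back(std::make_pair(start, strand));
                    // locate genome and require the window inside it
                    int g = (int)(std::upper_bound(idx->gstart.begin(),
                                                   idx->gstart.end(), start)
                                  - idx->gstart.begin()) - 1;
                    if (g < 0 || g >= n_genomes) continue;
                    if (start + (uint64_t)L > idx->gstart[g + 1]) continue;
                    int mm = 0;
                    const uint8_t* ref = &idx->seq[start];
                    for (int i = 0; i < L; ++i) {
                        // reference N mismatches every base
                        if (ref[i] > 3 || ref[i] != q[i]) {
                            if (++mm > k) break;
                        }
                    }
                    if (mm > k) continue;
                    Hit h;
                    h.g = (uint32_t)g;
                    h.start = (uint32_t)(start - idx->gstart[g]);
                    h.strand = strand;
                    h.mm = (uint8_t)mm;
                    hits.push_back(h);
                }
            }
        }
        for (size_t h = 0; h < hits.size(); ++h) {
            o_read.push_back((int)r + 1);
            o_genome.push_back((int)hits[h].g + 1);
            o_pos.push_back((int)hits[h].start + 1);
            o_strand.push_back(hits[h].strand);
            o_mm.push_back(hits[h].mm);
        }
    }
    return List::create(
        _["read"]   = wrap(o_read),
        _["genome"] = wrap(o_genome),
        _["pos"]    = wrap(o_pos),
        _["strand"] = wrap(o_strand),
        _["mismatches"] = wrap(o_mm),
        _["too_short"]  = wrap(too_short));
}
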