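#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

// Substitution-only (ungapped) forward-strand alignment of short reads against a
// small set of reference sequences. Candidate loci come from exact k-mer seeds
// placed by the pigeonhole principle (max_mm + 1 near-equal read segments: any
// alignment with <= max_mm substitutions must contain one exactly matching
// segment, hence an exactly matching k-mer at that segment's start). Every
// candidate is verified by full Hamming comparison, so the seeding is only a
// candidate generator and never changes the result.

static const int KIDX = 6; // seed k-mer width; segments of 18-nt reads at 2 mm are >= 6

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1; // N or anything else: matches nothing
    }
}

struct KmerIndex {
    // key -> packed (ref << 32 | pos) occurrence list
    std::vector< std::vector<uint64_t> > slots;
    KmerIndex() : slots(1u << (2 * KIDX)) {}
};

static void index_refs(const std::vector<std::string>& refs, KmerIndex& idx) {
    for (size_t r = 0; r < refs.size(); ++r) {
        const std::string& s = refs[r];
        if ((int)s.size() < KIDX) continue;
        uint32_t key = 0;
        int valid = 0; // run length of valid bases ending at i
        for (size_t i = 0; i < s.size(); ++i) {
            int c = base_code(s[i]);
            if (c < 0) { valid = 0; key = 0; continue; }
            key = ((key << 2) | (uint32_t)c) & ((1u << (2 * KIDX)) - 1u);
            ++valid;
            if (valid >= KIDX) {
                size_t pos = i + 1 - KIDX;
                idx.slots[key].push_back(((uint64_t)r << 32) | (uint64_t)pos);
            }
        }
    }
}

// near-equal pigeonhole split: first (len %% k) segments get the extra base
static void segment_offsets(int len, int nseg, std::vector<int>& off, std::vector<int>& seglen) {
    int base = len / nseg, rem = len % nseg, cur = 0;
    off.clear(); seglen.clear();
    for (int j = 0; j < nseg; ++j) {
        int l = base + (j < rem ? 1 : 0);
        off.push_back(cur); seglen.push_back(l);
        cur += l;
    }
}

static inline int hamming_leq(const char* a, const char* b, int len, int maxd) {
    int d = 0;
    for (int i = 0; i < len; ++i) {
        if (a[i] != b[i] || base_code(a[i]) < 0) {
            if (++d > maxd) return maxd + 1;
        }
    }
    return d;
}

struct Hit { int ref; int pos; int nm; };

static void collect_hits(const std::string& read, const std::vector<std::string>& refs,
                         const KmerIndex& idx, int max_mm, std::vector<Hit>& best) {
    best.clear();
    int L = (int)read.size();
    int nseg = max_mm + 1;
    std::vector<int> off, seglen;
    segment_offsets(L, nseg, off, seglen);
    bool brute = false;
    for (int j = 0; j < nseg; ++j) if (seglen[j] < KIDX) brute = true;
    for (int i = 0; i < L && !brute; ++i) if (base_code(read[i]) < 0) brute = true;

    int best_nm = max_mm + 1;
    if (brute) {
        // short reads or reads with ambiguous bases: scan every window
        for (size_t r = 0; r < refs.size(); ++r) {
            const std::string& s = refs[r];
            if ((int)s.size() < L) continue;
            for (int p = 0; p + L <= (int)s.size(); ++p) {
                int d = hamming_leq(read.c_str(), s.c_str() + p, L, max_mm);
                if (d <= max_mm) {
                    if (d < best_nm) { best_nm = d; best.clear(); }
                    if (d == best_nm) best.push_back(Hit{(int)r, p, d});
                }
            }
        }
        return;
    }

    std::unordered_set<uint64_t> seen;
    for (int j = 0; j < nseg; ++j) {
        uint32_t key = 0;
        for (int i = 0; i < KIDX; ++i) key = (key << 2) | (uint32_t)base_code(read[off[j] + i]);
        const std::vector<uint64_t>& occ = idx.slots[key];
        for (uint64_t packed : occ) {
            int r = (int)(packed >> 32);
            long p = (long)(packed & 0xffffffffu) - off[j];
            if (p < 0 || p + L > (long)refs[r].size()) continue;
            uint64_t cand = ((uint64_t)r << 32) | (uint64_t)p;
            if (!seen.insert(cand).second) continue;
            int d = hamming_leq(read.c_str(), refs[r].c_str() + p, L, max_mm);
            if (d <= max_mm) {
                if (d < best_nm) { best_nm = d; best.clear(); }
                if (d == best_nm) best.push_back(Hit{r, (int)p, d});
            }
        }
    }
}

// [[Rcpp::export]]
DataFrame map_reads_cpp(CharacterVector read_seqs, CharacterVector read_ids,
                        CharacterVector ref_seqs, CharacterVector ref_ids,
                        int max_mm) {
    std::vector<std::string> refs(ref_seqs.size());
    for (int i = 0; i < ref_seqs.size(); ++i) refs[i] = as<std::string>(ref_seqs[i]);
    KmerIndex idx;
    index_refs(refs, idx);

    std::vector<std::string> out_read, out_ref, out_mm;
    std::vector<int> out_start, out_nm, out_best;
    std::vector<Hit> best;

    for (int i = 0; i < read_seqs.size(); ++i) {
        std::string read = as<std::string>(read_seqs[i]);
        collect_hits(read, refs, idx, max_mm, best);
        int nb = (int)best.size();
        for (const Hit& h : best) {
            std::string mmdesc;
            const std::string& s = refs[h.ref];
            for (int q = 0; q < (int)read.size(); ++q) {
                if (read[q] != s[h.pos + q] || base_code(read[q]) < 0) {
                    if (!mmdesc.empty()) mmdesc += ",";
                    mmdesc += std::to_string(q + 1);
                    mmdesc += ":";
                    mmdesc += s[h.pos + q];
                    mmdesc += ">";
                    mmdesc += read[q];
                }
            }
            out_read.push_back(as<std::string>(read_ids[i]));
            out_ref.push_back(as<std::string>(ref_ids[h.ref]));
            out_start.push_back(h.pos + 1); // 1-based for all external interfaces
            out_nm.push_back(h.nm);
            out_mm.push_back(mmdesc);
            out_best.push_back(nb);
        }
    }
    return DataFrame::create(
        _["read_id"] = out_read, _["ref_id"] = out_ref,
        _["start"] = out_start, _["nm"] = out_nm,
        _["mismatches"] = out_mm, _["n_best_loci"] = out_best,
        _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
LogicalVector has_hit_cpp(CharacterVector read_seqs, CharacterVector ref_seqs, int max_mm) {
    // brute-force screen: does each read align anywhere at <= max_mm substitutions?
    std::vector<std::string> refs(ref_seqs.size());
    for (int i = 0; i < ref_seqs.size(); ++i) refs[i] = as<std::string>(ref_seqs[i]);
    LogicalVector out(read_seqs.size());
    for (int i = 0; i < read_seqs.size(); ++i) {
        std::string read = as<std::string>(read_seqs[i]);
        int L = (int)read.size();
        bool found = false;
        for (size_t r = 0; r < refs.size() && !found; ++r) {
            const std::string& s = refs[r];
            for (int p = 0; p + L <= (int)s.size(); ++p) {
                if (hamming_leq(read.c_str(), s.c_str() + p, L, max_mm) <= max_mm) {
                    found = true; break;
                }
            }
        }
        out[i] = found;
    }
    return out;
}
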