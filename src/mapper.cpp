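#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Exhaustive ungapped paired-end placement enumeration.
//
// Two search strategies share the same placement semantics:
//  * an indexed pigeonhole search (seed length k = floor(len/(t+1)); any
//    placement with <= t mismatches must contain at least one exact seed,
//    so enumeration is exhaustive), used for toy genomes;
//  * a full positional scan with early exit, used for short consensus
//    references where the per-mate mismatch budget is too large for seeds.
//
// A concordant placement is forward-reverse: one mate on +, the other on -,
// plus-mate start <= minus-mate start, minus-mate end >= plus-mate end, and
// fragment span (minus-mate end - plus-mate start) <= max_insert.

struct MatePlacement {
    int chrom;     // index into reference vector
    int pos;       // 0-based start
    bool fwd;      // true if mate aligns to + strand as given
    int mm;        // mismatches
};

struct PairPlacement {
    int chrom;
    int m1_start, m1_end, m2_start, m2_end;
    bool m1_fwd;
    int mm1, mm2;
};

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 'T'; case 'c': return 'G';
    case 'g': return 'C'; case 't': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) c = comp_base(c);
    return r;
}

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// mismatches of read vs ref at pos, early exit beyond cap; non-ACGT never match
static int count_mm(const std::string& ref, const std::string& read, int pos, int cap) {
    int mm = 0;
    const int L = (int)read.size();
    for (int i = 0; i < L; ++i) {
        int a = base_code(ref[pos + i]);
        int b = base_code(read[i]);
        if (a < 0 || b < 0 || a != b) {
            if (++mm > cap) return mm;
        }
    }
    return mm;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > SeedIndex;

static bool encode_kmer(const std::string& s, int pos, int k, uint64_t& out) {
    uint64_t v = 0;
    for (int i = 0; i < k; ++i) {
        int c = base_code(s[pos + i]);
        if (c < 0) return false;
        v = (v << 2) | (uint64_t)c;
    }
    out = v;
    return true;
}

static void build_index(const std::vector<std::string>& refs, int k, SeedIndex& idx) {
    for (int ci = 0; ci < (int)refs.size(); ++ci) {
        const std::string& ref = refs[ci];
        if ((int)ref.size() < k) continue;
        for (int p = 0; p + k <= (int)ref.size(); ++p) {
            uint64_t key;
            if (encode_kmer(ref, p, k, key))
                idx[key].push_back(std::make_pair(ci, p));
        }
    }
}

// all placements of one mate sequence (given orientation already applied)
static void mate_hits_indexed(const std::vector<std::string>& refs,
                              const SeedIndex& idx, int k, int n_seeds,
                              const std::string& seq, bool fwd, int max_mm,
                              std::vector<MatePlacement>& out,
                              std::vector<char>& seen_buf) {
    const int L = (int)seq.size();
    for (int s = 0; s < n_seeds; ++s) {
        int off = s * k;
        if (off + k > L) break;
        uint64_t key;
        if (!encode_kmer(seq, off, k, key)) continue;
        SeedIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
            int ci = it->second[h].first;
            int pos = it->second[h].second - off;
            if (pos < 0 || pos + L > (int)refs[ci].size()) continue;
            // dedupe across seeds
            bool dup = false;
            for (size_t j = 0; j < out.size(); ++j)
                if (out[j].chrom == ci && out[j].pos == pos && out[j].fwd == fwd) { dup = true; break; }
            if (dup) continue;
            int mm = count_mm(refs[ci], seq, pos, max_mm);
            if (mm <= max_mm) {
                MatePlacement mp; mp.chrom = ci; mp.pos = pos; mp.fwd = fwd; mp.mm = mm;
                out.push_back(mp);
            }
        }
    }
    (void)seen_buf;
}

static void mate_hits_scan(const std::vector<std::string>& refs,
                           const std::string& seq, bool fwd, int max_mm,
                           std::vector<MatePlacement>& out) {
    const int L = (int)seq.size();
    for (int ci = 0; ci < (int)refs.size(); ++ci) {
        const std::string& ref = refs[ci];
        for (int pos = 0; pos + L <= (int)ref.size(); ++pos) {
            int mm = count_mm(ref, seq, pos, max_mm);
            if (mm <= max_mm) {
                MatePlacement mp; mp.chrom = ci; mp.pos = pos; mp.fwd = fwd; mp.mm = mm;
                out.push_back(mp);
            }
        }
    }
}

// combine mate placements into concordant FR pair placements
static void combine_pairs(const std::vector<MatePlacement>& h1, int len1,
                          const std::vector<MatePlacement>& h2, int len2,
                          int max_insert, int max_mm_pair,
                          std::vector<PairPlacement>& out) {
    for (size_t i = 0; i < h1.size(); ++i) {
        for (size_t j = 0; j < h2.size(); ++j) {
            const MatePlacement& a = h1[i];
            const MatePlacement& b = h2[j];
            if (a.chrom != b.chrom) continue;
            if (a.fwd == b.fwd) continue;              // opposite strands required
            if (a.mm + b.mm > max_mm_pair) continue;
            int a_end = a.pos + len1, b_end = b.pos + len2;
            const MatePlacement& plus  = a.fwd ? a : b;
            const MatePlacement& minus = a.fwd ? b : a;
            int plus_end  = plus.pos  + (a.fwd ? len1 : len2);
            int minus_end = minus.pos + (a.fwd ? len2 : len1);
            if (plus.pos > minus.pos) continue;
            if (minus_end < plus_end) continue;        // no dovetail past the mate
            int frag = minus_end - plus.pos;
            if (frag > max_insert) continue;
            PairPlacement pp;
            pp.chrom = a.chrom;
            pp.m1_start = a.pos; pp.m1_end = a_end;
            pp.m2_start = b.pos; pp.m2_end = b_end;
            pp.m1_fwd = a.fwd; pp.mm1 = a.mm; pp.mm2 = b.mm;
            out.push_back(pp);
        }
    }
}

static List map_pairs_core(CharacterVector ref_seqs,
                           CharacterVector r1, CharacterVector r2,
                           int max_mm_mate, int max_mm_pair,
                           int max_insert, int max_report, bool use_index) {
    std::vector<std::string> refs;
    for (int i = 0; i < ref_seqs.size(); ++i)
        refs.push_back(as<std::string>(ref_seqs[i]));

    const int n = r1.size();
    if (r2.size() != n) stop("mate vectors differ in length");

    // seed parameters from the shortest mate
    int min_len = INT_MAX;
    for (int i = 0; i < n; ++i) {
        min_len = std::min(min_len, (int)LENGTH(STRING_ELT(r1, i)));
        min_len = std::min(min_len, (int)LENGTH(STRING_ELT(r2, i)));
    }
    int n_seeds = max_mm_mate + 1;
    int k = (n > 0) ? min_len / n_seeds : 0;
    if (use_index && n > 0) {
        if (k < 8) stop("reads too short for indexed search at this mismatch budget; use the scan mapper");
        if (k > 31) k = 31;
    }

    SeedIndex idx;
    if (use_index && n > 0) build_index(refs, k, idx);

    IntegerVector n_place(n), n_hits_m1(n), n_hits_m2(n);
    std::vector<int> o_pair, o_chrom, o_m1s, o_m1e, o_m2s, o_m2e, o_mm1, o_mm2;
    std::vector<int> o_m1fwd;

    std::vector<char> buf;
    for (int i = 0; i < n; ++i) {
        std::string s1 = as<std::string>(r1[i]);
        std::string s2 = as<std::string>(r2[i]);
        std::string s1r = revcomp(s1), s2r = revcomp(s2);

        std::vector<MatePlacement> h1, h2;
        if (use_index) {
            mate_hits_indexed(refs, idx, k, n_seeds, s1,  true,  max_mm_mate, h1, buf);
            mate_hits_indexed(refs, idx, k, n_seeds, s1r, false, max_mm_mate, h1, buf);
            mate_hits_indexed(refs, idx, k, n_seeds, s2,  true,  max_mm_mate, h2, buf);
            mate_hits_indexed(refs, idx, k, n_seeds, s2r, false, max_mm_mate, h2, buf);
        } else {
            mate_hits_scan(refs, s1,  true,  max_mm_mate, h1);
            mate_hits_scan(refs, s1r, false, max_mm_mate, h1);
            mate_hits_scan(refs, s2,  true,  max_mm_mate, h2);
            mate_hits_scan(refs, s2r, false, max_mm_mate, h2);
        }

        std::vector<PairPlacement> pp;
        combine_pairs(h1, (int)s1.size(), h2, (int)s2.size(),
                      max_insert, max_mm_pair, pp);
        n_place[i] = (int)pp.size();
        n_hits_m1[i] = (int)h1.size();
        n_hits_m2[i] = (int)h2.size();
        int report = std::min((int)pp.size(), max_report);
        for (int r = 0; r < report; ++r) {
            o_pair.push_back(i + 1);
            o_chrom.push_back(pp[r].chrom + 1);
            o_m1s.push_back(pp[r].m1_start);
            o_m1e.push_back(pp[r].m1_end);
            o_m2s.push_back(pp[r].m2_start);
            o_m2e.push_back(pp[r].m2_end);
            o_m1fwd.push_back(pp[r].m1_fwd ? 1 : 0);
            o_mm1.push_back(pp[r].mm1);
            o_mm2.push_back(pp[r].mm2);
        }
        if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    }

    DataFrame placements = DataFrame::create(
        _["pair"] = wrap(o_pair),
        _["chrom_idx"] = wrap(o_chrom),
        _["m1_start"] = wrap(o_m1s), _["m1_end"] = wrap(o_m1e),
        _["m2_start"] = wrap(o_m2s), _["m2_end"] = wrap(o_m2e),
        _["m1_forward"] = wrap(o_m1fwd),
        _["mm1"] = wrap(o_mm1), _["mm2"] = wrap(o_mm2));
    return List::create(_["n_placements"] = n_place,
                        _["n_hits_m1"] = n_hits_m1,
                        _["n_hits_m2"] = n_hits_m2,
                        _["placements"] = placements);
}

// [[Rcpp::export]]
List cpp_map_pairs_indexed(CharacterVector ref_seqs,
                           CharacterVector r1, CharacterVector r2,
                           int max_mm_mate, int max_mm_pair,
                           int max_insert, int max_report) {
    return map_pairs_core(ref_seqs, r1, r2, max_mm_mate, max_mm_pair,
                          max_insert, max_report, true);
}

// [[Rcpp::export]]
List cpp_map_pairs_scan(CharacterVector ref_seqs,
                        CharacterVector r1, CharacterVector r2,
                        int max_mm_mate, int max_mm_pair,
                        int max_insert, int max_report) {
    return map_pairs_core(ref_seqs, r1, r2, max_mm_mate, max_mm_pair,
                          max_insert, max_report, false);
}
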