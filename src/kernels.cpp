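#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else (incl. N) invalid.
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// splitmix64 finalizer: stable, well-mixed 64-bit hash of a packed k-mer.
static inline uint64_t mix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

// Bottom-s MinHash sketch over canonical k-mers (numeric min of the 2-bit
// packed forward and reverse-complement codes, which for this encoding is
// the lexicographically smaller strand). k-mers overlapping an ambiguous
// base are skipped. Hashes are truncated to their top 53 bits so they are
// exactly representable as R doubles; returned sorted ascending.
// [[Rcpp::export]]
NumericVector sketch_hashes_cpp(const std::string& seq, int k, int s,
                                double hash_seed) {
    if (k < 1 || k > 32) stop("k must be in [1, 32]");
    const uint64_t seed = (uint64_t) hash_seed;
    const int n = (int) seq.size();
    if (n < k) stop("sequence shorter than k");
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    const int rc_shift = 2 * (k - 1);

    std::vector<uint64_t> hashes;
    hashes.reserve(n - k + 1);
    uint64_t fwd = 0, rc = 0;
    int run = 0;  // length of current valid-base run
    for (int i = 0; i < n; ++i) {
        int c = base_code(seq[i]);
        if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t) c) & mask;
        rc = (rc >> 2) | (((uint64_t) (3 - c)) << rc_shift);
        if (++run >= k) {
            uint64_t canon = fwd < rc ? fwd : rc;
            hashes.push_back(mix64(canon ^ seed) >> 11);
        }
    }
    if (hashes.empty()) stop("no valid k-mers (all windows contain N)");
    std::sort(hashes.begin(), hashes.end());
    hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
    const int keep = std::min((size_t) s, hashes.size());
    NumericVector out(keep);
    for (int i = 0; i < keep; ++i) out[i] = (double) hashes[i];
    return out;
}

// Fragment-based ANI: cut the query into non-overlapping fragments, place
// each fragment in the target by exact seed matches (packed seed_len-mers),
// score every distinct candidate placement by ungapped identity over the
// full fragment, and keep the best. Returns one best identity per fragment,
// or -1 when no seed placed the fragment.
// [[Rcpp::export]]
NumericVector ani_fragment_identities_cpp(const std::string& query,
                                          const std::string& target,
                                          int fragment_len,
                                          int seed_len = 15,
                                          int max_candidates = 64) {
    const int qn = (int) query.size(), tn = (int) target.size();
    if (fragment_len < seed_len) stop("fragment_len must be >= seed_len");
    if (qn < fragment_len || tn < fragment_len)
        stop("both sequences must be at least fragment_len long");
    const uint64_t smask = (1ULL << (2 * seed_len)) - 1ULL;

    // index all valid seed_len-mers of the target
    std::unordered_map<uint64_t, std::vector<int>> index;
    index.reserve(tn);
    {
        uint64_t w = 0; int run = 0;
        for (int i = 0; i < tn; ++i) {
            int c = base_code(target[i]);
            if (c < 0) { run = 0; w = 0; continue; }
            w = ((w << 2) | (uint64_t) c) & smask;
            if (++run >= seed_len) index[w].push_back(i - seed_len + 1);
        }
    }

    const int n_frag = qn / fragment_len;
    NumericVector best(n_frag);
    std::vector<int> cands;
    for (int f = 0; f < n_frag; ++f) {
        const int q0 = f * fragment_len;
        cands.clear();
        uint64_t w = 0; int run = 0;
        for (int i = q0; i < q0 + fragment_len; ++i) {
            int c = base_code(query[i]);
            if (c < 0) { run = 0; w = 0; continue; }
            w = ((w << 2) | (uint64_t) c) & smask;
            if (++run >= seed_len) {
                auto it = index.find(w);
                if (it == index.end()) continue;
                const int off = i - seed_len + 1 - q0;
                for (int tpos : it->second) {
                    int t0 = tpos - off;
                    if (t0 >= 0 && t0 + fragment_len <= tn)
                        cands.push_back(t0);
                    if ((int) cands.size() >= 4 * max_candidates) break;
                }
            }
            if ((int) cands.size() >= 4 * max_candidates) break;
        }
        std::sort(cands.begin(), cands.end());
        cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
        if ((int) cands.size() > max_candidates) cands.resize(max_candidates);
        double bi = -1.0;
        for (int t0 : cands) {
            int m = 0;
            for (int i = 0; i < fragment_len; ++i)
                if (query[q0 + i] == target[t0 + i]) ++m;
            double id = (double) m / fragment_len;
            if (id > bi) bi = id;
        }
        best[f] = bi;
    }
    return best;
}
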