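#ifndef LCSCLUST_CORE_H
#define LCSCLUST_CORE_H

#include <cstdint>
#include <vector>
#include <string>
#include <utility>
#include <algorithm>

namespace lcsclust {

// 2-bit base codes; 4 is the N sentinel (matches nothing, codes no k-mer).
inline std::vector<uint8_t> encode_seq(const std::string& s) {
    std::vector<uint8_t> out(s.size());
    for (std::size_t i = 0; i < s.size(); ++i) {
        switch (s[i]) {
        case 'A': case 'a': out[i] = 0; break;
        case 'C': case 'c': out[i] = 1; break;
        case 'G': case 'g': out[i] = 2; break;
        case 'T': case 't': out[i] = 3; break;
        default:            out[i] = 4; break;
        }
    }
    return out;
}

// Per-base position masks over a sequence X, blocked into w-bit words
// (LSB of block 0 = position 0).  Each 64-bit word carries only its low
// w bits; carries/borrows are chained across blocks explicitly.
struct PositionMasks {
    int m = 0;
    int w = 64;
    int nblocks = 0;
    std::vector<uint64_t> bits;  // symbol-major: 4 * nblocks words

    uint64_t block_mask() const {
        return w == 64 ? ~0ULL : ((1ULL << w) - 1ULL);
    }
};

inline PositionMasks compute_pm(const std::vector<uint8_t>& x, int w) {
    PositionMasks pm;
    pm.m = static_cast<int>(x.size());
    pm.w = w;
    pm.nblocks = pm.m == 0 ? 0 : (pm.m + w - 1) / w;
    pm.bits.assign(static_cast<std::size_t>(4) * pm.nblocks, 0ULL);
    for (int i = 0; i < pm.m; ++i) {
        uint8_t c = x[i];
        if (c >= 4) continue;  // N appears in no mask
        pm.bits[static_cast<std::size_t>(c) * pm.nblocks + i / w] |=
            (1ULL << (i % w));
    }
    return pm;
}

// Bit-parallel LCS length: V starts all-ones; per character c of Y,
//   U = V & PM[c];  V = (V + U) | (V - U)
// and LLCS is the number of cleared bits among the low m positions of V.
// Arithmetic is chained across w-bit blocks with explicit carry/borrow.
inline int llcs_bitparallel(const PositionMasks& pm,
                            const std::vector<uint8_t>& y) {
    const int nb = pm.nblocks, w = pm.w;
    if (nb == 0 || y.empty()) return 0;
    const uint64_t mask = pm.block_mask();
    std::vector<uint64_t> V(nb, mask);
    for (uint8_t c : y) {
        if (c >= 4) continue;  // N matches nothing
        const uint64_t* M = &pm.bits[static_cast<std::size_t>(c) * nb];
        uint64_t carry = 0, borrow = 0;
        for (int b = 0; b < nb; ++b) {
            const uint64_t v = V[b], u = v & M[b];
            uint64_t sum, diff;
            if (w == 64) {
                uint64_t t1 = v + u;
                uint64_t c1 = t1 < v;
                sum = t1 + carry;
                carry = c1 | (sum < t1);
                uint64_t ub = u + borrow;
                uint64_t b1 = ub < u;           // u + borrow wrapped
                diff = v - ub;
                borrow = b1 | (v < ub);
            } else {
                sum = v + u + carry;            // < 2^64 for w <= 63
                carry = sum >> w;
                sum &= mask;
                uint64_t ub = u + borrow;
                if (v >= ub) { diff = v - ub; borrow = 0; }
                else { diff = (v + (1ULL << w)) - ub; borrow = 1; }
            }
            V[b] = (sum | diff) & mask;
        }
    }
    int llcs = 0;
    for (int b = 0; b < nb; ++b) {
        int vb = std::min(w, pm.m - b * w);
        uint64_t vmask = (vb == 64) ? ~0ULL : ((1ULL << vb) - 1ULL);
        llcs += vb - __builtin_popcountll(V[b] & vmask);
    }
    return llcs;
}

// O(mn) dynamic-programming oracle for the LCS length.
inline int llcs_dp(const std::vector<uint8_t>& x,
                   const std::vector<uint8_t>& y) {
    const int m = static_cast<int>(x.size()), n = static_cast<int>(y.size());
    if (m == 0 || n == 0) return 0;
    std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            if (x[i - 1] == y[j - 1] && x[i - 1] < 4)
                cur[j] = prev[j - 1] + 1;
            else
                cur[j] = std::max(cur[j - 1], prev[j]);
        }
        std::swap(prev, cur);
    }
    return prev[n];
}

struct AlignScheme {
    double match = 2.0, mismatch = -2.0;
    double gap_open = -6.0, gap_extend = -1.0;  // gap of len L: open + L*extend
    bool end_gaps_free = true;
};

struct AlignOut {
    double score = 0.0;
    int matches = 0;
    int aligned_length = 0;
};

// Three-state (Gotoh) global affine-gap alignment with optional free end
// gaps; traceback prefers the diagonal state, then gaps in Y, then gaps
// in X, so co-optimal alignments resolve deterministically.
AlignOut align_affine(const std::vector<uint8_t>& x,
                      const std::vector<uint8_t>& y,
                      const AlignScheme& sc);

// Short word table: direct-address index from k-mer code (radix 4) to the
// representatives registered under that code, with the registered position.
struct SWTable {
    int k;
    int n_reps = 0;
    std::vector<std::vector<std::pair<int, int>>> buckets;  // (rep, pos)

    explicit SWTable(int k_) : k(k_) {
        buckets.resize(static_cast<std::size_t>(1) << (2 * k));
    }

    // Register every k-th k-mer of a representative (positions 0, k, 2k, ...),
    // plus the final window ending at the last base when (L - k) is not a
    // multiple of k.  Windows containing N are skipped.  Returns the number
    // of words registered (0 when L < k).
    int register_rep(const std::vector<uint8_t>& seq, int rep_index) {
        if (rep_index >= n_reps) n_reps = rep_index + 1;
        const int L = static_cast<int>(seq.size());
        if (L < k) return 0;
        int registered = 0;
        int last = L - k;
        std::vector<int> positions;
        for (int p = 0; p <= last; p += k) positions.push_back(p);
        if (last % k != 0) positions.push_back(last);
        for (int p : positions) {
            uint64_t code = 0;
            bool ok = true;
            for (int i = 0; i < k; ++i) {
                uint8_t c = seq[p + i];
                if (c >= 4) { ok = false; break; }
                code = (code << 2) | c;
            }
            if (!ok) continue;
            buckets[code].emplace_back(rep_index, p);
            ++registered;
        }
        return registered;
    }

    // Count, per representative, the number of query positions whose k-mer
    // is registered for it (representative-side multiplicity ignored), and
    // return representatives with count >= t in creation (index) order.
    // last_seen / counts are caller-owned scratch, resized as needed.
    std::vector<std::pair<int, int>> find(const std::vector<uint8_t>& seq,
                                          int t,
                                          std::vector<int>& last_seen,
                                          std::vector<int>& counts) const {
        std::vector<std::pair<int, int>> hits;
        const int L = static_cast<int>(seq.size());
        if (L < k) return hits;
        if (static_cast<int>(last_seen.size()) < n_reps) {
            last_seen.assign(n_reps, -1);
            counts.assign(n_reps, 0);
        }
        std::vector<int> touched;
        const uint64_t code_mask = (static_cast<uint64_t>(1) << (2 * k)) - 1;
        uint64_t code = 0;
        int valid = 0;  // bases accumulated since the last N
        for (int p = 0; p < L; ++p) {
            uint8_t c = seq[p];
            if (c >= 4) { valid = 0; code = 0; continue; }
            code = ((code << 2) | c) & code_mask;
            if (++valid < k) continue;
            const int qpos = p - k + 1;
            for (const auto& e : buckets[code]) {
                const int rep = e.first;
                if (last_seen[rep] == qpos) continue;  // once per query position
                last_seen[rep] = qpos;
                if (counts[rep] == 0) touched.push_back(rep);
                ++counts[rep];
            }
        }
        std::sort(touched.begin(), touched.end());
        for (int rep : touched) {
            if (counts[rep] >= t) hits.emplace_back(rep, counts[rep]);
            counts[rep] = 0;
            last_seen[rep] = -1;
        }
        return hits;
    }
};

}  // namespace lcsclust

#endif
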