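#include <Rcpp.h>

#include <memory>

#include "core.h"

using namespace Rcpp;
using namespace lcsclust;

// Greedy incremental clustering over sequences already in processing order.
//
// For each query q: (a) the short word table yields representatives sharing
// >= t common k-mers; (b) each candidate must pass the LCS filter
// LLCS(q, r) / min(|q|, |r|) >= s, a no-false-negative upper bound on the
// attainable identity; (c) survivors are aligned (affine gaps) and q joins
// the first cluster with identity >= s (or the best one when best_hit),
// else q founds a new cluster and is registered in the table.
//
// Returns 0-based cluster ids per input, identity to the representative,
// representative input indices in creation order, and per-stage pair counts.
// [[Rcpp::export]]
List cpp_cluster_greedy(CharacterVector seqs, double s, int k, int t,
                        double match, double mismatch, double gap_open,
                        double gap_extend, bool end_gaps_free, bool best_hit,
                        int w) {
    const int n = seqs.size();
    AlignScheme sc;
    sc.match = match;
    sc.mismatch = mismatch;
    sc.gap_open = gap_open;
    sc.gap_extend = gap_extend;
    sc.end_gaps_free = end_gaps_free;

    SWTable table(k);
    std::vector<std::unique_ptr<PositionMasks>> pm_cache;  // per rep, lazy
    std::vector<int> rep_seq;                              // rep -> input index
    std::vector<std::vector<uint8_t>> rep_enc;             // rep -> encoded seq

    IntegerVector assign(n);
    NumericVector identity(n);
    double n_sw = 0, n_lcs = 0, n_aln = 0, n_acc = 0;

    std::vector<int> last_seen, counts;

    for (int qi = 0; qi < n; ++qi) {
        if ((qi & 1023) == 0) Rcpp::checkUserInterrupt();
        std::vector<uint8_t> qe = encode_seq(as<std::string>(seqs[qi]));
        const int ql = static_cast<int>(qe.size());

        int joined = -1;
        double joined_id = 0.0;

        if (ql >= k) {
            auto cands = table.find(qe, t, last_seen, counts);
            n_sw += static_cast<double>(cands.size());
            for (const auto& cand : cands) {
                const int r = cand.first;
                const std::vector<uint8_t>& re = rep_enc[r];
                const int nmin = std::min(ql, static_cast<int>(re.size()));
                if (nmin == 0) continue;
                if (!pm_cache[r])
                    pm_cache[r].reset(
                        new PositionMasks(compute_pm(re, w)));
                const int llcs = llcs_bitparallel(*pm_cache[r], qe);
                if (static_cast<double>(llcs) / nmin < s) continue;
                ++n_lcs;
                AlignOut a = align_affine(qe, re, sc);
                ++n_aln;
                const double id = static_cast<double>(a.matches) / nmin;
                if (id >= s) {
                    ++n_acc;
                    if (!best_hit) {
                        joined = r;
                        joined_id = id;
                        break;
                    }
                    if (id > joined_id || joined < 0) {
                        joined = r;
                        joined_id = id;
                    }
                }
            }
        }

        if (joined >= 0) {
            assign[qi] = joined;
            identity[qi] = joined_id;
        } else {
            const int r = static_cast<int>(rep_seq.size());
            table.register_rep(qe, r);
            rep_seq.push_back(qi);
            rep_enc.push_back(std::move(qe));
            pm_cache.emplace_back(nullptr);
            assign[qi] = r;
            identity[qi] = 1.0;
        }
    }

    IntegerVector reps(rep_seq.begin(), rep_seq.end());
    NumericVector stats = NumericVector::create(
        _["sequences"] = static_cast<double>(n),
        _["clusters"] = static_cast<double>(rep_seq.size()),
        _["shortword_pairs"] = n_sw, _["lcs_pass_pairs"] = n_lcs,
        _["aligned_pairs"] = n_aln, _["accepted_pairs"] = n_acc);
    return List::create(_["assign"] = assign, _["identity"] = identity,
                        _["reps"] = reps, _["stats"] = stats);
}
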