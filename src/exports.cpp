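#include <Rcpp.h>
#include <cstring>

#include "core.h"

using namespace Rcpp;
using namespace lcsclust;

namespace {

PositionMasks pm_from_r(const List& masks, int m, int w) {
    PositionMasks pm;
    pm.m = m;
    pm.w = w;
    pm.nblocks = m == 0 ? 0 : (m + w - 1) / w;
    pm.bits.assign(static_cast<std::size_t>(4) * pm.nblocks, 0ULL);
    for (int s = 0; s < 4; ++s) {
        RawVector rv = masks[s];
        if (static_cast<int>(rv.size()) != 8 * pm.nblocks)
            stop("corrupt position mask: wrong byte length");
        if (pm.nblocks > 0)
            std::memcpy(&pm.bits[static_cast<std::size_t>(s) * pm.nblocks],
                        RAW(rv), 8 * pm.nblocks);
    }
    return pm;
}

AlignScheme scheme_from_args(double match, double mismatch,
                             double gap_open, double gap_extend,
                             bool end_gaps_free) {
    AlignScheme sc;
    sc.match = match;
    sc.mismatch = mismatch;
    sc.gap_open = gap_open;
    sc.gap_extend = gap_extend;
    sc.end_gaps_free = end_gaps_free;
    return sc;
}

}  // namespace

// [[Rcpp::export]]
List cpp_compute_pm(std::string x, int w) {
    std::vector<uint8_t> xe = encode_seq(x);
    PositionMasks pm = compute_pm(xe, w);
    List masks(4);
    for (int s = 0; s < 4; ++s) {
        RawVector rv(8 * pm.nblocks);
        if (pm.nblocks > 0)
            std::memcpy(RAW(rv),
                        &pm.bits[static_cast<std::size_t>(s) * pm.nblocks],
                        8 * pm.nblocks);
        masks[s] = rv;
    }
    masks.attr("names") = CharacterVector::create("A", "C", "G", "T");
    return List::create(_["masks"] = masks, _["m"] = pm.m, _["w"] = pm.w,
                        _["nblocks"] = pm.nblocks);
}

// [[Rcpp::export]]
int cpp_llcs_bitparallel(List masks, int m, int w, std::string y) {
    PositionMasks pm = pm_from_r(masks, m, w);
    std::vector<uint8_t> ye = encode_seq(y);
    return llcs_bitparallel(pm, ye);
}

// [[Rcpp::export]]
int cpp_llcs_dp(std::string x, std::string y) {
    return llcs_dp(encode_seq(x), encode_seq(y));
}

// [[Rcpp::export]]
List cpp_align_affine(std::string x, std::string y, double match,
                      double mismatch, double gap_open, double gap_extend,
                      bool end_gaps_free) {
    AlignScheme sc = scheme_from_args(match, mismatch, gap_open, gap_extend,
                                      end_gaps_free);
    AlignOut out = align_affine(encode_seq(x), encode_seq(y), sc);
    return List::create(_["score"] = out.score, _["matches"] = out.matches,
                        _["aligned_length"] = out.aligned_length);
}

// Identity (matches / shorter length) of one sequence against a set.
// [[Rcpp::export]]
NumericVector cpp_identity_vs_set(std::string q, CharacterVector set,
                                  double match, double mismatch,
                                  double gap_open, double gap_extend,
                                  bool end_gaps_free) {
    AlignScheme sc = scheme_from_args(match, mismatch, gap_open, gap_extend,
                                      end_gaps_free);
    std::vector<uint8_t> qe = encode_seq(q);
    NumericVector out(set.size());
    for (R_xlen_t i = 0; i < set.size(); ++i) {
        std::vector<uint8_t> re = encode_seq(as<std::string>(set[i]));
        int nmin = static_cast<int>(std::min(qe.size(), re.size()));
        if (nmin == 0) { out[i] = NA_REAL; continue; }
        AlignOut a = align_affine(qe, re, sc);
        out[i] = static_cast<double>(a.matches) / nmin;
    }
    return out;
}

// ---- short word table (external pointer) ----

// [[Rcpp::export]]
SEXP cpp_swt_create(int k) {
    XPtr<SWTable> xp(new SWTable(k), true);
    return xp;
}

// [[Rcpp::export]]
int cpp_swt_register(SEXP table, std::string seq, int rep_index) {
    XPtr<SWTable> xp(table);
    return xp->register_rep(encode_seq(seq), rep_index);
}

// [[Rcpp::export]]
List cpp_swt_find(SEXP table, std::string seq, int t) {
    XPtr<SWTable> xp(table);
    std::vector<int> last_seen, counts;
    auto hits = xp->find(encode_seq(seq), t, last_seen, counts);
    IntegerVector rep(hits.size()), count(hits.size());
    for (std::size_t i = 0; i < hits.size(); ++i) {
        rep[i] = hits[i].first;
        count[i] = hits[i].second;
    }
    return List::create(_["rep"] = rep, _["count"] = count);
}

// [[Rcpp::export]]
DataFrame cpp_swt_entries(SEXP table) {
    XPtr<SWTable> xp(table);
    std::vector<double> code;
    std::vector<int> rep, pos;
    for (std::size_t c = 0; c < xp->buckets.size(); ++c) {
        for (const auto& e : xp->buckets[c]) {
            code.push_back(static_cast<double>(c));
            rep.push_back(e.first);
            pos.push_back(e.second);
        }
    }
    return DataFrame::create(_["code"] = code, _["rep"] = rep, _["pos"] = pos);
}

// [[Rcpp::export]]
int cpp_swt_k(SEXP table) {
    XPtr<SWTable> xp(table);
    return xp->k;
}

// [[Rcpp::export]]
int cpp_swt_nreps(SEXP table) {
    XPtr<SWTable> xp(table);
    return xp->n_reps;
}
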