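#include "core.h"

#include <limits>

namespace lcsclust {

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

enum State : uint8_t { ST_M = 0, ST_X = 1, ST_Y = 2, ST_ORIGIN = 3 };

inline std::size_t idx(int i, int j, int ncol) {
    return static_cast<std::size_t>(i) * ncol + j;
}

}  // namespace

AlignOut align_affine(const std::vector<uint8_t>& x_in,
                      const std::vector<uint8_t>& y_in,
                      const AlignScheme& sc) {
    // Scoring is symmetric in the two sequences, but the choice among
    // co-optimal tracebacks is not; orient the pair canonically (shorter,
    // then lexicographically smaller, sequence as x) so the reported match
    // count — and hence the identity — is a symmetric function of the pair.
    const bool swap_args = (x_in.size() > y_in.size()) ||
        (x_in.size() == y_in.size() && x_in > y_in);
    const std::vector<uint8_t>& x = swap_args ? y_in : x_in;
    const std::vector<uint8_t>& y = swap_args ? x_in : y_in;
    const int m = static_cast<int>(x.size());
    const int n = static_cast<int>(y.size());
    const int nc = n + 1;
    const double go = sc.gap_open, ge = sc.gap_extend;

    // Score matrices for the three states: M (x_i ~ y_j), X (x_i ~ gap),
    // Y (gap ~ y_j), plus per-state predecessor-state pointers.
    std::vector<double> M(idx(m, n, nc) + 1, NEG_INF);
    std::vector<double> X(M), Y(M);
    std::vector<uint8_t> pM(M.size(), ST_ORIGIN), pX(pM), pY(pM);

    M[idx(0, 0, nc)] = 0.0;
    for (int i = 1; i <= m; ++i) {
        std::size_t c = idx(i, 0, nc);
        if (sc.end_gaps_free) {
            X[c] = 0.0;  // free leading overhang of x
        } else if (i == 1) {
            X[c] = go + ge;
            pX[c] = ST_M;
        } else {
            X[c] = X[idx(i - 1, 0, nc)] + ge;
            pX[c] = ST_X;
        }
    }
    for (int j = 1; j <= n; ++j) {
        std::size_t c = idx(0, j, nc);
        if (sc.end_gaps_free) {
            Y[c] = 0.0;
        } else if (j == 1) {
            Y[c] = go + ge;
            pY[c] = ST_M;
        } else {
            Y[c] = Y[idx(0, j - 1, nc)] + ge;
            pY[c] = ST_Y;
        }
    }

    // best-of-three with deterministic preference M > X > Y
    auto best3 = [](double a, double b, double c, uint8_t& which) {
        double v = a;
        which = ST_M;
        if (b > v) { v = b; which = ST_X; }
        if (c > v) { v = c; which = ST_Y; }
        return v;
    };

    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            const std::size_t c = idx(i, j, nc);
            const std::size_t d = idx(i - 1, j - 1, nc);
            const std::size_t up = idx(i - 1, j, nc);
            const std::size_t lf = idx(i, j - 1, nc);
            const bool is_match = (x[i - 1] == y[j - 1] && x[i - 1] < 4);
            const double sub = is_match ? sc.match : sc.mismatch;
            uint8_t w;
            double v = best3(M[d], X[d], Y[d], w);
            if (v > NEG_INF) { M[c] = v + sub; pM[c] = w; }
            v = best3(M[up] + go + ge, X[up] + ge, Y[up] + go + ge, w);
            if (v > NEG_INF) { X[c] = v; pX[c] = w; }
            v = best3(M[lf] + go + ge, Y[lf] + ge, X[lf] + go + ge, w);
            if (v > NEG_INF) {
                Y[c] = v;
                // best3 slot b held Y here; remap
                pY[c] = (w == ST_M) ? ST_M : (w == ST_X ? ST_Y : ST_X);
            }
        }
    }

    // Locate the alignment end.  With free end gaps the optimum may sit
    // anywhere on the last row/column (the remainder is a free overhang);
    // ties prefer the corner, then cells closer to it, then state M.
    int ei = m, ej = n;
    uint8_t est = ST_M;
    double best = NEG_INF;
    auto consider = [&](int i, int j) {
        const std::size_t c = idx(i, j, nc);
        const double vals[3] = { M[c], X[c], Y[c] };
        for (int s = 0; s < 3; ++s) {
            if (vals[s] > best) {
                best = vals[s];
                ei = i; ej = j; est = static_cast<uint8_t>(s);
            }
        }
    };
    if (sc.end_gaps_free) {
        consider(m, n);
        for (int j = n - 1; j >= 0; --j) consider(m, j);
        for (int i = m - 1; i >= 0; --i) consider(i, n);
    } else {
        consider(m, n);
    }

    AlignOut out;
    out.score = best;

    // Traceback from (ei, ej, est); overhang columns outside the walk are
    // counted but hold no matches.
    int i = ei, j = ej, cols = 0, matches = 0;
    uint8_t st = est;
    int leading = 0;
    while (true) {
        const std::size_t c = idx(i, j, nc);
        const uint8_t p = (st == ST_M) ? pM[c] : (st == ST_X ? pX[c] : pY[c]);
        if (st == ST_M && i == 0 && j == 0) { leading = 0; break; }
        if (p == ST_ORIGIN && st != ST_M) { leading = i + j; break; }
        if (st == ST_M) {
            ++cols;
            if (x[i - 1] == y[j - 1] && x[i - 1] < 4) ++matches;
            --i; --j;
        } else if (st == ST_X) {
            ++cols;
            --i;
        } else {
            ++cols;
            --j;
        }
        st = p;
    }
    out.matches = matches;
    out.aligned_length = leading + cols + (m - ei) + (n - ej);
    return out;
}

}  // namespace lcsclust
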