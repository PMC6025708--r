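#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Grid-search maximal information coefficient.
//
// Admissible grid shapes (cx, cy) are bounded by n^alpha: per the printed
// MIC equation each axis' bin count satisfies cx < n^alpha and cy < n^alpha
// (axis bound, the default); the product bound cx * cy < n^alpha used by
// the MINE reference implementations is available as an option.  For each
// shape the characteristic-matrix entry is the maximum, over grid
// placements, of the mutual information of the induced 2-D histogram
// divided by log2(min(cx, cy)); MIC is the maximum entry.
//
// The placement search is the standard approximation: one axis is
// equipartitioned by rank, the other optimised exactly by dynamic
// programming over clump boundaries; both orientations are searched and the
// larger value kept.  Points are ordered by (value, original index), so
// tied values have a deterministic rank order and grid lines may fall
// between them; all partition logic is rank-based, which makes the
// statistic exactly invariant under strictly increasing transforms.

static const double EPS = 1e-9;

static std::vector<int> order_idx(const NumericVector& v) {
    std::vector<int> o(v.size());
    std::iota(o.begin(), o.end(), 0);
    std::stable_sort(o.begin(), o.end(),
                     [&](int a, int b) { return v[a] < v[b]; });
    return o;
}

// rank equipartition: sorted position p of n goes to bin floor(p * k / n),
// giving k contiguous rank blocks whose sizes differ by at most one
static std::vector<int> equipartition(const std::vector<int>& ord, int k) {
    const int n = static_cast<int>(ord.size());
    std::vector<int> assign(n);
    for (int p = 0; p < n; ++p)
        assign[ord[p]] = static_cast<int>((static_cast<long long>(p) * k) / n);
    return assign;
}

struct Clumps {
    std::vector<int> size;              // points per clump, in axis order
    std::vector<std::vector<int>> row;  // per-clump counts in each rank-bin
};

// Merge consecutive points (in the optimised axis' rank order) falling in
// the same rank-bin of the other axis; optimal cuts never fall inside such
// runs, so clump boundaries are the only cut candidates the DP needs.
static Clumps get_clumps(const std::vector<int>& ord,
                         const std::vector<int>& q, int nrow) {
    Clumps cl;
    int prev = -1;
    for (int p = 0; p < static_cast<int>(ord.size()); ++p) {
        const int r = q[ord[p]];
        if (r == prev) {
            cl.size.back() += 1;
            cl.row.back()[r] += 1;
        } else {
            cl.size.push_back(1);
            cl.row.push_back(std::vector<int>(nrow, 0));
            cl.row.back()[r] = 1;
            prev = r;
        }
    }
    return cl;
}

// Cap the number of cut candidates: regroup clumps into at most chat
// superclumps of near-equal point count (clumps stay atomic).
static Clumps superclumps(const Clumps& cl, int chat, int n) {
    Clumps out;
    double desired = static_cast<double>(n) / chat;
    double filled = 0.0;
    int cur = 0, seen = 0;
    for (size_t g = 0; g < cl.size.size(); ++g) {
        const double s = cl.size[g];
        if (filled > 0.0 &&
            std::fabs(filled + s - desired) >= std::fabs(filled - desired) &&
            cur < chat - 1) {
            ++cur;
            filled = 0.0;
            desired = static_cast<double>(n - seen) / (chat - cur);
        }
        if (filled == 0.0) {
            out.size.push_back(0);
            out.row.push_back(std::vector<int>(cl.row[g].size(), 0));
        }
        out.size.back() += cl.size[g];
        for (size_t r = 0; r < cl.row[g].size(); ++r)
            out.row.back()[r] += cl.row[g][r];
        filled += s;
        seen += cl.size[g];
    }
    return out;
}

// Exact DP over clump boundaries: best[l] = max mutual information (bits)
// of any partition of the optimised axis into at most l bins, l = 2..L,
// against the fixed rank-bin assignment with entropy hq.
static std::vector<double> optimize_axis(const Clumps& cl, int L, int n,
                                         double hq, int nrow) {
    const int k = static_cast<int>(cl.size.size());
    std::vector<int> csum(k + 1, 0);
    std::vector<std::vector<int>> cum(k + 1, std::vector<int>(nrow, 0));
    for (int t = 1; t <= k; ++t) {
        csum[t] = csum[t - 1] + cl.size[t - 1];
        for (int r = 0; r < nrow; ++r)
            cum[t][r] = cum[t - 1][r] + cl.row[t - 1][r];
    }
    // bin score g(s,t) = -np log2 np + sum_q d_q log2 d_q over points in
    // clumps s+1..t; sum of bin scores / n + H(Q) = I(P;Q)
    auto g = [&](int s, int t) {
        const double np = csum[t] - csum[s];
        double val = -np * std::log2(np);
        for (int r = 0; r < nrow; ++r) {
            const double d = cum[t][r] - cum[s][r];
            if (d > 0) val += d * std::log2(d);
        }
        return val;
    };
    const int Leff = std::min(L, k);
    const double NEG = -std::numeric_limits<double>::infinity();
    std::vector<std::vector<double>> G(Leff + 1,
                                       std::vector<double>(k + 1, NEG));
    for (int t = 1; t <= k; ++t) G[1][t] = g(0, t);
    for (int l = 2; l <= Leff; ++l)
        for (int t = l; t <= k; ++t)
            for (int s = l - 1; s < t; ++s) {
                const double cand = G[l - 1][s] + g(s, t);
                if (cand > G[l][t]) G[l][t] = cand;
            }
    std::vector<double> best(L + 1, 0.0);
    double run = 0.0;  // a single bin gives I = 0
    for (int l = 2; l <= L; ++l) {
        if (l <= Leff) {
            const double I = hq + G[l][k] / n;
            if (I > run) run = I;
        }
        best[l] = std::max(run, 0.0);
    }
    return best;
}

// [[Rcpp::export]]
List cpp_mic(NumericVector x, NumericVector y, double alpha, int clumps,
             bool keep_matrix, bool axis_bound) {
    const int n = x.size();
    const double B = std::pow(static_cast<double>(n), alpha);
    auto admissible = [&](int cx, int cy) {
        if (axis_bound)
            return static_cast<double>(cx) < B - EPS &&
                   static_cast<double>(cy) < B - EPS;
        return static_cast<double>(cx) * cy < B - EPS;
    };
    if (n < 4 || !admissible(2, 2))
        return List::create(_["no_grid"] = true);

    int maxax = 2;
    while (admissible(maxax + 1, 2)) ++maxax;

    // constant inputs carry no grid information
    int dx = 1, dy = 1;
    {
        std::vector<int> ox = order_idx(x), oy = order_idx(y);
        for (int i = 1; i < n; ++i) {
            if (x[ox[i]] != x[ox[i - 1]]) ++dx;
            if (y[oy[i]] != y[oy[i - 1]]) ++dy;
        }
    }
    if (dx < 2 || dy < 2)
        return List::create(_["mic"] = 0.0, _["best_cx"] = NA_INTEGER,
                            _["best_cy"] = NA_INTEGER, _["degenerate"] = true,
                            _["char_matrix"] = R_NilValue);

    NumericMatrix M(maxax - 1, maxax - 1);
    std::fill(M.begin(), M.end(), NA_REAL);

    const std::vector<int> ordx = order_idx(x), ordy = order_idx(y);
    // swapped = false: equipartition y into r rows, optimise x into l columns
    for (int swapped = 0; swapped < 2; ++swapped) {
        const std::vector<int>& ord_eq = swapped ? ordx : ordy;
        const std::vector<int>& ord_opt = swapped ? ordy : ordx;
        for (int r = 2; admissible(2, r); ++r) {
            int L = 2;
            while (admissible(L + 1, r)) ++L;
            const std::vector<int> q = equipartition(ord_eq, r);
            std::vector<int> tot(r, 0);
            for (int i = 0; i < n; ++i) tot[q[i]]++;
            double hq = 0.0;
            for (int rr = 0; rr < r; ++rr)
                if (tot[rr] > 0) {
                    const double p = static_cast<double>(tot[rr]) / n;
                    hq -= p * std::log2(p);
                }
            Clumps cl = get_clumps(ord_opt, q, r);
            const int chat = std::max(clumps * L, 2);
            if (static_cast<int>(cl.size.size()) > chat)
                cl = superclumps(cl, chat, n);
            const std::vector<double> best = optimize_axis(cl, L, n, hq, r);
            for (int l = 2; l <= L; ++l) {
                const double nmi =
                    best[l] / std::log2(static_cast<double>(std::min(l, r)));
                const int cx = swapped ? r : l;
                const int cy = swapped ? l : r;
                double& cell = M(cx - 2, cy - 2);
                if (NumericMatrix::is_na(cell) || nmi > cell) cell = nmi;
            }
        }
    }

    double mic = 0.0;
    int bcx = 2, bcy = 2;
    for (int cy = 2; cy <= maxax; ++cy)
        for (int cx = 2; cx <= maxax; ++cx) {
            if (!admissible(cx, cy)) continue;
            const double v = M(cx - 2, cy - 2);
            if (!NumericMatrix::is_na(v) && v > mic + 1e-12) {
                mic = v;
                bcx = cx;
                bcy = cy;
            }
        }
    if (mic > 1.0) mic = 1.0;

    return List::create(_["mic"] = mic, _["best_cx"] = bcx,
                        _["best_cy"] = bcy, _["degenerate"] = false,
                        _["char_matrix"] = keep_matrix ? M : NumericMatrix(0, 0));
}
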