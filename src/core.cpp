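#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Ranking: rank each row of a matrix, ties broken by first occurrence
// (columns are samples). Ranks are a permutation of 1..n.
// ---------------------------------------------------------------------------

static void rank_row(const double* v, int n, int* out) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return v[a] < v[b]; });
    for (int r = 0; r < n; ++r) out[idx[r]] = r + 1;
}

// [[Rcpp::export(name = ".rank_rows_cpp")]]
IntegerMatrix rank_rows_cpp(NumericMatrix x) {
    int g = x.nrow(), n = x.ncol();
    IntegerMatrix out(g, n);
    std::vector<double> row(n);
    std::vector<int> rr(n);
    for (int i = 0; i < g; ++i) {
        for (int j = 0; j < n; ++j) row[j] = x(i, j);
        rank_row(row.data(), n, rr.data());
        for (int j = 0; j < n; ++j) out(i, j) = rr[j];
    }
    return out;
}

// ---------------------------------------------------------------------------
// Mutual information estimators on rank permutations (1..n).
//
// Adaptive partitioning: recursively split the rank plane into quadrants
// while a chi-square test (3 d.f., alpha = 0.05 -> 7.8147) rejects
// uniformity of the cell; leaf cells contribute p*log(p/(px*py)).
// Minimum cell size for a split attempt is 8 points (expected count 2 per
// quadrant).
// ---------------------------------------------------------------------------

static const double CHI3_95 = 7.814727903251179;

struct APState {
    const int* xr;
    const int* yr;
    double n;
    double mi;
};

static void ap_rec(APState& st, std::vector<int>& idx,
                   int x1, int x2, int y1, int y2) {
    int k = (int)idx.size();
    if (k == 0) return;
    int w = x2 - x1 + 1, h = y2 - y1 + 1;
    bool split = false;
    int xm = (x1 + x2) / 2, ym = (y1 + y2) / 2;
    std::vector<int> q[4];
    if (w >= 2 && h >= 2 && k >= 8) {
        int cnt[4] = {0, 0, 0, 0};
        for (int i : idx) {
            int qx = st.xr[i] > xm, qy = st.yr[i] > ym;
            ++cnt[qx * 2 + qy];
        }
        double e = k / 4.0, chi2 = 0.0;
        for (int q4 = 0; q4 < 4; ++q4) {
            double d = cnt[q4] - e;
            chi2 += d * d / e;
        }
        if (chi2 > CHI3_95) {
            split = true;
            for (int q4 = 0; q4 < 4; ++q4) q[q4].reserve(cnt[q4]);
            for (int i : idx) {
                int qx = st.xr[i] > xm, qy = st.yr[i] > ym;
                q[qx * 2 + qy].push_back(i);
            }
        }
    }
    if (split) {
        idx.clear(); idx.shrink_to_fit();
        ap_rec(st, q[0], x1, xm, y1, ym);
        ap_rec(st, q[1], x1, xm, ym + 1, y2);
        ap_rec(st, q[2], xm + 1, x2, y1, ym);
        ap_rec(st, q[3], xm + 1, x2, ym + 1, y2);
    } else {
        double p = k / st.n;
        double px = w / st.n, py = h / st.n;
        st.mi += p * std::log(p / (px * py));
    }
}

static double mi_adaptive(const int* xr, const int* yr, int n) {
    APState st;
    st.xr = xr; st.yr = yr; st.n = (double)n; st.mi = 0.0;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    ap_rec(st, idx, 1, n, 1, n);
    return st.mi > 0 ? st.mi : 0.0;
}

// Equal-frequency binning plug-in estimator: bin b = floor((rank-1)*B/n).
static double mi_eqfreq(const int* xr, const int* yr, int n, int B) {
    std::vector<int> cnt(B * B, 0), rx(B, 0), cy(B, 0);
    for (int i = 0; i < n; ++i) {
        int bx = (int)(((long long)(xr[i] - 1)) * B / n);
        int by = (int)(((long long)(yr[i] - 1)) * B / n);
        ++cnt[bx * B + by];
        ++rx[bx];
        ++cy[by];
    }
    double mi = 0.0, dn = (double)n;
    for (int i = 0; i < B; ++i)
        for (int j = 0; j < B; ++j) {
            int c = cnt[i * B + j];
            if (c > 0)
                mi += (c / dn) * std::log((c * dn) / ((double)rx[i] * cy[j]));
        }
    return mi > 0 ? mi : 0.0;
}

// estimator: 1 = adaptive_partition, 2 = equifreq_bins
// [[Rcpp::export(name = ".mi_pair_cpp")]]
double mi_pair_cpp(IntegerVector xr, IntegerVector yr, int estimator, int bins) {
    int n = xr.size();
    if (estimator == 1) return mi_adaptive(&xr[0], &yr[0], n);
    return mi_eqfreq(&xr[0], &yr[0], n, bins);
}

// MI between every regulator row and every row of the rank matrix.
// ranks: genes x samples, each row a permutation of 1..n.
// regIdx: 1-based row indices of the regulators.
// Returns length(regIdx) x nrow(ranks) matrix, diagonal (self) = NA.
// [[Rcpp::export(name = ".mi_all_pairs_cpp")]]
NumericMatrix mi_all_pairs_cpp(IntegerMatrix ranks, IntegerVector regIdx,
                               int estimator, int bins) {
    int g = ranks.nrow(), n = ranks.ncol(), r = regIdx.size();
    // copy to row-major buffers for locality
    std::vector<int> buf((size_t)g * n);
    for (int i = 0; i < g; ++i)
        for (int j = 0; j < n; ++j)
            buf[(size_t)i * n + j] = ranks(i, j);
    NumericMatrix out(r, g);
    for (int a = 0; a < r; ++a) {
        const int* xr = &buf[(size_t)(regIdx[a] - 1) * n];
        for (int b = 0; b < g; ++b) {
            if (regIdx[a] - 1 == b) { out(a, b) = NA_REAL; continue; }
            const int* yr = &buf[(size_t)b * n];
            out(a, b) = (estimator == 1) ? mi_adaptive(xr, yr, n)
                                         : mi_eqfreq(xr, yr, n, bins);
        }
    }
    return out;
}

// ---------------------------------------------------------------------------
// Weighted running-sum statistic.
//
// Genes are sorted by expression (descending).  For a weight profile with
// support positions pos (1-based ranks, unsorted) and per-gene foreground
// mass wabs = weight * |expression|, the foreground F(k) is the cumulative
// share of total foreground mass at rank k and the background B(k) the
// cumulative share of the zero-weight genes.  Returns F(k*) - B(k*) at the
// first k* maximising |F - B|.  Piecewise linearity confines the scan to
// support positions and the ranks just before them.
// ---------------------------------------------------------------------------

static double running_sum_dev(std::vector<int>& pos, std::vector<double>& wabs,
                              int N, bool* degenerate) {
    int m = (int)pos.size();
    int m0 = N - m;
    *degenerate = false;
    if (m == 0) { *degenerate = true; return 0.0; }
    if (m0 <= 0) { *degenerate = true; return NA_REAL; }
    std::vector<int> ord(m);
    for (int i = 0; i < m; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return pos[a] < pos[b]; });
    // accumulate the normaliser in rank order so the final foreground
    // point is exactly 1 (guards |deviation| ties at rational values)
    long double S = 0.0;
    for (int i = 0; i < m; ++i) S += wabs[ord[i]];
    if (!(S > 0.0)) { *degenerate = true; return 0.0; }
    double bestAbs = -1.0, bestVal = 0.0;
    long double cum = 0.0;
    // interval before the first support gene: |dev| max at k = pos[0]-1
    if (pos[ord[0]] > 1) {
        double dev = -((double)(pos[ord[0]] - 1)) / m0;
        if (std::fabs(dev) > bestAbs) { bestAbs = std::fabs(dev); bestVal = dev; }
    }
    for (int j = 0; j < m; ++j) {
        int k = pos[ord[j]];
        cum += wabs[ord[j]];
        double F = (double)(cum / S);
        double dev = F - ((double)(k - (j + 1))) / m0;
        if (std::fabs(dev) > bestAbs) { bestAbs = std::fabs(dev); bestVal = dev; }
        int kend = (j < m - 1) ? pos[ord[j + 1]] - 1 : N;
        if (kend > k) {
            double dev2 = F - ((double)(kend - (j + 1))) / m0;
            if (std::fabs(dev2) > bestAbs) { bestAbs = std::fabs(dev2); bestVal = dev2; }
        }
    }
    return bestVal;
}

// [[Rcpp::export(name = ".running_sum_dev_cpp")]]
NumericVector running_sum_dev_cpp(IntegerVector pos, NumericVector wabs, int N) {
    std::vector<int> p(pos.begin(), pos.end());
    std::vector<double> w(wabs.begin(), wabs.end());
    bool deg = false;
    double d = running_sum_dev(p, w, N, &deg);
    NumericVector out = NumericVector::create(d);
    out.attr("degenerate") = deg;
    return out;
}

// Sample m distinct integers from 1..N (Floyd), then shuffle so that every
// ordering of the sampled set is equally likely — the caller splits the
// sequence into the up- and down-profile positions.
static void sample_distinct(std::mt19937& rng, int N, int m, std::vector<int>& out) {
    out.clear();
    for (int j = N - m + 1; j <= N; ++j) {
        std::uniform_int_distribution<int> U(1, j);
        int t = U(rng);
        bool dup = false;
        for (int v : out) if (v == t) { dup = true; break; }
        out.push_back(dup ? j : t);
    }
    for (int i = m - 1; i > 0; --i) {
        std::uniform_int_distribution<int> U(0, i);
        std::swap(out[i], out[U(rng)]);
    }
}

// Null pre-iExpr values: support genes are re-assigned uniformly random
// ranks; foreground mass uses the |expression| found at the sampled rank.
// valsAbs: |expression| in descending-expression order (length N).
// [[Rcpp::export(name = ".perm_null_cpp")]]
NumericVector perm_null_cpp(NumericVector valsAbs, NumericVector wUp,
                            NumericVector wDown, int nPerm, double seed) {
    int N = valsAbs.size();
    int mu = wUp.size(), md = wDown.size();
    int m = mu + md;
    if (m >= N) stop("profile support covers the whole universe; background undefined");
    std::mt19937 rng((uint32_t)((long long)seed & 0xffffffffLL));
    NumericVector out(nPerm);
    std::vector<int> samp, posU(mu), posD(md);
    std::vector<double> wbU(mu), wbD(md);
    bool deg;
    for (int p = 0; p < nPerm; ++p) {
        sample_distinct(rng, N, m, samp);
        double devU = 0.0, devD = 0.0;
        if (mu > 0) {
            for (int i = 0; i < mu; ++i) {
                posU[i] = samp[i];
                wbU[i] = wUp[i] * std::fabs(valsAbs[samp[i] - 1]);
            }
            devU = running_sum_dev(posU, wbU, N, &deg);
        }
        if (md > 0) {
            for (int i = 0; i < md; ++i) {
                posD[i] = samp[mu + i];
                wbD[i] = wDown[i] * std::fabs(valsAbs[samp[mu + i] - 1]);
            }
            devD = running_sum_dev(posD, wbD, N, &deg);
        }
        out[p] = devU - devD;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Full iExpr matrix: observed pre-iExpr plus permutation-null summaries for
// every (lncRNA, sample) cell.  rankPos[g, s] = descending-expression rank of
// gene g in sample s; valsAbs[k, s] = |expression| at rank k of sample s.
// profiles: list per lncRNA of list(upIdx, upW, downIdx, downW) with 1-based
// gene indices; zero-length components encode an invalid profile.
// cellSeeds: L x S matrix of RNG seeds.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".infer_iexpr_cpp")]]
List infer_iexpr_cpp(IntegerMatrix rankPos, NumericMatrix valsAbs,
                     List profiles, int nPerm, NumericMatrix cellSeeds) {
    int N = rankPos.nrow(), S = rankPos.ncol(), L = profiles.size();
    NumericMatrix pre(L, S), nullPos(L, S), nullNeg(L, S), nullMean(L, S);
    std::vector<int> samp;
    for (int l = 0; l < L; ++l) {
        List pf = profiles[l];
        IntegerVector upIdx = pf["upIdx"];
        NumericVector upW = pf["upW"];
        IntegerVector dnIdx = pf["downIdx"];
        NumericVector dnW = pf["downW"];
        int mu = upIdx.size(), md = dnIdx.size(), m = mu + md;
        if (m == 0 || m >= N) {
            for (int s = 0; s < S; ++s) {
                pre(l, s) = NA_REAL; nullPos(l, s) = NA_REAL;
                nullNeg(l, s) = NA_REAL; nullMean(l, s) = NA_REAL;
            }
            continue;
        }
        std::vector<int> posU(mu), posD(md);
        std::vector<double> wbU(mu), wbD(md);
        bool deg;
        for (int s = 0; s < S; ++s) {
            // observed deviation
            double devU = 0.0, devD = 0.0;
            for (int i = 0; i < mu; ++i) {
                posU[i] = rankPos(upIdx[i] - 1, s);
                wbU[i] = upW[i] * std::fabs(valsAbs(posU[i] - 1, s));
            }
            if (mu > 0) devU = running_sum_dev(posU, wbU, N, &deg);
            for (int i = 0; i < md; ++i) {
                posD[i] = rankPos(dnIdx[i] - 1, s);
                wbD[i] = dnW[i] * std::fabs(valsAbs(posD[i] - 1, s));
            }
            if (md > 0) devD = running_sum_dev(posD, wbD, N, &deg);
            pre(l, s) = devU - devD;
            // permutation null
            std::mt19937 rng((uint32_t)((long long)cellSeeds(l, s) & 0xffffffffLL));
            double sumAll = 0.0, sumP = 0.0, sumN = 0.0;
            int nP = 0, nN = 0;
            for (int p = 0; p < nPerm; ++p) {
                sample_distinct(rng, N, m, samp);
                double dU = 0.0, dD = 0.0;
                if (mu > 0) {
                    for (int i = 0; i < mu; ++i) {
                        posU[i] = samp[i];
                        wbU[i] = upW[i] * std::fabs(valsAbs(samp[i] - 1, s));
                    }
                    dU = running_sum_dev(posU, wbU, N, &deg);
                }
                if (md > 0) {
                    for (int i = 0; i < md; ++i) {
                        posD[i] = samp[mu + i];
                        wbD[i] = dnW[i] * std::fabs(valsAbs(samp[mu + i] - 1, s));
                    }
                    dD = running_sum_dev(posD, wbD, N, &deg);
                }
                double v = dU - dD;
                sumAll += v;
                if (v > 0) { sumP += v; ++nP; }
                else if (v < 0) { sumN += v; ++nN; }
            }
            nullMean(l, s) = sumAll / nPerm;
            nullPos(l, s) = nP > 0 ? sumP / nP : NA_REAL;
            nullNeg(l, s) = nN > 0 ? sumN / nN : NA_REAL;
        }
    }
    return List::create(_["pre"] = pre, _["nullPosMean"] = nullPos,
                        _["nullNegMean"] = nullNeg, _["nullMean"] = nullMean);
}
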