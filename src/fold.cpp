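#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log(exp(a) + exp(b)) without overflow
static inline double logadd(double a, double b) {
    if (a == NEG_INF) return b;
    if (b == NEG_INF) return a;
    if (a < b) std::swap(a, b);
    return a + std::log1p(std::exp(b - a));
}

// Base-pairing probability matrix for the log-linear pair-weight model.
//
// Structures are nested pair sets generated by the unambiguous grammar
//   S(i,j) -> i unpaired, S(i+1,j)
//   S(i,j) -> pair (i,k),  S(i+1,k-1) S(k+1,j)
// with Boltzmann weight prod over pairs of exp(lw[a,b]).  Inside and
// outside quantities are accumulated in log space, so the computation is
// overflow-safe at any length; total cost is O(n^3).
//
// seq: 0-based nucleotide codes (A=0, C=1, G=2, U=3)
// lw:  4x4 matrix of log pair weights, -Inf for disallowed pairs
// minLoop: minimal number of unpaired bases enclosed by a pair (j - i > minLoop)
// [[Rcpp::export(name = ".fold_bppm")]]
NumericMatrix fold_bppm(IntegerVector seq, NumericMatrix lw, int minLoop) {
    const int n = seq.size();
    NumericMatrix P(n, n);
    if (n < 2) return P;

    std::vector<int> s(n + 1);
    for (int i = 1; i <= n; ++i) s[i] = seq[i - 1];

    // logZ indexed [i][j], 1 <= i <= n+1, 0 <= j <= n; empty span -> log 1 = 0
    std::vector<std::vector<double> > Z(n + 2, std::vector<double>(n + 1, 0.0));
    const double* lwp = lw.begin();
    auto W = [&](int i, int j) { return lwp[s[i] + 4 * s[j]]; };
    auto LZ = [&](int i, int j) { return (j < i) ? 0.0 : Z[i][j]; };

    for (int len = 1; len <= n; ++len) {
        for (int i = 1; i + len - 1 <= n; ++i) {
            const int j = i + len - 1;
            double v = LZ(i + 1, j);
            for (int k = i + minLoop + 1; k <= j; ++k) {
                const double w = W(i, k);
                if (w == NEG_INF) continue;
                v = logadd(v, w + LZ(i + 1, k - 1) + LZ(k + 1, j));
            }
            Z[i][j] = v;
        }
    }

    // outside: O[i][j] = log of the summed weight of all derivation contexts
    // of nonterminal S(i,j); computed from longer spans downward
    std::vector<std::vector<double> > O(n + 1, std::vector<double>(n + 1, NEG_INF));
    O[1][n] = 0.0;
    for (int len = n - 1; len >= 1; --len) {
        for (int i = 1; i + len - 1 <= n; ++i) {
            const int j = i + len - 1;
            if (i == 1 && j == n) continue;
            double acc = NEG_INF;
            if (i >= 2) {
                // parent S(i-1,j), position i-1 unpaired
                acc = logadd(acc, O[i - 1][j]);
                // left child of pair (i-1, j+1) in parent S(i-1, q), q >= j+1
                if (j + 1 <= n && (j + 1) - (i - 1) > minLoop) {
                    const double w = W(i - 1, j + 1);
                    if (w != NEG_INF) {
                        for (int q = j + 1; q <= n; ++q)
                            acc = logadd(acc, w + O[i - 1][q] + LZ(j + 2, q));
                    }
                }
            }
            // right child of pair (p, i-1) in parent S(p, j)
            for (int p = 1; p <= i - 2; ++p) {
                if ((i - 1) - p <= minLoop) continue;
                const double w = W(p, i - 1);
                if (w == NEG_INF) continue;
                acc = logadd(acc, w + O[p][j] + LZ(p + 1, i - 2));
            }
            O[i][j] = acc;
        }
    }

    const double logZtot = Z[1][n];
    for (int a = 1; a <= n; ++a) {
        for (int b = a + minLoop + 1; b <= n; ++b) {
            const double w = W(a, b);
            if (w == NEG_INF) continue;
            double ctx = NEG_INF;
            for (int q = b; q <= n; ++q)
                ctx = logadd(ctx, O[a][q] + LZ(b + 1, q));
            const double lp = w + LZ(a + 1, b - 1) + ctx - logZtot;
            P(a - 1, b - 1) = std::exp(lp);
        }
    }
    return P;
}
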