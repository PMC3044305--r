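#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logadd(double a, double b) {
    if (a == NEG_INF) return b;
    if (b == NEG_INF) return a;
    if (a < b) std::swap(a, b);
    return a + std::log1p(std::exp(b - a));
}

// log of the local alignment kernel K(x, y) = sum over all local
// alignments pi of exp(beta * Score(pi)).
//
// Direct transcription of the sum-product Smith-Waterman recurrences
// (states M, I_X, I_Y, T_X, T_Y; termination 1 + T_X + T_Y + M), carried
// out in log space so that K, which grows exponentially with sequence
// length, never overflows.  O(|x||y|) time.
//
// S: |x| x |y| position score matrix; g gap open, d gap extension.
// [[Rcpp::export(name = ".log_la_kernel")]]
double log_la_kernel(NumericMatrix S, double beta, double g, double d) {
    const int n = S.nrow(), m = S.ncol();
    if (n == 0 || m == 0) return 0.0;  // only the empty alignment: K = 1

    typedef std::vector<double> row;
    // (n+1) x (m+1) log-space DP tables; boundary cells hold log 0
    std::vector<row> M(n + 1, row(m + 1, NEG_INF));
    std::vector<row> IX(n + 1, row(m + 1, NEG_INF));
    std::vector<row> IY(n + 1, row(m + 1, NEG_INF));
    std::vector<row> TX(n + 1, row(m + 1, NEG_INF));
    std::vector<row> TY(n + 1, row(m + 1, NEG_INF));

    const double bg = beta * g, bd = beta * d;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double prev = logadd(0.0, M[i - 1][j - 1]);
            prev = logadd(prev, IX[i - 1][j - 1]);
            prev = logadd(prev, IY[i - 1][j - 1]);
            M[i][j] = beta * S(i - 1, j - 1) + prev;
            IX[i][j] = logadd(bg + M[i - 1][j], bd + IX[i - 1][j]);
            IY[i][j] = logadd(bg + logadd(M[i][j - 1], IX[i][j - 1]),
                              bd + IY[i][j - 1]);
            TX[i][j] = logadd(M[i - 1][j], TX[i - 1][j]);
            TY[i][j] = logadd(logadd(M[i][j - 1], TX[i][j - 1]), TY[i][j - 1]);
        }
    }
    double k = logadd(0.0, TX[n][m]);
    k = logadd(k, TY[n][m]);
    k = logadd(k, M[n][m]);
    return k;
}
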