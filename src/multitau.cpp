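#include <Rcpp.h>
#include <vector>

// Multi-tau correlator with symmetric normalization.
//
// Level 0 evaluates lags 1..2m in raw bin units; each further level halves
// the time resolution by pairwise averaging and evaluates lags (m+1)..2m in
// rebinned units. For every lag the estimator is
//   G(k) = [ <a_t b_{t+k}> - <a>_head <b>_tail ] / ( <a>_head <b>_tail )
// where the head/tail means are taken over the overlapping windows
// (symmetric normalization, which suppresses drift bias). Lag 0 is excluded:
// it is shot-noise dominated for photon counting data.

static void level_lags(const std::vector<double> &a,
                       const std::vector<double> &b,
                       int kmin, int kmax, double scale,
                       std::vector<double> &lags, std::vector<double> &g) {
    const long M = static_cast<long>(a.size());
    double tot_a = 0.0, tot_b = 0.0;
    for (long t = 0; t < M; ++t) { tot_a += a[t]; tot_b += b[t]; }
    double tail_a = 0.0; // sum of last k elements of a
    double head_b = 0.0; // sum of first k elements of b
    for (int k = 1; k <= kmax && k < M; ++k) {
        tail_a += a[M - k];
        head_b += b[k - 1];
        if (k < kmin) continue;
        const long n = M - k;
        double s = 0.0;
        const double *pa = a.data();
        const double *pb = b.data() + k;
        for (long t = 0; t < n; ++t) s += pa[t] * pb[t];
        const double ma = (tot_a - tail_a) / n;
        const double mb = (tot_b - head_b) / n;
        if (ma <= 0.0 || mb <= 0.0)
            Rcpp::stop("zero-mean channel: correlation undefined");
        lags.push_back(k * scale);
        g.push_back((s / n - ma * mb) / (ma * mb));
    }
}

static void rebin(std::vector<double> &x) {
    const long M = static_cast<long>(x.size()) / 2;
    for (long t = 0; t < M; ++t) x[t] = 0.5 * (x[2 * t] + x[2 * t + 1]);
    x.resize(M);
}

// [[Rcpp::export]]
Rcpp::List multitau_cpp(Rcpp::NumericVector a, Rcpp::NumericVector b,
                        int m, double bin_us) {
    if (a.size() != b.size()) Rcpp::stop("channel lengths differ");
    if (m < 1) Rcpp::stop("m must be positive");
    const long N = a.size();
    if (N < 4L * m) Rcpp::stop("trace too short for correlation");

    std::vector<double> va(a.begin(), a.end());
    std::vector<double> vb(b.begin(), b.end());
    std::vector<double> lags, g;

    level_lags(va, vb, 1, 2 * m, bin_us, lags, g);
    double scale = bin_us;
    while (static_cast<long>(va.size()) / 2 >= 4L * m) {
        rebin(va);
        rebin(vb);
        scale *= 2.0;
        level_lags(va, vb, m + 1, 2 * m, scale, lags, g);
    }

    return Rcpp::List::create(Rcpp::Named("lag_us") = Rcpp::wrap(lags),
                              Rcpp::Named("g") = Rcpp::wrap(g));
}
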