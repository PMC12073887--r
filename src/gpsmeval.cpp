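#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// index of ordered pair (i, j), 0-based, i < j, among the L*(L-1)/2 pairs
// enumerated as (0,1), (0,2), ..., (0,L-1), (1,2), ...
static inline int pidx(int i, int j, int L) {
    return i * L - i * (i + 1) / 2 + (j - i - 1);
}

// Fraction of identical positions for every sequence pair.
// gap_exclude: ignore columns where either row holds the gap code (= q);
// a pair with no comparable columns gets identity 0.
// [[Rcpp::export]]
NumericMatrix cpp_identity_matrix(IntegerMatrix codes, bool gap_exclude,
                                  int gap_code) {
    const int N = codes.nrow(), L = codes.ncol();
    NumericMatrix out(N, N);
    for (int a = 0; a < N; ++a) {
        out(a, a) = 1.0;
        for (int b = a + 1; b < N; ++b) {
            int m = 0, denom = 0;
            for (int c = 0; c < L; ++c) {
                int x = codes(a, c), y = codes(b, c);
                if (gap_exclude && (x == gap_code || y == gap_code)) continue;
                ++denom;
                if (x == y) ++m;
            }
            double f = gap_exclude ? (denom > 0 ? (double)m / denom : 0.0)
                                   : (double)m / L;
            out(a, b) = f;
            out(b, a) = f;
        }
    }
    return out;
}

// Unweighted bivariate counts: array (q, q, npair), counts of (a, b) at
// each ordered column pair i < j. Codes are 1-based.
// [[Rcpp::export]]
NumericVector cpp_pair_counts(IntegerMatrix codes, int q) {
    const int N = codes.nrow(), L = codes.ncol();
    const int npair = L * (L - 1) / 2;
    NumericVector out((R_xlen_t)q * q * npair);
    double *o = REAL(out);
    for (int i = 0; i < L; ++i) {
        for (int j = i + 1; j < L; ++j) {
            double *blk = o + (R_xlen_t)pidx(i, j, L) * q * q;
            for (int s = 0; s < N; ++s) {
                int a = codes(s, i) - 1, b = codes(s, j) - 1;
                blk[b * q + a] += 1.0;
            }
        }
    }
    out.attr("dim") = IntegerVector::create(q, q, npair);
    return out;
}

// Weighted bivariate marginals over an enumerated state table.
// [[Rcpp::export]]
NumericVector cpp_pair_counts_weighted(IntegerMatrix codes, NumericVector w,
                                       int q) {
    const int N = codes.nrow(), L = codes.ncol();
    const int npair = L * (L - 1) / 2;
    NumericVector out((R_xlen_t)q * q * npair);
    double *o = REAL(out);
    const double *wp = REAL(w);
    for (int i = 0; i < L; ++i) {
        for (int j = i + 1; j < L; ++j) {
            double *blk = o + (R_xlen_t)pidx(i, j, L) * q * q;
            for (int s = 0; s < N; ++s) {
                int a = codes(s, i) - 1, b = codes(s, j) - 1;
                blk[b * q + a] += wp[s];
            }
        }
    }
    out.attr("dim") = IntegerVector::create(q, q, npair);
    return out;
}

// Potts energy E(S) = sum_{i<j} J[s_i, s_j, (i,j)] + sum_i h[i, s_i].
// [[Rcpp::export]]
NumericVector cpp_energies(IntegerMatrix codes, NumericVector J,
                           Nullable<NumericMatrix> h_, int q) {
    const int N = codes.nrow(), L = codes.ncol();
    const double *Jp = REAL(J);
    const bool has_h = h_.isNotNull();
    NumericMatrix h = has_h ? NumericMatrix(h_) : NumericMatrix(0, 0);
    NumericVector out(N);
    for (int s = 0; s < N; ++s) {
        double e = 0.0;
        for (int i = 0; i < L; ++i) {
            int a = codes(s, i) - 1;
            for (int j = i + 1; j < L; ++j) {
                const double *blk = Jp + (R_xlen_t)pidx(i, j, L) * q * q;
                e += blk[(codes(s, j) - 1) * q + a];
            }
            if (has_h) e += h(i, a);
        }
        out[s] = e;
    }
    return out;
}

// Single-site Metropolis MCMC over P(S) propto exp(-E(S)). Each row of
// `init` is an independent chain advanced `nsweeps` full sweeps (sequential
// site updates, uniform state proposal). Uses R's RNG, so runs are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_sample_potts(IntegerMatrix init, NumericVector J,
                               Nullable<NumericMatrix> h_, int q,
                               int nsweeps) {
    IntegerMatrix codes = clone(init);
    const int N = codes.nrow(), L = codes.ncol();
    const double *Jp = REAL(J);
    const bool has_h = h_.isNotNull();
    NumericMatrix h = has_h ? NumericMatrix(h_) : NumericMatrix(0, 0);
    std::vector<int> s((size_t)L);
    for (int c = 0; c < N; ++c) {
        for (int i = 0; i < L; ++i) s[i] = codes(c, i) - 1;
        for (int sw = 0; sw < nsweeps; ++sw) {
            for (int i = 0; i < L; ++i) {
                int a = s[i];
                int b = (int)(unif_rand() * q);
                if (b >= q) b = q - 1;
                if (b == a) continue;
                double dE = 0.0;
                for (int j = 0; j < i; ++j) {
                    const double *blk = Jp + (R_xlen_t)pidx(j, i, L) * q * q;
                    dE += blk[b * q + s[j]] - blk[a * q + s[j]];
                }
                for (int j = i + 1; j < L; ++j) {
                    const double *blk = Jp + (R_xlen_t)pidx(i, j, L) * q * q;
                    dE += blk[s[j] * q + b] - blk[s[j] * q + a];
                }
                if (has_h) dE += h(i, b) - h(i, a);
                if (dE <= 0.0 || unif_rand() < std::exp(-dE)) s[i] = b;
            }
        }
        for (int i = 0; i < L; ++i) codes(c, i) = s[i] + 1;
        if ((c & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    return codes;
}

// Random-scan Metropolis: `nsteps` single-site update attempts per chain
// (site chosen uniformly each step). Sub-sweep granularity is needed to
// model small divergence, e.g. recently diverged cluster leaves.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_potts_steps(IntegerMatrix init, NumericVector J,
                                     Nullable<NumericMatrix> h_, int q,
                                     int nsteps) {
    IntegerMatrix codes = clone(init);
    const int N = codes.nrow(), L = codes.ncol();
    const double *Jp = REAL(J);
    const bool has_h = h_.isNotNull();
    NumericMatrix h = has_h ? NumericMatrix(h_) : NumericMatrix(0, 0);
    std::vector<int> s((size_t)L);
    for (int c = 0; c < N; ++c) {
        for (int i = 0; i < L; ++i) s[i] = codes(c, i) - 1;
        for (int st = 0; st < nsteps; ++st) {
            int i = (int)(unif_rand() * L);
            if (i >= L) i = L - 1;
            int a = s[i];
            int b = (int)(unif_rand() * q);
            if (b >= q) b = q - 1;
            if (b == a) continue;
            double dE = 0.0;
            for (int j = 0; j < i; ++j) {
                const double *blk = Jp + (R_xlen_t)pidx(j, i, L) * q * q;
                dE += blk[b * q + s[j]] - blk[a * q + s[j]];
            }
            for (int j = i + 1; j < L; ++j) {
                const double *blk = Jp + (R_xlen_t)pidx(i, j, L) * q * q;
                dE += blk[s[j] * q + b] - blk[s[j] * q + a];
            }
            if (has_h) dE += h(i, b) - h(i, a);
            if (dE <= 0.0 || unif_rand() < std::exp(-dE)) s[i] = b;
        }
        for (int i = 0; i < L; ++i) codes(c, i) = s[i] + 1;
        if ((c & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    return codes;
}
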