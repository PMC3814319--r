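#include <Rcpp.h>
using namespace Rcpp;

// Fisher-Yates shuffle of 0..n-1 using R's RNG (so set.seed() controls it)
static void shuffle_idx(std::vector<int> &idx) {
    int n = idx.size();
    for (int i = n - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(idx[i], idx[j]);
    }
}

//' Mantel permutation null distribution (internal C++ core)
//'
//' Computes z = sum_{i<j} A_ij * B_ij for the observed matrices and for
//' n_perm simultaneous row/column permutations of B.
//'
//' @noRd
// [[Rcpp::export(name = ".mantel_perm_cpp")]]
NumericVector mantel_perm_cpp(NumericMatrix A, NumericMatrix B, int n_perm) {
    int n = A.nrow();
    NumericVector z(n_perm + 1);
    double z0 = 0.0;
    for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j)
            z0 += A(i, j) * B(i, j);
    z[0] = z0;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    GetRNGstate();
    for (int p = 1; p <= n_perm; ++p) {
        shuffle_idx(idx);
        double zp = 0.0;
        for (int i = 0; i < n - 1; ++i) {
            int pi = idx[i];
            for (int j = i + 1; j < n; ++j)
                zp += A(i, j) * B(pi, idx[j]);
        }
        z[p] = zp;
    }
    PutRNGstate();
    return z;
}

//' Ewens sampling-formula configurations conditional on k (internal C++ core)
//'
//' Chinese-restaurant sequential construction at the supplied theta, with
//' rejection on the realised number of alleles. Returns the homozygosity
//' statistic F = sum((n_i/n)^2) for each accepted configuration.
//'
//' @noRd
// [[Rcpp::export(name = ".ewens_f_cpp")]]
NumericVector ewens_f_cpp(int n, int k, double theta, int n_sim,
                          double max_tries) {
    NumericVector out(n_sim);
    std::vector<double> tab;
    tab.reserve(n);
    GetRNGstate();
    double tries = 0.0;
    int got = 0;
    while (got < n_sim) {
        if (++tries > max_tries) {
            PutRNGstate();
            stop("Ewens rejection sampler acceptance rate below threshold; "
                 "use direct enumeration for this (n, k)");
        }
        tab.clear();
        tab.push_back(1.0);
        for (int i = 1; i < n; ++i) {
            double u = unif_rand() * (theta + i);
            if (u < theta) {
                tab.push_back(1.0);
            } else {
                // pick existing table proportional to its size
                double target = u - theta;  // uniform on (0, i)
                double acc = 0.0;
                size_t t = 0;
                for (; t < tab.size(); ++t) {
                    acc += tab[t];
                    if (target < acc) break;
                }
                if (t == tab.size()) t = tab.size() - 1;
                tab[t] += 1.0;
            }
            if ((int)tab.size() > k) break;  // table count never decreases
        }
        if ((int)tab.size() != k) continue;
        double F = 0.0;
        for (size_t t = 0; t < tab.size(); ++t) {
            double p = tab[t] / n;
            F += p * p;
        }
        out[got++] = F;
    }
    PutRNGstate();
    return out;
}
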