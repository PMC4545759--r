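#include <Rcpp.h>
using namespace Rcpp;

// Single-site Metropolis dynamics for the binary (FG=1 / BG=0) label field
// with boundary-only Gibbs coupling. The local log-probability of voxel n
// carrying label z is
//   -gamma * (# face neighbors with a different label)
//   - (x_n - mu_z)^2 / (2 sigma_z^2),
// neighbor pairs counted once (sum over m in M_n only); neighbors outside
// the grid are skipped (free boundary). mu/sigma index 0 = FG, 1 = BG.

static inline double loglik_term(double x, int z, const double *mu,
                                 const double *sigma) {
    double d = x - mu[z == 1 ? 0 : 1];
    double s = sigma[z == 1 ? 0 : 1];
    return -d * d / (2.0 * s * s);
}

static inline int discordant(const IntegerVector &lab, const int *dim,
                             int i, int j, int k, int z) {
    int n = 0;
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int idx = i + nx * (j + ny * k);
    if (i > 0      && lab[idx - 1]       != z) ++n;
    if (i < nx - 1 && lab[idx + 1]       != z) ++n;
    if (j > 0      && lab[idx - nx]      != z) ++n;
    if (j < ny - 1 && lab[idx + nx]      != z) ++n;
    if (k > 0      && lab[idx - nx * ny] != z) ++n;
    if (k < nz - 1 && lab[idx + nx * ny] != z) ++n;
    return n;
}

// One raster-scan sweep, updating labels in place sequentially.
// Returns the number of accepted flips.
static int sweep(const NumericVector &x, IntegerVector &lab, const int *dim,
                 const double *mu, const double *sigma, double gamma) {
    int accepted = 0;
    int idx = 0;
    for (int k = 0; k < dim[2]; ++k)
        for (int j = 0; j < dim[1]; ++j)
            for (int i = 0; i < dim[0]; ++i, ++idx) {
                const int z_old = lab[idx];
                const int z_new = 1 - z_old;
                const double dlog =
                    (-gamma * discordant(lab, dim, i, j, k, z_new)
                     + loglik_term(x[idx], z_new, mu, sigma))
                  - (-gamma * discordant(lab, dim, i, j, k, z_old)
                     + loglik_term(x[idx], z_old, mu, sigma));
                if (dlog >= 0.0 || unif_rand() < std::exp(dlog)) {
                    lab[idx] = z_new;
                    ++accepted;
                }
            }
    return accepted;
}

// [[Rcpp::export]]
List cpp_metropolis_sweep(NumericVector x, IntegerVector labels,
                          IntegerVector dims, NumericVector mu,
                          NumericVector sigma, double gamma) {
    IntegerVector lab = clone(labels);
    int acc = sweep(x, lab, INTEGER(dims), REAL(mu), REAL(sigma), gamma);
    return List::create(_["labels"] = lab, _["accepted"] = acc);
}

// [[Rcpp::export]]
List cpp_run_chain(NumericVector x, IntegerVector labels, IntegerVector dims,
                   NumericVector mu, NumericVector sigma, double gamma,
                   int burn_in, int L) {
    IntegerVector lab = clone(labels);
    const int n = lab.size();
    NumericVector avg(n);
    IntegerVector accepts(burn_in + L);
    for (int s = 0; s < burn_in; ++s)
        accepts[s] = sweep(x, lab, INTEGER(dims), REAL(mu), REAL(sigma), gamma);
    for (int l = 0; l < L; ++l) {
        accepts[burn_in + l] =
            sweep(x, lab, INTEGER(dims), REAL(mu), REAL(sigma), gamma);
        for (int i = 0; i < n; ++i) avg[i] += lab[i];
    }
    if (L > 0) for (int i = 0; i < n; ++i) avg[i] /= L;
    return List::create(_["average"] = avg, _["labels"] = lab,
                        _["accepted"] = accepts);
}

// Post-sweep states encoded as bit masks; for enumeration cross-checks on
// grids of at most 30 voxels.
// [[Rcpp::export]]
IntegerVector cpp_chain_states(NumericVector x, IntegerVector labels,
                               IntegerVector dims, NumericVector mu,
                               NumericVector sigma, double gamma,
                               int nsweeps) {
    IntegerVector lab = clone(labels);
    const int n = lab.size();
    if (n > 30) stop("state encoding supports at most 30 voxels");
    IntegerVector states(nsweeps);
    for (int s = 0; s < nsweeps; ++s) {
        sweep(x, lab, INTEGER(dims), REAL(mu), REAL(sigma), gamma);
        int code = 0;
        for (int i = 0; i < n; ++i) if (lab[i]) code |= (1 << i);
        states[s] = code;
    }
    return states;
}
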