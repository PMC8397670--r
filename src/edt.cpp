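#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared Euclidean distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. `h2` is the squared sample spacing so that
// anisotropic lattices are handled per axis.
static void dt1d(const double* f, double* d, int* v, double* z,
                 int n, double h2) {
    int k = 0;
    v[0] = 0;
    z[0] = -std::numeric_limits<double>::infinity();
    z[1] = std::numeric_limits<double>::infinity();
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            int p = v[k];
            s = ((f[q] + (double)q * q * h2) - (f[p] + (double)p * p * h2)) /
                (2.0 * h2 * (q - p));
            if (s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        double dq = (double)(q - v[k]);
        d[q] = dq * dq * h2 + f[v[k]];
    }
}

// Squared Euclidean distance (mm^2) from every voxel centre to the nearest
// voxel centre where `mask` is TRUE, on a regular lattice with per-axis
// spacing in mm. Voxels are stored in column-major (x fastest) order.
// Returns +Inf everywhere if the mask is empty.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");
    const double big = 1e300;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : big;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x
    double h2 = spacing[0] * spacing[0];
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
            for (int i = 0; i < nx; ++i) f[i] = out[base + i];
            dt1d(f.data(), d.data(), v.data(), z.data(), nx, h2);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    // pass along y
    h2 = spacing[1] * spacing[1];
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + i;
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
            dt1d(f.data(), d.data(), v.data(), z.data(), ny, h2);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
        }
    // pass along z
    h2 = spacing[2] * spacing[2];
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)j * nx + i;
            for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
            dt1d(f.data(), d.data(), v.data(), z.data(), nz, h2);
            for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = d[k];
        }
    for (R_xlen_t i = 0; i < n; ++i)
        if (out[i] >= 1e250) out[i] = R_PosInf;
    return out;
}
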