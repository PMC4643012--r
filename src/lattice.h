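#ifndef PATTERNEVENTS_LATTICE_H
#define PATTERNEVENTS_LATTICE_H

#include <Rcpp.h>

// boundary codes: 0 = no_flux (zero-gradient, mirrored ghost cells),
//                 1 = periodic
inline int pe_wrap(int i, int n) { return (i % n + n) % n; }
inline int pe_clamp(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }
inline int pe_fix(int i, int n, int bc) {
    return bc == 1 ? pe_wrap(i, n) : pe_clamp(i, n);
}

// five-point Laplacian at (i, j) of an nx x ny matrix stored column-major
inline double pe_lap5(const double* f, int i, int j, int nx, int ny,
                      double inv_dx2, int bc) {
    const int im = pe_fix(i - 1, nx, bc), ip = pe_fix(i + 1, nx, bc);
    const int jm = pe_fix(j - 1, ny, bc), jp = pe_fix(j + 1, ny, bc);
    const double c = f[i + nx * j];
    return (f[im + nx * j] + f[ip + nx * j] +
            f[i + nx * jm] + f[i + nx * jp] - 4.0 * c) * inv_dx2;
}

// equal-weight eight-point Laplacian: (sum of 8 neighbours - 8 * centre)/dx^2
inline double pe_lap8(const double* f, int i, int j, int nx, int ny,
                      double inv_dx2, int bc) {
    const int im = pe_fix(i - 1, nx, bc), ip = pe_fix(i + 1, nx, bc);
    const int jm = pe_fix(j - 1, ny, bc), jp = pe_fix(j + 1, ny, bc);
    const double c = f[i + nx * j];
    double s = f[im + nx * jm] + f[i + nx * jm] + f[ip + nx * jm] +
               f[im + nx * j]                   + f[ip + nx * j] +
               f[im + nx * jp] + f[i + nx * jp] + f[ip + nx * jp];
    return (s - 8.0 * c) * inv_dx2;
}

#endif
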