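#include <Rcpp.h>
#include "lattice.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix laplacian5Cpp(NumericMatrix f, double dx, int bc) {
    const int nx = f.nrow(), ny = f.ncol();
    const double inv_dx2 = 1.0 / (dx * dx);
    NumericMatrix out(nx, ny);
    const double* p = f.begin();
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
            out(i, j) = pe_lap5(p, i, j, nx, ny, inv_dx2, bc);
    return out;
}

// [[Rcpp::export]]
NumericMatrix laplacian8Cpp(NumericMatrix f, double dx, int bc) {
    const int nx = f.nrow(), ny = f.ncol();
    const double inv_dx2 = 1.0 / (dx * dx);
    NumericMatrix out(nx, ny);
    const double* p = f.begin();
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
            out(i, j) = pe_lap8(p, i, j, nx, ny, inv_dx2, bc);
    return out;
}
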