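#include <Rcpp.h>
#include "lattice.h"
using namespace Rcpp;

// Forward-Euler integration of the Schnakenberg activator-inhibitor system
//   du/dt = gamma (c1 - c_{-1} u + c3 u^2 v) + Du lap5(u)
//   dv/dt = gamma (c2 - c3 u^2 v)           + Dv lap5(v)
// Records u every record_every steps (initial state included).

// [[Rcpp::export]]
NumericVector schnakenbergSimCpp(NumericMatrix u0, NumericMatrix v0,
                                 double c1, double cm1, double c2, double c3,
                                 double gamma, double Du, double Dv,
                                 double dx, double dt,
                                 int n_steps, int record_every, int bc) {
    const int nx = u0.nrow(), ny = u0.ncol();
    const double inv_dx2 = 1.0 / (dx * dx);
    const int n_frames = n_steps / record_every + 1;
    NumericVector cube(static_cast<R_xlen_t>(nx) * ny * n_frames);

    std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
    std::vector<double> un(u.size()), vn(v.size());

    int frame = 0;
    for (int step = 0; step <= n_steps; ++step) {
        if (step % record_every == 0) {
            R_xlen_t off = static_cast<R_xlen_t>(frame) * nx * ny;
            for (size_t k = 0; k < u.size(); ++k) {
                if (!std::isfinite(u[k]))
                    stop("numerical blow-up at step %d", step);
                cube[off + k] = u[k];
            }
            ++frame;
        }
        if (step == n_steps) break;
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                const size_t k = i + static_cast<size_t>(nx) * j;
                const double uu = u[k], vv = v[k];
                const double uv2 = c3 * uu * uu * vv;
                un[k] = uu + dt * (gamma * (c1 - cm1 * uu + uv2) +
                                   Du * pe_lap5(u.data(), i, j, nx, ny, inv_dx2, bc));
                vn[k] = vv + dt * (gamma * (c2 - uv2) +
                                   Dv * pe_lap5(v.data(), i, j, nx, ny, inv_dx2, bc));
            }
        }
        u.swap(un);
        v.swap(vn);
    }
    cube.attr("dim") = IntegerVector::create(nx, ny, n_frames);
    return cube;
}
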