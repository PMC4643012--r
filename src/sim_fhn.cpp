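#include <Rcpp.h>
#include "lattice.h"
using namespace Rcpp;

// Diffusively coupled FitzHugh-Nagumo lattice
//   du/dt = (1/eps) ((a - u)(u - 1) u - v) + D lap5(u)
//   dv/dt = b u - gamma v + c_{ij}(t)
// Static mode: c_{ij} fixed (cmap).  Path mode: c_{ij}(t) =
// c0 tanh((t - t_c + dt_offset_{ij}) / T_c), refreshed every
// path_update_every steps (the path timescale T_c is slow compared
// with the integration step, so this introduces no visible error).

// [[Rcpp::export]]
NumericVector fhnSimCpp(NumericMatrix u0, NumericMatrix v0,
                        NumericMatrix cmap, bool path_mode,
                        NumericMatrix offsets,
                        double c0, double t_c, double T_c,
                        double a, double b, double gamma, double eps,
                        double D, double dx, double dt,
                        int n_steps, int record_every,
                        int path_update_every, int bc) {
    const int nx = u0.nrow(), ny = u0.ncol();
    const double inv_dx2 = 1.0 / (dx * dx);
    const double inv_eps = 1.0 / eps;
    const int n_frames = n_steps / record_every + 1;
    NumericVector cube(static_cast<R_xlen_t>(nx) * ny * n_frames);

    std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
    std::vector<double> un(u.size()), vn(v.size());
    std::vector<double> c(cmap.begin(), cmap.end());

    int frame = 0;
    for (int step = 0; step <= n_steps; ++step) {
        if (path_mode && (step % path_update_every == 0)) {
            const double t = step * dt;
            for (size_t k = 0; k < c.size(); ++k)
                c[k] = c0 * std::tanh((t - t_c + offsets[k]) / T_c);
        }
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
                un[k] = uu + dt * (inv_eps * ((a - uu) * (uu - 1.0) * uu - vv) +
                                   D * pe_lap5(u.data(), i, j, nx, ny, inv_dx2, bc));
                vn[k] = vv + dt * (b * uu - gamma * vv + c[k]);
            }
        }
        u.swap(un);
        v.swap(vn);
    }
    cube.attr("dim") = IntegerVector::create(nx, ny, n_frames);
    return cube;
}
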