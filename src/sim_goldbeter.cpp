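#include <Rcpp.h>
#include "lattice.h"
using namespace Rcpp;

// Reduced three-variable Martiel-Goldbeter cAMP relay model on a lattice:
//   drho/dt  = -f1(g) rho + f2(g)(1 - rho)
//   dbeta/dt = q sigma Phi(rho, g, alpha) - (k_i + k_t) beta
//   dg/dt    = k_t beta / h - k_e g + Dg lap5(g)
// with
//   f1 = (k1 + k2 g)/(1 + g),  f2 = (k1 L1 + k2 L2 c g)/(1 + c g),
//   Phi = alpha (lambda theta + eps Y^2) / (1 + alpha + eps Y^2 (1 + alpha)),
//   Y = rho g / (1 + g).
// Developmental path: per-site sigma and k_e follow shifted sigmoids of
// global time (shared time offset per site), refreshed every
// path_update_every steps.  States are clamped to their physical ranges
// (rho in [0,1]; beta, g >= 0) to absorb Euler overshoot.

// [[Rcpp::export]]
NumericVector goldbeterSimCpp(NumericMatrix rho0, NumericMatrix beta0,
                              NumericMatrix g0, NumericMatrix offsets,
                              double k1, double k2, double L1, double L2,
                              double cc, double q, double ki, double kt,
                              double h, double lambda, double theta,
                              double epsY, double alpha,
                              double sigma_av, double sigma_amp,
                              double t_sigma, double T_sigma,
                              double k_av, double k_amp,
                              double t_k, double T_k,
                              double Dg, double dx, double dt,
                              int n_steps, int record_every,
                              int path_update_every, int bc) {
    const int nx = rho0.nrow(), ny = rho0.ncol();
    const size_t n = static_cast<size_t>(nx) * ny;
    const double inv_dx2 = 1.0 / (dx * dx);
    const int n_frames = n_steps / record_every + 1;
    NumericVector cube(static_cast<R_xlen_t>(n) * n_frames);

    std::vector<double> rho(rho0.begin(), rho0.end());
    std::vector<double> be(beta0.begin(), beta0.end());
    std::vector<double> ga(g0.begin(), g0.end());
    std::vector<double> rn(n), bn(n), gn(n);
    std::vector<double> sig(n), ke(n);

    int frame = 0;
    for (int step = 0; step <= n_steps; ++step) {
        if (step % path_update_every == 0) {
            const double t = step * dt;
            for (size_t k = 0; k < n; ++k) {
                sig[k] = sigma_av +
                    sigma_amp * std::tanh((t - t_sigma + offsets[k]) / T_sigma);
                ke[k] = k_av +
                    k_amp * std::tanh((t - t_k + offsets[k]) / T_k);
            }
        }
        if (step % record_every == 0) {
            R_xlen_t off = static_cast<R_xlen_t>(frame) * n;
            for (size_t k = 0; k < n; ++k) {
                if (!std::isfinite(ga[k]))
                    stop("numerical blow-up at step %d", step);
                cube[off + k] = ga[k];
            }
            ++frame;
        }
        if (step == n_steps) break;
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                const size_t k = i + static_cast<size_t>(nx) * j;
                const double g = ga[k], r = rho[k], b = be[k];
                const double f1 = (k1 + k2 * g) / (1.0 + g);
                const double f2 = (k1 * L1 + k2 * L2 * cc * g) / (1.0 + cc * g);
                const double Y = r * g / (1.0 + g);
                const double eY2 = epsY * Y * Y;
                const double phi = alpha * (lambda * theta + eY2) /
                    (1.0 + alpha + eY2 * (1.0 + alpha));
                rn[k] = r + dt * (-f1 * r + f2 * (1.0 - r));
                bn[k] = b + dt * (q * sig[k] * phi - (ki + kt) * b);
                gn[k] = g + dt * (kt * b / h - ke[k] * g +
                        Dg * pe_lap5(ga.data(), i, j, nx, ny, inv_dx2, bc));
                if (rn[k] < 0.0) rn[k] = 0.0; else if (rn[k] > 1.0) rn[k] = 1.0;
                if (bn[k] < 0.0) bn[k] = 0.0;
                if (gn[k] < 0.0) gn[k] = 0.0;
            }
        }
        rho.swap(rn);
        be.swap(bn);
        ga.swap(gn);
    }
    cube.attr("dim") = IntegerVector::create(nx, ny, n_frames);
    return cube;
}
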