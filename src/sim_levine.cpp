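#include <Rcpp.h>
#include "lattice.h"
using namespace Rcpp;

// Hybrid cellular-automaton/ODE model of Dictyostelium cAMP signalling.
// Continuous fields (extracellular cAMP c, excitability E):
//   dc/dt = -Gamma c + r_F s + D lap8(c)
//   dE/dt = eta + beta c                (capped at e_max)
// Discrete per-cell phase machine:
//   ready -> firing -> absolute refractory (T_ARP) ->
//   relative refractory (T_RRP) -> ready
// A ready or relative-refractory cell fires when c exceeds the threshold
//   t(tau) = [c_max - A tau / (tau + T_ARP)] (1 - E),
//   A = (T_RRP + T_ARP)(c_max - c_min)/T_RRP,
// with tau = T_RRP for the ready state.  Pacemakers in the ready state fire
// spontaneously with probability p_F per step.  Pacemaker mask codes:
// 0 = ordinary cell, 1 = fixed pacemaker, 2 = extra (random) pacemaker that
// stays silent for the first extra_disable_steps steps (time advantage of
// the fixed set).

// [[Rcpp::export]]
List levineSimCpp(IntegerMatrix pm,
                  double Gamma, double r_F, double D,
                  double eta, double beta, double e_max,
                  double c_max, double c_min,
                  double T_ARP, double T_RRP,
                  double firing_duration, double p_F, double E0,
                  double dx, double dt, int n_steps, int record_every,
                  int extra_disable_steps, int bc) {
    const int nx = pm.nrow(), ny = pm.ncol();
    const size_t n = static_cast<size_t>(nx) * ny;
    const double inv_dx2 = 1.0 / (dx * dx);
    const double A = (T_RRP + T_ARP) * (c_max - c_min) / T_RRP;
    const int n_frames = n_steps / record_every + 1;
    NumericVector cube(static_cast<R_xlen_t>(n) * n_frames);

    std::vector<double> c(n, 0.0), cn(n), E(n, E0), tau(n, 0.0);
    std::vector<int> phase(n, 0);   // 0 ready, 1 firing, 2 ARP, 3 RRP
    std::vector<double> s(n, 0.0);  // firing indicator

    int frame = 0;
    for (int step = 0; step <= n_steps; ++step) {
        if (step % record_every == 0) {
            R_xlen_t off = static_cast<R_xlen_t>(frame) * n;
            for (size_t k = 0; k < n; ++k) {
                if (!std::isfinite(c[k]))
                    stop("numerical blow-up at step %d", step);
                cube[off + k] = c[k];
            }
            ++frame;
        }
        if (step == n_steps) break;

        // 1. cell phase machine + firing decisions on the current field
        for (size_t k = 0; k < n; ++k) {
            switch (phase[k]) {
            case 1:
                tau[k] += dt;
                if (tau[k] >= firing_duration) { phase[k] = 2; tau[k] = 0.0; }
                break;
            case 2:
                tau[k] += dt;
                if (tau[k] >= T_ARP) { phase[k] = 3; tau[k] = 0.0; }
                break;
            case 3: {
                tau[k] += dt;
                if (tau[k] >= T_RRP) { phase[k] = 0; tau[k] = 0.0; break; }
                const double thr =
                    (c_max - A * tau[k] / (tau[k] + T_ARP)) * (1.0 - E[k]);
                if (c[k] > thr) { phase[k] = 1; tau[k] = 0.0; }
                break;
            }
            default: {  // ready: threshold at its floor c_min (1 - E)
                const double thr = c_min * (1.0 - E[k]);
                bool fire = c[k] > thr;
                if (!fire && pm[k] != 0 && p_F > 0.0) {
                    const bool active =
                        pm[k] == 1 || step >= extra_disable_steps;
                    if (active && unif_rand() < p_F) fire = true;
                }
                if (fire) { phase[k] = 1; tau[k] = 0.0; }
            }
            }
            s[k] = (phase[k] == 1) ? 1.0 : 0.0;
        }

        // 2. Euler step of the cAMP field (8-point Laplacian) and E
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                const size_t k = i + static_cast<size_t>(nx) * j;
                cn[k] = c[k] + dt * (-Gamma * c[k] + r_F * s[k] +
                        D * pe_lap8(c.data(), i, j, nx, ny, inv_dx2, bc));
            }
        }
        for (size_t k = 0; k < n; ++k) {
            E[k] += (eta + beta * c[k]) * dt;
            if (E[k] > e_max) E[k] = e_max;
        }
        c.swap(cn);
    }
    cube.attr("dim") = IntegerVector::create(nx, ny, n_frames);
    NumericMatrix Eout(nx, ny);
    std::copy(E.begin(), E.end(), Eout.begin());
    return List::create(_["cube"] = cube, _["E"] = Eout);
}
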