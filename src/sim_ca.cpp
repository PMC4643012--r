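#include <Rcpp.h>
using namespace Rcpp;

// Internal state coding for the deterministic automaton:
//   0            susceptible S
//   1            excited E
//   k in 2..r+1  refractory R with (k - 1) steps of refractoriness remaining
//
// Neighbours outside the lattice do not exist (no excitation enters through
// the boundary).

static inline bool excited_neighbor(const IntegerMatrix& g, int i, int j) {
    const int nx = g.nrow(), ny = g.ncol();
    if (i > 0      && g(i - 1, j) == 1) return true;
    if (i < nx - 1 && g(i + 1, j) == 1) return true;
    if (j > 0      && g(i, j - 1) == 1) return true;
    if (j < ny - 1 && g(i, j + 1) == 1) return true;
    return false;
}

// [[Rcpp::export]]
IntegerMatrix caStepCpp(IntegerMatrix g, int r) {
    const int nx = g.nrow(), ny = g.ncol();
    IntegerMatrix out(nx, ny);
    for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
            const int s = g(i, j);
            if (s == 0) {
                out(i, j) = excited_neighbor(g, i, j) ? 1 : 0;
            } else if (s == 1) {
                out(i, j) = r + 1;       // enter R with r steps remaining
            } else {
                out(i, j) = (s == 2) ? 0 : s - 1;
            }
        }
    }
    return out;
}

// Stochastic variant: codes 0 = S, 1 = E, 2 = R (no refractory clock).
// S -> E if an excited neighbour exists, otherwise with probability f;
// E -> R; R -> S with probability p per step.  Uses R's RNG so runs are
// reproducible under set.seed().

// [[Rcpp::export]]
IntegerMatrix caStepStochasticCpp(IntegerMatrix g, double f, double p) {
    const int nx = g.nrow(), ny = g.ncol();
    IntegerMatrix out(nx, ny);
    for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
            const int s = g(i, j);
            if (s == 0) {
                if (excited_neighbor(g, i, j)) {
                    out(i, j) = 1;
                } else {
                    out(i, j) = (f > 0.0 && unif_rand() < f) ? 1 : 0;
                }
            } else if (s == 1) {
                out(i, j) = 2;
            } else {
                out(i, j) = (p > 0.0 && unif_rand() < p) ? 0 : 2;
            }
        }
    }
    return out;
}

// Full deterministic run recording collapsed codes (S = 0, E = 1, R = 2)
// every record_every steps, the initial state included.

// [[Rcpp::export]]
IntegerVector caSimulateCpp(IntegerMatrix g0, int r, int n_steps,
                            int record_every) {
    const int nx = g0.nrow(), ny = g0.ncol();
    const int n_frames = n_steps / record_every + 1;
    IntegerVector cube(static_cast<R_xlen_t>(nx) * ny * n_frames);
    IntegerMatrix g = clone(g0);
    int frame = 0;
    for (int step = 0; step <= n_steps; ++step) {
        if (step % record_every == 0) {
            R_xlen_t off = static_cast<R_xlen_t>(frame) * nx * ny;
            for (int j = 0; j < ny; ++j)
                for (int i = 0; i < nx; ++i) {
                    const int s = g(i, j);
                    cube[off + i + static_cast<R_xlen_t>(nx) * j] =
                        (s <= 1) ? s : 2;
                }
            ++frame;
        }
        if (step < n_steps) g = caStepCpp(g, r);
    }
    cube.attr("dim") = IntegerVector::create(nx, ny, n_frames);
    return cube;
}
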