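#include <Rcpp.h>
using namespace Rcpp;

// Polar ("modified") Box-Muller: standard normal variates from uniform
// pairs without trigonometric calls. Uses R's RNG so set.seed() governs
// reproducibility. One draw of the pair is kept per acceptance; the spare
// variate is carried over to the next request.
static double polar_gauss(bool &have_spare, double &spare) {
  if (have_spare) {
    have_spare = false;
    return spare;
  }
  double u, v, s;
  do {
    u = 2.0 * unif_rand() - 1.0;
    v = 2.0 * unif_rand() - 1.0;
    s = u * u + v * v;
  } while (s >= 1.0 || s == 0.0);
  double f = std::sqrt(-2.0 * std::log(s) / s);
  spare = v * f;
  have_spare = true;
  return u * f;
}

// [[Rcpp::export(name = ".polar_gaussians")]]
NumericVector polar_gaussians(int n, double sigma) {
  NumericVector out(n);
  if (sigma == 0.0) return out;
  bool have_spare = false;
  double spare = 0.0;
  for (int i = 0; i < n; ++i)
    out[i] = sigma * polar_gauss(have_spare, spare);
  return out;
}

// Sub-stepped Brownian walk of particles inside fenestration channels.
//
// Each particle in a pore performs n_sub sub-steps of an isotropic Gaussian
// walk with per-axis standard deviation sigma (nm). The channel is a
// cylinder of accessible radius rho_max (pore radius - particle radius)
// and length chan_len along the radial (depth) axis. Lateral excursions
// reflect specularly at rho_max; crossing depth >= chan_len means the
// particle has translocated (absorbing); depth < 0 returns it to the lumen.
//
// state: matrix with one row per in-pore particle:
//   col 0 depth (nm), col 1 lateral a (nm), col 2 lateral b (nm)
// Returns an integer outcome per particle: 0 in_transit, 1 translocated,
// 2 returned; `state` is updated in place for in-transit particles.
// [[Rcpp::export(name = ".pore_walk_cpp")]]
IntegerVector pore_walk_cpp(NumericMatrix state, NumericVector sigma,
                            NumericVector rho_max, double chan_len,
                            int n_sub) {
  int np = state.nrow();
  IntegerVector outcome(np);
  bool have_spare = false;
  double spare = 0.0;
  for (int i = 0; i < np; ++i) {
    double x = state(i, 0), a = state(i, 1), b = state(i, 2);
    double sg = sigma[i], rm = rho_max[i];
    int res = 0;
    for (int s = 0; s < n_sub; ++s) {
      x += sg * polar_gauss(have_spare, spare);
      a += sg * polar_gauss(have_spare, spare);
      b += sg * polar_gauss(have_spare, spare);
      double rho = std::sqrt(a * a + b * b);
      if (rho > rm && rho > 0.0) {
        // specular mirror about the cylinder rho = rm (single fold)
        double rho_new = 2.0 * rm - rho;
        if (rho_new < 0.0) rho_new = 0.0;
        double f = rho_new / rho;
        a *= f;
        b *= f;
      }
      if (x >= chan_len) { res = 1; break; }
      if (x < 0.0)       { res = 2; break; }
    }
    outcome[i] = res;
    state(i, 0) = x;
    state(i, 1) = a;
    state(i, 2) = b;
  }
  return outcome;
}
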