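#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reflect a coordinate into [-h, h].
static inline double reflect1(double x, double h) {
  while (x > h || x < -h) {
    if (x > h) x = 2.0 * h - x;
    if (x < -h) x = -2.0 * h - x;
  }
  return x;
}

// Wrap a coordinate into [-h, h) (periodic box of length 2h).
static inline double wrap1(double x, double h) {
  double L = 2.0 * h;
  return x - L * std::floor((x + h) / L) - h;
}

// Fused Brownian walk + PSF-weighted Poisson photon emission for a single
// molecule. Coordinates are relative to the box/PSF centre (um). The FRET
// efficiency is a right-continuous step function of the step index:
// segment s applies from step eff_start_step[s] (inclusive) until the next
// segment starts. Uses R's RNG so results are set.seed()-reproducible.
//
// Photon timestamps are the (0-based) step index of the emitting step;
// channel is 1 = donor, 2 = acceptor. When the PSF exponent exceeds ~30
// the emission intensity is below ~1e-13 of peak and the Poisson draw is
// skipped for speed (the draw would return 0 with overwhelming probability,
// and the skip is itself deterministic given the trajectory).
// [[Rcpp::export]]
List cpp_diffuse_emit(NumericVector pos0, int n_steps, double dt,
                      NumericVector box_len, int periodic,
                      NumericVector psf_sigma, double max_rate, double d_b,
                      NumericVector eff_values, NumericVector eff_start_step,
                      bool record_positions) {
  double x = pos0[0], y = pos0[1], z = pos0[2];
  const double hx = box_len[0] / 2.0, hy = box_len[1] / 2.0,
               hz = box_len[2] / 2.0;
  const double sd = std::sqrt(2.0 * d_b * dt);
  const double isx = 1.0 / (2.0 * psf_sigma[0] * psf_sigma[0]);
  const double isy = 1.0 / (2.0 * psf_sigma[1] * psf_sigma[1]);
  const double isz = 1.0 / (2.0 * psf_sigma[2] * psf_sigma[2]);
  const double rate_dt = max_rate * dt;

  std::vector<double> ticks;
  std::vector<int> chan;
  NumericMatrix pos;
  if (record_positions) pos = NumericMatrix(n_steps, 3);

  int seg = 0;
  const int nseg = eff_values.size();

  for (int i = 0; i < n_steps; ++i) {
    if (sd > 0) {
      x += sd * norm_rand();
      y += sd * norm_rand();
      z += sd * norm_rand();
      if (periodic) {
        x = wrap1(x, hx); y = wrap1(y, hy); z = wrap1(z, hz);
      } else {
        x = reflect1(x, hx); y = reflect1(y, hy); z = reflect1(z, hz);
      }
    }
    if (record_positions) {
      pos(i, 0) = x; pos(i, 1) = y; pos(i, 2) = z;
    }
    while (seg + 1 < nseg && eff_start_step[seg + 1] <= i) ++seg;
    if (rate_dt > 0) {
      double q = x * x * isx + y * y * isy + z * z * isz;
      if (q < 30.0) {
        double lam = rate_dt * std::exp(-q);
        int k = (int) R::rpois(lam);
        if (k > 0) {
          double e = eff_values[seg];
          for (int j = 0; j < k; ++j) {
            ticks.push_back((double) i);
            chan.push_back(unif_rand() < e ? 2 : 1);
          }
        }
      }
    }
  }

  List out = List::create(
    _["tick"] = NumericVector(ticks.begin(), ticks.end()),
    _["channel"] = IntegerVector(chan.begin(), chan.end()),
    _["final_pos"] = NumericVector::create(x, y, z));
  if (record_positions) out["positions"] = pos;
  return out;
}

// Euler-Maruyama propagation of the overdamped Langevin equation
//   r <- r - beta * D_L * V'(r) * dt_sub + N(0, 2 * D_L * dt_sub)
// on a harmonic (kind 0) or bistable (kind 1) landscape. Each of the
// n_steps retained samples is separated by `substeps` fine steps of
// dt_sub nanoseconds. Returns the retained samples (excluding r0).
// [[Rcpp::export]]
NumericVector cpp_langevin_em(double r0, int n_steps, int substeps,
                              double dt_sub, double beta, double d_l,
                              int kind, double k, double center, double w) {
  NumericVector out(n_steps);
  const double drift = beta * d_l * dt_sub;
  const double sd = std::sqrt(2.0 * d_l * dt_sub);
  double r = r0;
  for (int i = 0; i < n_steps; ++i) {
    for (int s = 0; s < substeps; ++s) {
      double dr = r - center;
      double g = (kind == 0) ? k * dr : k * (dr * dr - w * w) * dr;
      r += -drift * g + sd * norm_rand();
    }
    if (!std::isfinite(r))
      stop("Langevin integration overflowed at step %d: the update is "
           "numerically unstable (reduce the step or the stiffness bound)",
           i + 1);
    out[i] = r;
  }
  return out;
}
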