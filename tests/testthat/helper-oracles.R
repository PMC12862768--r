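# Shared oracles and memoized simulations for the test suite.
# Heavy simulations are computed once per session and reused across
# test files.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Example-2 discrete switching dataset, two minutes of trace on a 2-us
# engine step. 45 molecules reproduce the reference dataset's
# burst-region density (~26 regions/s), the statistic that controls
# molecule-coincidence effects in burst and HMM analyses.
switching_sim <- function() cached("switching_sim", {
  sc <- builtin_scenario("example2_switching", n_molecules = 45,
                         engine_dt = 2e-6, seed = 401L)
  sc$duration <- 120
  simulate_experiment(sc)
})

# Fixed-efficiency single-state dataset (Example 1 conditions), 400
# molecule-seconds.
fixed_sim <- function() cached("fixed_sim", {
  sc <- builtin_scenario("example1_fixed", n_molecules = 40,
                         engine_dt = 2e-6, seed = 402L)
  sc$duration <- 10
  simulate_experiment(sc)
})

# Langevin single-state dataset (Example 1 conditions).
langevin_sim <- function() cached("langevin_sim", {
  sc <- builtin_scenario("example1_langevin", n_molecules = 40,
                         engine_dt = 2e-6, seed = 403L)
  sc$duration <- 10
  simulate_experiment(sc)
})

# Numeric CDF of a landscape's Boltzmann density, for KS tests.
boltzmann_cdf <- function(landscape, thermo, n_grid = 8192L) {
  sup <- smfretsim:::boltzmann_support(landscape, thermo)
  g <- seq(sup[1], sup[2], length.out = n_grid)
  d <- boltzmann_density(landscape, thermo, g)
  cdf <- smfretsim:::cumtrapz(g, d)
  cdf <- cdf / cdf[length(cdf)]
  approxfun(g, cdf, yleft = 0, yright = 1)
}

# Brute-force run-length oracle for burst regions over a logical mask.
runs_oracle <- function(mask) {
  out <- list()
  i <- 1L
  while (i <= length(mask)) {
    if (mask[i]) {
      j <- i
      while (j < length(mask) && mask[j + 1L]) j <- j + 1L
      out[[length(out) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Construct a binned_trace directly from count vectors (test scaffold).
make_trace <- function(donor, acceptor, bin_width = 1e-3) {
  combined <- donor + acceptor
  out <- data.frame(bin = seq_along(donor) - 1L, donor = donor,
                    acceptor = acceptor, combined = combined,
                    efficiency = ifelse(combined > 0,
                                        acceptor / pmax(combined, 1),
                                        NA_real_))
  attr(out, "bin_width") <- bin_width
  class(out) <- c("binned_trace", "data.frame")
  out
}

# Poisson stream at a constant rate (ticks on a dt clock).
constant_rate_stream <- function(rate, duration, dt = 1e-6, E = 0.5,
                                 seed = 1L) {
  set.seed(seed)
  n <- rpois(1L, rate * duration)
  ticks <- sort(floor(runif(n, 0, duration / dt)))
  photon_stream(ticks, ifelse(runif(n) < E, 2L, 1L), 1L, tick = dt)
}
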