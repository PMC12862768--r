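#' Langevin integrator configuration
#'
#' Settings for propagating the dye--dye distance by overdamped Langevin
#' dynamics,
#' \deqn{r(t+\delta t) = r(t) - \beta D_L V'(r)\,\delta t + \xi, \quad
#'   \xi \sim N(0, 2 D_L \delta t).}
#' The naive Euler--Maruyama update is unstable when the dimensionless
#' stiffness \eqn{\beta D_L |V''| \delta t} exceeds O(1) -- the shipped
#' single-state condition has stiffness ~2000 at its stated 50-ns step.
#' The `exact_ou` integrator therefore uses the exact Ornstein--Uhlenbeck
#' transition density (harmonic landscapes only, exact at any step), and
#' `substepped` subdivides the step until the stiffness is below
#' `max_stability`. `auto` picks `exact_ou` for harmonic landscapes and
#' `substepped` otherwise.
#'
#' @param D_conf conformational diffusion coefficient, A^2/ns; > 0.
#' @param dt retained time step, ns; > 0.
#' @param thermo a [thermo_state()].
#' @param integrator one of `"auto"`, `"exact_ou"`, `"euler_maruyama"`,
#'   `"substepped"`.
#' @param max_stability stiffness bound for substepping, in (0, 2).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return an object of class `langevin_config`.
#' @export
langevin_config <- function(D_conf, dt, thermo,
                            integrator = c("auto", "exact_ou",
                                           "euler_maruyama", "substepped"),
                            max_stability = 0.1, seed = NULL) {
  stopifnot_scalar(D_conf, "D_conf", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot(inherits(thermo, "thermo_state"))
  stopifnot_scalar(max_stability, "max_stability", positive = TRUE)
  if (max_stability >= 2) stop("`max_stability` must be in (0, 2)")
  structure(list(D_conf = D_conf, dt = dt, thermo = thermo,
                 integrator = match.arg(integrator),
                 max_stability = max_stability, seed = seed),
            class = "langevin_config")
}

resolve_integrator <- function(landscape, config) {
  integ <- config$integrator
  if (integ == "auto")
    integ <- if (landscape$kind == "harmonic") "exact_ou" else "substepped"
  if (integ == "exact_ou" && landscape$kind != "harmonic")
    stop("the exact OU integrator applies to harmonic landscapes only")
  integ
}

# Number of Euler-Maruyama substeps needed to respect the stiffness bound.
n_substeps <- function(landscape, config) {
  stiff <- config$thermo$beta * config$D_conf * max_curvature(landscape) *
    config$dt
  max(1L, as.integer(ceiling(stiff / config$max_stability)))
}

new_distance_trajectory <- function(times, distances, molecule_id) {
  if (length(times) != length(distances))
    stop("times and distances must have equal length")
  if (any(!is.finite(distances)))
    stop("distances must be finite")
  structure(list(times = times, distances = distances,
                 molecule_id = as.integer(molecule_id)),
            class = "distance_trajectory")
}

#' @export
print.distance_trajectory <- function(x, ...) {
  cat(sprintf("<distance trajectory: molecule %d, %d samples, %.3g s>\n",
              x$molecule_id, length(x$times),
              if (length(x$times)) diff(range(x$times)) else 0))
  invisible(x)
}

#' Propagate overdamped Langevin dynamics
#'
#' Generates a dye--dye distance trajectory on a landscape, retaining a
#' sample every `config$dt` nanoseconds (including the initial point at
#' t = 0). Harmonic landscapes may use the exact OU update; all other
#' kinds use (sub-stepped) Euler--Maruyama. Deterministic given
#' `config$seed`.
#'
#' @param landscape a free-energy landscape (see [harmonic_landscape()]).
#' @param config a [langevin_config()].
#' @param r0 initial distance, A.
#' @param n_steps number of retained steps.
#' @param molecule_id integer identifier stored with the trajectory.
#' @return a `distance_trajectory`: times (s), distances (A).
#' @export
propagate_langevin <- function(landscape, config, r0, n_steps,
                               molecule_id = 1L) {
  stopifnot(inherits(landscape, "fel"), inherits(config, "langevin_config"))
  stopifnot_scalar(r0, "r0")
  n_steps <- as.integer(n_steps)
  if (!is.null(config$seed)) set.seed(config$seed)
  r <- langevin_samples(landscape, config, r0, n_steps)
  new_distance_trajectory(ns_to_s(config$dt) * (0:n_steps), c(r0, r),
                          molecule_id)
}

# Core sampler: returns the n_steps retained samples after r0 (no times).
langevin_samples <- function(landscape, config, r0, n_steps) {
  integ <- resolve_integrator(landscape, config)
  beta <- config$thermo$beta
  if (integ == "exact_ou") {
    theta <- beta * config$D_conf * landscape$k_harmonic     # 1/ns
    a <- exp(-theta * config$dt)
    sd_stat <- sqrt(1 / (beta * landscape$k_harmonic))
    innov <- rnorm(n_steps, sd = sd_stat * sqrt(1 - a^2))
    as.numeric(stats::filter(innov, a, method = "recursive",
                             init = r0 - landscape$center)) +
      landscape$center
  } else {
    sub <- if (integ == "substepped") n_substeps(landscape, config) else 1L
    stiff <- beta * config$D_conf * max_curvature(landscape) * config$dt / sub
    if (stiff > 2)
      stop(sprintf(
        "Euler-Maruyama update is unstable: stiffness beta*D*|V''|*dt = %.3g > 2; use integrator = 'substepped' or 'exact_ou'",
        stiff))
    if (landscape$kind == "tabulated") {
      langevin_em_r(landscape, config, r0, n_steps, sub)
    } else {
      kind <- if (landscape$kind == "harmonic") 0L else 1L
      k <- if (kind == 0L) landscape$k_harmonic else landscape$k_bistable
      w <- if (kind == 0L) 0 else landscape$well_offset
      cpp_langevin_em(r0, n_steps, sub, config$dt / sub, beta,
                      config$D_conf, kind, k, landscape$center, w)
    }
  }
}

# R fallback for tabulated landscapes (gradient needs interpolation).
langevin_em_r <- function(landscape, config, r0, n_steps, substeps) {
  dt_sub <- config$dt / substeps
  drift <- config$thermo$beta * config$D_conf * dt_sub
  sdn <- sqrt(2 * config$D_conf * dt_sub)
  out <- numeric(n_steps)
  r <- r0
  g <- landscape$grid
  for (i in seq_len(n_steps)) {
    for (s in seq_len(substeps)) {
      r <- r - drift * evaluate_gradient(landscape, r) + rnorm(1, sd = sdn)
      r <- min(max(r, g[1]), g[length(g)])   # clamp to tabulated support
    }
    if (!is.finite(r))
      stop("Langevin integration overflowed (stiffness too high)")
    out[i] <- r
  }
  out
}

#' Propagate an ensemble of independent Langevin walkers
#'
#' Vectorized Euler--Maruyama (or exact OU) propagation of many walkers
#' at once; used for stationary-distribution checks where a large number
#' of independent samples is needed quickly.
#'
#' @inheritParams propagate_langevin
#' @param r0 numeric vector of initial distances (one walker each).
#' @return numeric vector of final distances after `n_steps` steps.
#' @export
propagate_langevin_ensemble <- function(landscape, config, r0, n_steps) {
  stopifnot(inherits(landscape, "fel"), inherits(config, "langevin_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  integ <- resolve_integrator(landscape, config)
  beta <- config$thermo$beta
  n <- length(r0)
  if (integ == "exact_ou") {
    theta <- beta * config$D_conf * landscape$k_harmonic
    a <- exp(-theta * config$dt)
    sd_step <- sqrt((1 - a^2) / (beta * landscape$k_harmonic))
    x <- r0 - landscape$center
    for (i in seq_len(n_steps)) x <- a * x + rnorm(n, sd = sd_step)
    return(x + landscape$center)
  }
  sub <- if (integ == "substepped") n_substeps(landscape, config) else 1L
  dt_sub <- config$dt / sub
  drift <- beta * config$D_conf * dt_sub
  sdn <- sqrt(2 * config$D_conf * dt_sub)
  r <- r0
  for (i in seq_len(n_steps * sub)) {
    r <- r - drift * evaluate_gradient(landscape, r) + rnorm(n, sd = sdn)
  }
  if (any(!is.finite(r)))
    stop("Langevin ensemble overflowed (stiffness too high)")
  r
}

#' Draw initial distances from the Boltzmann density
#'
#' Inverse-CDF sampling on a dense grid of the landscape's Boltzmann
#' density; used to initialize molecules at equilibrium.
#'
#' @inheritParams partition_function
#' @param n number of draws.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param grid_n grid resolution for the CDF inversion.
#' @return numeric vector of distances, A.
#' @export
sample_initial_distance <- function(landscape, thermo, n = 1L, seed = NULL,
                                    grid_n = 8192L) {
  if (!is.null(seed)) set.seed(seed)
  sup <- boltzmann_support(landscape, thermo)
  g <- seq(sup[1], sup[2], length.out = grid_n)
  dens <- exp(-thermo$beta * evaluate_potential(landscape, g))
  cdf <- cumtrapz(g, dens)
  if (cdf[grid_n] <= 0 || !is.finite(cdf[grid_n]))
    stop("landscape is not normalizable over its support")
  cdf <- cdf / cdf[grid_n]
  approx(cdf, g, xout = runif(n), ties = "ordered")$y
}

new_state_trajectory <- function(switch_times, efficiencies, molecule_id) {
  if (length(switch_times) != length(efficiencies))
    stop("switch_times and efficiencies must have equal length")
  if (length(switch_times) == 0L)
    stop("a state trajectory needs at least one segment")
  if (switch_times[1] != 0)
    stop("the first switch time must be 0")
  if (any(diff(switch_times) <= 0))
    stop("switch times must be increasing")
  if (any(efficiencies < 0 | efficiencies > 1))
    stop("efficiencies must lie in [0, 1]")
  structure(list(switch_times = switch_times,
                 efficiencies = efficiencies,
                 molecule_id = as.integer(molecule_id)),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state trajectory: molecule %d, %d segments, E in [%.3g, %.3g]>\n",
              x$molecule_id, length(x$switch_times),
              min(x$efficiencies), max(x$efficiencies)))
  invisible(x)
}

#' Two-state switching trajectory with exponential residences
#'
#' Piecewise-constant efficiency trajectory that strictly alternates
#' between two states, with residence times drawn i.i.d. from an
#' exponential distribution. This is the discrete ("non-Langevin")
#' stand-in for bistable interconversion; the shipped two-state example
#' uses a mean residence of 31.126 ms.
#'
#' @param efficiencies length-2 vector of state efficiencies in \[0, 1\].
#' @param mean_residence mean residence time, ms; > 0.
#' @param duration total covered time, s; > 0.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param start_state 1, 2, or `NULL` to draw the initial state uniformly.
#' @param molecule_id integer identifier.
#' @return a `state_trajectory` covering `[0, duration]`.
#' @export
generate_switching_trajectory <- function(efficiencies, mean_residence,
                                          duration, seed = NULL,
                                          start_state = NULL,
                                          molecule_id = 1L) {
  if (length(efficiencies) != 2L || any(efficiencies < 0 | efficiencies > 1))
    stop("`efficiencies` must be two values in [0, 1]")
  stopifnot_scalar(mean_residence, "mean_residence", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  mean_s <- ms_to_s(mean_residence)
  res <- numeric(0)
  while (sum(res) < duration) {
    need <- max(16L, ceiling((duration - sum(res)) / mean_s * 1.5))
    res <- c(res, rexp(need, rate = 1 / mean_s))
  }
  starts <- c(0, cumsum(res))
  starts <- starts[starts < duration]
  s0 <- if (is.null(start_state)) sample(1:2, 1L) else as.integer(start_state)
  states <- rep_len(c(s0, 3L - s0), length(starts))
  new_state_trajectory(starts, efficiencies[states], molecule_id)
}

#' Constant-efficiency trajectory
#'
#' Single-segment state trajectory, used for fixed-efficiency molecule
#' populations and for donor-only molecules (E = 0, i.e. an incompletely
#' labeled molecule lacking an acceptor).
#'
#' @param efficiency FRET efficiency in \[0, 1\].
#' @param duration covered time, s; > 0.
#' @param molecule_id integer identifier.
#' @return a `state_trajectory` with one segment.
#' @export
constant_trajectory <- function(efficiency, duration, molecule_id = 1L) {
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency < 0 || efficiency > 1)
    stop("`efficiency` must be a single value in [0, 1]")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be > 0 (an empty trajectory is not allowed)")
  traj <- new_state_trajectory(0, efficiency, molecule_id)
  traj$duration <- duration
  traj
}

#' Import an external dye--dye distance trajectory
#'
#' Reads a two-column time/distance table (whitespace- or comma-separated;
#' time in the file's native unit, distance in A), optionally rescaling
#' the time axis -- the adapter for distance trajectories
#' extracted from molecular-dynamics simulations, whose nominal duration
#' is usually far too short to mimic diffusing smFRET data directly
#' (e.g. a 320-ns trajectory stretched to 60 s uses
#' `time_rescale = 60 / 320e-9`).
#'
#' @param path file path.
#' @param time_rescale multiplicative factor applied to the time column.
#' @param molecule_id integer identifier.
#' @return a `distance_trajectory` with times in the rescaled unit
#'   (seconds, if `time_rescale` maps the native unit onto seconds).
#' @export
import_distance_trajectory <- function(path, time_rescale = 1,
                                       molecule_id = 1L) {
  stopifnot_scalar(time_rescale, "time_rescale", positive = TRUE)
  tab <- tryCatch(
    data.table::fread(path, header = FALSE, colClasses = "numeric"),
    warning = function(w) stop("failed to parse `", path, "`: ",
                               conditionMessage(w), call. = FALSE),
    error = function(e) stop("failed to parse `", path, "`: ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0L) stop("empty trajectory file: ", path)
  if (ncol(tab) < 2L) stop("expected two numeric columns in ", path)
  tms <- as.numeric(tab[[1]]); d <- as.numeric(tab[[2]])
  bad <- which(!is.finite(tms) | !is.finite(d))
  if (length(bad))
    stop(sprintf("non-numeric row %d in %s", bad[1], path))
  nonmono <- which(diff(tms) <= 0)
  if (length(nonmono))
    stop(sprintf("times not strictly increasing at row %d in %s",
                 nonmono[1] + 1L, path))
  new_distance_trajectory(tms * time_rescale, d, molecule_id)
}

#' Resample a trajectory onto a regular clock
#'
#' Evaluates a distance or state trajectory at every engine step
#' (nearest previous sample / current segment), returning one value per
#' step. Used to couple conformational trajectories to the photon clock.
#'
#' @param traj a `distance_trajectory` or `state_trajectory`.
#' @param dt engine step, s.
#' @param n_steps number of steps.
#' @return numeric vector of length `n_steps`.
#' @export
resample_to_clock <- function(traj, dt, n_steps) {
  tt <- dt * (seq_len(n_steps) - 1L)
  if (inherits(traj, "state_trajectory")) {
    idx <- findInterval(tt, traj$switch_times)
    idx[idx < 1L] <- 1L
    return(traj$efficiencies[idx])
  }
  if (inherits(traj, "distance_trajectory")) {
    if (max(tt) > max(traj$times) + dt)
      stop("trajectory is shorter than the simulated time span")
    idx <- findInterval(tt, traj$times)
    idx[idx < 1L] <- 1L
    return(traj$distances[idx])
  }
  stop("`traj` must be a distance or state trajectory")
}

#' Write / read a trajectory as CSV
#'
#' Serializes a distance trajectory as a two-column `time_s,value` CSV.
#'
#' @param traj a `distance_trajectory`.
#' @param path file path.
#' @return `read_trajectory()` returns a `distance_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "distance_trajectory"))
  data.table::fwrite(data.table::data.table(time_s = traj$times,
                                            value = traj$distances),
                     path)
  invisible(path)
}

#' @rdname write_trajectory
#' @param molecule_id integer identifier for the read trajectory.
#' @export
read_trajectory <- function(path, molecule_id = 1L) {
  tab <- data.table::fread(path)
  new_distance_trajectory(tab[[1]], tab[[2]], molecule_id)
}
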