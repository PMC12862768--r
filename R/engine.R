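#' Simulation box, PSF and emission settings
#'
#' `simulation_box()` defines the rectangular volume in which molecules
#' diffuse (the confocal PSF sits at its centre); `psf_model()` the 3D
#' Gaussian point spread function; `emission_config()` the photon
#' physics: peak emission rate at the PSF centre, the two background
#' rates, the engine clock step and the Brownian diffusion coefficient.
#' The defaults reproduce the confocal geometry used throughout the
#' shipped scenarios: an 8 x 8 x 12 um box, sigma = 0.3/0.3/0.5 um,
#' 200,000 cps peak rate, 1800/1200 cps donor/acceptor background and
#' D_B = 30 um^2/s.
#'
#' @param Lx,Ly,Lz box edge lengths, um; > 0.
#' @param boundary `"reflecting"` or `"periodic"`.
#' @param sigma_x,sigma_y,sigma_z PSF standard deviations, um; > 0.
#' @param max_rate peak emission rate at the PSF centre, counts/s.
#' @param bg_donor,bg_acceptor background rates, counts/s.
#' @param dt engine clock step, s; > 0.
#' @param D_B Brownian diffusion coefficient, um^2/s; > 0.
#' @param seed optional integer seed.
#' @return objects of class `simulation_box`, `psf_model`,
#'   `emission_config`.
#' @export
simulation_box <- function(Lx = 8, Ly = 8, Lz = 12,
                           boundary = c("reflecting", "periodic")) {
  for (v in c(Lx, Ly, Lz)) stopifnot_scalar(v, "box length", positive = TRUE)
  structure(list(L = c(Lx, Ly, Lz), boundary = match.arg(boundary)),
            class = "simulation_box")
}

#' @rdname simulation_box
#' @export
psf_model <- function(sigma_x = 0.3, sigma_y = 0.3, sigma_z = 0.5) {
  for (v in c(sigma_x, sigma_y, sigma_z))
    stopifnot_scalar(v, "psf sigma", positive = TRUE)
  structure(list(sigma = c(sigma_x, sigma_y, sigma_z)), class = "psf_model")
}

#' @rdname simulation_box
#' @export
emission_config <- function(max_rate = 2e5, bg_donor = 1800,
                            bg_acceptor = 1200, dt = 5e-8, D_B = 30,
                            seed = NULL) {
  for (v in c(max_rate, bg_donor, bg_acceptor))
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop("rates must be single non-negative numbers")
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(D_B, "D_B", positive = TRUE)
  structure(list(max_rate = max_rate, bg_donor = bg_donor,
                 bg_acceptor = bg_acceptor, dt = dt, D_B = D_B,
                 seed = seed),
            class = "emission_config")
}

#' Relative PSF intensity
#'
#' Gaussian excitation/detection profile
#' \eqn{\exp(-\Delta x^2/2\sigma_x^2 - \Delta y^2/2\sigma_y^2
#'   - \Delta z^2/2\sigma_z^2)}, peak 1 at the centre.
#'
#' @param psf a [psf_model()].
#' @param position numeric vector of length 3 or an n x 3 matrix, um.
#' @param center PSF centre, um (default origin).
#' @return relative intensity in \[0, 1\].
#' @export
psf_intensity <- function(psf, position, center = c(0, 0, 0)) {
  stopifnot(inherits(psf, "psf_model"))
  p <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  d <- sweep(p, 2, center)
  exp(-rowSums(sweep(d^2, 2, 2 * psf$sigma^2, "/")))
}

#' Brownian positions of a molecule
#'
#' Propagates one molecule's 3D Brownian motion (per-axis increments
#' N(0, 2 D_B dt)) with reflecting or periodic boundaries, returning the
#' full position record. Coordinates are relative to the box centre.
#' For long runs prefer the fused photon engine
#' ([simulate_experiment()]), which never materializes positions.
#'
#' @param box a [simulation_box()].
#' @param config an [emission_config()] (supplies `D_B` and `dt`).
#' @param position initial position, um (relative to the box centre).
#' @param n_steps number of steps.
#' @return an `n_steps` x 3 matrix of positions.
#' @export
propagate_brownian <- function(box, config, position, n_steps) {
  stopifnot(inherits(box, "simulation_box"),
            inherits(config, "emission_config"))
  if (any(abs(position) > box$L / 2)) stop("initial position outside the box")
  res <- cpp_diffuse_emit(position, as.integer(n_steps), config$dt,
                          box$L, as.integer(box$boundary == "periodic"),
                          c(1, 1, 1), 0, config$D_B,
                          0.5, 0, record_positions = TRUE)
  res$positions
}

# Convert a conformational model into the (values, start_step) step
# function the C++ engine consumes.
efficiency_steps <- function(traj, model, dt, n_steps) {
  if (is.numeric(traj) && length(traj) == n_steps) {
    return(list(values = traj, starts = as.numeric(seq_len(n_steps) - 1L)))
  }
  if (inherits(traj, "state_trajectory")) {
    starts <- floor(traj$switch_times / dt)
    keep <- !duplicated(starts, fromLast = TRUE) & starts < n_steps
    return(list(values = traj$efficiencies[keep],
                starts = as.numeric(starts[keep])))
  }
  if (inherits(traj, "distance_trajectory")) {
    if (is.null(model))
      stop("a distance trajectory needs an efficiency model")
    e <- efficiency_from_distance(model, resample_to_clock(traj, dt, n_steps))
    return(list(values = e, starts = as.numeric(seq_len(n_steps) - 1L)))
  }
  stop("unsupported conformational input")
}

#' Emit photons along a position record
#'
#' PSF-weighted Poisson emission: at each step the expected photon count
#' is `max_rate * psf_intensity * dt`; each emitted photon is assigned
#' to the acceptor channel with probability equal to the molecule's
#' FRET efficiency at that step, to the donor channel otherwise.
#' Timestamps are the emitting step's clock tick.
#'
#' @param positions n x 3 matrix of positions, um (relative to the PSF
#'   centre), as produced by [propagate_brownian()].
#' @param efficiency a `state_trajectory`, a `distance_trajectory`
#'   (requires `model`), or a numeric vector with one efficiency per
#'   step.
#' @param config an [emission_config()].
#' @param psf a [psf_model()].
#' @param model an [efficiency_model()] for distance trajectories.
#' @param molecule_id id stored with the photons.
#' @return a [photon_stream()].
#' @export
emit_photons <- function(positions, efficiency, config, psf, model = NULL,
                         molecule_id = 1L) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            inherits(config, "emission_config"), inherits(psf, "psf_model"))
  n <- nrow(positions)
  # a state trajectory's last segment extends right-continuously, so
  # coverage is only checkable when an explicit duration is recorded
  if (inherits(efficiency, "state_trajectory") &&
      !is.null(efficiency$duration) &&
      efficiency$duration < (n - 1L) * config$dt - 1e-12)
    stop("efficiency trajectory does not cover the simulated time span")
  es <- efficiency_steps(efficiency, model, config$dt, n)
  e_per_step <- es$values[findInterval(seq_len(n) - 1L, es$starts)]
  lambda <- config$max_rate * config$dt * psf_intensity(psf, positions)
  counts <- rpois(n, lambda)
  idx <- rep.int(seq_len(n), counts)
  chan <- ifelse(runif(length(idx)) < e_per_step[idx], 2L, 1L)
  photon_stream(idx - 1, chan, molecule_id, tick = config$dt)
}

#' Background photon stream
#'
#' Two independent homogeneous Poisson processes (donor and acceptor
#' background), quantized to clock ticks, with molecule id 0.
#'
#' @param config an [emission_config()].
#' @param duration covered time, s; > 0.
#' @return a [photon_stream()].
#' @export
generate_background <- function(config, duration) {
  stopifnot(inherits(config, "emission_config"))
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_ticks <- round(duration / config$dt)
  one <- function(rate, channel) {
    n <- rpois(1L, rate * duration)
    ticks <- floor(runif(n, 0, n_ticks))
    photon_stream(ticks, rep.int(channel, n), 0L, tick = config$dt)
  }
  merge_streams(list(one(config$bg_donor, 1L),
                     one(config$bg_acceptor, 2L)))
}
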