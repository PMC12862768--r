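#' Simulate a freely diffusing smFRET experiment
#'
#' Runs the full pipeline for one scenario: per-molecule conformational
#' dynamics (fixed efficiency, exponential-residence state switching,
#' Langevin dynamics on a landscape, or an imported distance
#' trajectory), 3D Brownian diffusion through the Gaussian PSF, Poisson
#' photon emission, background generation, and a deterministic merge.
#' One root seed drives everything: per-molecule and background child
#' seeds are derived from it, so any stage can be reproduced in
#' isolation and the full photon stream is bit-identical across runs.
#'
#' Molecules are processed in bounded time chunks so that Langevin
#' efficiency tracks never occupy more than ~16 MB at a time.
#'
#' @param scenario a scenario list as produced by [builtin_scenario()]
#'   or [scenario_config()].
#' @param seed root seed; defaults to the scenario's seed.
#' @param keep_trajectories record thinned conformational trajectories
#'   in the ground truth (memory permitting).
#' @return list with elements `stream` (a [photon_stream()]),
#'   `ground_truth` (per-molecule model descriptions, switching
#'   trajectories, seeds) and `scenario`.
#' @export
simulate_experiment <- function(scenario, seed = scenario$seed,
                                keep_trajectories = FALSE) {
  sc <- validate_scenario(scenario)
  if (is.null(seed)) stop("a seed is required for reproducible simulation")
  dt <- sc$dt
  n_steps <- as.integer(round(sc$duration / dt))
  box <- sc$box; psf <- sc$psf; em <- sc$emission

  mol_tab <- molecule_table(sc)
  n_mol <- nrow(mol_tab)
  seeds <- derive_seeds(seed, n_mol + 1L)

  streams <- vector("list", n_mol + 1L)
  gt <- vector("list", n_mol)
  chunk_steps <- 2000000L

  for (m in seq_len(n_mol)) {
    set.seed(seeds[m])
    pop <- sc$populations[[mol_tab$pop[m]]]
    model <- pop$model
    pos <- runif(3, -box$L / 2, box$L / 2)
    state <- init_conformation(model, sc, dt, molecule_id = m)
    gt[[m]] <- list(molecule_id = m, population = mol_tab$pop[m],
                    kind = model$kind, seed = seeds[m],
                    truth = state$truth)
    ticks <- list(); chans <- list()
    done <- 0L
    ri <- state$r    # carried Langevin state (distance, A)
    while (done < n_steps) {
      nc <- min(chunk_steps, n_steps - done)
      eff <- chunk_efficiency(state, model, sc, dt, done, nc, ri)
      ri <- eff$r
      res <- cpp_diffuse_emit(pos, nc, dt, box$L,
                              as.integer(box$boundary == "periodic"),
                              psf$sigma, em$max_rate, em$D_B,
                              eff$values, eff$starts,
                              record_positions = FALSE)
      if (length(res$tick)) {
        ticks[[length(ticks) + 1L]] <- res$tick + done
        chans[[length(chans) + 1L]] <- res$channel
      }
      pos <- res$final_pos
      done <- done + nc
    }
    tk <- unlist(ticks, use.names = FALSE)
    streams[[m]] <- photon_stream(
      if (is.null(tk)) numeric(0) else tk,
      unlist(chans, use.names = FALSE) %||% integer(0),
      m, tick = dt, sorted = TRUE)
    if (keep_trajectories && !is.null(state$traj))
      gt[[m]]$trajectory <- state$traj
  }

  em_bg <- em; em_bg$seed <- seeds[n_mol + 1L]; em_bg$dt <- dt
  streams[[n_mol + 1L]] <- generate_background(em_bg, sc$duration)

  list(stream = merge_streams(streams),
       ground_truth = list(molecules = gt, seeds = seeds,
                           background_seed = seeds[n_mol + 1L]),
       scenario = sc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One row per molecule, mapping to its population index.
molecule_table <- function(sc) {
  pops <- sc$populations
  data.frame(pop = rep(seq_along(pops),
                       vapply(pops, function(p) p$n, numeric(1))))
}

# Prepare per-molecule conformational state. Uses the current RNG stream
# (already seeded per molecule).
init_conformation <- function(model, sc, dt, molecule_id) {
  switch(model$kind,
    fixed = list(truth = list(efficiency = model$efficiency)),
    donor_only = list(truth = list(efficiency = 0)),
    switching = {
      traj <- generate_switching_trajectory(
        model$efficiencies, model$mean_residence_ms, sc$duration,
        molecule_id = molecule_id)
      list(truth = list(switch_times = traj$switch_times,
                        efficiencies = traj$efficiencies),
           traj = traj)
    },
    langevin = {
      r0 <- sample_initial_distance(model$landscape, model$thermo)
      list(r = r0, truth = list(r0 = r0))
    },
    trajectory = {
      traj <- import_distance_trajectory(model$path, model$time_rescale,
                                         molecule_id)
      list(truth = list(path = model$path, n_samples = length(traj$times)),
           traj = traj)
    },
    stop("unknown conformational model kind: ", model$kind))
}

# Efficiency step function for steps [done, done + nc) of one molecule.
chunk_efficiency <- function(state, model, sc, dt, done, nc, r_last) {
  switch(model$kind,
    fixed = list(values = model$efficiency, starts = 0, r = NULL),
    donor_only = list(values = 0, starts = 0, r = NULL),
    switching = {
      # last segment starting at/before the chunk, plus all inside it
      starts <- floor(state$traj$switch_times / dt) - done
      vals <- state$traj$efficiencies
      before <- which(starts <= 0)
      inside <- which(starts > 0 & starts < nc)
      idx <- c(if (length(before)) max(before), inside)
      st <- pmax(starts[idx], 0)
      dup <- duplicated(st, fromLast = TRUE)
      list(values = vals[idx][!dup], starts = st[!dup], r = NULL)
    },
    langevin = {
      cfg <- langevin_config(model$D_conf, s_to_ns(dt), model$thermo,
                             integrator = model$integrator %||% "auto",
                             max_stability = model$max_stability %||% 0.1)
      r <- langevin_samples(model$landscape, cfg, r_last, nc)
      e <- efficiency_from_distance(sc$efficiency_model, r)
      list(values = e, starts = as.numeric(seq_len(nc) - 1L),
           r = r[length(r)])
    },
    trajectory = {
      tt <- dt * (done + seq_len(nc) - 1L)
      idx <- findInterval(tt, state$traj$times)
      idx[idx < 1L] <- 1L
      if (max(tt) > max(state$traj$times) + dt)
        stop("imported trajectory is shorter than the simulated span")
      e <- efficiency_from_distance(model$efficiency_model %||%
                                      sc$efficiency_model,
                                    state$traj$distances[idx])
      list(values = e, starts = as.numeric(seq_len(nc) - 1L), r = NULL)
    })
}
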