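#' Scenario configuration
#'
#' A scenario bundles everything needed for one simulated experiment:
#' molecule populations (each with a conformational model), the shared
#' efficiency model, the confocal geometry and emission physics, the
#' engine step, the total duration, a root seed and the analysis
#' defaults. Population models are lists with a `kind` of `"fixed"`
#' (`efficiency`), `"donor_only"`, `"switching"` (`efficiencies`,
#' `mean_residence_ms`), `"langevin"` (`landscape`, `thermo`, `D_conf`),
#' or `"trajectory"` (`path`, `time_rescale`).
#'
#' @param name scenario label.
#' @param populations list of populations, each `list(n = ..., model =
#'   list(kind = ..., ...))` with `n` > 0.
#' @param efficiency_model an [efficiency_model()].
#' @param duration total simulated time, s.
#' @param dt engine clock step, s.
#' @param box a [simulation_box()].
#' @param psf a [psf_model()].
#' @param emission an [emission_config()].
#' @param seed default root seed.
#' @param analysis list of analysis defaults (bin width, photon
#'   threshold, burst-search settings, component counts).
#' @return a list of class `smfret_scenario`.
#' @export
scenario_config <- function(name, populations, efficiency_model,
                            duration, dt = 5e-8,
                            box = simulation_box(),
                            psf = psf_model(),
                            emission = emission_config(),
                            seed = 1L,
                            analysis = list()) {
  sc <- structure(list(
    name = name, populations = populations,
    efficiency_model = efficiency_model,
    duration = duration, dt = dt, box = box, psf = psf,
    emission = emission, seed = seed,
    analysis = modifyList(list(bin_width = 1e-3, threshold = 40,
                               burst_window = 200L, burst_rate = 4e4,
                               burst_min_photons = 100L, bva_n = 10L,
                               mixture_K = 2L, hmm_K = 2L),
                          analysis)),
    class = "smfret_scenario")
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  if (!inherits(sc, "smfret_scenario")) stop("not a scenario config")
  stopifnot_scalar(sc$duration, "duration", positive = TRUE)
  stopifnot_scalar(sc$dt, "dt", positive = TRUE)
  stopifnot(inherits(sc$box, "simulation_box"),
            inherits(sc$psf, "psf_model"),
            inherits(sc$emission, "emission_config"),
            inherits(sc$efficiency_model, "efficiency_model"))
  if (length(sc$populations) < 1L) stop("scenario needs >= 1 population")
  for (p in sc$populations) {
    if (is.null(p$n) || p$n < 1L) stop("population counts must be > 0")
    if (is.null(p$model$kind)) stop("population model needs a `kind`")
  }
  sc
}

#' @export
print.smfret_scenario <- function(x, ...) {
  n <- vapply(x$populations, function(p) p$n, numeric(1))
  kinds <- vapply(x$populations, function(p) p$model$kind, character(1))
  cat(sprintf("<smFRET scenario '%s': %d molecules (%s), %.3g s at dt = %.3g s>\n",
              x$name, sum(n),
              paste(sprintf("%d %s", n, kinds), collapse = ", "),
              x$duration, x$dt))
  invisible(x)
}

#' Built-in study scenarios
#'
#' Fully parameterized configurations of the two example systems and
#' the MD-adapter demonstration:
#'
#' * `example1_fixed`: 100 molecules, 50 at each of the two fixed
#'   efficiencies obtained by applying the inverse-2.65 model
#'   (R0 = 56 A) to 40 and 65 A; 30 s total (three 10-s runs' worth).
#' * `example1_langevin`: the same populations evolving on harmonic
#'   wells (k = 0.025 kcal/(mol A^2), centres 40/65 A) with
#'   beta = 1.339 (kcal/mol)^-1 and D_L = 1300 A^2/ns.
#' * `example2_langevin`: 90 molecules on the symmetric bistable
#'   landscape (k = 1e-4 kcal/(mol A^4), centre 50 A, wells at 35/65 A,
#'   barrier 1.265625 kcal/mol) with beta = 1.679 and
#'   D_L = 0.002 A^2/ns, plus 10 donor-only molecules; sixth-power
#'   efficiency model, R0 = 56 A; 20 min.
#' * `example2_switching`: the discrete counterpart -- 90 molecules
#'   alternating between the sixth-power efficiencies of the two well
#'   minima (E = 0.944 at 35 A, E = 0.290 at 65 A) with exponential
#'   residences of mean 31.126 ms; donor-only molecules excluded by
#'   default (set `include_donor_only = TRUE` to add them).
#' * `md_adapter_demo`: 16 molecules driven by a synthetic stand-in
#'   distance trajectory (see [synthetic_md_trajectory()]) rescaled
#'   from 320 ns to 60 s, inverse-2.65 model with R0 = 57 A, binning
#'   threshold 20.
#'
#' All scenarios share the confocal defaults (8 x 8 x 12 um box,
#' sigma = 0.3/0.3/0.5 um PSF, 200,000 cps peak, 1800/1200 cps
#' donor/acceptor background, D_B = 30 um^2/s, 50-ns step).
#' `duration_scale` and `n_molecules` shrink the run for desk-scale
#' work without touching any physics parameter; `engine_dt` coarsens
#' the engine clock (diffusion and photon statistics on millisecond
#' scales are insensitive to steps up to a few microseconds).
#'
#' @param name one of the scenario names above.
#' @param duration_scale multiplies the total duration.
#' @param n_molecules optional total molecule count (population
#'   proportions preserved).
#' @param engine_dt optional engine step override, s.
#' @param include_donor_only include the donor-only population in
#'   `example2_switching`.
#' @param seed root seed stored in the scenario.
#' @return an `smfret_scenario`.
#' @export
builtin_scenario <- function(name = c("example1_fixed", "example1_langevin",
                                      "example2_langevin",
                                      "example2_switching",
                                      "md_adapter_demo"),
                             duration_scale = 1, n_molecules = NULL,
                             engine_dt = NULL, include_donor_only = FALSE,
                             seed = 1L) {
  if (!is.character(name) || !(name[1] %in% c(
    "example1_fixed", "example1_langevin", "example2_langevin",
    "example2_switching", "md_adapter_demo")))
    stop("unknown scenario `", name[1], "`; available: example1_fixed, ",
         "example1_langevin, example2_langevin, example2_switching, ",
         "md_adapter_demo")
  name <- name[1]
  thermo1 <- thermo_state(1.339, temperature = 378)
  thermo2 <- thermo_state(1.679, temperature = 300)
  eq4_56 <- heterogeneous_model(56)
  eq6_56 <- forster_model(56)
  bistable <- bistable_landscape(1e-4, 50, 15)

  sc <- switch(name,
    example1_fixed = {
      e <- efficiency_from_distance(eq4_56, c(40, 65))
      scenario_config(name, list(
        list(n = 50, model = list(kind = "fixed", efficiency = e[1])),
        list(n = 50, model = list(kind = "fixed", efficiency = e[2]))),
        efficiency_model = eq4_56, duration = 30, seed = seed)
    },
    example1_langevin = scenario_config(name, list(
        list(n = 50, model = list(kind = "langevin",
                                  landscape = harmonic_landscape(0.025, 40),
                                  thermo = thermo1, D_conf = 1300)),
        list(n = 50, model = list(kind = "langevin",
                                  landscape = harmonic_landscape(0.025, 65),
                                  thermo = thermo1, D_conf = 1300))),
        efficiency_model = eq4_56, duration = 30, seed = seed),
    example2_langevin = scenario_config(name, list(
        list(n = 90, model = list(kind = "langevin", landscape = bistable,
                                  thermo = thermo2, D_conf = 0.002)),
        list(n = 10, model = list(kind = "donor_only"))),
        efficiency_model = eq6_56, duration = 1200, seed = seed),
    example2_switching = {
      e <- efficiency_from_distance(eq6_56, c(35, 65))
      pops <- list(
        list(n = 90, model = list(kind = "switching", efficiencies = e,
                                  mean_residence_ms = 31.126)))
      if (include_donor_only)
        pops <- c(pops, list(list(n = 10,
                                  model = list(kind = "donor_only"))))
      scenario_config(name, pops, efficiency_model = eq6_56,
                      duration = 1200, seed = seed)
    },
    md_adapter_demo = {
      path <- tempfile("md_demo_", fileext = ".csv")
      traj <- synthetic_md_trajectory(seed = seed)
      data.table::fwrite(data.table::data.table(traj$times,
                                                traj$distances),
                         path, col.names = FALSE)
      scenario_config(name, list(
        list(n = 16, model = list(kind = "trajectory", path = path,
                                  time_rescale = 60 / 320e-9))),
        efficiency_model = heterogeneous_model(57), duration = 60,
        seed = seed, analysis = list(threshold = 20))
    })

  if (!is.null(n_molecules)) sc <- rescale_molecules(sc, n_molecules)
  if (duration_scale != 1) {
    stopifnot_scalar(duration_scale, "duration_scale", positive = TRUE)
    sc$duration <- sc$duration * duration_scale
  }
  if (!is.null(engine_dt)) {
    stopifnot_scalar(engine_dt, "engine_dt", positive = TRUE)
    sc$dt <- engine_dt
  }
  validate_scenario(sc)
}

rescale_molecules <- function(sc, n_total) {
  n_old <- vapply(sc$populations, function(p) p$n, numeric(1))
  n_new <- pmax(1L, round(n_total * n_old / sum(n_old)))
  for (i in seq_along(sc$populations)) sc$populations[[i]]$n <- n_new[i]
  sc
}

#' Synthetic stand-in MD distance trajectory
#'
#' A short (320 ns nominal) dye--dye distance trajectory used by the
#' MD-adapter demonstration. It is *synthetic* -- an
#' Ornstein--Uhlenbeck-like meander between compact and extended
#' distances mimicking the qualitative shape of a disordered-protein
#' dye--dye distance trace -- and stands in for real MD output so that
#' the import/rescale code path can be exercised without external data.
#'
#' @param n_samples number of samples.
#' @param t_total nominal duration, s (default 320 ns).
#' @param seed integer seed.
#' @return a `distance_trajectory` (times in s, distances in A).
#' @export
synthetic_md_trajectory <- function(n_samples = 3200, t_total = 320e-9,
                                    seed = 1L) {
  set.seed(seed)
  dt <- t_total / n_samples
  # slow meander plus fast jitter, kept within a plausible 25-90 A band
  a <- 0.995
  slow <- as.numeric(stats::filter(rnorm(n_samples, sd = 1.2), a,
                                   method = "recursive", init = 0))
  d <- 55 + slow + rnorm(n_samples, sd = 1.5)
  d <- pmin(pmax(d, 25), 90)
  new_distance_trajectory(dt * seq_len(n_samples), d, molecule_id = 1L)
}

#' Deterministic unit-test fixtures
#'
#' Small, sub-second photon streams with exactly known generation
#' parameters, for fast tests: `background_only` (pure background),
#' `pinned_molecule` (one molecule fixed at the PSF centre, E = 0.7,
#' no background), and `two_state_mini` (one switching molecule plus
#' background). Byte-identical for identical `(name, seed)`.
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @return list with `stream`, `expected` (exact expectation values of
#'   the main summary counts) and the generating `scenario` or
#'   parameters.
#' @export
generate_fixture <- function(name = c("background_only", "pinned_molecule",
                                      "two_state_mini"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    background_only = {
      em <- emission_config(dt = 1e-6, seed = seed)
      stream <- generate_background(em, duration = 0.5)
      list(stream = stream,
           expected = list(donor = em$bg_donor * 0.5,
                           acceptor = em$bg_acceptor * 0.5),
           emission = em)
    },
    pinned_molecule = {
      em <- emission_config(bg_donor = 0, bg_acceptor = 0, dt = 1e-6)
      n <- 500000L
      set.seed(seed)
      pos <- matrix(0, n, 3)
      stream <- emit_photons(pos, rep(0.7, n), em, psf_model())
      list(stream = stream,
           expected = list(photons = em$max_rate * n * em$dt,
                           acceptor_fraction = 0.7),
           emission = em)
    },
    two_state_mini = {
      sc <- scenario_config("two_state_mini", list(
        list(n = 2, model = list(kind = "switching",
                                 efficiencies = c(0.9, 0.2),
                                 mean_residence_ms = 10))),
        efficiency_model = forster_model(56), duration = 0.5, dt = 1e-6,
        seed = seed)
      sim <- simulate_experiment(sc)
      list(stream = sim$stream, expected = list(),
           scenario = sc, ground_truth = sim$ground_truth)
    })
}

#' Read / write scenario configurations as YAML
#'
#' Serializes the plain-parameter content of a scenario (landscapes,
#' thermodynamics and efficiency models are stored by their fields and
#' reconstructed on read).
#'
#' @param sc an `smfret_scenario`.
#' @param path file path.
#' @return `read_scenario()` returns an `smfret_scenario`.
#' @export
write_scenario <- function(sc, path) {
  sc <- validate_scenario(sc)
  ser_model <- function(m) {
    out <- m
    if (!is.null(m$landscape)) out$landscape <- unclass(m$landscape)
    if (!is.null(m$thermo)) out$thermo <- unclass(m$thermo)
    if (!is.null(m$efficiency_model))
      out$efficiency_model <- unclass(m$efficiency_model)
    out
  }
  obj <- list(
    name = sc$name,
    duration = sc$duration, dt = sc$dt, seed = sc$seed,
    box = list(L = sc$box$L, boundary = sc$box$boundary),
    psf = list(sigma = sc$psf$sigma),
    emission = unclass(sc$emission)[c("max_rate", "bg_donor",
                                      "bg_acceptor", "dt", "D_B")],
    efficiency_model = unclass(sc$efficiency_model),
    populations = lapply(sc$populations,
                         function(p) list(n = p$n,
                                          model = ser_model(p$model))),
    analysis = sc$analysis)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  de_model <- function(m) {
    if (!is.null(m$landscape)) {
      l <- m$landscape
      m$landscape <- switch(l$kind,
        harmonic = harmonic_landscape(l$k_harmonic, l$center),
        bistable = bistable_landscape(l$k_bistable, l$center,
                                      l$well_offset),
        tabulated = tabulated_landscape(unlist(l$grid), unlist(l$values)))
    }
    if (!is.null(m$thermo))
      m$thermo <- thermo_state(m$thermo$beta, m$thermo$temperature)
    if (!is.null(m$efficiency_model)) {
      e <- m$efficiency_model
      m$efficiency_model <- efficiency_model(e$R0, e$exponent, e$prefactor)
    }
    m
  }
  em <- obj$efficiency_model
  scenario_config(
    name = obj$name,
    populations = lapply(obj$populations,
                         function(p) list(n = p$n, model = de_model(p$model))),
    efficiency_model = efficiency_model(em$R0, em$exponent, em$prefactor),
    duration = obj$duration, dt = obj$dt,
    box = simulation_box(obj$box$L[1], obj$box$L[2], obj$box$L[3],
                         boundary = obj$box$boundary),
    psf = psf_model(obj$psf$sigma[1], obj$psf$sigma[2], obj$psf$sigma[3]),
    emission = emission_config(obj$emission$max_rate, obj$emission$bg_donor,
                               obj$emission$bg_acceptor, obj$emission$dt,
                               obj$emission$D_B),
    seed = obj$seed, analysis = obj$analysis)
}
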