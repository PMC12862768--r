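test_that("PSF intensity follows the 3D Gaussian profile", {
  psf <- psf_model(0.3, 0.3, 0.5)
  expect_equal(psf_intensity(psf, c(0, 0, 0)), 1)
  expect_equal(psf_intensity(psf, c(0.3, 0, 0)), exp(-0.5))
  expect_equal(psf_intensity(psf, c(0, 0, 0.5)), exp(-0.5))
  expect_equal(psf_intensity(psf, c(0.3, 0.3, 0.5)), exp(-1.5))
  # matrix input and off-centre PSF
  p <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  expect_equal(psf_intensity(psf, p, center = c(0.3, 0, 0)),
               c(exp(-0.5), 1))
})

test_that("Brownian increments have variance 2 D dt and respect the box", {
  box <- simulation_box(50, 50, 50)
  em <- emission_config(dt = 1e-6, D_B = 30)
  set.seed(21)
  pos <- propagate_brownian(box, em, c(0, 0, 0), 1e6)
  inc <- diff(pos[, 1])
  v_target <- 2 * 30 * 1e-6
  expect_lt(abs(var(inc) - v_target), 3 * v_target * sqrt(2 / 1e6))

  # near-zero diffusion: positions essentially constant
  em0 <- emission_config(dt = 1e-6, D_B = 1e-12)
  set.seed(22)
  pos0 <- propagate_brownian(box, em0, c(1, 1, 1), 1000)
  expect_lt(max(abs(sweep(pos0, 2, c(1, 1, 1)))), 1e-3)

  # reflecting walls keep every step inside a tight box
  tight <- simulation_box(0.4, 0.4, 0.4)
  em_hot <- emission_config(dt = 1e-4, D_B = 30)
  set.seed(23)
  posr <- propagate_brownian(tight, em_hot, c(0, 0, 0), 5000)
  expect_true(all(abs(posr) <= 0.2 + 1e-12))
})

test_that("mean-squared displacement grows as 6 D t before boundaries", {
  box <- simulation_box(200, 200, 200)
  em <- emission_config(dt = 1e-5, D_B = 30)
  set.seed(24)
  n_traj <- 400; n_steps <- 200
  msd_end <- replicate(n_traj, {
    p <- propagate_brownian(box, em, c(0, 0, 0), n_steps)
    sum(p[n_steps, ]^2)
  })
  t_end <- n_steps * em$dt
  target <- 6 * 30 * t_end
  # chi-square_3 scaled: sd of the mean = target * sqrt(2/3) / sqrt(n)
  expect_lt(abs(mean(msd_end) - target),
            3 * target * sqrt(2 / 3) / sqrt(n_traj))
})

test_that("photon emission respects efficiency and Poisson statistics", {
  em <- emission_config(bg_donor = 0, bg_acceptor = 0, dt = 1e-6)
  psf <- psf_model()
  n <- 200000L
  pos <- matrix(0, n, 3)
  set.seed(25)
  s0 <- emit_photons(pos, rep(0, n), em, psf)
  expect_equal(sum(s0$channel == 2L), 0L)      # E = 0: no acceptor
  s1 <- emit_photons(pos, rep(1, n), em, psf)
  expect_equal(sum(s1$channel == 1L), 0L)      # E = 1: no donor
  # acceptor fraction converges at binomial rate
  s3 <- emit_photons(pos, rep(0.3, n), em, psf)
  nph <- length(s3)
  expect_lt(abs(mean(s3$channel == 2L) - 0.3), 3 * sqrt(0.3 * 0.7 / nph))
  # total counts: mean 0.2/step at the centre
  expect_lt(abs(nph - em$max_rate * n * em$dt),
            3 * sqrt(em$max_rate * n * em$dt))
})

test_that("emission follows a piecewise-constant efficiency trajectory", {
  em <- emission_config(bg_donor = 0, bg_acceptor = 0, dt = 1e-5)
  psf <- psf_model()
  n <- 100000L          # 1 s
  pos <- matrix(0, n, 3)
  traj <- smfretsim:::new_state_trajectory(c(0, 0.5), c(1, 0), 1L)
  set.seed(29)
  s <- emit_photons(pos, traj, em, psf)
  tt <- photon_times(s)
  expect_true(all(s$channel[tt < 0.5] == 2L))   # E = 1 half: acceptor only
  expect_true(all(s$channel[tt >= 0.5] == 1L))  # E = 0 half: donor only
  # an explicitly too-short trajectory is refused
  short <- constant_trajectory(0.5, duration = 0.2)
  expect_error(emit_photons(pos, short, em, psf), "cover")
  # a covering constant trajectory is fine
  ok <- constant_trajectory(0.5, duration = 1)
  expect_s3_class(emit_photons(pos, ok, em, psf), "photon_stream")
})

test_that("counts from a pinned molecule are Poisson-dispersed", {
  # 100 s of emission from a molecule fixed at the PSF centre, counted
  # in 1000 equal intervals: index of dispersion ~ 1 for a Poisson
  # process (1000 intervals give the test real power at the 10% band)
  em <- emission_config(bg_donor = 0, bg_acceptor = 0, dt = 1e-4)
  psf <- psf_model()
  set.seed(26)
  n_steps <- 1e6L   # 100 s
  s <- emit_photons(matrix(0, n_steps, 3), rep(0.5, n_steps), em, psf)
  counts <- tabulate(floor(photon_times(s) / 0.1) + 1L, nbins = 1000L)
  dispersion <- var(counts) / mean(counts)
  expect_gt(dispersion, 0.9)
  expect_lt(dispersion, 1.1)
})

test_that("background is two independent Poisson processes", {
  em <- emission_config(dt = 1e-6, seed = 27L)
  s <- generate_background(em, duration = 10)
  nd <- sum(s$channel == 1L)
  na <- sum(s$channel == 2L)
  expect_lt(abs(nd - 18000), 3 * sqrt(18000))
  expect_lt(abs(na - 12000), 3 * sqrt(12000))
  # exponential inter-arrivals (donor channel); sub-tick jitter undoes
  # the clock quantization that would otherwise produce ties
  tt <- sort(photon_times(s)[s$channel == 1L] +
               runif(nd, 0, s$tick))
  expect_gt(ks.test(diff(tt), "pexp", rate = 1800)$p.value, 0.01)
  # zero rates: empty stream
  em0 <- emission_config(bg_donor = 0, bg_acceptor = 0, dt = 1e-6,
                         seed = 28L)
  expect_equal(length(generate_background(em0, 1)), 0L)
})

test_that("stream merging is order-preserving and validated", {
  a <- photon_stream(c(0, 5, 9), c(1L, 2L, 1L), 1L, tick = 1e-6)
  b <- photon_stream(c(2, 5, 7), c(2L, 1L, 2L), 2L, tick = 1e-6)
  m <- merge_streams(list(a, b))
  expect_equal(length(m), 6L)
  expect_true(all(diff(m$tick_index) >= 0))
  # deterministic tie-break at tick 5: donor (mol 2) before acceptor (mol 1)
  at5 <- which(m$tick_index == 5)
  expect_equal(m$channel[at5], c(1L, 2L))
  empty <- photon_stream(numeric(0), integer(0), integer(0), tick = 1e-6)
  expect_equal(merge_streams(list(a, empty))$tick_index, a$tick_index)
  other <- photon_stream(1, 1L, 1L, tick = 2e-6)
  expect_error(merge_streams(list(a, other)), "tick")
})

test_that("photon files round-trip losslessly", {
  s <- photon_stream(c(0, 3, 3, 10, 2^40), c(1L, 2L, 1L, 2L, 1L),
                     c(1L, 2L, 0L, 1L, 3L), tick = 5e-8)
  path <- tempfile(fileext = ".csv")
  write_photons(s, path)
  back <- read_photons(path)
  expect_identical(back$tick_index, s$tick_index)
  expect_identical(back$channel, s$channel)
  expect_identical(back$molecule_id, s$molecule_id)
  expect_identical(back$tick, s$tick)
  # empty stream round-trips, tick metadata intact
  e <- photon_stream(numeric(0), integer(0), integer(0), tick = 2e-6)
  write_photons(e, path)
  back_e <- read_photons(path)
  expect_equal(length(back_e), 0L)
  expect_identical(back_e$tick, 2e-6)
  suppressWarnings(expect_error(read_photons(tempfile()),
                                "cannot open|No such"))
})

test_that("the full pipeline is deterministic and covers edge scenarios", {
  sc <- scenario_config("mini", list(
    list(n = 2, model = list(kind = "fixed", efficiency = 0.7)),
    list(n = 1, model = list(kind = "donor_only"))),
    efficiency_model = forster_model(56), duration = 0.2, dt = 1e-6,
    seed = 30L)
  sim1 <- simulate_experiment(sc)
  sim2 <- simulate_experiment(sc)
  expect_identical(sim1$stream, sim2$stream)
  # donor-only molecule contributed no acceptor photons
  expect_equal(sum(sim1$stream$channel == 2L &
                     sim1$stream$molecule_id == 3L), 0L)
  # molecule-free scenario is background-only
  sc_bg <- scenario_config("bg", list(
    list(n = 1, model = list(kind = "fixed", efficiency = 0.5))),
    efficiency_model = forster_model(56), duration = 0.2, dt = 1e-6,
    seed = 31L)
  sc_bg$emission$max_rate <- 0
  sim_bg <- simulate_experiment(sc_bg)
  expect_true(all(sim_bg$stream$molecule_id == 0L))
})
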