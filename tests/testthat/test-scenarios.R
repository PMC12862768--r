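test_that("built-in scenarios carry the study parameters verbatim", {
  e1 <- builtin_scenario("example1_langevin")
  expect_equal(e1$emission$max_rate, 2e5)
  expect_equal(e1$emission$bg_donor, 1800)
  expect_equal(e1$emission$bg_acceptor, 1200)
  expect_equal(e1$emission$D_B, 30)
  expect_equal(e1$box$L, c(8, 8, 12))
  expect_equal(e1$psf$sigma, c(0.3, 0.3, 0.5))
  expect_equal(e1$dt, 5e-8)
  m1 <- e1$populations[[1]]$model
  expect_equal(m1$thermo$beta, 1.339)
  expect_equal(m1$D_conf, 1300)
  expect_equal(m1$landscape$k_harmonic, 0.025)
  expect_equal(vapply(e1$populations,
                      function(p) p$model$landscape$center, numeric(1)),
               c(40, 65))
  expect_equal(e1$efficiency_model$exponent, 2.65)
  expect_equal(e1$efficiency_model$prefactor, 0.975)
  expect_equal(e1$efficiency_model$R0, 56)

  e1f <- builtin_scenario("example1_fixed")
  effs <- vapply(e1f$populations, function(p) p$model$efficiency,
                 numeric(1))
  expect_equal(round(sort(effs), 2), c(0.41, 0.71))

  e2 <- builtin_scenario("example2_langevin")
  expect_equal(vapply(e2$populations, function(p) p$n, numeric(1)),
               c(90, 10))
  expect_equal(e2$populations[[2]]$model$kind, "donor_only")
  l <- e2$populations[[1]]$model$landscape
  expect_equal(l$k_bistable, 1e-4)
  expect_equal(l$center, 50)
  expect_equal(l$well_offset, 15)
  expect_equal(barrier_height(l), 1.265625)
  expect_equal(e2$populations[[1]]$model$thermo$beta, 1.679)
  expect_equal(e2$populations[[1]]$model$D_conf, 0.002)
  expect_equal(e2$efficiency_model$exponent, 6)
  expect_equal(e2$duration, 1200)

  sw <- builtin_scenario("example2_switching")
  msw <- sw$populations[[1]]$model
  expect_equal(msw$mean_residence_ms, 31.126)
  expect_equal(round(sort(msw$efficiencies), 3), c(0.290, 0.944))
  expect_equal(length(sw$populations), 1L)   # donor-only off by default
  sw2 <- builtin_scenario("example2_switching", include_donor_only = TRUE)
  expect_equal(length(sw2$populations), 2L)

  md <- builtin_scenario("md_adapter_demo")
  expect_equal(md$populations[[1]]$model$time_rescale, 60 / 320e-9)
  expect_equal(md$efficiency_model$R0, 57)
  expect_equal(md$analysis$threshold, 20)

  expect_error(builtin_scenario("nope"), "example1_fixed")
})

test_that("desk-scale knobs shrink runs without touching physics", {
  sc <- builtin_scenario("example1_fixed", duration_scale = 0.1,
                        n_molecules = 10, engine_dt = 2e-6)
  expect_equal(sc$duration, 3)
  expect_equal(sc$dt, 2e-6)
  expect_equal(vapply(sc$populations, function(p) p$n, numeric(1)),
               c(5, 5))
  expect_equal(sc$emission$max_rate, 2e5)     # physics untouched
})

test_that("fixtures are deterministic with recorded expectations", {
  f1 <- generate_fixture("background_only", seed = 9L)
  f2 <- generate_fixture("background_only", seed = 9L)
  expect_identical(f1$stream, f2$stream)
  expect_lt(abs(length(f1$stream) -
                  (f1$expected$donor + f1$expected$acceptor)),
            3 * sqrt(f1$expected$donor + f1$expected$acceptor))
  p <- generate_fixture("pinned_molecule", seed = 10L)
  expect_lt(abs(mean(p$stream$channel == 2L) - 0.7), 0.01)
  m <- generate_fixture("two_state_mini", seed = 11L)
  expect_s3_class(m$stream, "photon_stream")
  expect_gt(length(m$stream), 0)
})

test_that("scenario YAML round-trips the full parameter set", {
  for (name in c("example1_fixed", "example1_langevin",
                 "example2_switching")) {
    sc <- builtin_scenario(name, seed = 3L)
    path <- tempfile(fileext = ".yaml")
    write_scenario(sc, path)
    back <- read_scenario(path)
    expect_equal(back$duration, sc$duration)
    expect_equal(back$dt, sc$dt)
    expect_equal(back$efficiency_model, sc$efficiency_model)
    expect_equal(length(back$populations), length(sc$populations))
    expect_equal(back$populations[[1]]$model$kind,
                 sc$populations[[1]]$model$kind)
    if (name == "example1_langevin")
      expect_equal(back$populations[[1]]$model$landscape,
                   sc$populations[[1]]$model$landscape)
  }
})

test_that("the pipeline writes a reproducible report bundle", {
  sc <- scenario_config("pipe_mini", list(
    list(n = 6, model = list(kind = "switching",
                             efficiencies = c(0.9, 0.2),
                             mean_residence_ms = 15))),
    efficiency_model = forster_model(56), duration = 6, dt = 2e-6,
    seed = 77L)
  out1 <- tempfile("pipe1_"); out2 <- tempfile("pipe2_")
  r1 <- run_pipeline(sc, out1, plots = FALSE)
  r2 <- run_pipeline(sc, out2, plots = FALSE)
  expect_true(file.exists(file.path(out1, "photons.csv")))
  expect_true(file.exists(file.path(out1, "report.json")))
  expect_equal(r1$n_photons, r2$n_photons)
  if (!is.null(r1$gmm)) expect_equal(r1$gmm$means, r2$gmm$means)
  expect_identical(readLines(file.path(out1, "photons.csv")),
                   readLines(file.path(out2, "photons.csv")))
})

test_that("the MD-adapter path feeds imported distances through the engine", {
  md <- builtin_scenario("md_adapter_demo", seed = 12L)
  md$duration <- 2
  md <- smfretsim:::rescale_molecules(md, 3)
  sim <- simulate_experiment(md)
  expect_gt(length(sim$stream), 0)
  # acceptor fraction should reflect mid-range distances, not E ~ 0 or 1
  frac <- mean(sim$stream$channel == 2L)
  expect_gt(frac, 0.2); expect_lt(frac, 0.9)
})
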