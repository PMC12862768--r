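test_that("drift holds a near-noiseless walker at the minimum", {
  th <- thermo_state(1.679)
  b <- bistable_landscape(1e-4, 50, 15)
  cfg <- langevin_config(D_conf = 1e-12, dt = 50, th,
                         integrator = "euler_maruyama", seed = 1L)
  traj <- propagate_langevin(b, cfg, r0 = 35, n_steps = 2000)
  expect_lt(max(abs(traj$distances - 35)), 0.01)
})

test_that("free diffusion produces i.i.d. Gaussian increments", {
  # flat tabulated landscape: V' = 0, increments ~ N(0, 2 D dt)
  flat <- tabulated_landscape(c(-1e5, 1e5), c(0, 0))
  cfg <- langevin_config(D_conf = 2, dt = 50, thermo_state(1),
                         integrator = "euler_maruyama", seed = 2L)
  n <- 1e5
  traj <- propagate_langevin(flat, cfg, r0 = 0, n_steps = n)
  inc <- diff(traj$distances)
  v_target <- 2 * 2 * 50
  se <- v_target * sqrt(2 / n)
  expect_lt(abs(var(inc) - v_target), 3 * se)
  expect_lt(abs(mean(inc)), 3 * sqrt(v_target / n))
})

test_that("stiff harmonic dynamics recover the Boltzmann distribution", {
  # single-state conditions: naive Euler-Maruyama would have stiffness
  # beta*D*k*dt ~ 2176; the exact OU update must still equilibrate
  th <- thermo_state(1.339)
  h <- harmonic_landscape(0.025, 40)
  cfg <- langevin_config(1300, 50, th, integrator = "exact_ou", seed = 3L)
  traj <- propagate_langevin(h, cfg, r0 = 40, n_steps = 1e5)
  sd_target <- sqrt(1 / (1.339 * 0.025))          # ~5.47 A
  x <- traj$distances[-1]
  expect_gt(ks.test(x, "pnorm", 40, sd_target)$p.value, 0.01)
})

test_that("exact OU and substepped Euler-Maruyama agree on the harmonic well", {
  th <- thermo_state(1.339)
  h <- harmonic_landscape(0.025, 40)
  n <- 1e5
  v_target <- 1 / (1.339 * 0.025)
  cfg_ou <- langevin_config(13, 50, th, integrator = "exact_ou", seed = 4L)
  v_ou <- var(propagate_langevin(h, cfg_ou, 40, n)$distances)
  # tight substep bound keeps the O(dt) variance bias below the tolerance
  cfg_em <- langevin_config(13, 50, th, integrator = "substepped",
                            max_stability = 0.01, seed = 4L)
  v_em <- var(propagate_langevin(h, cfg_em, 40, n)$distances)
  expect_lt(abs(v_ou / v_target - 1), 0.01)
  expect_lt(abs(v_em / v_target - 1), 0.01)
})

test_that("unstable explicit integration is refused with a diagnostic", {
  th <- thermo_state(1.339)
  h <- harmonic_landscape(0.025, 40)
  cfg <- langevin_config(1300, 50, th, integrator = "euler_maruyama")
  expect_error(propagate_langevin(h, cfg, 40, 100), "stiffness")
  expect_error(langevin_config(1300, 50, th, max_stability = 2), "\\(0, 2\\)")
})

test_that("initial distances follow the landscape's Boltzmann density", {
  th <- thermo_state(1.339)
  h <- harmonic_landscape(0.025, 40)
  x <- sample_initial_distance(h, th, n = 1e4, seed = 5L)
  sd_t <- sqrt(1 / (1.339 * 0.025))
  expect_lt(abs(mean(x) - 40), 3 * sd_t / sqrt(1e4))
  b <- bistable_landscape(1e-4, 50, 15)
  y <- sample_initial_distance(b, thermo_state(1.679), n = 1e4, seed = 6L)
  expect_lt(abs(mean(y < 50) - 0.5), 3 * 0.5 / sqrt(1e4))
  expect_identical(sample_initial_distance(h, th, n = 10, seed = 7L),
                   sample_initial_distance(h, th, n = 10, seed = 7L))
})

test_that("switching trajectories alternate with exponential residences", {
  traj <- generate_switching_trajectory(c(0.944, 0.290), 31.126,
                                        duration = 400, seed = 8L)
  res <- diff(traj$switch_times)
  expect_gt(length(res), 1e4)
  m <- mean(res) * 1e3
  se <- 31.126 / sqrt(length(res))    # exponential: sd = mean
  expect_lt(abs(m - 31.126), 3 * se)
  expect_true(all(diff(match(traj$efficiencies,
                             c(0.944, 0.290))) != 0))  # strict alternation
  expect_equal(traj$switch_times[1], 0)
  expect_lt(max(traj$switch_times), 400)  # segments cover [0, duration]
})

test_that("constant trajectories represent fixed and donor-only states", {
  d0 <- constant_trajectory(0, duration = 1)
  expect_equal(d0$efficiencies, 0)
  hi <- constant_trajectory(0.944, duration = 1)
  expect_equal(hi$efficiencies, 0.944)
  expect_error(constant_trajectory(0.5, duration = 0), "> 0")
  expect_error(constant_trajectory(1.2, duration = 1), "\\[0, 1\\]")
})

test_that("external distance trajectories import, rescale and resample", {
  path <- tempfile(fileext = ".csv")
  tms <- seq(1e-10, 320e-9, length.out = 64)
  writeLines(sprintf("%.12e,%g", tms, 50 + sin(seq_len(64))), path)
  t1 <- import_distance_trajectory(path, time_rescale = 1)
  expect_equal(max(t1$times), 320e-9)
  t2 <- import_distance_trajectory(path, time_rescale = 60 / 320e-9)
  expect_equal(max(t2$times), 60)
  expect_equal(t1$distances, t2$distances)
  # nearest-previous-sample resampling
  e <- resample_to_clock(t2, dt = 60 / 64, n_steps = 64)
  expect_equal(e[2], t2$distances[1])
  # malformed inputs
  empty <- tempfile(); file.create(empty)
  expect_error(import_distance_trajectory(empty), "empty|parse")
  bad <- tempfile()
  writeLines(c("1,50", "3,51", "2,52"), bad)
  expect_error(import_distance_trajectory(bad), "row 3")
})

test_that("stochastic trajectory generation is seed-reproducible", {
  th <- thermo_state(1.679)
  b <- bistable_landscape(1e-4, 50, 15)
  cfg <- langevin_config(0.002, 50, th, seed = 11L)
  t1 <- propagate_langevin(b, cfg, 35, 5000)
  t2 <- propagate_langevin(b, cfg, 35, 5000)
  expect_identical(t1$distances, t2$distances)
  s1 <- generate_switching_trajectory(c(0.9, 0.2), 10, 5, seed = 12L)
  s2 <- generate_switching_trajectory(c(0.9, 0.2), 10, 5, seed = 12L)
  expect_identical(s1$switch_times, s2$switch_times)
})

test_that("trajectories round-trip through CSV", {
  th <- thermo_state(1.339)
  cfg <- langevin_config(13, 50, th, seed = 13L)
  traj <- propagate_langevin(harmonic_landscape(0.025, 40), cfg, 40, 500)
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$times, traj$times)
  expect_equal(back$distances, traj$distances)
})
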