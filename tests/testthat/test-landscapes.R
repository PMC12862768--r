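test_that("potentials and gradients match closed forms", {
  h <- harmonic_landscape(0.025, 40)
  expect_equal(evaluate_potential(h, 40), 0)
  expect_equal(evaluate_potential(h, 50), 1.25)       # (k/2) * 10^2
  expect_equal(evaluate_gradient(h, 50), 0.25)        # k * (r - rc)
  expect_equal(evaluate_gradient(h, 40), 0)

  b <- bistable_landscape(1e-4, 50, 15)
  expect_equal(evaluate_potential(b, 50), 1.265625)
  expect_equal(evaluate_potential(b, 35), 0)
  expect_equal(evaluate_potential(b, 65), 0)
  expect_equal(evaluate_gradient(b, 35), 0)
  expect_equal(evaluate_gradient(b, 65), 0)
  expect_equal(evaluate_gradient(b, 50), 0)           # symmetric barrier top

  # vectorized evaluation agrees with scalar
  r <- seq(20, 80, by = 2.5)
  expect_equal(evaluate_potential(b, r),
               vapply(r, function(x) evaluate_potential(b, x), numeric(1)))
})

test_that("tabulated landscapes interpolate and respect their range", {
  h <- harmonic_landscape(0.025, 40)
  g <- seq(10, 70, by = 0.05)
  tab <- tabulated_landscape(g, evaluate_potential(h, g))
  r <- seq(12, 68, by = 1.7)
  expect_equal(evaluate_potential(tab, r), evaluate_potential(h, r),
               tolerance = 1e-5)
  expect_equal(evaluate_gradient(tab, r), evaluate_gradient(h, r),
               tolerance = 1e-3)
  expect_error(evaluate_potential(tab, 5), "grid range")
  expect_error(evaluate_gradient(tab, 75), "grid range")
  expect_error(tabulated_landscape(c(1, 1, 2), c(0, 0, 0)),
               "strictly increasing")
})

test_that("barrier height follows k_B W^4 / 4", {
  b <- bistable_landscape(1e-4, 50, 15)
  expect_equal(barrier_height(b), 1.265625)
  b2 <- bistable_landscape(2e-4, 50, 15)
  expect_equal(barrier_height(b2), 2 * barrier_height(b))
  expect_error(barrier_height(harmonic_landscape(1, 0)), "bistable")
  expect_error(bistable_landscape(1e-4, 50, 0), "must be > 0")
})

test_that("Boltzmann densities normalize and respect symmetry", {
  th <- thermo_state(1.679)
  b <- bistable_landscape(1e-4, 50, 15)
  expect_equal(boltzmann_density(b, th, 35), boltzmann_density(b, th, 65))
  for (l in list(b, harmonic_landscape(0.025, 40),
                 tabulated_landscape(seq(0, 120, by = 0.02),
                                     evaluate_potential(b, seq(0, 120,
                                                               by = 0.02))))) {
    sup <- smfretsim:::boltzmann_support(l, th)
    g <- seq(sup[1], sup[2], length.out = 4e5)
    d <- boltzmann_density(l, th, g)
    z <- sum((d[-1] + d[-length(d)]) / 2) * (g[2] - g[1])
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("two-harmonic closed-form density matches its quoted value", {
  th <- thermo_state(1.339)
  # equal-weight mixture of wells at 40 and 65 A, k = 0.025
  expect_equal(harmonic_pair_density(0.025, th, c(40, 65), 40),
               0.0365, tolerance = 2e-3)
  # integrates to 1 over the real line
  z <- integrate(function(r) harmonic_pair_density(0.025, th, c(40, 65), r),
                 -Inf, Inf)
  expect_equal(z$value, 1, tolerance = 1e-8)
  # and agrees with the quadrature route applied to each well separately
  h1 <- harmonic_landscape(0.025, 40)
  r <- seq(25, 55, by = 3)
  expect_equal(harmonic_pair_density(0.025, th, c(40, 40), r),
               boltzmann_density(h1, th, r), tolerance = 1e-7)
})

test_that("thermo_state validates beta", {
  expect_error(thermo_state(0), "> 0")
  expect_error(thermo_state(-1), "> 0")
  expect_equal(thermo_state(1.339)$beta, 1.339)
})
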