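test_that("sliding-window search flags rate excursions", {
  # constant 100,000 cps stream: every window beats 40,000 cps
  s_hot <- constant_rate_stream(1e5, 1, seed = 71)
  b_hot <- sliding_window_burst_search(s_hot, m = 200, rate_threshold = 4e4)
  expect_equal(nrow(b_hot), 1L)
  expect_equal(b_hot$n_photons, length(s_hot))
  # constant 10,000 cps: nothing passes
  s_cold <- constant_rate_stream(1e4, 1, seed = 72)
  expect_equal(nrow(sliding_window_burst_search(s_cold, 200, 4e4)), 0L)
  # stream shorter than the window: no bursts, gracefully
  s_tiny <- photon_stream(1:50, rep(1L, 50), 1L, tick = 1e-6)
  expect_equal(nrow(sliding_window_burst_search(s_tiny, 200, 4e4)), 0L)
  expect_error(sliding_window_burst_search(s_tiny, 1, 4e4), ">= 2")
})

test_that("a burst embedded in sparse background is delimited", {
  set.seed(73)
  dt <- 1e-6
  bg <- sort(floor(runif(300, 0, 1e6)))          # 300 cps over 1 s
  burst <- sort(floor(runif(400, 450000, 453000)))  # ~133,000 cps for 3 ms
  ticks <- sort(c(bg, burst))
  s <- photon_stream(ticks, rep(1L, length(ticks)), 1L, tick = dt)
  b <- sliding_window_burst_search(s, m = 50, rate_threshold = 4e4)
  expect_equal(nrow(b), 1L)
  expect_gt(b$n_photons, 350)
  expect_lt(abs(b$start_time - 0.45), 0.01)
})

test_that("burst selection keeps bursts with at least the minimum photons", {
  s <- constant_rate_stream(1e5, 1, seed = 74)
  b <- sliding_window_burst_search(s, 200, 4e4)
  fake <- b[rep(1, 3), ]
  fake$n_photons <- c(99L, 100L, 150L)
  class(fake) <- class(b)
  sel <- select_bursts(fake, 100)
  expect_equal(sel$n_photons, c(100L, 150L))
  expect_equal(nrow(select_bursts(fake, 0)), 3L)
  expect_equal(nrow(select_bursts(fake[0, ], 100)), 0L)
})

test_that("the binomial reference curve matches its closed form", {
  expect_equal(bva_reference(0.5, 10), sqrt(0.025))   # 0.1581
  expect_equal(bva_reference(0, 10), 0)
  expect_equal(bva_reference(1, 10), 0)
})

test_that("BVA sub-burst statistics match a hand oracle", {
  # one burst of 35 photons: sub-bursts of 10 -> 3 complete windows
  chan <- c(rep(2L, 10),                       # E = 1.0
            rep(c(2L, 1L), 5),                 # E = 0.5
            rep(1L, 10),                       # E = 0.0
            rep(2L, 5))                        # remainder, discarded
  s <- photon_stream(seq_along(chan), chan, 1L, tick = 1e-6)
  b <- data.frame(start_idx = 1L, end_idx = 35L, n_photons = 35L,
                  start_time = 0, duration = 35e-6,
                  efficiency = mean(chan == 2L))
  class(b) <- c("burst_set", "data.frame")
  res <- burst_variance_analysis(b, s, n = 10)
  expect_equal(res$n_sub_bursts, 3L)
  expect_equal(res$mean_efficiency, 0.5)
  expect_equal(res$sigma, sd(c(1, 0.5, 0)))
  # a burst with < 2n photons is excluded and counted
  b2 <- b; b2$end_idx <- 15L; b2$n_photons <- 15L
  class(b2) <- c("burst_set", "data.frame")
  res2 <- burst_variance_analysis(b2, s, n = 10)
  expect_equal(nrow(res2), 0L)
  expect_equal(attr(res2, "n_excluded"), 1L)
})

test_that("static bursts sit on the binomial curve", {
  # synthetic bursts: binomial channel draws at fixed E, no dynamics
  set.seed(75)
  for (E in c(0.2, 0.5, 0.8)) {
    n_b <- 300
    sizes <- sample(100:250, n_b, replace = TRUE)
    chan <- unlist(lapply(sizes, function(k)
      ifelse(runif(k) < E, 2L, 1L)))
    starts <- cumsum(c(1L, head(sizes, -1)))
    s <- photon_stream(seq_along(chan), chan, 1L, tick = 1e-6)
    b <- data.frame(start_idx = starts, end_idx = starts + sizes - 1L,
                    n_photons = sizes, start_time = 0, duration = 0,
                    efficiency = E)
    class(b) <- c("burst_set", "data.frame")
    res <- burst_variance_analysis(b, s, n = 10)
    expect_lt(abs(mean(res$sigma) / bva_reference(E, 10) - 1), 0.05)
  }
})
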