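# Generators: exact OU update, refractory-exponential intervals,
# single- and dual-scale trains, benchmark grid.

test_that("OU phase noise follows the exact discrete transition", {
  expect_identical(sample_ou_phase_noise(0.01, 0, T = 1, seed = 1),
                   numeric(1e5 + 1))
  sig <- 0.4 * pi * 12 / 1000  # ~0.01508 rad
  x <- sample_ou_phase_noise(0.01, sig, T = 100, dt = 1e-4, seed = 5)
  expect_lt(abs(sd(x) - sig) / sig, 0.05)
  lag <- round(0.01 / 1e-4)
  ac <- cor(x[seq_len(length(x) - lag)], x[-seq_len(lag)])
  expect_lt(abs(ac - exp(-1)), 0.02)
  expect_error(sample_ou_phase_noise(-1, 0.1, T = 1), "tau_OU")
})

test_that("refractory-exponential intervals have the stated mean and support", {
  x <- sample_refractory_exponential(10, 0, 20000, seed = 2)
  expect_lt(abs(mean(x) - 0.1), 3 * 0.1 / sqrt(20000))
  # rate parameter and shift of the non-rhythmic half-cycle process at f0 = 12
  lam <- 2 * 12 * exp(0.1)
  expect_equal(lam, 26.524, tolerance = 1e-4)
  y <- sample_refractory_exponential(lam, 0.1 / 24, 20000, seed = 3)
  expect_true(all(y >= 0.1 / 24))
  expect_lt(abs(mean(y) - (0.1 / 24 + 1 / lam)), 3 * (1 / lam) / sqrt(20000))
  expect_error(sample_refractory_exponential(10, 0, -1), "n must")
})

test_that("single-scale m = 0 conserves the refractory-thinned rate", {
  p <- single_scale_params(r0 = 8, m = 0, f0 = 12, rhythmic = TRUE,
                           N = 100, T = 10)
  st <- generate_single_scale(p, seed = 11)
  expected <- 100 * 10 * 8 / (1 + 8 * 0.004)
  pooled <- sum(lengths(st$spikes))
  expect_lt(abs(pooled - expected), 3 * sqrt(expected))
  # refractory support
  isis <- unlist(lapply(st$spikes, diff))
  expect_true(all(isis > 0.004))
})

test_that("rhythmic m = 1 trains concentrate spectral power at f0", {
  p <- single_scale_params(r0 = 12, m = 1, f0 = 12, rhythmic = TRUE,
                           N = 50, T = 10)
  st <- generate_single_scale(p, seed = 21)
  sp <- power_spectrum(population_rate(st))
  df <- sp$freq[2] - sp$freq[1]
  expect_lt(abs(sp$f_max - 12), df + 1e-9)
})

test_that("sequential phase offsets shift first vs last neuron by ~Dc/f0", {
  p <- single_scale_params(r0 = 36, m = 1, f0 = 12, rhythmic = TRUE,
                           Dc = 0.4, N = 10, T = 30)
  st <- generate_single_scale(p, seed = 31)
  a <- st$spikes[[1]]
  b <- st$spikes[[10]]
  # cross-correlogram: lag of b relative to a, binned at 2 ms
  lags <- seq(-0.05, 0.05, by = 0.002)
  counts <- vapply(lags, function(l)
    hcspike:::count_within_cpp(a + l, b, 0.001), numeric(1))
  peak_lag <- lags[which.max(counts)]
  # neuron 1 leads by Dc/f0 = 33 ms
  expect_lt(abs(peak_lag - 0.4 / 12), 0.008)
})

test_that("dual-scale spikes sit on population events as prescribed", {
  # tight jitter: all spikes within 4 sigma of an event
  p <- dual_scale_params(Sigma = 0.001, p_fail = 0, f0 = 12,
                         rhythmic = TRUE, N = 20, T = 10)
  st <- generate_dual_scale(p, seed = 41, trace = TRUE)
  ev <- st$trace$population_events
  sig <- 0.001 / 12
  for (s in st$spikes) {
    d <- vapply(s, function(t) min(abs(t - ev)), numeric(1))
    expect_true(all(d <= 4 * sig + 1e-12))
  }
  # non-rhythmic event count follows the shifted-exponential closed form
  p2 <- dual_scale_params(Sigma = 0.2, p_fail = 0, f0 = 12,
                          rhythmic = FALSE, N = 5, T = 10)
  counts <- vapply(1:8, function(k) {
    tr <- generate_dual_scale(p2, seed = 100 + k, trace = TRUE)
    length(tr$trace$population_events)
  }, numeric(1))
  expected <- 10 / ((0.05 + exp(-0.05)) / 12)  # ~119.85
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected) / sqrt(8))
  # deletion thinning
  p3 <- dual_scale_params(Sigma = 0.1, p_fail = 0.8, f0 = 12,
                          rhythmic = FALSE, N = 50, T = 10)
  st3 <- generate_dual_scale(p3, seed = 43, trace = TRUE)
  nev <- length(st3$trace$population_events)
  per_neuron <- mean(lengths(st3$spikes))
  expect_lt(abs(per_neuron - 0.2 * nev), 3 * sqrt(0.2 * 0.8 * nev))
})

test_that("Dc = 0 is bit-identical to the non-sequential path", {
  for (fam in c("single", "dual")) {
    if (fam == "single") {
      p0 <- single_scale_params(r0 = 12, m = 0.5, f0 = 12, rhythmic = FALSE,
                                Dc = 0, N = 5, T = 5)
    } else {
      p0 <- dual_scale_params(Sigma = 0.2, p_fail = 0.2, f0 = 12,
                              rhythmic = TRUE, Dc = 0, N = 5, T = 5)
    }
    gen <- if (fam == "single") generate_single_scale else generate_dual_scale
    s1 <- gen(p0, seed = 7)
    s2 <- gen(p0, seed = 7)
    expect_identical(s1$spikes, s2$spikes)  # determinism
  }
})

test_that("benchmark grid reproduces the full design", {
  g <- build_benchmark_grid()
  expect_equal(nrow(g), 900)
  expect_equal(sum(g$family == "single_scale" & !g$sequential), 150)
  expect_equal(sum(g$family == "dual_scale" & !g$sequential), 150)
  expect_equal(sum(g$family == "single_scale" & g$sequential), 300)
  expect_equal(sum(g$family == "dual_scale" & g$sequential), 300)
  # population refractory period formula holds for every entry
  for (i in c(1, 451, 900)) {
    pp <- grid_params(g, i)
    expect_equal(pp$t_refr_pop, 0.1 / (2 * pp$f0))
  }
  # grid trains are reproducible under the master seed
  t1 <- generate_grid_train(g, 3, seed = 5)
  t2 <- generate_grid_train(g, 3, seed = 5)
  expect_identical(t1$spikes, t2$spikes)
})
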