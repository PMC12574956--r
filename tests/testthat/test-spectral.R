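# Population rate, Welch spectrum, and the aperiodic + periodic
# spectral parameterization.

test_that("population rate conserves spike mass", {
  empty <- spike_train(rep(list(numeric(0)), 3), T = 2)
  pr0 <- population_rate(empty)
  expect_true(all(pr0$rate == 0))
  one <- spike_train(list(c(1.0), numeric(0), numeric(0), numeric(0)), T = 2)
  pr1 <- population_rate(one)
  expect_equal(sum(pr1$rate) * pr1$dt, 1 / 4, tolerance = 1e-6)
  s <- sort(runif(50, 0, 2))
  two <- spike_train(list(s, s), T = 2)
  single <- spike_train(list(s), T = 2)
  expect_equal(population_rate(two)$rate, population_rate(single)$rate,
               tolerance = 1e-10)
})

test_that("Welch spectrum localizes a sinusoidal rate and is flat for noise", {
  dt <- 0.001
  tt <- seq(0, 10 - dt, by = dt)
  pr <- list(rate = 10 + 5 * sin(2 * pi * 12 * tt), dt = dt)
  sp <- power_spectrum(pr)
  df <- sp$freq[2] - sp$freq[1]
  expect_lt(abs(sp$f_max - 12), df + 1e-9)
  set.seed(17)
  prn <- list(rate = rnorm(10000), dt = dt)
  spn <- power_spectrum(prn)
  # log-spectrum flat across the band: low/high halves agree
  h <- length(spn$log_power) %/% 2
  m1 <- mean(spn$log_power[1:h])
  m2 <- mean(spn$log_power[(h + 1):length(spn$log_power)])
  expect_lt(abs(m1 - m2), 0.1)
  # constant series is flagged degenerate
  spc <- power_spectrum(list(rate = rep(3, 10000), dt = dt))
  expect_true(spc$degenerate)
  expect_equal(spc$f_max, spc$freq[1])
})

test_that("noiseless aperiodic spectra are recovered exactly", {
  f <- seq(1, 100, by = 0.5)
  lp <- 2 - 1 * log10(f)
  fit <- fit_fooof(f, lp, n_peaks = 1)
  expect_equal(fit$b_L, 2, tolerance = 1e-8)
  expect_equal(fit$chi_L, 1, tolerance = 1e-8)
  expect_equal(fit$R2, 1, tolerance = 1e-8)
  expect_null(fit$peaks)
  # flat spectrum: no significant peak
  fit0 <- fit_fooof(f, rep(1.5, length(f)), n_peaks = 1)
  expect_null(fit0$peaks)
  expect_error(fit_fooof(f[1:4], lp[1:4], n_peaks = 1), "fewer")
})

test_that("a Gaussian bump is recovered within tolerance", {
  f <- seq(1, 100, by = 0.5)
  lp <- 2 - 1 * log10(f) + 0.8 * exp(-(f - 12)^2 / (2 * 2^2))
  set.seed(18)
  lp <- lp + rnorm(length(f), sd = 0.02)
  fit <- fit_fooof(f, lp, n_peaks = 1)
  expect_false(is.null(fit$peaks))
  expect_lt(abs(fit$peaks$f_G[1] - 12), 0.5)
  expect_lt(abs(fit$peaks$A_G[1] - 0.8) / 0.8, 0.1)
})

test_that("randomized spectra are recovered with <10% median error", {
  set.seed(19)
  rel_err <- matrix(NA_real_, 100, 5)
  f <- seq(1, 100, by = 0.5)
  for (k in 1:100) {
    b <- runif(1, 0, 3); chi <- runif(1, 0.5, 2)
    fg <- runif(1, 6, 60); ag <- runif(1, 0.7, 1.5); sg <- runif(1, 1, 4)
    lp <- b - chi * log10(f) + ag * exp(-(f - fg)^2 / (2 * sg^2)) +
      rnorm(length(f), sd = 0.02)
    fit <- fit_fooof(f, lp, n_peaks = 1)
    if (is.null(fit$peaks)) next
    rel_err[k, ] <- abs(c(fit$b_L - b, fit$chi_L - chi,
                          fit$peaks$f_G[1] - fg, fit$peaks$A_G[1] - ag,
                          fit$peaks$sigma_G[1] - sg)) /
      abs(c(b, chi, fg, ag, sg))
  }
  expect_gt(mean(!is.na(rel_err[, 1])), 0.9)
  med <- apply(rel_err, 2, median, na.rm = TRUE)
  expect_true(all(med < 0.10))
})

test_that("rhythmic trains yield spectral peaks, non-rhythmic mostly not", {
  n_peak <- function(rhythmic, m, k) {
    p <- single_scale_params(r0 = 12, m = m, f0 = 12, rhythmic = rhythmic,
                             N = 20, T = 10)
    st <- generate_single_scale(p, seed = 500 + k)
    sv <- spectral_measures(st, "core")
    is.finite(sv["A_G"])
  }
  rhy <- vapply(1:10, function(k) n_peak(TRUE, 1, k), logical(1))
  non <- vapply(1:10, function(k) n_peak(FALSE, 0, k + 50), logical(1))
  expect_gt(mean(rhy), 0.8)
  expect_lt(mean(non), 0.2)
})

test_that("dual-peak spectral measures order peaks by the single-peak center", {
  p <- single_scale_params(r0 = 20, m = 1, f0 = 12, rhythmic = TRUE,
                           N = 30, T = 10)
  st <- generate_single_scale(p, seed = 23)
  sv <- spectral_measures(st, "extended")
  expect_length(sv, 23)
  if (is.finite(sv["f_G"]) && is.finite(sv["f_G_2p1"]) &&
      is.finite(sv["f_G_2p2"])) {
    expect_lte(abs(sv["f_G_2p1"] - sv["f_G"]), abs(sv["f_G_2p2"] - sv["f_G"]))
  }
})
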