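# Measure library: hand-computable identities, oracle equivalences,
# statistical chance levels, symmetry/bound/permutation properties.

test_that("univariate measures on hand inputs", {
  reg <- seq(0.1, 0.9, by = 0.1)  # perfectly regular, ISI = 100 ms
  u <- univariate_measures(reg, T = 1)
  expect_equal(unname(u[c("CV_ISI", "CV2_ISI", "Lv", "IR")]),
               c(0, 0, 0, 0), tolerance = 1e-12)
  u2 <- univariate_measures(c(0.1, 0.2, 0.4), T = 1)
  expect_equal(unname(u2["r"]), 3)
  expect_equal(unname(u2["CV2_ISI"]), 2 * abs(0.2 - 0.1) / 0.3,
               tolerance = 1e-12)
  # too few spikes: rate defined, ISI statistics missing
  u3 <- univariate_measures(c(0.5), T = 1)
  expect_equal(unname(u3["r"]), 1)
  expect_true(all(is.na(u3[-1])))
  expect_error(univariate_measures(c(0.1), T = -1), "T must")
})

test_that("Poisson ISI statistics sit at their theoretical values", {
  set.seed(2)
  cvs <- lvs <- numeric(8)
  for (k in 1:8) {
    s <- poisson_train(10, 100)
    u <- univariate_measures(s, 100)
    cvs[k] <- u["CV_ISI"]
    lvs[k] <- u["Lv"]
  }
  expect_lt(abs(mean(cvs) - 1), 3 * sd(cvs) / sqrt(8))
  expect_lt(abs(mean(lvs) - 1), 3 * sd(lvs) / sqrt(8))
})

test_that("bivariate self-comparison identities", {
  set.seed(4)
  a <- poisson_train(10, 5)
  T <- 5
  expect_equal(victor_purpura(a, a), 0)
  expect_equal(van_rossum(a, a), 0, tolerance = 1e-6)
  expect_equal(earth_movers(a, a, T), 0)
  expect_equal(spike_distance(a, a, T), 0, tolerance = 1e-12)
  expect_equal(isi_distance(a, a, T), 0, tolerance = 1e-12)
  expect_equal(modulus_metric(a, a, T), 0, tolerance = 1e-12)
  expect_equal(schreiber_correlation(a, a), 1, tolerance = 1e-12)
  expect_equal(mean_phase_coherence(a, a), 1, tolerance = 1e-12)
  expect_equal(event_synchronization(a, a, T, adaptive = TRUE)[["Q"]], 1)
  expect_equal(hunter_milton(a, a), 1)
})

test_that("Victor-Purpura edit costs on minimal cases", {
  # deleting the only spike costs 1
  expect_equal(victor_purpura(c(0.1), numeric(0)), 1)
  # a 0.5 ms shift at tau = 1 ms costs 2*0.0005/0.001 = 1 < 2
  expect_equal(victor_purpura(c(0.1000), c(0.1005), tau = 0.001), 1)
  # far spikes: delete + insert
  expect_equal(victor_purpura(c(0.1), c(0.9), tau = 0.001), 2)
})

test_that("Victor-Purpura DP matches the exhaustive matching oracle", {
  vp_oracle <- function(a, b, q) {
    na <- length(a); nb <- length(b)
    best <- na + nb
    if (na > 0 && nb > 0) {
      for (k in seq_len(min(na, nb))) {
        for (ia in utils::combn(na, k, simplify = FALSE))
          for (ib in utils::combn(nb, k, simplify = FALSE)) {
            cost <- (na - k) + (nb - k) + sum(q * abs(a[ia] - b[ib]))
            best <- min(best, cost)
          }
      }
    }
    best
  }
  set.seed(5)
  for (r in 1:40) {
    a <- sort(runif(sample(1:4, 1)))
    b <- sort(runif(sample(1:4, 1)))
    tau <- sample(c(0.05, 0.2, 1), 1)
    expect_equal(victor_purpura(a, b, tau), vp_oracle(a, b, 2 / tau),
                 tolerance = 1e-10)
  }
})

test_that("van Rossum closed form matches the brute-force double sum", {
  set.seed(6)
  for (r in 1:25) {
    pr <- random_pair()
    tau <- sample(c(0.001, 0.01, 0.1), 1)
    E <- function(x, y) sum(exp(-abs(outer(x, y, "-")) / tau))
    brute <- sqrt(max(0, 0.5 * E(pr$a, pr$a) + 0.5 * E(pr$b, pr$b) -
                        E(pr$a, pr$b)))
    expect_equal(van_rossum(pr$a, pr$b, tau), brute, tolerance = 1e-8)
  }
  # distance to the empty train
  expect_equal(van_rossum(sort(runif(5)), numeric(0), 0.001),
               sqrt(5 / 2), tolerance = 1e-6)
})

test_that("independent Poisson pairs sit at chance levels", {
  set.seed(7)
  sttc <- ci <- numeric(10)
  for (k in 1:10) {
    a <- poisson_train(10, 100)
    b <- poisson_train(10, 100)
    sttc[k] <- spike_time_tiling(a, b, 100, tau = 0.005)
    ci[k] <- correlation_index(a, b, 100, tau = 0.005)
  }
  expect_lt(abs(mean(sttc)), 3 * sd(sttc) / sqrt(10))
  expect_lt(abs(mean(ci) - 1), 3 * sd(ci) / sqrt(10))
})

test_that("symmetric measures are symmetric, delay asymmetries flip sign", {
  set.seed(8)
  sym <- c("MPC", "STTC", "C_i", "D_ISI", "D_S", "PPC", "D_VP", "D_VPN",
           "D_vR", "D_vRn", "C_S", "C_K", "S_HM", "S_QQ", "S_QQA",
           "D_EMD", "D_EMDN", "D_MM", "D_MMN")
  for (r in 1:5) {
    pr <- random_pair()
    for (nm in sym) {
      v1 <- bivariate_measure(nm, pr$a, pr$b, pr$T, tau = 0.02)
      v2 <- bivariate_measure(nm, pr$b, pr$a, pr$T, tau = 0.02)
      expect_equal(v1, v2, tolerance = 1e-9, label = nm)
    }
    for (nm in c("S_qq", "S_qqa")) {
      v1 <- bivariate_measure(nm, pr$a, pr$b, pr$T, tau = 0.02)
      v2 <- bivariate_measure(nm, pr$b, pr$a, pr$T, tau = 0.02)
      expect_equal(v1, -v2, tolerance = 1e-9, label = nm)
    }
  }
})

test_that("bounded measures respect their documented ranges", {
  set.seed(9)
  grid <- build_benchmark_grid(N = 6, T = 3)
  idx <- seq(1, 900, by = 37)  # a spread of parameter combinations
  for (i in idx) {
    tr <- generate_grid_train(grid, i, seed = 99)
    mv <- measure_vector(tr, "core")
    expect_true(is.na(mv["S_GR"]) || (mv["S_GR"] >= 0 && mv["S_GR"] <= 1 + 1e-6))
    expect_true(is.na(mv["S_S"]) || (mv["S_S"] >= 0 && mv["S_S"] <= 1))
    expect_true(is.na(mv["S_C"]) || (mv["S_C"] >= 0 && mv["S_C"] <= 1 + 1e-9))
    expect_true(is.na(mv["STTC"]) || abs(mv["STTC"]) <= 1 + 1e-9)
    expect_true(is.na(mv["MPC"]) || (mv["MPC"] >= 0 && mv["MPC"] <= 1 + 1e-9))
    expect_true(is.na(mv["C_S"]) || (mv["C_S"] >= -1e-9 && mv["C_S"] <= 1 + 1e-9))
    expect_true(is.na(mv["S_QQ"]) || (mv["S_QQ"] >= 0 && mv["S_QQ"] <= 1))
    for (d in c("D_VP", "D_vR", "D_EMD", "D_MM"))
      expect_true(is.na(mv[d]) || mv[d] >= 0)
  }
})

test_that("multivariate measures behave on identical and independent trains", {
  st_id <- identical_mnt(8, 10, 10, seed = 10)
  expect_equal(spike_synchronization(st_id), 1)
  expect_gt(golomb_rinzel(st_id, tau = 0.005), 0.99)
  # N independent Poisson trains: chi ~ 1/sqrt(N)
  set.seed(11)
  chis <- vapply(1:6, function(k)
    golomb_rinzel(poisson_mnt(100, 10, 10, seed = 200 + k), tau = 0.01),
    numeric(1))
  expect_lt(abs(mean(chis) - 0.1), 3 * sd(chis) / sqrt(6) + 0.02)
  # synfire indicator prefers sequential trains
  ps <- dual_scale_params(Sigma = 0.1, p_fail = 0, f0 = 12, rhythmic = FALSE,
                          Dc = 0.4, N = 8, T = 10)
  p0 <- dual_scale_params(Sigma = 0.1, p_fail = 0, f0 = 12, rhythmic = FALSE,
                          Dc = 0, N = 8, T = 10)
  fs_seq <- synfire_indicator(generate_dual_scale(ps, seed = 12))
  fs_non <- synfire_indicator(generate_dual_scale(p0, seed = 12))
  expect_gt(fs_seq, fs_non)
})

test_that("non-sequential multivariate measures are permutation invariant", {
  st <- poisson_mnt(7, 12, 5, seed = 13)
  set.seed(14)
  perm <- sample(7)
  stp <- spike_train(st$spikes[perm], st$T)
  expect_equal(tiesinga_sejnowski(st), tiesinga_sejnowski(stp))
  expect_equal(golomb_rinzel(st), golomb_rinzel(stp), tolerance = 1e-10)
  expect_equal(spike_synchronization(st), spike_synchronization(stp))
  expect_equal(spike_contrast(st), spike_contrast(stp))
  expect_equal(synfire_indicator(st), synfire_indicator(stp),
               tolerance = 1e-10)
})

test_that("measure vectors have the documented composition", {
  st <- poisson_mnt(5, 8, 6, seed = 15)
  mv <- measure_vector(st, "core")
  expect_length(mv, 46)
  mve <- measure_vector(st, "extended")
  expect_length(mve, 131)
  spc <- measure_specs("extended")
  expect_equal(sum(is.na(spc$tau)), 34 + 13)  # timescale-free + dual-peak
  expect_equal(sum(!is.na(spc$tau)), 12 * 7)
  # core values agree with the tau = 1 ms columns of the extended set
  ce <- core_from_extended(t(as.matrix(mve)))
  expect_equal(unname(ce[1, ]), unname(mv[colnames(ce)]), tolerance = 1e-9)
  # identical neurons: distances 0, similarities 1
  sti <- identical_mnt(4, 10, 5, seed = 16)
  mvi <- measure_vector(sti, "core")
  expect_equal(unname(mvi[c("D_VP", "D_vR", "D_EMD", "D_MM", "D_S", "D_ISI")]),
               rep(0, 6), tolerance = 1e-6)
  expect_equal(unname(mvi[c("C_S", "MPC", "S_QQA", "S_HM")]),
               rep(1, 4), tolerance = 1e-9)
})

test_that("correlation index tracks the modulation amplitude", {
  # mean C_i increases with m at fixed r0, f0 (single-scale family)
  ms <- c(0, 0.5, 1)
  ci <- vapply(seq_along(ms), function(k) {
    vals <- vapply(1:6, function(r) {
      p <- single_scale_params(r0 = 12, m = ms[k], f0 = 12, rhythmic = TRUE,
                               N = 10, T = 10)
      st <- generate_single_scale(p, seed = 300 + 100 * k + r)
      mean(vapply(utils::combn(10, 2, simplify = FALSE), function(ij)
        correlation_index(st$spikes[[ij[1]]], st$spikes[[ij[2]]], 10),
        numeric(1)))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(ci) > 0))
})
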