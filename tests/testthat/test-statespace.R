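# Windowed recordings: window matrices, clustering/MDS, silhouette
# fingerprinting, A' decoding with synergy, intrinsic dimension.

test_that("windowed matrix tiles the recording and z-scores columns", {
  st <- poisson_mnt(5, 10, 120, seed = 30)
  wm <- windowed_measure_matrix(st, window_s = 30, "core", zscore = FALSE)
  expect_equal(nrow(wm), 4)
  expect_equal(ncol(wm), 46)
  wz <- windowed_measure_matrix(st, window_s = 30, "core", zscore = TRUE)
  r_col <- wz[, "r"]
  expect_equal(mean(r_col), 0, tolerance = 1e-12)
  expect_equal(sd(r_col), 1, tolerance = 1e-12)
  expect_error(windowed_measure_matrix(st, window_s = 100), "two windows")
})

test_that("window similarity/distance/MDS satisfy their geometry", {
  set.seed(31)
  base <- matrix(rnorm(5 * 20), 5, 20)
  wm <- rbind(base, base[1, , drop = FALSE])  # duplicated window
  rownames(wm) <- paste0("w", 1:6)
  D <- window_distance(wm)
  expect_equal(D["w1", "w6"], 0, tolerance = 1e-12)
  xy <- mds_2d(D)
  expect_equal(unname(xy["w1", ]), unname(xy["w6", ]), tolerance = 1e-8)
  # classical MDS of 3 equidistant points: equilateral triangle
  D3 <- matrix(1, 3, 3) - diag(3)
  xyz <- mds_2d(D3)
  dd <- dist(xyz)
  expect_equal(max(dd) - min(dd), 0, tolerance = 1e-9)
})

test_that("windows of the same synthetic recording cluster together", {
  p1 <- single_scale_params(r0 = 25, m = 1, f0 = 12, rhythmic = TRUE,
                            N = 8, T = 60)
  p2 <- dual_scale_params(Sigma = 0.4, p_fail = 0.6, f0 = 4,
                          rhythmic = FALSE, N = 8, T = 60)
  st1 <- generate_single_scale(p1, seed = 32)
  st2 <- generate_dual_scale(p2, seed = 33)
  wm1 <- windowed_measure_matrix(st1, 10, "core", zscore = FALSE)
  wm2 <- windowed_measure_matrix(st2, 10, "core", zscore = FALSE)
  wm <- scale_columns_test(rbind(wm1, wm2))
  rownames(wm) <- paste0("w", 1:12)
  labels <- rep(c("rec1", "rec2"), each = 6)
  D <- window_distance(wm)
  within <- c(D[1:6, 1:6][upper.tri(diag(6))], D[7:12, 7:12][upper.tri(diag(6))])
  across <- D[1:6, 7:12]
  expect_gt(mean(across), mean(within))
  sf <- silhouette_fingerprint(stats::as.dist(D), labels, n_perm = 200,
                               alpha = 0.01, seed = 1)
  expect_gt(sf$mean_s, sf$threshold)
  expect_true(all(abs(sf$s_i) <= 1))
})

test_that("silhouette permutation null rejects random labels", {
  set.seed(34)
  X <- matrix(rnorm(40 * 5), 40, 5)
  labs <- rep(c("a", "b"), each = 20)
  hits <- vapply(1:20, function(k) {
    sf <- silhouette_fingerprint(X, sample(labs), n_perm = 200, alpha = 0.05)
    sf$mean_s > sf$threshold
  }, logical(1))
  expect_lt(mean(hits), 0.25)
  expect_error(silhouette_fingerprint(X, rep("a", 40), n_perm = 10),
               "single label")
})

test_that("A' decoding: separability, chance level, invariance, synergy", {
  set.seed(35)
  labs <- factor(rep(c("wake", "nrem"), each = 50))
  sep <- c(rnorm(50, 0), rnorm(50, 8))
  expect_equal(decode(sep, labs)$A_prime, 1)
  # monotone transform invariance of single-feature A'
  noisy <- c(rnorm(50, 0), rnorm(50, 1.2))
  expect_equal(decode(noisy, labs)$A_prime,
               decode(exp(noisy), labs)$A_prime)
  # label-independent feature stays inside the permutation band
  flat <- rnorm(200)
  labs2 <- factor(rep(c("a", "b"), each = 100))
  d0 <- decode(flat, labs2, n_perm = 200, alpha = 0.01, seed = 2)
  expect_lt(d0$A_prime, d0$threshold)
  # pair decoding with a duplicated feature adds nothing
  X <- cbind(noisy, noisy)
  dp <- decode(X, labs, scheme = "within", seed = 3)
  du <- decode(noisy, labs)
  syn <- decoding_synergy(dp$A_prime, du$A_prime, du$A_prime)
  expect_lt(abs(syn), 0.12)
  expect_equal(decoding_synergy(0.9, 0.8, 0.7), (0.9 - 0.8) / 0.3)
  # LORO scheme runs with recording ids
  rec <- rep(1:4, times = 25)
  dl <- decode(cbind(sep, rnorm(100)), labs, scheme = "loro", recording = rec)
  expect_gt(dl$A_prime, 0.95)
})

test_that("intrinsic dimension estimators recover known manifolds", {
  set.seed(36)
  # rank-1 matrix
  u <- rnorm(60)
  M1 <- outer(u, rnorm(8))
  expect_equal(pca_id(M1, 0.95)$value, 1)
  # isotropic 10-D Gaussian needs all 10 components at 95%
  G <- matrix(rnorm(400 * 10), ncol = 10)
  expect_equal(pca_id(G, 0.95)$value, 10)
  # 2-D plane embedded in 10-D
  X <- cbind(matrix(runif(2 * 1500), ncol = 2), matrix(0, 1500, 8))
  X <- X %*% qr.Q(qr(matrix(rnorm(100), 10)))  # rotate into general position
  tn <- nn_id(X, "twonn", seed = 1)
  expect_lt(abs(tn$value - 2) / 2, 0.1)
  gr <- nn_id(X, "gride", seed = 1)
  expect_true(all(abs(gr$value - 2) / 2 < 0.15))
  # scale invariance
  gr2 <- nn_id(X * 1000, "gride", seed = 1)
  expect_equal(gr$value, gr2$value, tolerance = 1e-6)
  # duplicated points are dropped with a warning
  expect_warning(nn_id(rbind(G, G[1, ]), "twonn", seed = 1), "duplicated")
})
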