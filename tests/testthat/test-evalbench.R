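# Evaluation framework: benchmark orchestration, correlation profiles,
# measure clustering, bias/variability arithmetic, matrix comparison.

small_grid <- function() {
  build_benchmark_grid(N = 5, T = 4, r0 = c(4, 12), m = c(0, 1),
                       Sigma = c(0.1, 0.4), p_fail = c(0, 0.6),
                       f0 = c(12), Dc = c(0, 0.2))
}

test_that("run_benchmark has the shape/determinism contract", {
  g <- small_grid()
  M1 <- run_benchmark(g, "core", seed = 3)
  expect_equal(dim(M1), c(nrow(g), 46))
  M2 <- run_benchmark(g, "core", seed = 3)
  expect_identical(M1, M2)
})

test_that("parameter correlations recover planted structure", {
  g <- small_grid()
  set.seed(20)
  # synthetic measure matrix: col1 = m itself, col2 = noise, col3 = constant
  gs <- g[g$family == "single_scale", ]
  M <- cbind(m_copy = gs$m,
             noise = rnorm(nrow(gs)),
             const = rep(1, nrow(gs)))
  rownames(M) <- paste0("train", gs$id)
  attr(M, "meta") <- gs
  pc <- param_correlations(M, "single_scale")
  expect_equal(unname(pc$rho["m_copy", "m"]), 1)
  expect_lt(unname(pc$rho["m_copy", "rhythmic"]), 0.2,
            label = "orthogonal grid")
  expect_true(is.na(pc$rho["const", "m"]))
  expect_false(isTRUE(pc$significant["const", "m"]))
  expect_equal(pc$order[1], "m_copy")
})

test_that("measure distance matrix is a proper |rho|-based distance", {
  set.seed(21)
  x <- rnorm(50)
  M <- cbind(a = x, b = -x, c = rnorm(50), d = rank(x) + rnorm(50, sd = 0.01))
  D <- measure_distance_matrix(M)
  expect_equal(diag(D), setNames(rep(0, 4), colnames(M)))
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D["a", "b"], 0)           # a measure and its negation
  expect_lt(D["a", "d"], 0.05)           # monotone transform
  # all-missing column excluded with warning
  M2 <- cbind(M, e = NA_real_)
  expect_warning(D2 <- measure_distance_matrix(M2), "excluding")
  expect_false("e" %in% rownames(D2))
})

test_that("average-linkage clustering merges as dictated by D", {
  D <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  D[1:3, 1:3] <- 0
  D[4:5, 4:5] <- 0
  diag(D) <- 0
  cl <- cluster_measures(D)
  h <- cl$hclust$height
  expect_equal(h[1:3], rep(0, 3))        # zero-distance triples merge at 0
  expect_equal(max(h), 1)                # final merge at the inter-block gap
  expect_equal(sort(unname(cl$cut(k = 2))), c(1, 1, 1, 2, 2))
})

test_that("bias/variability statistics match hand arithmetic", {
  s1 <- bias_variability_stats(c(1, 2, 3), S_hat = 2)
  expect_equal(s1$S_bar, 2)
  expect_equal(s1$sigma_S, 1)
  expect_equal(s1$V_S, 0.5)
  expect_equal(s1$B_S, 0)
  s2 <- bias_variability_stats(c(2, 4), S_hat = 1)
  expect_equal(s2$B_S, (3 - 1) / sqrt(2), tolerance = 1e-12)
  s3 <- bias_variability_stats(c(2, 2), S_hat = 2)
  expect_equal(s3$B_S, 0)
  expect_true(is.infinite(bias_variability_stats(c(2, 2), 1)$B_S))
})

test_that("bias/variability sweep applies the exclusion rule and formulas", {
  expect_error(
    bias_variability_sweep("single_scale",
                           list(r0 = 12, m = 0, f0 = 12, rhythmic = TRUE),
                           "time", c(1, 2), N_st = 3),
    "asynchronous")
  res <- bias_variability_sweep("single_scale",
                                list(r0 = 12, m = 0.5, f0 = 12,
                                     rhythmic = TRUE),
                                axis = "time", grid_points = c(1, 4),
                                N_st = 4, fixed = 8, seed = 5)
  expect_true(all(c("S_bar", "sigma_S", "V_S", "B_S", "S_hat") %in%
                    names(res)))
  expect_true(all(res$V_S >= 0, na.rm = TRUE))
  # at the largest grid point S_hat is the mean, so B_S = 0 there
  top <- res[res$point == 4 & is.finite(res$B_S), ]
  expect_true(all(abs(top$B_S) < 1e-9))
  expect_equal(unique(res$N_st), 4)
})

test_that("intermatrix correlation behaves on identity and shuffles", {
  set.seed(22)
  n <- 12
  D1 <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  rownames(D1) <- colnames(D1) <- paste0("m", 1:n)
  expect_equal(intermatrix_correlation(D1, D1), 1)
  cors <- vapply(1:50, function(k) {
    perm <- sample(n)
    D2 <- D1[perm, perm]
    rownames(D2) <- colnames(D2) <- rownames(D1)  # break the alignment
    intermatrix_correlation(D1, D2)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
  expect_error(intermatrix_correlation(unname(D1), unname(D1[1:5, 1:5])),
               "mismatch")
})
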