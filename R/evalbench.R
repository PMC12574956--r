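# Evaluation framework over the synthetic benchmark: measure matrices,
# measure-parameter correlation profiles, empirical clustering of
# measures, finite-sample bias/variability sweeps, and comparison of
# inter-measure geometries.

#' Run the benchmark: one measure vector per grid train
#'
#' Generates every train of a [build_benchmark_grid()] grid (per-train
#' sub-seeds derived from the master seed) and evaluates the chosen
#' measure set, producing the highly comparative data matrix: one row
#' per train, one column per measure, with the grid's generative
#' parameters attached as attribute `"meta"`.
#'
#' @param grid data.frame from [build_benchmark_grid()].
#' @param measure_set `"core"` or `"extended"`.
#' @param seed master seed.
#' @param progress print a dot every 50 trains.
#' @return numeric matrix (trains x measures) with attribute `"meta"`.
#' @export
run_benchmark <- function(grid, measure_set = c("core", "extended"),
                          seed = 1L, progress = FALSE) {
  measure_set <- match.arg(measure_set)
  specs <- measure_specs(measure_set)
  M <- matrix(NA_real_, nrow(grid), nrow(specs),
              dimnames = list(paste0("train", grid$id), specs$name))
  for (i in seq_len(nrow(grid))) {
    tr <- generate_grid_train(grid, i, seed)
    M[i, ] <- measure_vector(tr, measure_set)
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  attr(M, "meta") <- grid
  M
}

#' Correlation profile of measures against generative parameters
#'
#' Absolute Spearman correlation of every measure column with every
#' generative parameter of one synthetic family (single-scale:
#' `m`, `r0`, `f0`, `rhythmic`; dual-scale: `Sigma`, `p_fail`, `f0`,
#' `rhythmic`; the rhythmic flag is encoded 0/1), with significance
#' flags at an uncorrected threshold. Measures are ordered by
#' descending correlation with the synchrony-determining parameter
#' (`m`, or `Sigma` for the dual-scale family).
#'
#' @param dm measure matrix from [run_benchmark()] (attribute `"meta"`
#'   required, or pass `meta`).
#' @param family `"single_scale"` or `"dual_scale"`.
#' @param meta optional grid metadata overriding `attr(dm, "meta")`.
#' @param alpha significance level (uncorrected).
#' @return list with `rho` (measures x parameters matrix of absolute
#'   Spearman correlations), `p` (p-values), `significant` (logical),
#'   `order` (measure names by descending synchrony correlation).
#' @export
param_correlations <- function(dm, family = c("single_scale", "dual_scale"),
                               meta = attr(dm, "meta"), alpha = 0.05) {
  family <- match.arg(family)
  if (is.null(meta)) stop("grid metadata required")
  rows <- meta$family == family
  pars <- if (family == "single_scale") c("m", "r0", "f0", "rhythmic")
          else c("Sigma", "p_fail", "f0", "rhythmic")
  X <- dm[rows, , drop = FALSE]
  P <- meta[rows, pars]
  P$rhythmic <- as.numeric(P$rhythmic)
  rho <- matrix(NA_real_, ncol(X), length(pars),
                dimnames = list(colnames(X), pars))
  pval <- rho
  for (k in seq_along(pars)) {
    for (j in seq_len(ncol(X))) {
      ct <- spearman_test(X[, j], P[[pars[k]]])
      rho[j, k] <- abs(ct$rho)
      pval[j, k] <- ct$p
    }
  }
  sync <- pars[1L]
  ord <- order(rho[, sync], decreasing = TRUE, na.last = TRUE)
  list(rho = rho, p = pval, significant = !is.na(pval) & pval < alpha,
       order = rownames(rho)[ord], synchrony_parameter = sync)
}

# Spearman correlation with a large-sample t approximation for the
# p-value and an exact permutation fallback for small n.
spearman_test <- function(x, y, n_perm = 999L) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  r <- stats::cor(x[ok], y[ok], method = "spearman")
  if (abs(r) >= 1) return(list(rho = r, p = 0))
  if (n >= 20L) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    xs <- x[ok]; ys <- y[ok]
    null <- vapply(seq_len(n_perm), function(i)
      stats::cor(xs, sample(ys), method = "spearman"), numeric(1))
    p <- (1 + sum(abs(null) >= abs(r))) / (n_perm + 1)
  }
  list(rho = r, p = p)
}

#' Empirical distance matrix between measures
#'
#' `D = 1 - |rho|`, where `rho` is the Spearman correlation between
#' each pair of measure columns over the trains (pairwise-complete
#' observations). Measures missing on all rows, constant, or with more
#' than `max_missing` missing fraction are excluded with a warning.
#'
#' @param dm measure matrix (trains x measures).
#' @param max_missing maximum tolerated missing fraction per column.
#' @return symmetric distance matrix in `[0, 1]` with zero diagonal.
#' @export
measure_distance_matrix <- function(dm, max_missing = 0.5) {
  frac_na <- colMeans(is.na(dm))
  sds <- apply(dm, 2L, stats::sd, na.rm = TRUE)
  drop <- frac_na > max_missing | !is.finite(sds) | sds == 0
  if (any(drop))
    warning("excluding ", sum(drop), " measure(s) with too many missing ",
            "or constant values: ", paste(colnames(dm)[drop], collapse = ", "))
  X <- dm[, !drop, drop = FALSE]
  if (ncol(X) < 2L) stop("need at least 2 usable measures")
  rho <- suppressWarnings(stats::cor(X, method = "spearman",
                                     use = "pairwise.complete.obs"))
  rho[!is.finite(rho)] <- 0
  D <- 1 - abs(rho)
  D[D < 0] <- 0
  diag(D) <- 0
  0.5 * (D + t(D))
}

#' Hierarchical clustering of measures
#'
#' Average-linkage agglomerative clustering of the measure distance
#' matrix, with leaves ordered by the height of the first non-singleton
#' cluster each measure joins.
#'
#' @param D distance matrix from [measure_distance_matrix()].
#' @return list with `hclust` (the tree), `leaf_order` (measure names
#'   ordered by first-merge height), and `cut` function
#'   (`cut(k)` or `cut(h = )` returning cluster labels).
#' @export
cluster_measures <- function(D) {
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  lab <- hc$labels
  n <- length(lab)
  first_h <- rep(NA_real_, n)
  for (k in seq_along(hc$height)) {
    mem <- leaves_of_merge(hc, k)
    new <- mem[is.na(first_h[mem])]
    first_h[new] <- hc$height[k]
  }
  list(hclust = hc,
       leaf_order = lab[order(first_h, seq_len(n))],
       cut = function(k = NULL, h = NULL) stats::cutree(hc, k = k, h = h))
}

# leaf indices merged at step k of an hclust tree
leaves_of_merge <- function(hc, k) {
  out <- integer(0)
  stack <- hc$merge[k, ]
  while (length(stack)) {
    v <- stack[1L]
    stack <- stack[-1L]
    if (v < 0) out <- c(out, -v)
    else stack <- c(stack, hc$merge[v, ])
  }
  out
}

#' Finite-sample bias and variability sweep
#'
#' For each grid point of the sampled axis (time-window length or
#' number of neurons), generates `N_st` independent trains of the given
#' family/parameters, evaluates the measure set, and reports per
#' measure and point the across-realization mean `S_bar`, SD `sigma_S`,
#' variability `V_S = |sigma_S / S_bar|`, and bias
#' `B_S = (S_bar - S_hat) / sigma_S`, where the ground-truth proxy
#' `S_hat` is the mean at the largest grid point. When `sigma_S = 0`,
#' `B_S` is 0 if `S_bar = S_hat` and infinite otherwise.
#'
#' @param family `"single_scale"` or `"dual_scale"`.
#' @param params parameter list passed to [single_scale_params()] /
#'   [dual_scale_params()] (without `N` / `T` for the swept axis).
#' @param axis `"time"` (sweep `T`, fixed `N`) or `"space"` (sweep `N`,
#'   fixed `T`).
#' @param grid_points ascending vector of window lengths (s) or neuron
#'   counts.
#' @param N_st realizations per point (default 50).
#' @param fixed value of the non-swept dimension (N for the time axis,
#'   T for the space axis).
#' @param measure_set `"core"` or `"extended"`.
#' @param seed master seed.
#' @return data.frame with columns `measure`, `point`, `S_bar`,
#'   `sigma_S`, `V_S`, `B_S`, `S_hat`, `N_st`, `axis`.
#' @export
bias_variability_sweep <- function(family = c("single_scale", "dual_scale"),
                                   params, axis = c("time", "space"),
                                   grid_points, N_st = 50L, fixed = NULL,
                                   measure_set = c("core", "extended"),
                                   seed = 1L) {
  family <- match.arg(family)
  axis <- match.arg(axis)
  measure_set <- match.arg(measure_set)
  if (is.unsorted(grid_points)) stop("grid_points must be ascending")
  if (N_st < 2L) stop("N_st must be >= 2")
  if (family == "single_scale" && !is.null(params$m) && params$m == 0)
    stop("purely asynchronous trains (single-scale m = 0) are excluded ",
         "from bias/variability sweeps")
  if (is.null(fixed)) fixed <- if (axis == "time") 100L else 100
  specs <- measure_specs(measure_set)
  nmeas <- nrow(specs)
  means <- array(NA_real_, c(length(grid_points), nmeas))
  sds <- means
  ctr <- 0L
  for (g in seq_along(grid_points)) {
    vals <- matrix(NA_real_, N_st, nmeas)
    for (r in seq_len(N_st)) {
      ctr <- ctr + 1L
      sub <- train_subseed(seed, ctr)
      pa <- params
      if (axis == "time") { pa$T <- grid_points[g]; pa$N <- fixed }
      else { pa$N <- grid_points[g]; pa$T <- fixed }
      tr <- if (family == "single_scale")
        generate_single_scale(do.call(single_scale_params, pa), seed = sub)
      else
        generate_dual_scale(do.call(dual_scale_params, pa), seed = sub)
      vals[r, ] <- measure_vector(tr, measure_set)
    }
    means[g, ] <- colMeans(vals, na.rm = TRUE)
    sds[g, ] <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  }
  S_hat <- means[length(grid_points), ]
  out <- expand.grid(measure = specs$name, point = grid_points,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(out$point, grid_points)
  mi <- match(out$measure, specs$name)
  out$S_bar <- means[cbind(gi, mi)]
  out$sigma_S <- sds[cbind(gi, mi)]
  out$V_S <- abs(out$sigma_S / out$S_bar)
  out$S_hat <- S_hat[mi]
  out$B_S <- ifelse(out$sigma_S > 0, (out$S_bar - out$S_hat) / out$sigma_S,
                    ifelse(out$S_bar == out$S_hat, 0, Inf))
  out$N_st <- N_st
  out$axis <- axis
  out
}

#' Eq-style bias and variability statistics for one sample
#'
#' Arithmetic core of the bias/variability sweep on one vector of
#' realizations: mean, SD, absolute coefficient of variation, and the
#' SD-normalized deviation from the ground-truth proxy.
#'
#' @param S_i numeric vector of per-realization measure values.
#' @param S_hat ground-truth proxy.
#' @return list with `S_bar`, `sigma_S`, `V_S`, `B_S`.
#' @export
bias_variability_stats <- function(S_i, S_hat) {
  S_bar <- mean(S_i)
  sigma_S <- stats::sd(S_i)
  V_S <- abs(sigma_S / S_bar)
  B_S <- if (sigma_S > 0) (S_bar - S_hat) / sigma_S
         else if (S_bar == S_hat) 0 else Inf
  list(S_bar = S_bar, sigma_S = sigma_S, V_S = V_S, B_S = B_S)
}

#' Correlation between two inter-measure distance matrices
#'
#' Pearson correlation of the vectorized upper triangles of two
#' distance matrices over the same measure set and ordering (matrices
#' are aligned on their shared row/column names first).
#'
#' @param D1,D2 symmetric distance matrices with dimnames.
#' @return scalar in `[-1, 1]`.
#' @export
intermatrix_correlation <- function(D1, D2) {
  if (!is.null(rownames(D1)) && !is.null(rownames(D2))) {
    common <- intersect(rownames(D1), rownames(D2))
    if (length(common) < 3L) stop("fewer than 3 shared measures")
    D1 <- D1[common, common]
    D2 <- D2[common, common]
  }
  if (!all(dim(D1) == dim(D2))) stop("dimension mismatch")
  ut <- upper.tri(D1)
  stats::cor(D1[ut], D2[ut])
}
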