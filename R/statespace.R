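# Highly comparative analysis of windowed recordings: window-by-measure
# matrices, window clustering and MDS embedding, silhouette-based
# recording fingerprinting with permutation nulls, two-class
# discriminability (A') decoding with synergy, and intrinsic dimension
# estimation (PCA threshold and nearest-neighbor likelihood methods).

#' Window-by-measure matrix of a recording
#'
#' Tiles `[0, T)` with non-overlapping windows of length `window_s`,
#' evaluates the measure set on each window independently (spike times
#' re-referenced to the window start), and optionally z-scores each
#' measure column over windows. Windows without spikes keep their row
#' with NA values.
#'
#' @param train a [spike_train] with `T >= 2 * window_s`.
#' @param window_s window length (s), default 30.
#' @param measure_set `"core"` or `"extended"`.
#' @param zscore z-score columns over windows.
#' @return numeric matrix (windows x measures) with attributes
#'   `"window_s"` and `"window_start"`.
#' @export
windowed_measure_matrix <- function(train, window_s = 30,
                                    measure_set = c("core", "extended"),
                                    zscore = TRUE) {
  measure_set <- match.arg(measure_set)
  if (train$T < 2 * window_s) stop("T must be at least two windows")
  nw <- floor(train$T / window_s)
  starts <- (seq_len(nw) - 1L) * window_s
  specs <- measure_specs(measure_set)
  M <- matrix(NA_real_, nw, nrow(specs),
              dimnames = list(sprintf("w%03d", seq_len(nw)), specs$name))
  for (w in seq_len(nw)) {
    lo <- starts[w]; hi <- lo + window_s
    sub <- lapply(train$spikes, function(s) s[s >= lo & s < hi] - lo)
    M[w, ] <- measure_vector(spike_train(sub, window_s), measure_set)
  }
  if (zscore) M <- scale_columns(M)
  attr(M, "window_s") <- window_s
  attr(M, "window_start") <- starts
  M
}

# z-score columns, NA-tolerant; constant or all-NA columns become NA
scale_columns <- function(M) {
  mu <- colMeans(M, na.rm = TRUE)
  sd <- apply(M, 2L, stats::sd, na.rm = TRUE)
  out <- sweep(M, 2L, mu, "-")
  out <- sweep(out, 2L, ifelse(is.finite(sd) & sd > 0, sd, NA_real_), "/")
  attributes(out)[c("window_s", "window_start")] <-
    attributes(M)[c("window_s", "window_start")]
  out
}

#' Similarity, distance, clustering, and MDS over time windows
#'
#' `window_similarity()` returns the signed Spearman correlation matrix
#' between window rows (pairwise-complete over measures);
#' `window_distance()` the corresponding `D = 1 - rho` matrix;
#' `cluster_windows()` an average-linkage tree over windows with the
#' first-merge leaf ordering; and `mds_2d()` a classical metric MDS
#' embedding of a distance matrix into 2 dimensions.
#'
#' @param wm window-by-measure matrix (rows = windows).
#' @return `window_similarity`: correlation matrix;
#'   `window_distance`: distance matrix; `cluster_windows`: as
#'   [cluster_measures()]; `mds_2d`: windows x 2 coordinate matrix.
#' @export
window_similarity <- function(wm) {
  keep <- rowSums(is.finite(wm)) >= 3L
  if (any(!keep))
    warning("excluding ", sum(!keep), " window(s) with <3 finite measures")
  rho <- suppressWarnings(stats::cor(t(wm[keep, , drop = FALSE]),
                                     method = "spearman",
                                     use = "pairwise.complete.obs"))
  dimnames(rho) <- list(rownames(wm)[keep], rownames(wm)[keep])
  rho
}

#' @rdname window_similarity
#' @export
window_distance <- function(wm) {
  rho <- window_similarity(wm)
  D <- 1 - rho
  D[!is.finite(D)] <- 1
  diag(D) <- 0
  0.5 * (D + t(D))
}

#' @rdname window_similarity
#' @export
cluster_windows <- function(wm) {
  if (nrow(wm) < 3L) stop("need at least 3 windows")
  cluster_measures(window_distance(wm))
}

#' @rdname window_similarity
#' @param D a symmetric distance matrix (e.g. [window_distance()]).
#' @export
mds_2d <- function(D) {
  xy <- stats::cmdscale(stats::as.dist(D), k = 2)
  colnames(xy) <- c("mds1", "mds2")
  xy
}

#' Recording fingerprinting by silhouette score
#'
#' Quantifies how strongly windows of the same recording cluster
#' together: the silhouette score of each window under the recording
#' labels, its mean, and a permutation null obtained by shuffling
#' labels over windows; the significance threshold is the
#' `(1 - alpha)` quantile of permuted mean silhouettes.
#'
#' @param space windows x features matrix (Euclidean distances are
#'   used; NA entries are median-imputed) or a `dist`/distance matrix.
#' @param labels recording identifier per window (>= 2 levels, each
#'   with >= 2 windows).
#' @param n_perm number of label permutations.
#' @param alpha significance level of the permutation threshold.
#' @param seed optional seed for the permutation stream.
#' @return list of class `silhouette_result`: `s_i` (per window),
#'   `mean_s`, `threshold`, `alpha`, `n_perm`, `perm_means`.
#' @export
silhouette_fingerprint <- function(space, labels, n_perm = 1000L,
                                   alpha = 0.001, seed = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("silhouette undefined for a single label")
  if (any(table(labels) < 2L)) stop("every label needs at least 2 windows")
  if (inherits(space, "dist")) {
    d <- space
  } else if (is.matrix(space) && isSymmetric(unname(space)) &&
             all(abs(diag(space)) < 1e-12) && nrow(space) == length(labels)) {
    d <- stats::as.dist(space)
  } else {
    X <- as.matrix(space)
    for (j in seq_len(ncol(X))) {
      bad <- !is.finite(X[, j])
      if (any(bad)) X[bad, j] <- stats::median(X[, j], na.rm = TRUE)
    }
    X <- X[, apply(X, 2L, function(v) all(is.finite(v))), drop = FALSE]
    d <- stats::dist(X)
  }
  if (!is.null(seed)) set.seed(seed)
  li <- as.integer(labels)
  sil <- cluster::silhouette(li, d)
  s_i <- sil[, "sil_width"]
  perm <- vapply(seq_len(n_perm), function(k) {
    mean(cluster::silhouette(sample(li), d)[, "sil_width"])
  }, numeric(1))
  structure(list(s_i = s_i, mean_s = mean(s_i),
                 threshold = stats::quantile(perm, 1 - alpha, names = FALSE),
                 alpha = alpha, n_perm = n_perm, perm_means = perm),
            class = "silhouette_result")
}

# rank-based area under the ROC curve of scores against binary labels
auc_score <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-class discriminability (A') of measures
#'
#' Nonparametric two-class discriminability of one feature or a feature
#' pair, equivalent to the area under the ROC curve of held-out
#' classifier scores. A single feature is its own (monotone-invariant)
#' score, folded so that the reported value is `max(AUC, 1 - AUC)`; a
#' feature pair is read out by a logistic linear classifier on z-scored
#' features under cross-validation: stratified k-fold within a
#' recording (`scheme = "within"`) or leave-one-recording-out
#' (`scheme = "loro"`). Optional label permutations give significance
#' thresholds.
#'
#' @param features numeric vector (one feature) or 2-column matrix
#'   (feature pair), one row per window.
#' @param labels binary state label per window.
#' @param scheme `"within"` or `"loro"`.
#' @param recording recording id per window (required for `"loro"`).
#' @param n_folds folds for the within-recording scheme.
#' @param n_perm label permutations for the null (0 = none).
#' @param alpha significance level for the permutation threshold.
#' @param seed optional seed (fold assignment and permutations).
#' @return list of class `decoding_result`: `A_prime`, `scheme`,
#'   `threshold` (NA if `n_perm = 0`), `perm_A`, `n`.
#' @export
decode <- function(features, labels, scheme = c("within", "loro"),
                   recording = NULL, n_folds = 5L, n_perm = 0L,
                   alpha = 0.01, seed = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 classes")
  ok <- rowSums(!is.finite(X)) == 0L
  X <- X[ok, , drop = FALSE]
  labels <- droplevels(labels[ok])
  if (!is.null(recording)) recording <- recording[ok]
  if (nlevels(labels) != 2L) stop("a class is absent after NA removal")
  if (!is.null(seed)) set.seed(seed)
  ap <- cv_a_prime(X, labels, scheme, recording, n_folds)
  perm <- numeric(0)
  thr <- NA_real_
  if (n_perm > 0L) {
    perm <- vapply(seq_len(n_perm), function(k)
      cv_a_prime(X, sample(labels), scheme, recording, n_folds),
      numeric(1))
    thr <- stats::quantile(perm, 1 - alpha, na.rm = TRUE, names = FALSE)
  }
  structure(list(A_prime = ap, scheme = scheme, threshold = thr,
                 perm_A = perm, n = nrow(X)),
            class = "decoding_result")
}

cv_a_prime <- function(X, labels, scheme, recording, n_folds) {
  if (ncol(X) == 1L) {
    a <- auc_score(X[, 1L], labels)
    return(max(a, 1 - a))
  }
  y <- as.integer(labels) - 1L
  folds <- if (scheme == "loro") {
    if (is.null(recording)) stop("recording ids required for LORO")
    as.integer(as.factor(recording))
  } else {
    f <- integer(length(y))
    for (cl in 0:1) {
      idx <- which(y == cl)
      f[idx] <- rep_len(seq_len(n_folds), length(idx))[sample(length(idx))]
    }
    f
  }
  scores <- rep(NA_real_, length(y))
  for (fd in unique(folds)) {
    te <- folds == fd
    tr <- !te
    if (length(unique(y[tr])) < 2L) {
      warning("class absent in a training fold; fold skipped")
      next
    }
    mu <- colMeans(X[tr, , drop = FALSE])
    sd <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sd[sd == 0] <- 1
    Z <- sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
    df <- data.frame(y = y[tr], Z[tr, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    scores[te] <- suppressWarnings(
      stats::predict(fit, newdata = data.frame(Z[te, , drop = FALSE]),
                     type = "link"))
  }
  if (all(is.na(scores))) stop("all folds skipped")
  keep <- !is.na(scores)
  auc_score(scores[keep], labels[keep])
}

#' Decoding synergy of a feature pair
#'
#' Normalized improvement of pair decoding over the best constituent:
#' `(A_xy - max(A_x, A_y)) / (max(A_x, A_y) - 0.5)`. Zero for a
#' duplicated feature; negative when pairing hurts the linear readout.
#'
#' @param A_xy pair discriminability.
#' @param A_x,A_y single-feature discriminabilities.
#' @return synergy as a fraction (multiply by 100 for percent).
#' @export
decoding_synergy <- function(A_xy, A_x, A_y) {
  best <- max(A_x, A_y)
  if (best <= 0.5) return(NA_real_)
  (A_xy - best) / (best - 0.5)
}

#' Intrinsic dimension by PCA variance threshold
#'
#' Number of principal components needed to reach a cumulative
#' explained-variance threshold, on z-scored columns with median
#' imputation of missing entries.
#'
#' @param X data matrix (rows = items, columns = coordinates).
#' @param threshold cumulative variance threshold (e.g. 0.95 or 0.99).
#' @return list of class `id_estimate`: `method = "pca"`, `value`,
#'   `threshold`, `cumvar`.
#' @export
pca_id <- function(X, threshold = 0.95) {
  X <- impute_median(as.matrix(X))
  keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  cv <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  structure(list(method = "pca", value = which(cv >= threshold)[1L],
                 threshold = threshold, cumvar = cv),
            class = "id_estimate")
}

impute_median <- function(X) {
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- stats::median(X[, j], na.rm = TRUE)
  }
  X[, colSums(!is.finite(X)) == 0L, drop = FALSE]
}

#' Intrinsic dimension from nearest-neighbor distance ratios
#'
#' Likelihood-based intrinsic dimension of a point cloud from ratios of
#' neighbor distances, reported across scales. `method = "twonn"` uses
#' the ratio of second to first neighbor distances with the scale
#' varied by random subsampling (decimating points probes larger
#' scales); `method = "gride"` generalizes to ratios `r_{2k} / r_k` of
#' neighbor ranks `k = 1, 2, 4, ...` (larger ranks probe larger
#' scales) and maximizes the exact rank-ratio likelihood. Standard
#' errors come from the observed Fisher information. Points duplicated
#' at zero distance are removed first. Estimates are invariant to
#' global scaling of the coordinates.
#'
#' @param X data matrix (rows = points); z-score columns beforehand if
#'   coordinates have heterogeneous units.
#' @param method `"twonn"` or `"gride"`.
#' @param scales for `"gride"`, neighbor ranks `k` (default powers of 2
#'   up to n/4); for `"twonn"`, subsample fractions (default
#'   `1, 1/2, 1/4, ...` down to 64 points).
#' @param n_rep subsample repetitions per scale for `"twonn"`.
#' @param seed optional seed for subsampling.
#' @return list of class `id_estimate`: `method`, `value` (estimate at
#'   the smallest scale for `"twonn"`, vector over ranks for
#'   `"gride"`), and `by_scale` (data.frame with `scale`, `id`, `sem`).
#' @export
nn_id <- function(X, method = c("twonn", "gride"), scales = NULL,
                  n_rep = 5L, seed = NULL) {
  method <- match.arg(method)
  X <- impute_median(as.matrix(X))
  D <- as.matrix(stats::dist(X))
  # drop duplicated points (zero nearest-neighbor distance)
  repeat {
    nn1 <- apply(D + diag(Inf, nrow(D)), 1L, min)
    dup <- which(nn1 == 0)
    if (!length(dup)) break
    warning("removing ", length(dup), " duplicated point(s)")
    D <- D[-dup[1L], -dup[1L], drop = FALSE]
  }
  n <- nrow(D)
  if (n < 10L) stop("too few distinct points")
  if (!is.null(seed)) set.seed(seed)
  if (method == "twonn") {
    if (is.null(scales)) {
      scales <- 1 / 2^(0:20)
      scales <- scales[scales * n >= 64]
      if (!length(scales)) scales <- 1
    }
    rows <- lapply(scales, function(fr) {
      reps <- vapply(seq_len(max(1L, if (fr < 1) n_rep else 1L)), function(r) {
        idx <- if (fr < 1) sort(sample(n, round(fr * n))) else seq_len(n)
        twonn_mle(D[idx, idx])
      }, numeric(2))
      data.frame(scale = fr, id = mean(reps[1, ]), sem = mean(reps[2, ]))
    })
    by_scale <- do.call(rbind, rows)
    value <- by_scale$id[1L]
  } else {
    if (is.null(scales)) {
      scales <- 2^(0:20)
      scales <- scales[2 * scales <= max(4L, n %/% 4L)]
    }
    Dsort <- t(apply(D, 1L, sort))  # col k = k-th neighbor distance (col 1 = self)
    rows <- lapply(scales, function(k) {
      mu <- Dsort[, 2L * k + 1L] / Dsort[, k + 1L]
      est <- gride_mle(mu, k)
      data.frame(scale = k, id = est[1L], sem = est[2L])
    })
    by_scale <- do.call(rbind, rows)
    value <- by_scale$id
  }
  structure(list(method = method, value = value, by_scale = by_scale),
            class = "id_estimate")
}

# ratio-of-distances maximum likelihood (first vs second neighbor):
# mu = r2/r1 has density d * mu^(-d-1), MLE d = n / sum(log mu)
twonn_mle <- function(D) {
  n <- nrow(D)
  Dx <- D + diag(Inf, n)
  r1 <- apply(Dx, 1L, min)
  r2 <- apply(Dx, 1L, function(v) sort(v, partial = 2L)[2L])
  lmu <- log(r2 / r1)
  lmu <- lmu[is.finite(lmu) & lmu > 0]
  d <- length(lmu) / sum(lmu)
  c(d, d / sqrt(length(lmu)))
}

# rank-ratio maximum likelihood: u = mu^(-d) with mu = r_{2k}/r_k is
# Beta(k, k); profile the log-likelihood in d numerically
gride_mle <- function(mu, k) {
  mu <- mu[is.finite(mu) & mu > 1]
  if (length(mu) < 5L) return(c(NA_real_, NA_real_))
  lmu <- log(mu)
  negll <- function(d) {
    u <- exp(-d * lmu)
    -sum(log(d) - (k - 1) * d * lmu - (d + 1) * lmu +
           (k - 1) * log1p(-u))
  }
  opt <- stats::optimize(negll, c(1e-3, 200))
  d <- opt$minimum
  h <- 1e-3 * max(d, 1)
  curv <- (negll(d + h) - 2 * negll(d) + negll(d - h)) / h^2
  sem <- if (is.finite(curv) && curv > 0) 1 / sqrt(curv) else NA_real_
  c(d, sem)
}
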