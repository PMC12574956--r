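# Multivariate measures: a single scalar per multineuron spike train,
# computed from all constituent single-neuron trains jointly.

#' Tiesinga-Sejnowski synchrony
#'
#' Synchrony from the pooled spike train: the coefficient of variation
#' of the pooled inter-spike intervals exceeds 1 when spikes cluster
#' into population events; `S_TS = (CV_pool - 1) / sqrt(N)` is ~0 for
#' asynchronous Poisson firing and ~1 for full synchrony.
#'
#' @param train a [spike_train].
#' @return scalar, NA if the pooled train has fewer than 3 spikes.
#' @export
tiesinga_sejnowski <- function(train) {
  pooled <- sort(unlist(train$spikes))
  if (length(pooled) < 3L) return(NA_real_)
  isi <- diff(pooled)
  if (mean(isi) == 0) return(NA_real_)
  (stats::sd(isi) / mean(isi) - 1) / sqrt(train$N)
}

#' Golomb-Rinzel synchrony
#'
#' Variance-ratio synchrony of kernel-smoothed activity traces:
#' `chi^2 = Var_t(population mean trace) / mean_j Var_t(trace_j)`, with
#' each neuron's spike train binned and smoothed by a Gaussian kernel of
#' SD `tau`. Identical trains give 1; N independent trains give ~
#' `1/sqrt(N)`.
#'
#' @param train a [spike_train].
#' @param tau smoothing kernel SD (s).
#' @param dt_grid bin width of the activity grid (s).
#' @return value in `[0, 1]` (up to sampling noise), NA if no spikes.
#' @export
golomb_rinzel <- function(train, tau = 0.001, dt_grid = 0.001) {
  sm <- smoothed_activity(train, tau, dt_grid)
  golomb_rinzel_from_traces(sm)
}

golomb_rinzel_from_traces <- function(sm) {
  if (all(sm == 0)) return(NA_real_)
  pop <- rowMeans(sm)
  num <- stats::var(pop)
  den <- mean(apply(sm, 2L, stats::var))
  if (den == 0) return(NA_real_)
  sqrt(num / den)
}

# bins x neurons matrix of Gaussian-smoothed spike counts (FFT
# convolution, zero-padded to avoid wrap-around)
smoothed_activity <- function(train, tau, dt_grid = 0.001) {
  B <- binned_counts(train, dt_grid)
  smooth_columns_fft(B, sigma_bins = tau / dt_grid)
}

binned_counts <- function(train, dt_grid = 0.001) {
  nb <- max(1L, ceiling(train$T / dt_grid))
  vapply(train$spikes, function(s)
    as.numeric(tabulate(pmin(nb, floor(s / dt_grid) + 1L), nbins = nb)),
    numeric(nb))
}

# Golomb-Rinzel chi over several smoothing timescales, sharing one
# forward FFT of the binned count matrix across kernels.
golomb_rinzel_all_taus <- function(train, taus, dt_grid = 0.001) {
  B <- binned_counts(train, dt_grid)
  if (all(B == 0)) return(rep(NA_real_, length(taus)))
  n <- nrow(B)
  half_max <- ceiling(4 * max(taus) / dt_grid)
  np <- stats::nextn(n + 2L * half_max + 1L, c(2, 3, 5))
  FB <- stats::mvfft(rbind(B, matrix(0, np - n, ncol(B))))
  vapply(taus, function(tt) {
    sb <- tt / dt_grid
    half <- ceiling(4 * sb)
    k <- stats::dnorm(seq(-half, half), sd = sb)
    k <- k / sum(k)
    kpad <- numeric(np)
    kpad[1:(half + 1L)] <- k[(half + 1L):(2L * half + 1L)]
    kpad[(np - half + 1L):np] <- k[1:half]
    K <- stats::fft(kpad)
    sm <- Re(stats::mvfft(FB * K, inverse = TRUE))[seq_len(n), , drop = FALSE] / np
    golomb_rinzel_from_traces(sm)
  }, numeric(1))
}

smooth_columns_fft <- function(B, sigma_bins) {
  if (sigma_bins <= 0) return(B)
  n <- nrow(B)
  half <- ceiling(4 * sigma_bins)
  np <- stats::nextn(n + 2L * half + 1L, c(2, 3, 5))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  kpad <- numeric(np)
  kpad[1:(half + 1L)] <- k[(half + 1L):(2L * half + 1L)]
  kpad[(np - half + 1L):np] <- k[1:half]
  K <- stats::fft(kpad)
  Bp <- rbind(B, matrix(0, np - n, ncol(B)))
  F <- stats::mvfft(Bp)
  out <- Re(stats::mvfft(F * K, inverse = TRUE)) / np
  out[seq_len(n), , drop = FALSE]
}

#' SPIKE-synchronization
#'
#' Fraction of spikes that are part of a pairwise coincidence under the
#' timescale-adaptive window (half the minimum adjacent inter-spike
#' interval), averaged over all spikes and partner trains. 1 when every
#' spike has a matching partner in every other train; ~0 for sparse
#' independent firing.
#'
#' @param train a [spike_train] with `N >= 2`.
#' @return value in `[0, 1]`, NA if no spikes.
#' @export
spike_synchronization <- function(train) {
  N <- train$N
  if (N < 2L) return(NA_real_)
  total_hits <- 0
  total_spikes <- sum(lengths(train$spikes))
  if (total_spikes == 0L) return(NA_real_)
  for (i in seq_len(N - 1L)) {
    for (j in seq.int(i + 1L, N)) {
      h <- spike_sync_pair_cpp(train$spikes[[i]], train$spikes[[j]])
      total_hits <- total_hits + h[1] + h[2]
    }
  }
  total_hits / ((N - 1L) * total_spikes)
}

#' Synfire indicator
#'
#' Strength of sequential (leader-to-follower) structure: the adaptive
#' delay asymmetry is computed for every train pair, and neurons are
#' ordered to maximize the mean signed asymmetry over ordered pairs;
#' `F_S` is that maximum. The optimal ordering is found exhaustively for
#' `N <= max_exact` and by a leadership-score ordering with adjacent-swap
#' refinement above. Invariant under neuron relabeling by construction.
#'
#' @param train a [spike_train] with `N >= 2`.
#' @param max_exact largest N for exhaustive ordering search.
#' @return value in `[-1, 1]`, NA if fewer than 2 non-empty trains.
#' @export
synfire_indicator <- function(train, max_exact = 8L) {
  N <- train$N
  if (N < 2L) return(NA_real_)
  # A[x, y] = degree to which y follows x
  A <- matrix(0, N, N)
  any_pair <- FALSE
  for (i in seq_len(N - 1L)) {
    for (j in seq.int(i + 1L, N)) {
      q <- event_synchronization(train$spikes[[i]], train$spikes[[j]],
                                 train$T, adaptive = TRUE)[["q"]]
      if (is.na(q)) next
      any_pair <- TRUE
      A[j, i] <- q   # q > 0: i follows j  => i follows leader j
      A[i, j] <- -q
    }
  }
  if (!any_pair) return(NA_real_)
  best_ordering_score(A, max_exact)
}

# apply f to every permutation of v (Heap's algorithm, small N only)
perm_apply <- function(v, f) {
  n <- length(v)
  c_idx <- integer(n)
  f(v)
  i <- 1L
  while (i <= n) {
    if (c_idx[i] < i - 1L) {
      if (i %% 2L == 1L) v[c(1L, i)] <- v[c(i, 1L)]
      else {
        k <- c_idx[i] + 1L
        v[c(k, i)] <- v[c(i, k)]
      }
      f(v)
      c_idx[i] <- c_idx[i] + 1L
      i <- 1L
    } else {
      c_idx[i] <- 0L
      i <- i + 1L
    }
  }
  invisible(NULL)
}

#' Spike-contrast synchrony
#'
#' Timescale-free synchrony: for a cascade of bin sizes (from `T/2`
#' halving down to `bin_min`), half-overlapping bins of the pooled train
#' give a contrast term (temporal clustering of the population count)
#' and an active-train term (fraction of trains participating per bin);
#' the synchrony curve is their product and `S_C` is its maximum over
#' bin sizes. 1 for N identical trains.
#'
#' @param train a [spike_train] with `N >= 2`.
#' @param bin_min smallest bin size of the cascade (s).
#' @return value in `[0, 1]`, NA if no spikes or `N < 2`.
#' @export
spike_contrast <- function(train, bin_min = 0.001) {
  N <- train$N
  if (N < 2L) return(NA_real_)
  pooled <- sort(unlist(train$spikes))
  if (length(pooled) < 2L) return(NA_real_)
  Tw <- train$T
  dt <- Tw / 2
  best <- 0
  while (dt >= bin_min) {
    # half-overlapping bins [k*dt/2, k*dt/2 + dt), k = 0, 1, ...
    nbin <- ceiling(2 * Tw / dt)
    k1 <- floor(2 * pooled / dt)            # second bin containing t
    k0 <- k1 - 1L                           # first bin containing t
    idx <- c(k0[k0 >= 0L], k1) + 1L
    theta <- tabulate(idx, nbins = nbin)
    tot <- sum(theta)
    if (tot > 0) {
      contrast <- sum(abs(diff(theta))) / (2 * tot)
      # spikes weighted by the number of distinct active trains per bin
      nact <- numeric(nbin)
      for (j in seq_len(N)) {
        s <- train$spikes[[j]]
        if (!length(s)) next
        kj1 <- floor(2 * s / dt)
        kj0 <- kj1 - 1L
        u <- unique(c(kj0[kj0 >= 0L], kj1) + 1L)
        nact[u] <- nact[u] + 1
      }
      active <- (sum(nact * theta) / tot - 1) / (N - 1)
      best <- max(best, contrast * max(0, active))
    }
    dt <- dt / 2
  }
  best
}

#' Evaluate one multivariate measure by name
#'
#' @param name one of S_TS, S_GR, S_S, F_S, S_C.
#' @param train a [spike_train].
#' @param tau timescale (s), used by S_GR only.
#' @export
multivariate_measure <- function(name, train, tau = 0.001) {
  switch(name,
    S_TS = tiesinga_sejnowski(train),
    S_GR = golomb_rinzel(train, tau),
    S_S = spike_synchronization(train),
    F_S = synfire_indicator(train),
    S_C = spike_contrast(train),
    stop("unknown multivariate measure: ", name))
}
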