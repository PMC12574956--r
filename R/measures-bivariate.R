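# Bivariate spike train measures.
#
# Each function compares two single-neuron spike trains (sorted times
# over [0, T)). Timescale-dependent measures take the timescale tau in
# seconds: it is the coincidence/bin/tiling width for the count-based
# measures (C_i, STTC, C_K, S_QQ, S_qq), the kernel SD for the
# filtered-train correlations (C_S) and similarities (S_HM), the kernel
# decay constant for the van Rossum distance, and sets the shift cost
# 2|dt|/tau of the Victor-Purpura distance (so that a shift of exactly
# tau costs the same as delete + insert). Empty trains yield NA except
# where the distance to an empty train is well defined (D_VP, D_vR,
# D_EMD and normalized variants).

.biv_names <- c("MPC", "STTC", "C_i", "D_ISI", "D_S", "PPC",
                "D_VP", "D_VPN", "D_vR", "D_vRn", "D_LZ", "C_S", "C_K",
                "S_HM", "S_QQ", "S_qq", "S_QQA", "S_qqa",
                "D_EMD", "D_EMDN", "D_MM", "D_MMN")

.tau_dependent <- c("S_GR", "STTC", "C_i", "D_VP", "D_VPN", "D_vR",
                    "D_vRn", "C_S", "C_K", "S_HM", "S_QQ", "S_qq")

# --- phase-based measures -------------------------------------------------

# Linear-interpolation phases of `a`'s spikes within `b`'s inter-spike
# cycles; spikes outside b's span are dropped.
relative_phases <- function(a, b) {
  if (length(b) < 2L || length(a) == 0L) return(numeric(0))
  keep <- a >= b[1] & a < b[length(b)]
  a <- a[keep]
  if (!length(a)) return(numeric(0))
  j <- findInterval(a, b)
  2 * pi * (a - b[j]) / (b[j + 1L] - b[j])
}

mpc_dir <- function(a, b) {
  ph <- relative_phases(a, b)
  if (!length(ph)) return(NA_real_)
  sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
}

#' Mean phase coherence of a spike train pair
#'
#' Resultant length of the relative phases of each train's spikes within
#' the other train's inter-spike cycles (the Kuramoto order parameter of
#' the relative phase distribution), averaged over both directions.
#' Identical trains give 1.
#'
#' @param a,b sorted spike time vectors (s).
#' @return value in `[0, 1]`, or NA if no phases can be assigned.
#' @export
mean_phase_coherence <- function(a, b) {
  mean(c(mpc_dir(a, b), mpc_dir(b, a)), na.rm = TRUE)
}

ppc_dir <- function(a, b) {
  ph <- relative_phases(a, b)
  n <- length(ph)
  if (n < 2L) return(NA_real_)
  R2 <- sum(cos(ph))^2 + sum(sin(ph))^2
  (R2 - n) / (n * (n - 1))
}

#' Pairwise phase consistency
#'
#' Bias-free average cosine of phase differences between all spike pairs
#' (the unbiased counterpart of the squared resultant length), computed
#' on relative phases in both directions and averaged.
#'
#' @inheritParams mean_phase_coherence
#' @return value in `[-1, 1]`, NA if fewer than 2 phases per direction.
#' @export
pairwise_phase_consistency <- function(a, b) {
  mean(c(ppc_dir(a, b), ppc_dir(b, a)), na.rm = TRUE)
}

# --- coincidence-based measures ------------------------------------------

#' Spike time tiling coefficient
#'
#' Rate-robust coincidence measure: `P_A` is the fraction of spikes of
#' one train falling within `+-tau` of a spike of the other, `T_A` the
#' fraction of the window tiled by `+-tau` around the spikes;
#' `STTC = ((P_A - T_B)/(1 - P_A T_B) + (P_B - T_A)/(1 - P_B T_A)) / 2`.
#'
#' @inheritParams mean_phase_coherence
#' @param T window length (s).
#' @param tau tiling half-width (s).
#' @return value in `[-1, 1]`, NA for empty trains.
#' @export
spike_time_tiling <- function(a, b, T, tau = 0.001) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(NA_real_)
  PA <- count_hits(a, b, tau) / na
  PB <- count_hits(b, a, tau) / nb
  TA <- tiling_coverage_cpp(a, tau, T) / T
  TB <- tiling_coverage_cpp(b, tau, T) / T
  t1 <- if (PA * TB < 1) (PA - TB) / (1 - PA * TB) else NA_real_
  t2 <- if (PB * TA < 1) (PB - TA) / (1 - PB * TA) else NA_real_
  mean(c(t1, t2), na.rm = TRUE)
}

# number of spikes of a with at least one spike of b within +-tau
count_hits <- function(a, b, tau) {
  d <- nearest_dist_cpp(a, b)
  sum(d <= tau)
}

#' Correlation index
#'
#' Ratio of the observed number of spike pairs coincident within
#' `+-tau` to the number expected for independent homogeneous trains:
#' `C_i = N_coinc T / (2 tau n_a n_b)`. Independent Poisson trains give
#' values near 1; synchronous trains give values well above 1.
#'
#' @inheritParams spike_time_tiling
#' @return non-negative value, NA for empty trains.
#' @export
correlation_index <- function(a, b, T, tau = 0.001) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(NA_real_)
  count_within_cpp(a, b, tau) * T / (2 * tau * na * nb)
}

#' Event synchronization and delay asymmetry
#'
#' Directed counts of spikes of one train closely following spikes of
#' the other, within a fixed window `tau` (`adaptive = FALSE`) or the
#' adaptive window of half the minimum adjacent inter-spike interval
#' (`adaptive = TRUE`). Returns the symmetric synchronization
#' `Q = (c_ab + c_ba)/sqrt(n_a n_b)` and the antisymmetric delay
#' asymmetry `q = (c_ab - c_ba)/sqrt(n_a n_b)` (positive when the first
#' train tends to follow the second, i.e. the second train leads).
#'
#' @inheritParams spike_time_tiling
#' @param adaptive use the timescale-adaptive local window.
#' @return named vector `c(Q = ..., q = ...)`, NA for empty trains.
#' @export
event_synchronization <- function(a, b, T, tau = 0.001, adaptive = FALSE) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(c(Q = NA_real_, q = NA_real_))
  cc <- if (adaptive) qq_adaptive_cpp(a, b) else qq_counts_cpp(a, b, tau)
  den <- sqrt(na * nb)
  c(Q = min(1, (cc[1] + cc[2]) / den), q = (cc[1] - cc[2]) / den)
}

# --- distance measures ----------------------------------------------------

#' Victor-Purpura spike train distance
#'
#' Minimum-cost edit distance between two spike trains: insertions and
#' deletions cost 1, shifting a spike by `dt` costs `2 |dt| / tau`, so a
#' shift of exactly `tau` equals delete + insert. The normalized variant
#' divides by the total spike count `n_a + n_b` (the linear component of
#' the distance's spike-count dependence).
#'
#' @inheritParams spike_time_tiling
#' @param normalized divide by `n_a + n_b`.
#' @return non-negative distance; distance to an empty train is the
#'   other train's spike count (1 after normalization).
#' @export
victor_purpura <- function(a, b, tau = 0.001, normalized = FALSE) {
  d <- vp_distance_cpp(a, b, 2 / tau)
  if (normalized) {
    n <- length(a) + length(b)
    if (n == 0L) return(NA_real_)
    d <- d / n
  }
  d
}

#' Van Rossum spike train distance
#'
#' L2 distance between the trains convolved with causal exponential
#' kernels `exp(-t/tau)`, computed in closed form:
#' `D^2 = (E(a,a) + E(b,b))/2 - E(a,b)` with
#' `E(x,y) = sum_ij exp(-|x_i - y_j|/tau)`. The normalized variant
#' divides by `sqrt((n_a + n_b)/2)`, the distance of an
#' `(n_a + n_b)`-spike train to the empty train.
#'
#' @inheritParams victor_purpura
#' @return non-negative distance.
#' @export
van_rossum <- function(a, b, tau = 0.001, normalized = FALSE) {
  d2 <- 0.5 * exp_cross_sum_cpp(a, a, tau) + 0.5 * exp_cross_sum_cpp(b, b, tau) -
    exp_cross_sum_cpp(a, b, tau)
  d <- sqrt(max(0, d2))
  if (normalized) {
    n <- length(a) + length(b)
    if (n == 0L) return(NA_real_)
    d <- d / sqrt(n / 2)
  }
  d
}

#' Earth mover's distance between spike trains
#'
#' Area between the two cumulative spike count functions over `[0, T)`
#' (the 1-D optimal transport cost). The raw variant uses counting
#' functions (each spike has mass 1, so the distance to the empty train
#' is defined); the normalized variant uses unit-mass empirical CDFs and
#' is NA if either train is empty.
#'
#' @inheritParams victor_purpura
#' @param T window length (s).
#' @export
earth_movers <- function(a, b, T, normalized = FALSE) {
  na <- length(a); nb <- length(b)
  if (normalized && (na == 0L || nb == 0L)) return(NA_real_)
  if (na == 0L && nb == 0L) return(0)
  w <- if (normalized) c(rep(1 / na, na), rep(-1 / nb, nb))
       else c(rep(1, na), rep(-1, nb))
  tt <- c(a, b)
  o <- order(tt)
  tt <- tt[o]
  cum <- cumsum(w[o])
  sum(abs(cum) * (c(tt[-1L], T) - tt))
}

#' Modulus-metric spike train distance
#'
#' Integral over the window of the absolute difference between the two
#' trains' nearest-spike distance functions,
#' `D_MM = int |d(t, a) - d(t, b)| dt`, computed exactly from the
#' piecewise-linear structure. The normalized variant divides by
#' `T * (dbar_a + dbar_b)/2`, where `dbar_x` is the time-averaged
#' nearest-spike distance of train x, removing the overall scale set by
#' the firing rates.
#'
#' @inheritParams earth_movers
#' @export
modulus_metric <- function(a, b, T, normalized = FALSE) {
  d <- modulus_metric_cpp(a, b, T)
  if (is.na(d)) return(NA_real_)
  if (normalized) {
    den <- 0.5 * (mean_nearest_dist(a, T) + mean_nearest_dist(b, T)) * T
    d <- if (den > 0) d / den else NA_real_
  }
  d
}

# time-averaged distance to the nearest spike of one train
mean_nearest_dist <- function(a, T) {
  n <- length(a)
  if (n == 0L) return(Inf)
  gaps <- diff(a)
  (a[1]^2 / 2 + (T - a[n])^2 / 2 + sum(gaps^2) / 4) / T
}

#' ISI- and SPIKE-distance
#'
#' Parameter-free time-resolved dissimilarities based on interspike
#' intervals (`isi_distance`) and on nearest-spike timing
#' (`spike_distance`), time-averaged over the window with auxiliary edge
#' spikes at 0 and `T`. Both are 0 for identical trains.
#'
#' @inheritParams earth_movers
#' @export
isi_distance <- function(a, b, T) {
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  isi_distance_cpp(unique(a), unique(b), T)
}

#' @rdname isi_distance
#' @export
spike_distance <- function(a, b, T) {
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  spike_distance_cpp(unique(a), unique(b), T)
}

# --- filtered-train correlation / similarity measures ---------------------

#' Schreiber correlation
#'
#' Normalized inner product (cosine similarity) of the two trains
#' convolved with Gaussian kernels of SD `tau`, in closed form via
#' Gaussian cross sums. Identical trains give 1.
#'
#' @inheritParams victor_purpura
#' @export
schreiber_correlation <- function(a, b, tau = 0.001) {
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  s <- sqrt(2) * tau
  num <- gauss_cross_sum_cpp(a, b, s)
  den <- sqrt(gauss_cross_sum_cpp(a, a, s) * gauss_cross_sum_cpp(b, b, s))
  if (den == 0) return(NA_real_)
  num / den
}

#' Kruskal correlation
#'
#' Pearson correlation between the two trains' spike counts in a common
#' partition of the window into bins of width `tau`.
#'
#' @inheritParams spike_time_tiling
#' @export
kruskal_correlation <- function(a, b, T, tau = 0.001) {
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  nb <- max(1L, ceiling(T / tau))
  ca <- tabulate(pmin(nb, floor(a / tau) + 1L), nbins = nb)
  cb <- tabulate(pmin(nb, floor(b / tau) + 1L), nbins = nb)
  if (stats::sd(ca) == 0 || stats::sd(cb) == 0) return(NA_real_)
  stats::cor(ca, cb)
}

#' Hunter-Milton similarity
#'
#' Mean of `exp(-d_i / tau)` over the nearest-spike distances `d_i` from
#' each spike of one train to the other, averaged over both directions.
#'
#' @inheritParams victor_purpura
#' @export
hunter_milton <- function(a, b, tau = 0.001) {
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  0.5 * (mean(exp(-nearest_dist_cpp(a, b) / tau)) +
         mean(exp(-nearest_dist_cpp(b, a) / tau)))
}

#' Lempel-Ziv spike train distance
#'
#' Normalized conditional Lempel-Ziv complexity of the binarized trains
#' (bins of width `bin_s`):
#' `D_LZ = max(C(ab) - C(a), C(ba) - C(b)) / max(C(a), C(b))`, where
#' `C` is the LZ76 phrase count and `ab` denotes concatenation.
#'
#' @inheritParams earth_movers
#' @param bin_s binarization bin width (s).
#' @export
lz_distance <- function(a, b, T, bin_s = 0.001) {
  sa <- binarize_train(a, T, bin_s)
  sb <- binarize_train(b, T, bin_s)
  ca <- lz76_complexity_cpp(sa)
  cb <- lz76_complexity_cpp(sb)
  cab <- lz76_complexity_cpp(c(sa, sb))
  cba <- lz76_complexity_cpp(c(sb, sa))
  max(cab - ca, cba - cb) / max(ca, cb)
}

binarize_train <- function(a, T, bin_s) {
  nb <- max(1L, ceiling(T / bin_s))
  as.integer(tabulate(pmin(nb, floor(a / bin_s) + 1L), nbins = nb) > 0L)
}

#' Evaluate one bivariate measure by name
#'
#' Dispatcher over the 22 bivariate measures. Symmetric in its two
#' trains except for the delay-asymmetry measures `S_qq`/`S_qqa`, which
#' change sign when the trains are swapped.
#'
#' @param name measure identifier: one of MPC, STTC, C_i, D_ISI, D_S,
#'   PPC, D_VP, D_VPN, D_vR, D_vRn, D_LZ, C_S, C_K, S_HM, S_QQ, S_qq,
#'   S_QQA, S_qqa, D_EMD, D_EMDN, D_MM, D_MMN.
#' @inheritParams spike_time_tiling
#' @export
bivariate_measure <- function(name, a, b, T, tau = 0.001) {
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  switch(name,
    MPC = mean_phase_coherence(a, b),
    PPC = pairwise_phase_consistency(a, b),
    STTC = spike_time_tiling(a, b, T, tau),
    C_i = correlation_index(a, b, T, tau),
    D_ISI = isi_distance(a, b, T),
    D_S = spike_distance(a, b, T),
    D_VP = victor_purpura(a, b, tau),
    D_VPN = victor_purpura(a, b, tau, normalized = TRUE),
    D_vR = van_rossum(a, b, tau),
    D_vRn = van_rossum(a, b, tau, normalized = TRUE),
    D_LZ = lz_distance(a, b, T),
    C_S = schreiber_correlation(a, b, tau),
    C_K = kruskal_correlation(a, b, T, tau),
    S_HM = hunter_milton(a, b, tau),
    S_QQ = event_synchronization(a, b, T, tau)[["Q"]],
    S_qq = event_synchronization(a, b, T, tau)[["q"]],
    S_QQA = event_synchronization(a, b, T, adaptive = TRUE)[["Q"]],
    S_qqa = event_synchronization(a, b, T, adaptive = TRUE)[["q"]],
    D_EMD = earth_movers(a, b, T),
    D_EMDN = earth_movers(a, b, T, normalized = TRUE),
    D_MM = modulus_metric(a, b, T),
    D_MMN = modulus_metric(a, b, T, normalized = TRUE),
    stop("unknown bivariate measure: ", name)
  )
}
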