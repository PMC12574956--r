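# Synthetic multineuron spike train generators.
#
# Two generative families:
#  * single-scale: inhomogeneous Poisson processes whose rate is a
#    sinusoid with either linear phase plus Ornstein-Uhlenbeck phase
#    noise (pseudo-rhythmic) or piecewise-linear phase with
#    refractory-exponential inter-node intervals (non-rhythmic);
#  * dual-scale: doubly stochastic processes where population events are
#    produced at a higher level (phase threshold crossings or a
#    refractory-exponential renewal process) and spikes are Gaussian
#    jitters around each event, with optional deletion.
# Sequential structure is controlled by the duty cycle Dc through
# per-neuron phase offsets (single-scale) or per-neuron time biases
# (dual-scale); Dc = 0 recovers the non-sequential case on the same
# code path (hence bit-identically under a fixed seed).

.DT_SIM <- 1e-5  # simulation step, 0.01 ms

#' Ornstein-Uhlenbeck phase noise
#'
#' Samples a zero-mean Ornstein-Uhlenbeck process on the simulation grid
#' using the exact discrete transition: `x(t + dt)` is normal with mean
#' `x(t) * exp(-dt / tau_OU)` and standard deviation
#' `sigma_OU * sqrt(1 - exp(-2 dt / tau_OU))`, started at 0.
#'
#' @param tau_OU autocorrelation time constant (s, > 0).
#' @param sigma_OU stationary standard deviation (rad, >= 0).
#' @param T duration (s, > 0).
#' @param dt simulation step (s, > 0); default 0.01 ms.
#' @param seed optional integer seed.
#' @return numeric vector of length `ceiling(T / dt) + 1`.
#' @export
sample_ou_phase_noise <- function(tau_OU, sigma_OU, T, dt = .DT_SIM, seed = NULL) {
  if (!is.numeric(tau_OU) || tau_OU <= 0) stop("tau_OU must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (sigma_OU < 0) stop("sigma_OU must be >= 0")
  if (T <= 0) stop("T must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(T / dt)
  if (sigma_OU == 0) return(numeric(n + 1L))
  a <- exp(-dt / tau_OU)
  s <- sigma_OU * sqrt(1 - exp(-2 * dt / tau_OU))
  z <- stats::rnorm(n, sd = s)
  c(0, as.numeric(stats::filter(z, a, method = "recursive")))
}

#' Refractory-exponential intervals
#'
#' Samples intervals with density `lambda * exp(-lambda * x)` restricted
#' to `x >= t_refr` (equivalently, `t_refr` plus an exponential with
#' rate `lambda`, by memorylessness). Used for inter-node intervals of
#' the non-rhythmic piecewise-linear phase and for inter-event intervals
#' of non-rhythmic dual-scale trains.
#'
#' @param lambda exponential rate (1/s, > 0).
#' @param t_refr refractory shift (s, >= 0).
#' @param n number of intervals (> 0).
#' @param seed optional integer seed.
#' @return numeric vector of `n` intervals, each `>= t_refr`.
#' @export
sample_refractory_exponential <- function(lambda, t_refr, n, seed = NULL) {
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (t_refr < 0) stop("t_refr must be >= 0")
  if (!is.numeric(n) || n <= 0) stop("n must be a positive count")
  if (!is.null(seed)) set.seed(seed)
  t_refr + stats::rexp(n, rate = lambda)
}

#' Single-scale generator parameters
#'
#' Bundles and validates the parameters of the inhomogeneous-Poisson
#' family. Defaults follow the benchmark parameterization: neuronal
#' refractory period 4 ms, population refractory period `0.1 / (2 f0)` s,
#' OU noise with `tau_OU` = 10 ms and `sigma_OU = 0.4 * pi * f0 / 1000`
#' rad, 100 neurons, 10 s duration.
#'
#' @param r0 mean firing rate (Hz, >= 0).
#' @param m modulation amplitude in `[0, 1]`.
#' @param f0 modulation frequency (Hz, > 0).
#' @param rhythmic logical; pseudo-rhythmic (OU-perturbed linear phase)
#'   vs non-rhythmic (piecewise-linear phase).
#' @param Dc duty cycle in `[0, 1)`; 0 gives non-sequential trains.
#' @param N number of neurons (>= 1).
#' @param T duration (s, > 0).
#' @param t_refr_neu neuronal refractory period (s).
#' @param t_refr_pop population refractory period (s); default
#'   `0.1 / (2 * f0)`.
#' @param tau_OU,sigma_OU OU phase-noise time constant (s) and
#'   stationary SD (rad).
#' @param dt simulation step (s).
#' @param phi_ic initial phase (rad) for non-rhythmic trains; `NULL`
#'   draws it uniformly in `[0, 2 pi)` from the seed stream.
#' @return a list of class `single_scale_params`.
#' @export
single_scale_params <- function(r0, m, f0, rhythmic = TRUE, Dc = 0,
                                N = 100L, T = 10,
                                t_refr_neu = 0.004,
                                t_refr_pop = 0.1 / (2 * f0),
                                tau_OU = 0.01,
                                sigma_OU = 0.4 * pi * f0 / 1000,
                                dt = .DT_SIM, phi_ic = NULL) {
  if (r0 < 0) stop("r0 must be >= 0")
  if (m < 0 || m > 1) stop("m must be in [0, 1]")
  if (f0 <= 0) stop("f0 must be > 0")
  if (Dc < 0 || Dc >= 1) stop("Dc must be in [0, 1)")
  if (N < 1) stop("N must be >= 1")
  if (T <= 0) stop("T must be > 0")
  if (tau_OU <= 0 || dt <= 0) stop("tau_OU and dt must be > 0")
  if (r0 * (1 + m) * dt > 1)
    stop("peak rate r0*(1+m) too high for the simulation step: r*dt > 1")
  structure(list(r0 = r0, m = m, f0 = f0, rhythmic = isTRUE(rhythmic),
                 Dc = Dc, N = as.integer(N), T = T,
                 t_refr_neu = t_refr_neu, t_refr_pop = t_refr_pop,
                 tau_OU = tau_OU, sigma_OU = sigma_OU, dt = dt,
                 phi_ic = phi_ic),
            class = "single_scale_params")
}

#' Dual-scale generator parameters
#'
#' Bundles and validates the parameters of the doubly stochastic family.
#' The Gaussian jitter SD is `sigma = Sigma / f0`, i.e. `Sigma` is the
#' width expressed as a fraction of the mean inter-event interval.
#'
#' @param Sigma Gaussian width as a fraction of the mean IEI (> 0).
#' @param p_fail spike deletion probability in `[0, 1]`.
#' @param phi_thr reference phase for rhythmic event detection (rad);
#'   events are upward crossings of `phi mod 2 pi` through this value.
#' @inheritParams single_scale_params
#' @return a list of class `dual_scale_params`.
#' @export
dual_scale_params <- function(Sigma, p_fail, f0, rhythmic = TRUE, Dc = 0,
                              N = 100L, T = 10,
                              t_refr_neu = 0.004,
                              t_refr_pop = 0.1 / (2 * f0),
                              tau_OU = 0.01,
                              sigma_OU = 0.4 * pi * f0 / 1000,
                              dt = .DT_SIM, phi_thr = pi / 2) {
  if (Sigma <= 0) stop("Sigma must be > 0")
  if (p_fail < 0 || p_fail > 1) stop("p_fail must be in [0, 1]")
  if (f0 <= 0) stop("f0 must be > 0")
  if (Dc < 0 || Dc >= 1) stop("Dc must be in [0, 1)")
  if (N < 1) stop("N must be >= 1")
  if (T <= 0) stop("T must be > 0")
  structure(list(Sigma = Sigma, p_fail = p_fail, f0 = f0,
                 rhythmic = isTRUE(rhythmic), Dc = Dc,
                 N = as.integer(N), T = T,
                 t_refr_neu = t_refr_neu, t_refr_pop = t_refr_pop,
                 tau_OU = tau_OU, sigma_OU = sigma_OU, dt = dt,
                 phi_thr = phi_thr),
            class = "dual_scale_params")
}

# Enforce an absolute refractory period by forward deletion: the earlier
# retained spike wins; a spike is dropped if it follows the last retained
# spike by an interval <= t_refr.
enforce_refractory <- function(times, t_refr) {
  n <- length(times)
  if (n < 2L || t_refr <= 0) return(times)
  keep <- refractory_keep_cpp(times, t_refr)
  times[keep]
}

# Success step indices (1-based) of a homogeneous Bernoulli chain with
# per-step probability p over n steps, drawn sparsely via geometric gaps.
bernoulli_steps <- function(n, p) {
  if (p <= 0 || n < 1L) return(integer(0))
  if (p >= 1) return(seq_len(n))
  out <- integer(0)
  last <- 0
  while (last <= n) {
    k <- max(16L, ceiling((n - last) * p * 1.5 + 8 * sqrt((n - last) * p + 1)))
    gaps <- stats::rgeom(k, p) + 1
    idx <- last + cumsum(gaps)
    out <- c(out, idx)
    last <- idx[length(idx)]
  }
  out[out <= n]
}

# Piecewise-linear phase at times `tt` for a neuron whose node times are
# `nodes` (strictly increasing, nodes[1] <= 0 guaranteed by callers).
# Segment i (0-based) spans a half cycle: even segments sweep the phase
# from -pi/2 to pi/2, odd segments from pi/2 to 3*pi/2.
plp_phase_at <- function(tt, nodes) {
  i <- findInterval(tt, nodes)
  i[i < 1L] <- 1L
  i[i >= length(nodes)] <- length(nodes) - 1L
  frac <- (tt - nodes[i]) / (nodes[i + 1L] - nodes[i])
  i0 <- i - 1L
  base <- ifelse(i0 %% 2L == 0L, -pi / 2, pi / 2)
  base + pi * frac
}

#' Generate a single-scale multineuron spike train
#'
#' Realizes the inhomogeneous Poisson process by per-step Bernoulli
#' sampling with probability `r_j(t) * dt` on a 0.01 ms grid (computed
#' sparsely through a dominating homogeneous chain, which is
#' distributionally identical), then enforces the neuronal refractory
#' period by forward deletion. Pseudo-rhythmic trains share one
#' OU-perturbed linear phase across neurons; non-rhythmic trains share
#' one piecewise-linear phase skeleton, with sequential structure
#' entering through per-neuron phase offsets
#' `phi_j = 2 pi Dc (1/2 - (j-1)/(N-1))` (rhythmic) or per-neuron node
#' shifts (non-rhythmic).
#'
#' @param p a [single_scale_params] object.
#' @param seed integer seed fixing the realization.
#' @param trace if `TRUE`, attach generative intermediates (phase nodes,
#'   inter-node intervals, rate parameters) to the result.
#' @return a [spike_train] with generative metadata.
#' @export
generate_single_scale <- function(p, seed = NULL, trace = FALSE) {
  stopifnot(inherits(p, "single_scale_params"))
  if (!is.null(seed)) set.seed(seed)
  nsteps <- ceiling(p$T / p$dt)
  r_max <- p$r0 * (1 + p$m)
  p_max <- r_max * p$dt
  phi_j <- if (p$N > 1L)
    2 * pi * p$Dc * (0.5 - (seq_len(p$N) - 1) / (p$N - 1))
  else 0

  tr <- NULL
  if (p$rhythmic) {
    phi_n <- sample_ou_phase_noise(p$tau_OU, p$sigma_OU, p$T, p$dt)
    spikes <- vector("list", p$N)
    for (j in seq_len(p$N)) {
      idx <- bernoulli_steps(nsteps, p_max)
      tt <- (idx - 1) * p$dt
      if (length(idx)) {
        rate <- p$r0 * (1 + p$m * sin(2 * pi * p$f0 * tt + phi_n[idx] + phi_j[min(j, length(phi_j))]))
        acc <- stats::runif(length(idx)) < rate / r_max
        tt <- tt[acc]
      }
      spikes[[j]] <- enforce_refractory(tt, p$t_refr_neu)
    }
    if (trace) tr <- list(phase_noise_sd = stats::sd(phi_n))
  } else {
    phi_ic <- if (is.null(p$phi_ic)) stats::runif(1, 0, 2 * pi) else p$phi_ic
    lambda <- 2 * p$f0 * exp(p$t_refr_pop * 2 * p$f0)
    mean_ini <- p$t_refr_pop + 1 / lambda
    # base node skeleton, extended far enough that every neuron's shifted
    # node sequence covers [0, T)
    inis <- numeric(0)
    base <- 0
    while (base < p$T + 4 * mean_ini) {
      add <- sample_refractory_exponential(lambda, p$t_refr_pop,
                                           ceiling((p$T + 8 * mean_ini - base) / mean_ini) + 8L)
      inis <- c(inis, add)
      base <- sum(inis)
    }
    base_nodes <- c(0, cumsum(inis))
    nb <- length(base_nodes)
    cj <- if (p$N > 1L) (p$N - seq_len(p$N)) / (p$N - 1) else 0
    spikes <- vector("list", p$N)
    for (j in seq_len(p$N)) {
      # node i+1 of neuron j sits Dc*INI_i*(N-j)/(N-1) before base node i+1
      nodes_j <- c(0, base_nodes[-1] - p$Dc * inis * cj[min(j, length(cj))])
      idx <- bernoulli_steps(nsteps, p_max)
      tt <- (idx - 1) * p$dt
      if (length(tt)) {
        phi <- plp_phase_at(tt, nodes_j)
        rate <- p$r0 * (1 + p$m * sin(phi + phi_ic))
        acc <- stats::runif(length(tt)) < rate / r_max
        tt <- tt[acc]
      }
      spikes[[j]] <- enforce_refractory(tt, p$t_refr_neu)
    }
    if (trace) tr <- list(node_times = base_nodes, inter_node_intervals = inis,
                          lambda = lambda, phi_ic = phi_ic)
  }
  spike_train(spikes, p$T,
              meta = list(family = "single_scale", r0 = p$r0, m = p$m,
                          f0 = p$f0, rhythmic = p$rhythmic, Dc = p$Dc,
                          sequential = p$Dc > 0, seed = seed),
              trace = tr)
}

#' Generate a dual-scale multineuron spike train
#'
#' Population events are either upward crossings of an OU-perturbed
#' linear phase through the reference phase `phi_thr` (pseudo-rhythmic;
#' Euler-integrated on the simulation grid) or a refractory-exponential
#' renewal process with rate parameter `lambda = f0 exp(t_refr_pop f0)`
#' (non-rhythmic); both enforce the population refractory period. Each
#' neuron then receives one candidate spike per event, jittered by a
#' zero-mean Gaussian with SD `Sigma / f0`, shifted by the sequential
#' bias `(Dc / f0) ((j-1)/(N-1) - 1/2)` when `Dc > 0`, deleted
#' independently with probability `p_fail`, clipped to `[0, T)`, and
#' cleaned by the neuronal refractory period.
#'
#' @param p a [dual_scale_params] object.
#' @inheritParams generate_single_scale
#' @return a [spike_train] with generative metadata.
#' @export
generate_dual_scale <- function(p, seed = NULL, trace = FALSE) {
  stopifnot(inherits(p, "dual_scale_params"))
  if (!is.null(seed)) set.seed(seed)

  if (p$rhythmic) {
    phi_n <- sample_ou_phase_noise(p$tau_OU, p$sigma_OU, p$T, p$dt)
    nsteps <- ceiling(p$T / p$dt)
    # Euler integration of dphi/dt = 2*pi*f0 + phi_n
    dphi <- (2 * pi * p$f0 + phi_n[seq_len(nsteps)]) * p$dt
    phi <- c(0, cumsum(dphi))
    cyc <- floor((phi - p$phi_thr) / (2 * pi))
    k <- which(diff(cyc) >= 1)  # upward crossing inside step k
    target <- (cyc[k] + 1) * 2 * pi + p$phi_thr
    ev <- (k - 1) * p$dt + p$dt * (target - phi[k]) / (phi[k + 1L] - phi[k])
    iei_raw <- NULL
  } else {
    lambda <- p$f0 * exp(p$t_refr_pop * p$f0)
    mean_iei <- p$t_refr_pop + 1 / lambda
    ieis <- numeric(0)
    tot <- 0
    while (tot < p$T) {
      add <- sample_refractory_exponential(lambda, p$t_refr_pop,
                                           ceiling((p$T - tot) / mean_iei) + 8L)
      ieis <- c(ieis, add)
      tot <- sum(ieis)
    }
    ev <- cumsum(ieis)
    ev <- ev[ev < p$T]
    iei_raw <- diff(ev)
  }
  # population refractory period between retained events
  ev <- enforce_refractory(ev, p$t_refr_pop)
  ev <- ev[ev < p$T]
  ne <- length(ev)
  sigma <- p$Sigma / p$f0
  bias <- if (p$N > 1L)
    (p$Dc / p$f0) * ((seq_len(p$N) - 1) / (p$N - 1) - 0.5)
  else 0

  spikes <- vector("list", p$N)
  if (ne > 0L) {
    jit <- matrix(stats::rnorm(p$N * ne, sd = sigma), nrow = p$N)
    del <- if (p$p_fail > 0)
      matrix(stats::runif(p$N * ne) < p$p_fail, nrow = p$N)
    else matrix(FALSE, nrow = p$N, ncol = ne)
    for (j in seq_len(p$N)) {
      tt <- ev + bias[min(j, length(bias))] + jit[j, ]
      tt <- tt[!del[j, ]]
      tt <- sort(tt[tt >= 0 & tt < p$T])
      spikes[[j]] <- enforce_refractory(tt, p$t_refr_neu)
    }
  } else {
    spikes <- rep(list(numeric(0)), p$N)
  }
  tr <- NULL
  if (trace) tr <- list(population_events = ev,
                        inter_event_intervals = diff(ev),
                        sigma = sigma)
  spike_train(spikes, p$T,
              meta = list(family = "dual_scale", Sigma = p$Sigma,
                          p_fail = p$p_fail, f0 = p$f0,
                          rhythmic = p$rhythmic, Dc = p$Dc,
                          sequential = p$Dc > 0, seed = seed),
              trace = tr)
}

#' Benchmark parameter grid
#'
#' Full Cartesian parameter grid of the synthetic benchmark: for the
#' single-scale family, `r0 x m x f0 x {rhythmic, non-rhythmic} x Dc`;
#' for the dual-scale family, `Sigma x p_fail x f0 x {rhythmic,
#' non-rhythmic} x Dc`; `Dc = 0` rows are non-sequential, `Dc` in
#' `{0.2, 0.4}` sequential. With the default value grids this yields 900
#' trains: 150 non-sequential plus 300 sequential per family.
#'
#' @param N number of neurons per train (default 100).
#' @param T train duration in seconds (default 10).
#' @param r0,m,Sigma,p_fail,f0,Dc value grids for the generative
#'   parameters.
#' @return a data.frame with one row per train: `id`, `family`, the
#'   generative parameters (`NA` where not applicable), `rhythmic`,
#'   `Dc`, `sequential`, `N`, `T`.
#' @export
build_benchmark_grid <- function(N = 100L, T = 10,
                                 r0 = c(1, 4, 8, 12, 36),
                                 m = c(0, 0.25, 0.5, 0.75, 1),
                                 Sigma = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                 p_fail = c(0, 0.2, 0.4, 0.6, 0.8),
                                 f0 = c(4, 12, 36),
                                 Dc = c(0, 0.2, 0.4)) {
  ss <- expand.grid(r0 = r0, m = m, f0 = f0, rhythmic = c(TRUE, FALSE),
                    Dc = Dc, KEEP.OUT.ATTRS = FALSE)
  ss$family <- "single_scale"
  ss$Sigma <- NA_real_
  ss$p_fail <- NA_real_
  ds <- expand.grid(Sigma = Sigma, p_fail = p_fail, f0 = f0,
                    rhythmic = c(TRUE, FALSE), Dc = Dc,
                    KEEP.OUT.ATTRS = FALSE)
  ds$family <- "dual_scale"
  ds$r0 <- NA_real_
  ds$m <- NA_real_
  cols <- c("family", "r0", "m", "Sigma", "p_fail", "f0", "rhythmic", "Dc")
  g <- rbind(ss[, cols], ds[, cols])
  g$sequential <- g$Dc > 0
  g$N <- as.integer(N)
  g$T <- T
  g <- cbind(id = seq_len(nrow(g)), g)
  rownames(g) <- NULL
  g
}

#' Parameters for one benchmark grid row
#'
#' @param grid a data.frame from [build_benchmark_grid()].
#' @param i row index.
#' @return a [single_scale_params] or [dual_scale_params] object.
#' @export
grid_params <- function(grid, i) {
  row <- grid[i, ]
  if (row$family == "single_scale")
    single_scale_params(r0 = row$r0, m = row$m, f0 = row$f0,
                        rhythmic = row$rhythmic, Dc = row$Dc,
                        N = row$N, T = row$T)
  else
    dual_scale_params(Sigma = row$Sigma, p_fail = row$p_fail, f0 = row$f0,
                      rhythmic = row$rhythmic, Dc = row$Dc,
                      N = row$N, T = row$T)
}

#' Generate one train of the benchmark grid
#'
#' Per-train sub-seeds are derived deterministically from the master
#' seed and the row id, so grids are reproducible and trains
#' independent.
#'
#' @inheritParams grid_params
#' @param seed master seed (integer).
#' @return a [spike_train].
#' @export
generate_grid_train <- function(grid, i, seed = 1L) {
  sub <- train_subseed(seed, grid$id[i])
  p <- grid_params(grid, i)
  if (grid$family[i] == "single_scale") generate_single_scale(p, seed = sub)
  else generate_dual_scale(p, seed = sub)
}

# deterministic per-train sub-seed below 2^31
train_subseed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(id) * 9973) %% 2147483647)
}
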