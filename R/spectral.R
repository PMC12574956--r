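# Spectral measures: instantaneous population firing rate, its Welch
# power spectrum, and the parameterization of the log power spectrum as
# an aperiodic (offset + exponent) component plus Gaussian periodic
# peaks, in single- and dual-peak variants.

#' Instantaneous population firing rate
#'
#' Each neuron's spike train is convolved with a Gaussian kernel of SD
#' `kernel_bw` on a uniform grid of step `dt_grid` and the results are
#' averaged across neurons. The estimate is mass conserving: the
#' integral of the rate over the window equals total spikes / N (up to
#' edge truncation of the kernel).
#'
#' @param train a [spike_train].
#' @param kernel_bw Gaussian kernel SD (s, > 0); 2 ms default for
#'   analysis.
#' @param dt_grid grid step (s).
#' @return list of class `population_rate` with `times`, `rate` (Hz),
#'   `kernel_bw`, `dt` and `N`.
#' @export
population_rate <- function(train, kernel_bw = 0.002, dt_grid = 0.001) {
  if (kernel_bw <= 0) stop("kernel_bw must be > 0")
  nb <- max(1L, ceiling(train$T / dt_grid))
  pooled <- unlist(train$spikes)
  counts <- if (length(pooled))
    tabulate(pmin(nb, floor(pooled / dt_grid) + 1L), nbins = nb)
  else numeric(nb)
  sm <- smooth_columns_fft(matrix(counts, ncol = 1L), kernel_bw / dt_grid)[, 1L]
  sm[sm < 0] <- 0   # FFT round-off
  structure(list(times = (seq_len(nb) - 0.5) * dt_grid,
                 rate = sm / (train$N * dt_grid),
                 kernel_bw = kernel_bw, dt = dt_grid, N = train$N),
            class = "population_rate")
}

#' Welch power spectrum of a population rate
#'
#' Averaged periodogram of the mean-subtracted rate series: Hann-windowed
#' segments of length `segment_s` with 50% overlap, one-sided density
#' scaling. Also reports the log-power maximum over the analysis band
#' (`PSD_max`) and its frequency (`f_max`).
#'
#' @param pr a [population_rate] (or any list with `rate` and `dt`).
#' @param segment_s segment length (s).
#' @param band analysis band (Hz), `c(lo, hi)`.
#' @return list of class `rate_spectrum` with `freq`, `power`,
#'   `log_power` (log10), `PSD_max`, `f_max`, and `degenerate` flag
#'   (constant input series).
#' @export
power_spectrum <- function(pr, segment_s = 2, band = c(1, 100)) {
  x <- pr$rate - mean(pr$rate)
  dt <- pr$dt
  L <- round(segment_s / dt)
  if (L < 8) stop("segment too short for the grid step")
  if (length(x) < L) stop("series shorter than one segment")
  hop <- L %/% 2L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  acc <- numeric(L %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    X <- stats::fft(seg)[seq_len(L %/% 2L + 1L)]
    acc <- acc + Mod(X)^2
  }
  pw <- acc / length(starts) * (dt / sum(w^2))
  pw[c(-1L, -length(pw))] <- 2 * pw[c(-1L, -length(pw))]  # one-sided
  freq <- (seq_along(pw) - 1L) / (L * dt)
  keep <- freq >= band[1] & freq <= band[2]
  freq <- freq[keep]
  pw <- pw[keep]
  degenerate <- all(pw <= 0) || stats::sd(x) == 0
  lp <- ifelse(pw > 0, log10(pw), -Inf)
  if (degenerate) {
    psd_max <- -Inf
    f_max <- freq[1L]
  } else {
    imax <- which.max(lp)
    psd_max <- lp[imax]
    f_max <- freq[imax]
  }
  structure(list(freq = freq, power = pw, log_power = lp,
                 PSD_max = psd_max, f_max = f_max, degenerate = degenerate),
            class = "rate_spectrum")
}

#' Aperiodic + periodic parameterization of a log power spectrum
#'
#' Describes `log10 P(f)` as an aperiodic component
#' `b_L - chi_L * log10(f)` plus up to `n_peaks` Gaussian peaks in
#' log-power. The aperiodic component is fit robustly (ordinary least
#' squares, then a refit on the low-residual bins so that peaks do not
#' bias the slope); peaks are extracted greedily from the residual and
#' refined jointly by Levenberg-Marquardt least squares. A peak is
#' retained only if its amplitude exceeds both `sig_mult` times the SD
#' of the aperiodic-fit residuals and the absolute floor `min_height`
#' (log10-power units); the floor rejects the broad, shallow residual
#' bumps of non-oscillatory renewal-type firing, so that non-rhythmic
#' spike trains mostly yield no peak while strongly modulated rhythmic
#' trains almost always do. Spectra without a retained peak report NA
#' peak parameters.
#'
#' @param freq frequencies (Hz, > 0).
#' @param log_power log10 power at `freq`; non-finite bins are dropped.
#' @param n_peaks 1 or 2.
#' @param sig_mult peak significance multiplier.
#' @param min_height absolute minimum retained peak amplitude (log10
#'   power units).
#' @param sigma_bounds allowed Gaussian SD range (Hz).
#' @return list of class `fooof_fit`: `b_L`, `chi_L`, `peaks` (data.frame
#'   with `f_G`, `A_G`, `sigma_G`, `beta_G`), `MAE`, `R2`, `n_peaks`.
#' @export
fit_fooof <- function(freq, log_power, n_peaks = 1L, sig_mult = 2,
                      min_height = 0.6, sigma_bounds = c(0.5, 25)) {
  ok <- is.finite(log_power) & is.finite(freq) & freq > 0
  freq <- freq[ok]
  log_power <- log_power[ok]
  if (length(freq) < n_peaks * 3L + 3L)
    stop("fewer frequency bins than model parameters")
  lf <- log10(freq)
  fit0 <- stats::lm.fit(cbind(1, -lf), log_power)
  res0 <- fit0$residuals
  mask <- res0 <= stats::quantile(res0, 0.75)
  fit1 <- stats::lm.fit(cbind(1, -lf)[mask, , drop = FALSE], log_power[mask])
  b_L <- fit1$coefficients[1]
  chi_L <- fit1$coefficients[2]
  aper <- b_L - chi_L * lf
  resid <- log_power - aper
  sig_thr <- max(sig_mult * stats::sd(resid), min_height)

  # greedy peak guesses
  guesses <- list()
  r <- resid
  for (k in seq_len(n_peaks)) {
    i <- which.max(r)
    amp <- r[i]
    if (!is.finite(amp) || amp <= max(sig_thr, 1e-9)) break
    # half-height width guess
    half <- amp / 2
    li <- i; while (li > 1L && r[li - 1L] > half) li <- li - 1L
    ri <- i; while (ri < length(r) && r[ri + 1L] > half) ri <- ri + 1L
    fwhm <- max(freq[ri] - freq[li], 2 * (freq[2] - freq[1]))
    sg <- min(max(fwhm / 2.355, sigma_bounds[1]), sigma_bounds[2])
    guesses[[k]] <- c(A = amp, c = freq[i], s = sg)
    r <- r - amp * exp(-(freq - freq[i])^2 / (2 * sg^2))
  }

  peaks <- NULL
  if (length(guesses)) {
    np <- length(guesses)
    start <- unlist(guesses)
    names(start) <- paste0(rep(c("A", "c", "s"), np), rep(seq_len(np), each = 3L))
    model <- function(par) {
      m <- numeric(length(freq))
      for (k in seq_len(np)) {
        A <- par[3 * k - 2]; cc <- par[3 * k - 1]; s <- par[3 * k]
        m <- m + A * exp(-(freq - cc)^2 / (2 * s^2))
      }
      m
    }
    lower <- rep(c(0, min(freq), sigma_bounds[1]), np)
    upper <- rep(c(Inf, max(freq), sigma_bounds[2]), np)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start,
                         fn = function(p) resid - model(p),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    par <- if (!is.null(fit)) fit$par else start
    peaks <- data.frame(
      f_G = par[seq(2, 3 * np, by = 3)],
      A_G = par[seq(1, 3 * np, by = 3)],
      sigma_G = par[seq(3, 3 * np, by = 3)])
    peaks <- peaks[peaks$A_G > max(sig_thr, 1e-9), , drop = FALSE]
    if (nrow(peaks) == 0L) peaks <- NULL
  }
  if (!is.null(peaks)) {
    peaks$beta_G <- peaks$A_G / peaks$sigma_G
    rownames(peaks) <- NULL
  }

  full <- aper
  if (!is.null(peaks))
    for (k in seq_len(nrow(peaks)))
      full <- full + peaks$A_G[k] *
        exp(-(freq - peaks$f_G[k])^2 / (2 * peaks$sigma_G[k]^2))
  err <- log_power - full
  mae <- mean(abs(err))
  sst <- sum((log_power - mean(log_power))^2)
  r2 <- if (sst > 0) 1 - sum(err^2) / sst else 1
  structure(list(b_L = unname(b_L), chi_L = unname(chi_L), peaks = peaks,
                 MAE = mae, R2 = r2, n_peaks = n_peaks),
            class = "fooof_fit")
}

#' Spectral measure set of one train
#'
#' Computes the population-rate power spectrum and its parameterization
#' and returns the spectral measures: `PSD_max`, `f_max`, the
#' single-peak model parameters (`b_L`, `chi_L`, `f_G`, `A_G`,
#' `sigma_G`, `beta_G`, `MAE`, `R2`) and, for the extended set, the
#' dual-peak model (`*_2p`, two ordered peaks, `MAE_2p`, `R2_2p`,
#' `R2_ratio`). The first dual-peak is the one whose center frequency is
#' closer to the single-peak center (or the stronger peak when no
#' single-model peak was retained). Unassigned peak parameters are NA.
#'
#' @param train a [spike_train].
#' @param set `"core"` (10 values) or `"extended"` (23 values).
#' @param kernel_bw,dt_grid population-rate settings.
#' @param segment_s,band spectrum settings.
#' @return named numeric vector.
#' @export
spectral_measures <- function(train, set = c("core", "extended"),
                              kernel_bw = 0.002, dt_grid = 0.001,
                              segment_s = 2, band = c(1, 100)) {
  set <- match.arg(set)
  core_names <- c("PSD_max", "f_max", "b_L", "chi_L", "f_G", "A_G",
                  "sigma_G", "beta_G", "MAE", "R2")
  ext_names <- c("b_L_2p", "chi_L_2p",
                 "f_G_2p1", "A_G_2p1", "sigma_G_2p1", "beta_G_2p1",
                 "f_G_2p2", "A_G_2p2", "sigma_G_2p2", "beta_G_2p2",
                 "MAE_2p", "R2_2p", "R2_ratio")
  out <- stats::setNames(rep(NA_real_, 23L), c(core_names, ext_names))
  pr <- population_rate(train, kernel_bw, dt_grid)
  sp <- tryCatch(power_spectrum(pr, segment_s, band), error = function(e) NULL)
  if (is.null(sp) || sp$degenerate || sum(is.finite(sp$log_power)) < 10L)
    return(if (set == "core") out[core_names] else out)
  out["PSD_max"] <- sp$PSD_max
  out["f_max"] <- sp$f_max
  f1 <- tryCatch(fit_fooof(sp$freq, sp$log_power, n_peaks = 1L),
                 error = function(e) NULL)
  if (!is.null(f1)) {
    out["b_L"] <- f1$b_L
    out["chi_L"] <- f1$chi_L
    out["MAE"] <- f1$MAE
    out["R2"] <- f1$R2
    if (!is.null(f1$peaks) && nrow(f1$peaks) >= 1L) {
      out[c("f_G", "A_G", "sigma_G", "beta_G")] <-
        unlist(f1$peaks[1L, c("f_G", "A_G", "sigma_G", "beta_G")])
    }
  }
  if (set == "core") return(out[core_names])
  f2 <- tryCatch(fit_fooof(sp$freq, sp$log_power, n_peaks = 2L),
                 error = function(e) NULL)
  if (!is.null(f2)) {
    out["b_L_2p"] <- f2$b_L
    out["chi_L_2p"] <- f2$chi_L
    out["MAE_2p"] <- f2$MAE
    out["R2_2p"] <- f2$R2
    if (!is.null(f1) && is.finite(f1$R2) && f1$R2 > 0)
      out["R2_ratio"] <- f2$R2 / f1$R2
    pk <- f2$peaks
    if (!is.null(pk) && nrow(pk) >= 1L) {
      if (nrow(pk) == 2L) {
        ref <- if (!is.null(f1$peaks) && nrow(f1$peaks))
          f1$peaks$f_G[1L] else pk$f_G[which.max(pk$A_G)]
        o <- order(abs(pk$f_G - ref))
        pk <- pk[o, , drop = FALSE]
      }
      out[c("f_G_2p1", "A_G_2p1", "sigma_G_2p1", "beta_G_2p1")] <-
        unlist(pk[1L, c("f_G", "A_G", "sigma_G", "beta_G")])
      if (nrow(pk) == 2L)
        out[c("f_G_2p2", "A_G_2p2", "sigma_G_2p2", "beta_G_2p2")] <-
          unlist(pk[2L, c("f_G", "A_G", "sigma_G", "beta_G")])
    }
  }
  out
}
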