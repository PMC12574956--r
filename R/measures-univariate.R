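# Univariate firing intensity and variability measures.
#
# All ISI-based statistics operate on the ordered inter-spike-interval
# sequence of one neuron; trains with fewer than 3 spikes (2 ISIs) yield
# NA for them (the firing rate needs only the count). In a multineuron
# context they are applied per neuron and then averaged across neurons.

#' Univariate spike train measures
#'
#' Computes the 9 univariate measures for a single-neuron spike train:
#' mean firing rate `r`; global ISI variability `CV_ISI` (SD/mean of
#' ISIs) and `LCV_ISI` (SD of log ISIs); the local, rate-adaptation
#' robust statistics `CV2_ISI` (mean of `2|I_{k+1}-I_k|/(I_{k+1}+I_k)`),
#' `Lv` (local variation), `LvR` (refractoriness-corrected local
#' variation, refractoriness constant 5 ms) and `IR` (mean absolute log
#' consecutive-ISI ratio); `Ent`, the Shannon entropy (bits) of the
#' log-ISI histogram with fixed 0.2-nat bins; and `S_M`, the
#' consecutive-pair ISI irregularity
#' `mean(-log(4 I_k I_{k+1} / (I_k + I_{k+1})^2) / 2)`.
#'
#' A perfectly regular train gives 0 for all local variability measures;
#' a homogeneous Poisson process gives `CV_ISI` and `Lv` near 1.
#'
#' @param times sorted numeric vector of spike times (s).
#' @param T duration of the observation window (s, > 0).
#' @param lvr_R refractoriness constant of `LvR` (s).
#' @return named numeric vector of length 9.
#' @export
univariate_measures <- function(times, T, lvr_R = 0.005) {
  if (!is.numeric(T) || T <= 0) stop("T must be > 0")
  out <- c(r = length(times) / T, CV_ISI = NA_real_, LCV_ISI = NA_real_,
           CV2_ISI = NA_real_, Lv = NA_real_, LvR = NA_real_,
           IR = NA_real_, Ent = NA_real_, S_M = NA_real_)
  isi <- diff(times)
  isi <- isi[isi > 0]
  if (length(isi) < 2L) return(out)
  out["CV_ISI"] <- stats::sd(isi) / mean(isi)
  out["LCV_ISI"] <- stats::sd(log(isi))
  i1 <- isi[-length(isi)]
  i2 <- isi[-1L]
  s <- i1 + i2
  out["CV2_ISI"] <- mean(2 * abs(i2 - i1) / s)
  out["Lv"] <- mean(3 * ((i1 - i2) / s)^2)
  out["LvR"] <- mean(3 * (1 - 4 * i1 * i2 / s^2) * (1 + 4 * lvr_R / s))
  out["IR"] <- mean(abs(log(i2 / i1)))
  out["Ent"] <- log_isi_entropy(isi)
  out["S_M"] <- mean(-0.5 * log(4 * i1 * i2 / s^2))
  out
}

# Shannon entropy (bits) of the log-ISI distribution, histogram with a
# fixed 0.2-nat bin width anchored at 0.
log_isi_entropy <- function(isi, bin_nats = 0.2) {
  l <- log(isi)
  idx <- floor(l / bin_nats)
  p <- tabulate(idx - min(idx) + 1L)
  p <- p[p > 0] / length(l)
  -sum(p * log2(p))
}
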