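# The measure library: specification tables and evaluation of the full
# core (46) or extended (131) measure vector for one multineuron train.
#
# Core set: every measure at its default timescale (1 ms for the 12
# timescale-dependent measures) plus the single-peak spectral model.
# Extended set: the 34 timescale-free measures, the 12
# timescale-dependent measures at 7 timescales logarithmically spaced
# between 1 and 64 ms, and the 13 dual-peak spectral parameters.

.TAUS_MS <- c(1, 2, 4, 8, 16, 32, 64)

.univ_names <- c("r", "CV_ISI", "LCV_ISI", "CV2_ISI", "Lv", "LvR",
                 "IR", "Ent", "S_M")
.multi_names <- c("S_TS", "S_GR", "S_S", "F_S", "S_C")
.spec_core_names <- c("PSD_max", "f_max", "b_L", "chi_L", "f_G", "A_G",
                      "sigma_G", "beta_G", "MAE", "R2")
.spec_ext_names <- c("b_L_2p", "chi_L_2p",
                     "f_G_2p1", "A_G_2p1", "sigma_G_2p1", "beta_G_2p1",
                     "f_G_2p2", "A_G_2p2", "sigma_G_2p2", "beta_G_2p2",
                     "MAE_2p", "R2_2p", "R2_ratio")

.objectives <- c(
  S_TS = "synchrony", S_GR = "synchrony", S_S = "synchrony",
  F_S = "sequential structure", S_C = "synchrony",
  MPC = "phase relationships", STTC = "synchrony", C_i = "synchrony",
  D_ISI = "synchrony", D_S = "synchrony", PPC = "phase relationships",
  D_VP = "firing pattern distance", D_VPN = "firing pattern distance",
  D_vR = "firing pattern distance", D_vRn = "firing pattern distance",
  D_LZ = "firing pattern similarity", C_S = "firing pattern similarity",
  C_K = "firing pattern similarity", S_HM = "firing pattern similarity",
  S_QQ = "synchrony", S_qq = "delay asymmetry", S_QQA = "synchrony",
  S_qqa = "delay asymmetry", D_EMD = "firing pattern distance",
  D_EMDN = "firing pattern distance", D_MM = "firing pattern distance",
  D_MMN = "firing pattern distance",
  r = "firing intensity", CV_ISI = "firing variability",
  LCV_ISI = "firing variability", CV2_ISI = "firing variability",
  Lv = "firing variability", LvR = "firing variability",
  IR = "firing variability", Ent = "firing variability",
  S_M = "firing variability")

#' Measure specification table
#'
#' One row per measure in the chosen set, giving the measure name (with
#' `_t<ms>` suffixes for the timescale expansion of the extended set),
#' the base identifier, arity (univariate / bivariate / multivariate /
#' spectral), timescale in seconds (NA for timescale-free measures) and
#' the objective category.
#'
#' @param set `"core"` (46 rows) or `"extended"` (131 rows).
#' @return a data.frame with columns `name`, `base`, `arity`, `tau`,
#'   `objective`.
#' @export
measure_specs <- function(set = c("core", "extended")) {
  set <- match.arg(set)
  rows <- list()
  add <- function(base, arity) {
    dep <- base %in% .tau_dependent
    obj <- if (arity == "spectral") "oscillations"
           else unname(.objectives[base])
    if (!dep) {
      rows[[length(rows) + 1L]] <<-
        data.frame(name = base, base = base, arity = arity,
                   tau = NA_real_, objective = obj)
    } else if (set == "core") {
      rows[[length(rows) + 1L]] <<-
        data.frame(name = base, base = base, arity = arity,
                   tau = 0.001, objective = obj)
    } else {
      for (ms in .TAUS_MS)
        rows[[length(rows) + 1L]] <<-
          data.frame(name = sprintf("%s_t%d", base, ms), base = base,
                     arity = arity, tau = ms / 1000, objective = obj)
    }
  }
  for (b in .multi_names) add(b, "multivariate")
  for (b in .biv_names) add(b, "bivariate")
  for (b in .univ_names) add(b, "univariate")
  for (b in .spec_core_names) add(b, "spectral")
  if (set == "extended") for (b in .spec_ext_names) add(b, "spectral")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate the full measure vector of a multineuron spike train
#'
#' Applies every measure of the chosen set to the train: univariate
#' measures are computed per neuron and averaged across neurons;
#' bivariate measures are computed for every unordered pair of distinct
#' neurons and averaged (the delay-asymmetry measures `S_qq`/`S_qqa`
#' are averaged signed over pairs `i < j`); multivariate and spectral
#' measures act on the train as a whole. Measures undefined on the
#' train (too few spikes, no significant spectral peak) are NA.
#'
#' @param train a [spike_train].
#' @param set `"core"` or `"extended"`.
#' @return named numeric vector of length 46 (core) or 131 (extended),
#'   with the [measure_specs()] table attached as attribute `"specs"`.
#' @export
measure_vector <- function(train, set = c("core", "extended")) {
  set <- match.arg(set)
  specs <- measure_specs(set)
  out <- stats::setNames(rep(NA_real_, nrow(specs)), specs$name)
  T <- train$T
  N <- train$N
  taus <- if (set == "core") 0.001 else .TAUS_MS / 1000
  tau_lab <- function(base) {
    if (set == "core") base else sprintf("%s_t%d", base, .TAUS_MS)
  }

  # ---- univariate, averaged across neurons
  U <- t(vapply(train$spikes, univariate_measures, numeric(9L), T = T))
  um <- colMeans(U, na.rm = TRUE)
  um[!is.finite(um)] <- NA_real_
  out[.univ_names] <- um

  # ---- spectral
  smv <- spectral_measures(train, set)
  out[names(smv)] <- smv

  # ---- multivariate
  out["S_TS"] <- tiesinga_sejnowski(train)
  out["S_C"] <- spike_contrast(train)
  out[tau_lab("S_GR")] <- golomb_rinzel_all_taus(train, taus)

  # ---- bivariate (+ pooled pair statistics for S_S and F_S)
  if (N >= 2L) {
    sumv <- numeric(nrow(specs))
    cntv <- numeric(nrow(specs))
    ix <- function(nm) match(nm, specs$name)
    put <- function(i, v) {
      if (is.na(v) || !is.finite(v)) return()
      sumv[i] <<- sumv[i] + v
      cntv[i] <<- cntv[i] + 1
    }
    # precomputed column indices
    i_MPC <- ix("MPC"); i_PPC <- ix("PPC"); i_DISI <- ix("D_ISI")
    i_DS <- ix("D_S"); i_DEMD <- ix("D_EMD"); i_DEMDN <- ix("D_EMDN")
    i_DMM <- ix("D_MM"); i_DMMN <- ix("D_MMN"); i_DLZ <- ix("D_LZ")
    i_SQQA <- ix("S_QQA"); i_Sqqa <- ix("S_qqa")
    i_STTC <- ix(tau_lab("STTC")); i_Ci <- ix(tau_lab("C_i"))
    i_DVP <- ix(tau_lab("D_VP")); i_DVPN <- ix(tau_lab("D_VPN"))
    i_DvR <- ix(tau_lab("D_vR")); i_DvRn <- ix(tau_lab("D_vRn"))
    i_CS <- ix(tau_lab("C_S")); i_SHM <- ix(tau_lab("S_HM"))
    i_SQQ <- ix(tau_lab("S_QQ")); i_Sqq <- ix(tau_lab("S_qq"))
    i_CK <- ix(tau_lab("C_K"))
    # per-neuron precomputations
    sp <- train$spikes
    ns <- lengths(sp)
    cover <- vapply(taus, function(tt)
      vapply(sp, tiling_coverage_cpp, numeric(1), tau = tt, T = T) / T,
      numeric(N))
    cover <- matrix(cover, nrow = N)
    self_exp <- vapply(taus, function(tt)
      vapply(sp, function(s) exp_cross_sum_cpp(s, s, tt), numeric(1)),
      numeric(N))
    self_exp <- matrix(self_exp, nrow = N)
    self_gauss <- vapply(taus, function(tt)
      vapply(sp, function(s) gauss_cross_sum_cpp(s, s, sqrt(2) * tt),
             numeric(1)), numeric(N))
    self_gauss <- matrix(self_gauss, nrow = N)
    mnd <- vapply(sp, mean_nearest_dist, numeric(1), T = T)
    bin_seqs <- lapply(sp, binarize_train, T = T, bin_s = 0.001)
    lzc <- vapply(bin_seqs, lz76_complexity_cpp, integer(1))
    # Kruskal correlation over all pairs at once, per timescale
    CK <- lapply(taus, function(tt) {
      nbin <- max(1L, ceiling(T / tt))
      M <- vapply(sp, function(s)
        as.numeric(tabulate(pmin(nbin, floor(s / tt) + 1L), nbins = nbin)),
        numeric(nbin))
      suppressWarnings(stats::cor(M))
    })

    A <- matrix(0, N, N)     # delay-asymmetry matrix for F_S
    a_ok <- FALSE
    sync_hits <- 0
    for (i in seq_len(N - 1L)) {
      a <- sp[[i]]
      for (j in seq.int(i + 1L, N)) {
        b <- sp[[j]]
        put(i_MPC, mean_phase_coherence(a, b))
        put(i_PPC, pairwise_phase_consistency(a, b))
        put(i_DISI, isi_distance(a, b, T))
        put(i_DS, spike_distance(a, b, T))
        put(i_DEMD, earth_movers(a, b, T))
        put(i_DEMDN, earth_movers(a, b, T, normalized = TRUE))
        dmm <- modulus_metric_cpp(a, b, T)
        put(i_DMM, dmm)
        den <- 0.5 * (mnd[i] + mnd[j]) * T
        put(i_DMMN, if (!is.na(dmm) && is.finite(den) && den > 0)
          dmm / den else NA_real_)
        if (ns[i] > 0L && ns[j] > 0L) {
          cab <- lz76_complexity_cpp(c(bin_seqs[[i]], bin_seqs[[j]]))
          cba <- lz76_complexity_cpp(c(bin_seqs[[j]], bin_seqs[[i]]))
          put(i_DLZ, max(cab - lzc[i], cba - lzc[j]) / max(lzc[i], lzc[j]))
          qa <- qq_adaptive_cpp(a, b)
          dn <- sqrt(ns[i] * ns[j])
          put(i_SQQA, min(1, (qa[1] + qa[2]) / dn))
          qv <- (qa[1] - qa[2]) / dn
          put(i_Sqqa, qv)
          A[j, i] <- qv
          A[i, j] <- -qv
          a_ok <- TRUE
          h <- spike_sync_pair_cpp(a, b)
          sync_hits <- sync_hits + h[1] + h[2]
          dab <- nearest_dist_cpp(a, b)
          dba <- nearest_dist_cpp(b, a)
          for (k in seq_along(taus)) {
            tt <- taus[k]
            PA <- mean(dab <= tt)
            PB <- mean(dba <= tt)
            t1 <- if (PA * cover[j, k] < 1)
              (PA - cover[j, k]) / (1 - PA * cover[j, k]) else NA_real_
            t2 <- if (PB * cover[i, k] < 1)
              (PB - cover[i, k]) / (1 - PB * cover[i, k]) else NA_real_
            put(i_STTC[k], mean(c(t1, t2), na.rm = TRUE))
            put(i_Ci[k],
                count_within_cpp(a, b, tt) * T / (2 * tt * ns[i] * ns[j]))
            dvp <- vp_distance_cpp(a, b, 2 / tt)
            put(i_DVP[k], dvp)
            put(i_DVPN[k], dvp / (ns[i] + ns[j]))
            cross <- exp_cross_sum_cpp(a, b, tt)
            dvr <- sqrt(max(0, 0.5 * self_exp[i, k] +
                              0.5 * self_exp[j, k] - cross))
            put(i_DvR[k], dvr)
            put(i_DvRn[k], dvr / sqrt((ns[i] + ns[j]) / 2))
            gc <- gauss_cross_sum_cpp(a, b, sqrt(2) * tt)
            gden <- sqrt(self_gauss[i, k] * self_gauss[j, k])
            put(i_CS[k], if (gden > 0) gc / gden else NA_real_)
            put(i_SHM[k],
                0.5 * (mean(exp(-dab / tt)) + mean(exp(-dba / tt))))
            qc <- qq_counts_cpp(a, b, tt)
            put(i_SQQ[k], min(1, (qc[1] + qc[2]) / dn))
            put(i_Sqq[k], (qc[1] - qc[2]) / dn)
            ckv <- CK[[k]][i, j]
            put(i_CK[k], if (is.finite(ckv)) ckv else NA_real_)
          }
        }
      }
    }
    got <- cntv > 0
    out[got] <- sumv[got] / cntv[got]
    tot_spikes <- sum(ns)
    out["S_S"] <- if (tot_spikes > 0L)
      sync_hits / ((N - 1L) * tot_spikes) else NA_real_
    out["F_S"] <- if (a_ok) best_ordering_score(A) else NA_real_
  }
  attr(out, "specs") <- specs
  out
}

# maximum over neuron orderings of the mean signed delay asymmetry over
# ordered pairs; exhaustive for small N, leadership-sort + adjacent-swap
# refinement otherwise (shared by synfire_indicator and measure_vector)
best_ordering_score <- function(A, max_exact = 8L) {
  N <- nrow(A)
  score <- function(ord) {
    s <- 0
    for (k in seq_len(N - 1L))
      s <- s + sum(A[ord[k], ord[seq.int(k + 1L, N)]])
    s / (N * (N - 1L) / 2)
  }
  if (N <= max_exact) {
    best <- -Inf
    perm_apply(seq_len(N), function(ord) {
      s <- score(ord)
      if (s > best) best <<- s
    })
    return(best)
  }
  ord <- order(rowSums(A), decreasing = TRUE)
  best <- score(ord)
  repeat {
    improved <- FALSE
    for (k in seq_len(N - 1L)) {
      ord2 <- ord
      ord2[c(k, k + 1L)] <- ord2[c(k + 1L, k)]
      s2 <- score(ord2)
      if (s2 > best) { best <- s2; ord <- ord2; improved <- TRUE }
    }
    if (!improved) break
  }
  best
}
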