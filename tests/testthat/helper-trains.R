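# Shared fixtures, all generated in code.

# homogeneous Poisson spike train over [0, T)
poisson_train <- function(rate, T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, rate * T)
  sort(runif(n, 0, T))
}

# multineuron train of independent Poisson neurons
poisson_mnt <- function(N, rate, T, seed = 1) {
  set.seed(seed)
  spike_train(replicate(N, poisson_train(rate, T), simplify = FALSE), T)
}

# multineuron train of N identical copies of one Poisson train
identical_mnt <- function(N, rate, T, seed = 1) {
  set.seed(seed)
  s <- poisson_train(rate, T)
  spike_train(rep(list(s), N), T)
}

# small random spike train pair for property loops
random_pair <- function(max_n = 30, T = 2) {
  list(a = sort(runif(sample(2:max_n, 1), 0, T)),
       b = sort(runif(sample(2:max_n, 1), 0, T)),
       T = T)
}

# z-score columns (plain base-R version for test fixtures)
scale_columns_test <- function(M) {
  out <- scale(M)
  out[, attr(out, "scaled:scale") > 0, drop = FALSE]
}

# map extended measure columns onto the core measure set
core_from_extended <- function(M) {
  spc <- measure_specs("core")
  cols <- ifelse(is.na(spc$tau), spc$name, paste0(spc$base, "_t1"))
  Mc <- M[, cols, drop = FALSE]
  colnames(Mc) <- spc$name
  Mc
}
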