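# Run configuration: one flat key-value record collecting every tunable
# default of the pipeline, round-trippable through a plain text file.

#' Run configuration
#'
#' Collects the documented defaults of the whole pipeline in one flat
#' record: the master seed, measure set, the generator defaults
#' (rates, modulation, frequencies, refractory periods, OU noise,
#' population size and duration, simulation step), the spectral
#' analysis keys (kernel bandwidth, rate grid, Welch segment, analysis
#' band, peak significance), and the state-space settings (window
#' length, permutation count, cross-validation scheme). Values can be
#' overridden by name; unknown keys are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `run_config`.
#' @examples
#' cfg <- run_config(seed = 7, window_s = 10)
#' cfg$window_s
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    measure_set = "core",
    # generator defaults
    r0 = 12, m = 0.5, Sigma = 0.2, p_fail = 0, f0 = 12,
    rhythmic = TRUE, Dc = 0, N = 100L, T = 10,
    t_refr_neu = 0.004, tau_OU = 0.01, dt = 1e-5,
    # spectral analysis
    kernel_bw_ms = 2, grid_dt_ms = 1, welch_segment_s = 2,
    band_lo_hz = 1, band_hi_hz = 100, peak_sig_mult = 2,
    peak_min_height = 0.6,
    # state space
    window_s = 30, n_perm = 1000L, cv_scheme = "within")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read and write run configurations as flat key-value text
#'
#' One `key = value` pair per line; strings unquoted, logicals
#' TRUE/FALSE, numbers at full precision. Round-trips [run_config()]
#' objects losslessly.
#'
#' @param cfg a [run_config()] object.
#' @param path file path.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  fmt <- vapply(cfg, function(v) {
    if (is.character(v)) v
    else if (is.logical(v)) as.character(v)
    else format(v, digits = 17, scientific = TRUE)
  }, character(1))
  writeLines(paste(names(cfg), fmt, sep = " = "), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines,
                   regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=(.*)$",
                           lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad)) stop("unparseable config line: ", bad[1L])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  proto <- run_config()
  over <- stats::setNames(vector("list", length(keys)), keys)
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(proto)) stop("unknown config key: ", k)
    v <- vals[i]
    over[[i]] <- if (is.character(proto[[k]])) v
      else if (is.logical(proto[[k]])) as.logical(v)
      else if (is.integer(proto[[k]])) as.integer(as.numeric(v))
      else as.numeric(v)
  }
  do.call(run_config, over)
}
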