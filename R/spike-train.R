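#' Multineuron spike train
#'
#' Container for a multivariate point process: `N` per-neuron vectors of
#' spike times (seconds), sorted ascending, over the half-open observation
#' window `[0, T)`. Synthetic trains carry their generative family and
#' parameter values in `meta`, and optionally a `trace` with intermediate
#' generative quantities (phase noise, node/event times, jitters).
#'
#' @param spikes list of numeric vectors, one per neuron, spike times in
#'   seconds. Unsorted input is sorted; times must lie in `[0, T)`.
#' @param T observation window length in seconds (> 0).
#' @param meta optional named list of generative metadata.
#' @param trace optional list of generative intermediates.
#' @return An object of class `spike_train` with fields `spikes`, `T`,
#'   `N`, `meta`, `trace`.
#' @examples
#' st <- spike_train(list(c(0.1, 0.5), c(0.2)), T = 1)
#' st$N
#' @export
spike_train <- function(spikes, T, meta = list(), trace = NULL) {
  if (!is.list(spikes)) spikes <- list(spikes)
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("T must be a single positive number")
  spikes <- lapply(spikes, function(s) {
    s <- as.numeric(s)
    if (any(!is.finite(s))) stop("non-finite spike time")
    if (any(s < 0) || any(s >= T))
      stop("spike times must lie in [0, T)")
    sort(s)
  })
  structure(
    list(spikes = spikes, T = T, N = length(spikes),
         meta = meta, trace = trace),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- vapply(x$spikes, length, integer(1))
  cat(sprintf("spike_train: %d neurons over [0, %g) s, %d spikes (%.2f Hz/neuron)\n",
              x$N, x$T, sum(n), mean(n) / x$T))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta),
                         vapply(x$meta, function(v) paste(format(v), collapse = ","),
                                character(1)),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
format.spike_train <- function(x, ...) {
  sprintf("<spike_train N=%d T=%g>", x$N, x$T)
}

#' Read and write spike trains as two-column text
#'
#' The plain-text interchange format is one line per spike,
#' `unit_id<TAB>spike_time_s`, with unit ids `1..N`, preceded by a header
#' line `# T=<seconds> N=<count>`. Units without spikes are legal (they
#' are implied by `N`). `write_spike_trains()` writes full double
#' precision; `read_spike_trains()` validates times against the header
#' window and reports the offending line on failure.
#'
#' @param path file path.
#' @param train a [spike_train] object.
#' @return `read_spike_trains()` returns a [spike_train];
#'   `write_spike_trains()` returns `path` invisibly.
#' @examples
#' st <- spike_train(list(c(0.1, 0.5), numeric(0)), T = 1)
#' f <- tempfile(fileext = ".txt")
#' write_spike_trains(st, f)
#' identical(read_spike_trains(f)$spikes, st$spikes)
#' @export
read_spike_trains <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#\\s*T=", lines[1]))
    stop("missing header line '# T=<seconds> N=<count>'")
  hdr <- lines[1]
  T <- as.numeric(sub(".*T=([0-9.eE+-]+).*", "\\1", hdr))
  N <- as.integer(sub(".*N=([0-9]+).*", "\\1", hdr))
  if (!is.finite(T) || is.na(N)) stop("unparseable header: ", hdr)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  spikes <- rep(list(numeric(0)), N)
  if (length(body)) {
    parts <- strsplit(body, "[\t ]+")
    for (k in seq_along(parts)) {
      p <- parts[[k]]
      if (length(p) != 2L)
        stop("line ", k + 1L, ": expected 'unit_id<TAB>time', got: ", body[k])
      uid <- suppressWarnings(as.integer(p[1]))
      tm <- suppressWarnings(as.numeric(p[2]))
      if (is.na(uid) || uid < 1L || uid > N)
        stop("line ", k + 1L, ": unknown unit id '", p[1], "'")
      if (!is.finite(tm) || tm < 0 || tm >= T)
        stop("line ", k + 1L, ": spike time ", p[2], " outside [0, ", T, ")")
      spikes[[uid]] <- c(spikes[[uid]], tm)
    }
  }
  spike_train(spikes, T)
}

#' @rdname read_spike_trains
#' @export
write_spike_trains <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# T=%s N=%d", format(train$T, digits = 17), train$N), con)
  for (j in seq_len(train$N)) {
    s <- train$spikes[[j]]
    if (length(s))
      writeLines(sprintf("%d\t%s", j, format(s, digits = 17, scientific = FALSE,
                                             trim = TRUE)), con)
  }
  invisible(path)
}

#' Read and write spike trains as a JSON container
#'
#' JSON alternative to the two-column text format, carrying spikes plus
#' generative metadata. Round-trips [spike_train] objects losslessly
#' (times at full double precision).
#'
#' @inheritParams read_spike_trains
#' @return `read_spike_trains_json()` returns a [spike_train].
#' @export
write_spike_trains_json <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  obj <- list(T = train$T, N = train$N, meta = train$meta,
              spikes = train$spikes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_trains_json
#' @export
read_spike_trains_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spikes <- obj$spikes
  if (is.null(spikes)) spikes <- rep(list(numeric(0)), obj$N)
  if (!is.list(spikes)) spikes <- as.list(spikes)
  spikes <- lapply(spikes, function(s) if (is.null(s)) numeric(0) else as.numeric(s))
  while (length(spikes) < obj$N) spikes <- c(spikes, list(numeric(0)))
  meta <- obj$meta
  if (is.null(meta)) meta <- list()
  spike_train(spikes, obj$T, meta = as.list(meta))
}
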