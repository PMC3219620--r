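#' Spike train sets
#'
#' A `spike_trains` object is the universal currency between the input
#' generators, the network simulator and the analysis functions: a tibble with
#' one row per spike, columns `source` (integer train / neuron id, 1-based) and
#' `time` (ms), sorted by source then time, carrying the covered interval as
#' attributes `n_sources`, `t_start` and `duration`. Sources with no spikes are
#' legal; simultaneous duplicate spikes in one train are kept (trains are
#' multisets of times).
#'
#' @param time numeric vector of spike times (ms).
#' @param source integer vector of source ids in `1:n_sources`, same length as
#'   `time`.
#' @param n_sources number of trains covered by the set (including silent ones).
#' @param duration length of the covered interval (ms).
#' @param t_start onset of the covered interval (ms). Times must lie in
#'   `[t_start, t_start + duration]`.
#' @return A tibble of class `spike_trains`.
#' @examples
#' st <- spike_trains(c(1.5, 3.2, 2.0), c(1L, 1L, 2L), n_sources = 3, duration = 10)
#' n_sources(st)
#' @export
spike_trains <- function(time, source, n_sources, duration, t_start = 0) {
  stopifnot(length(time) == length(source))
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    abort("`duration` must be a single positive number (ms).")
  if (n_sources < 1) abort("`n_sources` must be >= 1.")
  source <- as.integer(source)
  if (length(time)) {
    if (any(time < t_start - 1e-9) || any(time > t_start + duration + 1e-9))
      abort("spike times must lie within [t_start, t_start + duration].")
    if (any(source < 1L) || any(source > n_sources))
      abort("`source` ids must lie in 1:n_sources.")
    o <- order(source, time)
    time <- time[o]
    source <- source[o]
  }
  out <- tibble(source = source, time = as.numeric(time))
  attr(out, "n_sources") <- as.integer(n_sources)
  attr(out, "t_start") <- as.numeric(t_start)
  attr(out, "duration") <- as.numeric(duration)
  class(out) <- c("spike_trains", class(out))
  out
}

#' @rdname spike_trains
#' @param x a `spike_trains` object.
#' @export
n_sources <- function(x) attr(x, "n_sources")

#' @rdname spike_trains
#' @export
t_start <- function(x) attr(x, "t_start")

#' @rdname spike_trains
#' @export
st_duration <- function(x) attr(x, "duration")

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains: %d spikes, %d sources, [%g, %g) ms>\n",
              nrow(x), n_sources(x), t_start(x), t_start(x) + st_duration(x)))
  NextMethod()
}

# list of per-source spike-time vectors (length n_sources, silent trains empty)
st_split <- function(x, ids = NULL) {
  if (is.null(ids)) ids <- seq_len(n_sources(x))
  f <- factor(x$source, levels = ids)
  keep <- !is.na(f)
  split(x$time[keep], f[keep])
}

#' Binned spike counts
#'
#' Bins each train of a spike-train set into contiguous time bins (anchored at
#' the start of the analysis window) and returns the bins x trains count
#' matrix. Used by the correlation estimator and the synchrony index.
#'
#' @param x a [spike_trains()] object.
#' @param binwidth bin width (ms).
#' @param ids train ids to include (default all).
#' @param window `c(t0, t1)` analysis window (ms); defaults to the covered
#'   interval. Bins are `[t0 + k*binwidth, t0 + (k+1)*binwidth)`; a trailing
#'   partial bin is dropped.
#' @return integer matrix, `n_bins` rows and `length(ids)` columns.
#' @export
binned_counts <- function(x, binwidth = 5, ids = NULL, window = NULL) {
  if (is.null(window)) window <- c(t_start(x), t_start(x) + st_duration(x))
  if (binwidth <= 0) abort("`binwidth` must be positive.")
  n_bins <- floor((window[2] - window[1]) / binwidth + 1e-9)
  if (n_bins < 1) abort("window shorter than one bin.")
  if (is.null(ids)) ids <- seq_len(n_sources(x))
  trains <- st_split(x, ids)
  m <- matrix(0L, nrow = n_bins, ncol = length(ids))
  for (j in seq_along(trains)) {
    tt <- trains[[j]]
    tt <- tt[tt >= window[1] & tt < window[1] + n_bins * binwidth]
    if (length(tt))
      m[, j] <- tabulate(floor((tt - window[1]) / binwidth) + 1L, nbins = n_bins)
  }
  m
}

# summed population count vector over bins
population_counts <- function(x, binwidth = 5, ids = NULL, window = NULL) {
  if (is.null(window)) window <- c(t_start(x), t_start(x) + st_duration(x))
  n_bins <- floor((window[2] - window[1]) / binwidth + 1e-9)
  if (n_bins < 1) abort("window shorter than one bin.")
  tt <- x$time
  if (!is.null(ids)) tt <- tt[x$source %in% ids]
  tt <- tt[tt >= window[1] & tt < window[1] + n_bins * binwidth]
  tabulate(floor((tt - window[1]) / binwidth) + 1L, nbins = n_bins)
}

#' Read and write spike trains as plain text
#'
#' The text dialect is two whitespace-separated columns, `source_id time_ms`,
#' sorted by time, preceded by a single header comment carrying the interval
#' metadata. The round trip is lossless.
#'
#' @param x a [spike_trains()] object.
#' @param path file path.
#' @return `write_spike_text()` returns `x` invisibly; `read_spike_text()`
#'   returns a [spike_trains()] object.
#' @export
write_spike_text <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_sources=%d t_start=%.17g duration=%.17g",
                     n_sources(x), t_start(x), st_duration(x)), con)
  o <- order(x$time, x$source)
  writeLines(sprintf("%d %.17g", x$source[o], x$time[o]), con)
  invisible(x)
}

#' @rdname write_spike_text
#' @export
read_spike_text <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "# n_sources=(\\S+) t_start=(\\S+) duration=(\\S+)", hdr))[[1]]
  if (length(m) != 4) abort("not a striatnet spike text file (missing header).")
  d <- utils::read.table(path, skip = 1, col.names = c("source", "time"),
                         colClasses = c("integer", "numeric"))
  spike_trains(d$time, d$source, n_sources = as.integer(m[2]),
               duration = as.numeric(m[4]), t_start = as.numeric(m[3]))
}

#' Subset a spike-train set by source
#'
#' @param x a [spike_trains()] object.
#' @param ids sources to keep; ids are renumbered `1:length(ids)` in the order
#'   given.
#' @return a [spike_trains()] object over the same interval.
#' @export
st_subset <- function(x, ids) {
  keep <- x$source %in% ids
  new_id <- match(x$source[keep], ids)
  spike_trains(x$time[keep], new_id, n_sources = length(ids),
               duration = st_duration(x), t_start = t_start(x))
}
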