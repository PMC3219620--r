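#' Mean population firing rate
#'
#' Mean spike count per second per neuron: total spikes of the id set inside
#' the window divided by `length(ids) * window length`.
#'
#' @param spikes a [spike_trains()] object.
#' @param ids neuron/train ids to include (default: all sources).
#' @param window `c(t0, t1)` analysis window (ms); default the covered
#'   interval. Spikes at exactly `t1` are counted when `t1` is the end of the
#'   covered interval.
#' @return rate in Hz (numeric scalar).
#' @export
mean_firing_rate <- function(spikes, ids = NULL, window = NULL) {
  if (is.null(ids)) ids <- seq_len(n_sources(spikes))
  if (!length(ids)) abort("empty id set.")
  t_end <- t_start(spikes) + st_duration(spikes)
  if (is.null(window)) window <- c(t_start(spikes), t_end)
  if (window[2] <= window[1]) abort("window must satisfy t1 > t0.")
  tt <- spikes$time[spikes$source %in% ids]
  closed_end <- abs(window[2] - t_end) < 1e-9
  k <- sum(tt >= window[1] & (tt < window[2] | (closed_end & tt <= window[2])))
  1000 * k / (length(ids) * (window[2] - window[1]))
}

#' Synchrony index (population Fano factor)
#'
#' The rate-scaled variance of the binned cumulative population spike count:
#' the spike trains of all selected neurons are summed, binned (default 5 ms),
#' and the Fano factor `var(N)/mean(N)` of the bin counts is returned. A
#' population of independent Poisson processes yields 1; mutual
#' synchronization drives the index above 1.
#'
#' @inheritParams mean_firing_rate
#' @param binwidth bin width (ms).
#' @return the synchrony index (numeric scalar); `NA` with a warning when the
#'   window contains no spikes.
#' @export
synchrony_index <- function(spikes, ids = NULL, binwidth = 5, window = NULL) {
  counts <- population_counts(spikes, binwidth = binwidth, ids = ids,
                              window = window)
  fano(counts)
}

# var/mean of a count vector; NA sentinel on an all-zero record
fano <- function(counts) {
  m <- mean(counts)
  if (m == 0) {
    warn("synchrony index undefined: no spikes in window.")
    return(NA_real_)
  }
  var(counts) / m
}

#' Signal-to-noise ratio of the stimulus representation
#'
#' Ratio of the mean firing rate of the stimulated MSNs to that of the
#' unstimulated MSNs, both measured over the stimulation epoch. The model's
#' saliency measure for signal representation.
#'
#' @param rate_stim mean rate of the stimulated MSNs (Hz).
#' @param rate_unstim mean rate of the unstimulated MSNs (Hz).
#' @return `rate_stim / rate_unstim`; `NA` with a warning when
#'   `rate_unstim = 0` (undefined SNR).
#' @export
signal_to_noise_ratio <- function(rate_stim, rate_unstim) {
  if (rate_stim < 0 || rate_unstim < 0) abort("rates must be non-negative.")
  if (rate_unstim == 0) {
    warn("SNR undefined: unstimulated rate is 0.")
    return(NA_real_)
  }
  rate_stim / rate_unstim
}

#' Peri-stimulus time histogram
#'
#' Per-bin population rate, `count / (n_ids * binwidth)`, in Hz.
#'
#' @inheritParams synchrony_index
#' @return a tibble with `time` (bin left edge, ms) and `rate` (Hz).
#' @export
psth <- function(spikes, ids = NULL, binwidth = 5, window = NULL) {
  if (is.null(ids)) ids <- seq_len(n_sources(spikes))
  if (!length(ids)) abort("empty id set.")
  if (is.null(window))
    window <- c(t_start(spikes), t_start(spikes) + st_duration(spikes))
  counts <- population_counts(spikes, binwidth = binwidth, ids = ids,
                              window = window)
  tibble(time = window[1] + (seq_along(counts) - 1) * binwidth,
         rate = 1000 * counts / (length(ids) * binwidth))
}

#' Summarize activity by group
#'
#' Rates and synchrony indices for named groups of neurons over a window, as
#' one tidy row per group.
#'
#' @param spikes a [spike_trains()] object.
#' @param groups named list of id vectors (e.g. stimulated / unstimulated
#'   MSNs, FSIs).
#' @param window analysis window (ms).
#' @param binwidth synchrony bin width (ms).
#' @return tibble with columns `group`, `n_ids`, `rate` (Hz), `sync`.
#' @export
summarize_activity <- function(spikes, groups, window = NULL, binwidth = 5) {
  purrr::imap_dfr(groups, function(ids, nm) {
    tibble(group = nm, n_ids = length(ids),
           rate = mean_firing_rate(spikes, ids, window),
           sync = suppressWarnings(
             synchrony_index(spikes, ids, binwidth, window)))
  })
}

# --- free membrane potential statistics -------------------------------------

#' Tidy free-membrane-potential traces
#'
#' Converts the `vm_traces` matrix recorded from non-spiking clones (rows =
#' samples at `dt` resolution, columns = cloned neurons) to a long tibble.
#'
#' @param x a `vm_traces` object from [simulate_network()].
#' @param ... unused.
#' @return tibble with `neuron`, `time` (ms), `v` (mV).
#' @export
tidy_vm <- function(x, ...) {
  ids <- attr(x, "ids")
  tt <- attr(x, "time")
  tibble(neuron = rep(ids, each = nrow(x)),
         time = rep(tt, times = ncol(x)),
         v = as.vector(unclass(x)))
}

#' Cross-correlation of free membrane potentials
#'
#' Pairwise normalized cross-correlation of the clone traces as a function of
#' time lag, after removing each trace's window mean; the zero-lag
#' coefficients (Pearson correlations) are averaged over pairs. Constant
#' traces are excluded with a warning.
#'
#' @param vm a `vm_traces` object (>= 2 traces).
#' @param max_lag maximum lag (ms).
#' @return list of class `vm_stats`: `zero_lag` (mean over pairs),
#'   `zero_lag_pairs` (per-pair coefficients), and `ccf`, a tibble with
#'   `lag` (ms) and `ccf` (mean over pairs).
#' @export
vm_cross_correlation <- function(vm, max_lag = 50) {
  m <- unclass(vm)
  attributes(m) <- attributes(m)["dim"]
  dt <- attr(vm, "dt")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("excluding %d constant trace(s)", sum(sds == 0)))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 2) abort("need at least 2 non-constant traces.")
  m <- scale(m, center = TRUE, scale = FALSE)
  n <- nrow(m)
  lag_steps <- seq(-floor(max_lag / dt), floor(max_lag / dt))
  pairs <- utils::combn(ncol(m), 2)
  sdv <- sqrt(colMeans(m^2))   # population normalization: identical traces -> 1
  acc <- numeric(length(lag_steps))
  zero <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- m[, pairs[1, p]]
    b <- m[, pairs[2, p]]
    cc <- vapply(lag_steps, function(l) {
      if (l >= 0) mean(a[seq_len(n - l)] * b[seq_len(n - l) + l])
      else mean(a[seq_len(n + l) - l] * b[seq_len(n + l)])
    }, numeric(1)) / (sdv[pairs[1, p]] * sdv[pairs[2, p]])
    acc <- acc + cc
    zero[p] <- cc[lag_steps == 0]
  }
  structure(list(zero_lag = mean(zero), zero_lag_pairs = zero,
                 ccf = tibble(lag = lag_steps * dt, ccf = acc / ncol(pairs))),
            class = "vm_stats")
}

#' @export
print.vm_stats <- function(x, ...) {
  cat(sprintf("<vm_stats: mean zero-lag correlation %.3f over %d pairs>\n",
              x$zero_lag, length(x$zero_lag_pairs)))
  invisible(x)
}

#' Standard deviation of free membrane potential fluctuations
#'
#' Per-trace standard deviation of the clone potentials over a window.
#'
#' @param vm a `vm_traces` object.
#' @param window `c(t0, t1)` (ms) within the recorded extent; default all.
#' @return tibble with `neuron` and `sd_mv`.
#' @export
vm_fluctuation_std <- function(vm, window = NULL) {
  m <- unclass(vm)
  attributes(m) <- attributes(m)["dim"]
  tt <- attr(vm, "time")
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    if (!any(keep)) abort("window outside the recorded extent.")
    m <- m[keep, , drop = FALSE]
  }
  tibble(neuron = attr(vm, "ids"), sd_mv = apply(m, 2, sd))
}
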