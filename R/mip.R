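#' Independent Poisson spike trains
#'
#' Homogeneous Poisson processes, the model for background cortico-striatal
#' input (and for uncorrelated FSI activity). Uses the session RNG, so
#' `set.seed()` makes draws reproducible.
#'
#' @param n number of trains.
#' @param rate firing rate per train (Hz).
#' @param duration interval length (ms).
#' @param t_start interval onset (ms).
#' @return a [spike_trains()] object.
#' @examples
#' set.seed(1)
#' st <- generate_poisson_trains(10, rate = 5, duration = 1000)
#' @export
generate_poisson_trains <- function(n, rate, duration, t_start = 0) {
  if (n < 1) abort("`n` must be >= 1.")
  if (rate < 0) abort("`rate` must be non-negative.")
  if (duration <= 0) abort("`duration` must be positive.")
  counts <- rpois(n, rate * duration / 1000)
  src <- rep.int(seq_len(n), counts)
  tt <- t_start + runif(sum(counts)) * duration
  spike_trains(tt, src, n_sources = n, duration = duration, t_start = t_start)
}

# mother/child machinery shared by the MIP generators ------------------------

# Poisson event times at `rate` Hz on [t_start, t_start + duration)
poisson_times <- function(rate, duration, t_start = 0) {
  k <- rpois(1, rate * duration / 1000)
  sort(t_start + runif(k) * duration)
}

# Bernoulli-thin each mother spike into n children with copy probability p;
# returns list(time, source) for the child ensemble
thin_children <- function(mother, n, p) {
  if (!length(mother) || p == 0)
    return(list(time = numeric(0), source = integer(0)))
  if (p == 1)
    return(list(time = rep(mother, n), source = rep(seq_len(n), each = length(mother))))
  keep <- runif(length(mother) * n) < p    # column-major: children vary slowest
  idx <- which(keep)
  list(time = mother[((idx - 1L) %% length(mother)) + 1L],
       source = ((idx - 1L) %/% length(mother)) + 1L)
}

#' MIP ensembles of correlated Poisson spike trains
#'
#' Generates a multiple-interaction-process (MIP) ensemble: spikes of a common
#' "mother" Poisson process are copied into each of `n_trains` child trains
#' independently with copy probability `c_w`. Every child is then itself a
#' Poisson process of rate `ensemble_rate / n_trains`, and the pairwise
#' spike-count correlation between children equals `c_w`. The mother rate is
#' `ensemble_rate / (n_trains * c_w)`, so the expected total ensemble rate is
#' conserved for every `c_w`. With `c_w = 0` the ensemble degenerates to
#' independent Poisson trains at the same per-train rate; with `c_w = 1` all
#' children are identical copies of the mother.
#'
#' @param n_trains number of child trains.
#' @param ensemble_rate total expected spike rate summed over the ensemble (Hz).
#' @param c_w copy probability = target pairwise correlation, in \[0, 1\].
#' @inheritParams generate_poisson_trains
#' @return a [spike_trains()] object.
#' @examples
#' set.seed(1)
#' st <- generate_mip(100, ensemble_rate = 400, c_w = 0.02, duration = 10000)
#' estimate_pairwise_correlation(st)
#' @export
generate_mip <- function(n_trains, ensemble_rate, c_w, duration, t_start = 0) {
  if (n_trains < 1) abort("`n_trains` must be >= 1.")
  if (ensemble_rate < 0) abort("`ensemble_rate` must be non-negative.")
  if (c_w < 0 || c_w > 1) abort("`c_w` must lie in [0, 1].")
  if (duration <= 0) abort("`duration` must be positive.")
  if (c_w == 0)
    return(generate_poisson_trains(n_trains, ensemble_rate / n_trains,
                                   duration, t_start))
  mother <- poisson_times(ensemble_rate / (n_trains * c_w), duration, t_start)
  ch <- thin_children(mother, n_trains, c_w)
  spike_trains(ch$time, ch$source, n_sources = n_trains,
               duration = duration, t_start = t_start)
}

#' Hierarchically correlated MIP ensembles
#'
#' Input configuration II: each of `n_pools` stimulated neurons has its own MIP
#' input pool with within-pool correlation `c_w`, and the pools' mother
#' processes are themselves correlated with copy probability `c_b` by thinning
#' a single shared "grandmother" Poisson process. A child is then a
#' `c_w * c_b` thinning of the grandmother, so the between-pool pairwise
#' correlation is `c_w * c_b`, while the within-pool correlation stays `c_w`.
#' `c_b = 0` reduces exactly to `n_pools` independent [generate_mip()] draws
#' (configuration I); `c_b = 1` makes all pools children of one common mother.
#'
#' @param n_pools number of independent presynaptic pools.
#' @param c_b copy probability correlating the pools' mothers, in \[0, 1\].
#' @inheritParams generate_mip
#' @return a list of `n_pools` [spike_trains()] objects.
#' @export
generate_hierarchical_mip <- function(n_pools, n_trains, ensemble_rate, c_w, c_b,
                                      duration, t_start = 0) {
  if (n_pools < 1) abort("`n_pools` must be >= 1.")
  if (c_b < 0 || c_b > 1) abort("`c_b` must lie in [0, 1].")
  if (c_b == 0 || c_w == 0)
    return(lapply(seq_len(n_pools), function(i)
      generate_mip(n_trains, ensemble_rate, c_w, duration, t_start)))
  if (c_w < 0 || c_w > 1) abort("`c_w` must lie in [0, 1].")
  if (duration <= 0) abort("`duration` must be positive.")
  mother_rate <- ensemble_rate / (n_trains * c_w)
  grandmother <- poisson_times(mother_rate / c_b, duration, t_start)
  lapply(seq_len(n_pools), function(i) {
    mother <- grandmother[runif(length(grandmother)) < c_b]
    ch <- thin_children(mother, n_trains, c_w)
    spike_trains(ch$time, ch$source, n_sources = n_trains,
                 duration = duration, t_start = t_start)
  })
}

#' Correlated FSI spike trains
#'
#' Output trains for fast-spiking interneurons with a prescribed pairwise
#' correlation `c_fsi`, built as a MIP ensemble with per-train rate
#' `rate_per_train`. With `c_fsi = 0` the trains are independent Poisson.
#'
#' @param n_fsi number of FSI sources.
#' @param rate_per_train target FSI firing rate (Hz).
#' @param c_fsi pairwise correlation among the FSI trains, in \[0, 1\].
#' @inheritParams generate_poisson_trains
#' @return a [spike_trains()] object.
#' @export
generate_correlated_fsi <- function(n_fsi, rate_per_train, c_fsi, duration,
                                    t_start = 0) {
  if (rate_per_train < 0) abort("`rate_per_train` must be non-negative.")
  if (c_fsi < 0 || c_fsi > 1) abort("`c_fsi` must lie in [0, 1].")
  generate_mip(n_fsi, ensemble_rate = n_fsi * rate_per_train, c_w = c_fsi,
               duration = duration, t_start = t_start)
}

# aggregate MIP representation: mother event times with Binomial(n, c_w)
# multiplicities -- the exact distribution of the ensemble's summed train,
# used to drive single target neurons without materializing all children
mip_aggregate <- function(n_trains, ensemble_rate, c_w, duration, t_start = 0) {
  if (c_w == 0) {
    tt <- poisson_times(ensemble_rate, duration, t_start)
    return(list(time = tt, mult = rep.int(1, length(tt))))
  }
  mother <- poisson_times(ensemble_rate / (n_trains * c_w), duration, t_start)
  mult <- rbinom(length(mother), n_trains, c_w)
  keep <- mult > 0
  list(time = mother[keep], mult = as.numeric(mult[keep]))
}

# hierarchical counterpart: one aggregate per pool, mothers thinned from a
# shared grandmother with probability c_b
hier_mip_aggregate <- function(n_pools, n_trains, ensemble_rate, c_w, c_b,
                               duration, t_start = 0) {
  if (c_b == 0 || c_w == 0)
    return(lapply(seq_len(n_pools), function(i)
      mip_aggregate(n_trains, ensemble_rate, c_w, duration, t_start)))
  mother_rate <- ensemble_rate / (n_trains * c_w)
  grandmother <- poisson_times(mother_rate / c_b, duration, t_start)
  lapply(seq_len(n_pools), function(i) {
    mother <- grandmother[runif(length(grandmother)) < c_b]
    mult <- rbinom(length(mother), n_trains, c_w)
    keep <- mult > 0
    list(time = mother[keep], mult = as.numeric(mult[keep]))
  })
}

#' Jitter spike times
#'
#' Displaces every spike independently by zero-mean Gaussian noise of standard
#' deviation `sd` ms, clipping displaced spikes to the interval boundaries and
#' re-sorting each train. Models the few-ms jitter of near-coincident input
#' spikes.
#'
#' @param x a [spike_trains()] object.
#' @param sd jitter standard deviation (ms); `sd = 0` returns `x` unchanged.
#' @return a [spike_trains()] object over the same interval.
#' @export
apply_jitter <- function(x, sd) {
  if (sd < 0) abort("`sd` must be non-negative.")
  if (sd == 0 || nrow(x) == 0) return(x)
  t0 <- t_start(x)
  t1 <- t0 + st_duration(x)
  tt <- x$time + rnorm(nrow(x), 0, sd)
  tt <- pmin(pmax(tt, t0), t1 - 1e-9)
  spike_trains(tt, x$source, n_sources = n_sources(x),
               duration = st_duration(x), t_start = t0)
}

#' Mean pairwise spike-count correlation
#'
#' The validation oracle for the MIP generators: bins each train
#' (default 5 ms, the synchrony-index bin convention), computes Pearson
#' correlations of the binned counts for all train pairs (optionally a random
#' subset of trains, to bound cost for large ensembles), and averages. Trains
#' with zero count variance are excluded with a warning.
#'
#' @param x a [spike_trains()] object with at least 2 trains.
#' @param binwidth bin width (ms).
#' @param max_trains cap on the number of trains entering the all-pairs
#'   estimate; a random subset is taken above it.
#' @param window analysis window `c(t0, t1)` (ms); default the whole interval.
#' @return the mean pairwise correlation (numeric scalar) with attributes
#'   `se` (standard error of the mean over pairs, treating pairs as
#'   independent) and `n_pairs`.
#' @export
estimate_pairwise_correlation <- function(x, binwidth = 5, max_trains = 200,
                                          window = NULL) {
  if (n_sources(x) < 2) abort("need at least 2 trains.")
  ids <- seq_len(n_sources(x))
  if (length(ids) > max_trains) ids <- sort(sample(ids, max_trains))
  m <- binned_counts(x, binwidth = binwidth, ids = ids, window = window)
  v <- apply(m, 2, var)
  if (any(v == 0)) {
    warn(sprintf("excluding %d train(s) with zero count variance", sum(v == 0)))
    m <- m[, v > 0, drop = FALSE]
  }
  if (ncol(m) < 2) abort("fewer than 2 trains with nonzero count variance.")
  cc <- cor(m)
  pairs <- cc[upper.tri(cc)]
  out <- mean(pairs)
  attr(out, "se") <- sd(pairs) / sqrt(length(pairs))
  attr(out, "n_pairs") <- length(pairs)
  out
}
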