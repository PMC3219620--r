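#' Stimulation parameter sweeps
#'
#' Runs the stimulation experiment over a grid of protocol/network parameters
#' and aggregates the activity descriptors per grid point. For every point the
#' network graph and the stimulated sets are rebuilt from a structure seed
#' derived from `seed` (identical across points of equal size, so sweeps over
#' conductances or input statistics share one network), and `n_trials` trials
#' are run with distinct derived trial seeds. Per point the sweep reports the
#' stimulated and unstimulated MSN rates over the stimulation epoch (means and
#' standard errors over trials), the SNR (ratio of the trial-mean rates), and
#' synchrony indices of both subpopulations over the stimulation epoch pooled
#' across trials.
#'
#' @param config a [network_config()] (already scaled, if desired; see
#'   [scale_config()]).
#' @param protocol a [stimulus_protocol()] providing the defaults for all
#'   fields not present in `grid`.
#' @param grid data frame of parameter combinations; recognized columns are
#'   the protocol fields `c_w`, `c_b`, `f_stim`, `ensemble_rate`, `c_fsi`,
#'   `jitter_sd` and the network fields `g_fb`, `g_ff`. Build it with
#'   [tidyr::expand_grid()].
#' @param n_trials trials per grid point (default `protocol$n_trials`).
#' @param seed base seed; every per-point, per-trial seed is derived from it
#'   and recorded in the `seeds` attribute of the result.
#' @return a tibble of class `striatal_sweep`: the grid columns plus
#'   `rate_stim`, `rate_stim_se`, `rate_unstim`, `rate_unstim_se`, `snr`,
#'   `sync_stim`, `sync_unstim`, `n_trials`.
#' @examples
#' \donttest{
#' cfg <- scale_config(network_config(), 0.1)
#' pr <- stimulus_protocol(t_on = 200)
#' sw <- run_sweep(cfg, pr, tidyr::expand_grid(c_w = c(0.005, 0.02)),
#'                 n_trials = 3, seed = 1)
#' }
#' @export
run_sweep <- function(config, protocol, grid, n_trials = NULL, seed = 1) {
  if (!nrow(grid)) abort("`grid` must have at least one row.")
  if (is.null(n_trials)) n_trials <- protocol$n_trials
  set.seed(seed)
  structure_seed <- sample.int(.Machine$integer.max, 1)
  trial_seeds <- matrix(sample.int(.Machine$integer.max, nrow(grid) * n_trials),
                        nrow = nrow(grid))
  net_fields <- intersect(names(grid), c("g_fb", "g_ff"))
  proto_fields <- intersect(names(grid),
                            c("c_w", "c_b", "f_stim", "ensemble_rate",
                              "c_fsi", "jitter_sd"))
  unknown <- setdiff(names(grid), c(net_fields, proto_fields))
  if (length(unknown))
    abort(paste("unknown grid column(s):", paste(unknown, collapse = ", ")))

  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    cfg <- config
    pr <- protocol
    for (f in net_fields) cfg[[f]] <- grid[[f]][g]
    for (f in proto_fields) pr[[f]] <- grid[[f]][g]
    point <- tryCatch(
      sweep_point(cfg, pr, n_trials, structure_seed, trial_seeds[g, ]),
      error = function(e) {
        warn(sprintf("grid point %d failed (%s); skipped.", g,
                     conditionMessage(e)))
        tibble(rate_stim = NA_real_, rate_stim_se = NA_real_,
               rate_unstim = NA_real_, rate_unstim_se = NA_real_,
               snr = NA_real_, sync_stim = NA_real_, sync_unstim = NA_real_,
               n_trials = 0L)
      })
    dplyr::bind_cols(grid[g, , drop = FALSE], point)
  })
  attr(rows, "seeds") <- list(base = seed, structure = structure_seed,
                              trials = trial_seeds)
  class(rows) <- c("striatal_sweep", class(rows))
  rows
}

# one grid point: fixed network + stimulated sets, n_trials trials
sweep_point <- function(cfg, pr, n_trials, structure_seed, trial_seeds) {
  set.seed(structure_seed)
  conn <- build_connectivity(cfg)
  sets <- select_stimulated(cfg, pr)
  epoch <- c(pr$t_on, pr$t_on + pr$duration)
  binw <- 5
  rs <- ru <- numeric(n_trials)
  cs <- cu <- NULL
  for (k in seq_len(n_trials)) {
    sim <- run_trial(cfg, conn, pr, seed = trial_seeds[k], stim_sets = sets)
    rs[k] <- mean_firing_rate(sim$spikes, sets$msn, epoch)
    ru[k] <- mean_firing_rate(sim$spikes, sets$msn_unstim, epoch)
    cs <- c(cs, population_counts(sim$spikes, binw, sets$msn, epoch))
    cu <- c(cu, population_counts(sim$spikes, binw, sets$msn_unstim, epoch))
  }
  tibble(rate_stim = mean(rs), rate_stim_se = sd(rs) / sqrt(n_trials),
         rate_unstim = mean(ru), rate_unstim_se = sd(ru) / sqrt(n_trials),
         snr = suppressWarnings(signal_to_noise_ratio(mean(rs), mean(ru))),
         sync_stim = suppressWarnings(fano(cs)),
         sync_unstim = suppressWarnings(fano(cu)),
         n_trials = as.integer(n_trials))
}

#' Inhibition-regime map of ongoing activity
#'
#' Baseline (no stimulus) runs over a grid of feedback and feedforward
#' inhibition strengths, reporting the MSN population rate and synchrony index
#' per point -- the map on which the model's operating point (low rate, weak
#' synchrony) is located.
#'
#' @param config a [network_config()].
#' @param grid data frame with columns among `g_fb`, `g_ff` (nS).
#' @param duration run length per seed (ms).
#' @param seeds seeds, one full run each, averaged per point.
#' @return a tibble of class `striatal_sweep`: grid columns plus `rate_msn`,
#'   `rate_fsi`, `sync_msn` (means over seeds).
#' @export
run_baseline_sweep <- function(config, grid, duration = 5000, seeds = 1) {
  if (!nrow(grid)) abort("`grid` must have at least one row.")
  ok <- names(grid) %in% c("g_fb", "g_ff")
  if (!all(ok)) abort("baseline grids may only vary g_fb and g_ff.")
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    cfg <- config
    for (f in names(grid)) cfg[[f]] <- grid[[f]][g]
    b <- baseline_activity(cfg, duration = duration, seeds = seeds)
    dplyr::bind_cols(grid[g, , drop = FALSE],
                     tibble(rate_msn = mean(b$rate_msn),
                            rate_fsi = mean(b$rate_fsi),
                            sync_msn = mean(b$sync_msn)))
  })
  class(rows) <- c("striatal_sweep", class(rows))
  rows
}

#' Two-group stimulus competition
#'
#' Two disjoint MSN groups are stimulated simultaneously with independent
#' input pools (configuration I). The green group receives ensemble rate
#' `rate_green` at fixed within-pool correlation `c_green`; the red group
#' receives twice the rate (`2 * rate_green` by default) while its within-pool
#' correlation is swept over `c_red`. The output rates of both groups over the
#' stimulation epoch are reported per swept value, together with the crossover
#' correlation at which the red group's output first exceeds the green
#' group's (linear interpolation between the bracketing grid points).
#'
#' @param config a [network_config()].
#' @param c_red within-pool correlations swept for the red group (increasing).
#' @param rate_green green-group ensemble rate (Hz).
#' @param rate_red red-group ensemble rate (Hz); default twice the green rate.
#' @param c_green green-group within-pool correlation.
#' @param f_group stimulated fraction of the MSN population per group.
#' @param protocol base [stimulus_protocol()] for timing/ensemble size.
#' @param n_trials trials per swept value.
#' @param seed base seed.
#' @return list of class `striatal_competition`: `results` (tibble with
#'   `c_red`, `rate_green`, `rate_red` and standard errors), `crossover`
#'   (interpolated correlation, `NA` when no crossing), `bracket` (grid values
#'   around it), and the group sizes.
#' @export
run_competition <- function(config, c_red, rate_green = 200, rate_red = NULL,
                            c_green = 0.01, f_group = 0.1,
                            protocol = stimulus_protocol(), n_trials = 10,
                            seed = 1) {
  if (is.null(rate_red)) rate_red <- 2 * rate_green
  if (is.unsorted(c_red)) abort("`c_red` must be increasing.")
  set.seed(seed)
  structure_seed <- sample.int(.Machine$integer.max, 1)
  trial_seeds <- matrix(sample.int(.Machine$integer.max,
                                   length(c_red) * n_trials),
                        nrow = length(c_red))
  set.seed(structure_seed)
  conn <- build_connectivity(config)
  k <- round(f_group * config$n_msn)
  both <- sample.int(config$n_msn, 2 * k)
  green_ids <- sort(both[seq_len(k)])
  red_ids <- sort(both[k + seq_len(k)])
  epoch <- c(protocol$t_on, protocol$t_on + protocol$duration)

  pg <- protocol
  pg$ensemble_rate <- rate_green
  pg$c_w <- c_green
  pg$c_b <- 0

  results <- purrr::map_dfr(seq_along(c_red), function(g) {
    pr <- protocol
    pr$ensemble_rate <- rate_red
    pr$c_w <- c_red[g]
    pr$c_b <- 0
    rg <- rr <- numeric(n_trials)
    for (k2 in seq_len(n_trials)) {
      set.seed(trial_seeds[g, k2])
      stim <- merge_stimuli(build_stimulus(green_ids, pg, config),
                            build_stimulus(red_ids, pr, config))
      sim <- simulate_network(config, conn,
                              duration = protocol$t_on + protocol$duration,
                              stim = stim)
      rg[k2] <- mean_firing_rate(sim$spikes, green_ids, epoch)
      rr[k2] <- mean_firing_rate(sim$spikes, red_ids, epoch)
    }
    tibble(c_red = c_red[g],
           rate_green = mean(rg), rate_green_se = sd(rg) / sqrt(n_trials),
           rate_red = mean(rr), rate_red_se = sd(rr) / sqrt(n_trials))
  })

  diffs <- results$rate_red - results$rate_green
  crossover <- NA_real_
  bracket <- c(NA_real_, NA_real_)
  above <- which(diffs > 0)
  if (length(above) && above[1] > 1) {
    i <- above[1]
    bracket <- c(c_red[i - 1], c_red[i])
    crossover <- c_red[i - 1] - diffs[i - 1] *
      (c_red[i] - c_red[i - 1]) / (diffs[i] - diffs[i - 1])
  } else if (length(above) && above[1] == 1) {
    crossover <- c_red[1]
    bracket <- c(NA_real_, c_red[1])
  }
  structure(list(results = results, crossover = crossover, bracket = bracket,
                 green_ids = green_ids, red_ids = red_ids,
                 rate_green = rate_green, rate_red = rate_red,
                 c_green = c_green,
                 seeds = list(base = seed, structure = structure_seed,
                              trials = trial_seeds)),
            class = "striatal_competition")
}

#' @export
print.striatal_competition <- function(x, ...) {
  cat(sprintf(
    "<striatal_competition: %d swept values, crossover at c_red ~ %.4g>\n",
    nrow(x$results), x$crossover))
  invisible(x)
}
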