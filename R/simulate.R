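#' Alpha-function conductance transient
#'
#' Closed form of the synaptic conductance kernel,
#' `g(t) = peak_g * (t/tau) * exp(1 - t/tau)` for `t >= 0` (0 before the
#' spike), which rises to its peak value `peak_g` exactly at `t = tau`. The
#' integrator realizes this kernel internally as an exactly-updated linear
#' second-order system; this closed form is its oracle.
#'
#' @param t time since the presynaptic spike (ms); vectorized.
#' @param peak_g peak conductance (nS).
#' @param tau rise time (ms).
#' @return conductance (nS), same length as `t`.
#' @examples
#' alpha_conductance(0.3, peak_g = 3.46, tau = 0.3)  # the peak
#' @export
alpha_conductance <- function(t, peak_g, tau) {
  if (tau <= 0) abort("`tau` must be positive.")
  ifelse(t >= 0, peak_g * (t / tau) * exp(1 - t / tau), 0)
}

#' Integrate the striatal network
#'
#' Clock-driven integration of the coupled conductance-based LIF network at
#' fixed step `config$dt`. Each neuron obeys
#' `C dV/dt = -g_rest (V - E_rest) - G_exc (V - E_exc) - G_inh (V - E_inh) + I`,
#' with alpha-function conductance transients advanced exactly on the grid and
#' the membrane advanced by exponential Euler using the exact step-average of
#' the conductances. A threshold crossing emits a spike at that step, resets V
#' to `E_rest` and starts the refractory pause, during which the membrane is
#' clamped at rest and arriving synaptic input is discarded. MSN spikes reach
#' their MSN targets after `delay_fb` with peak conductance `g_fb`; FSI spikes
#' reach their MSN targets after `delay_ff` with `g_ff`. Background input is
#' an independent Poisson process per neuron (`config$background_rate`) at the
#' cortical peak conductance of the target population; additional external
#' excitatory spikes (the stimulus) use the same cortical synapse.
#'
#' Neurons listed in `clone_ids` are additionally "cloned": the clone receives
#' the identical synaptic input but has spiking switched off, yielding the
#' free membrane potential used for subthreshold statistics.
#'
#' @param config a [network_config()].
#' @param connectivity a [build_connectivity()] result consistent with
#'   `config`.
#' @param duration simulated time (ms).
#' @param stim optional external excitatory input: a list with integer vector
#'   `ids` (global neuron ids: MSNs `1..n_msn`, FSIs `n_msn+1..n_msn+n_fsi`)
#'   and parallel lists `time` / `mult` of spike times (ms) and spike
#'   multiplicities (coincident-spike counts).
#' @param forced optional replacement spike sources: list with `ids` (global
#'   ids, typically FSIs) and list `time` of their prescribed spike trains;
#'   these neurons are not integrated, they only emit.
#' @param clone_ids global neuron ids to clone (free membrane potential).
#' @param record_window `c(t0, t1)` (ms) over which clone potentials are
#'   sampled at `dt` resolution; default the whole run.
#' @param init_v initial membrane potentials (mV): a vector of length
#'   `n_msn + n_fsi`, or `NULL` to draw Uniform(-80, -55) per neuron.
#' @param i_inj constant injected current (pA), scalar or per neuron
#'   (calibration/test hook; default 0).
#' @return list of class `striatal_sim` with `spikes` (a [spike_trains()] over
#'   all neurons, global ids) and `vm` (a `vm_traces` object, or `NULL`).
#' @export
simulate_network <- function(config, connectivity, duration,
                             stim = NULL, forced = NULL, clone_ids = integer(0),
                             record_window = NULL, init_v = NULL, i_inj = 0) {
  n_msn <- config$n_msn
  n_fsi <- config$n_fsi
  n <- n_msn + n_fsi
  if (connectivity$n_msn != n_msn || connectivity$n_fsi != n_fsi)
    abort("connectivity sizes do not match the configuration.")
  if (duration <= 0) abort("`duration` must be positive.")

  pv <- function(field) c(rep(config$msn[[field]], n_msn),
                          rep(config$fsi[[field]], n_fsi))
  bg_peak <- c(rep(config$g_cortex_msn, n_msn), rep(config$g_cortex_fsi, n_fsi))
  bg_rate <- rep(config$background_rate, n)

  stim_times <- stim_mult <- vector("list", 0)
  if (!is.null(stim) && length(stim$ids)) {
    stim_times <- rep(list(numeric(0)), n)
    stim_mult <- rep(list(numeric(0)), n)
    for (k in seq_along(stim$ids)) {
      tt <- stim$time[[k]]
      if (length(tt) && (min(tt) < 0 || max(tt) > duration))
        abort("stimulus spike outside the simulated interval.")
      o <- order(tt)
      stim_times[[stim$ids[k]]] <- tt[o]
      stim_mult[[stim$ids[k]]] <- (stim$mult[[k]] %||% rep.int(1, length(tt)))[o]
    }
  }

  forced_ids <- integer(0)
  forced_times <- list()
  if (!is.null(forced) && length(forced$ids)) {
    forced_ids <- as.integer(forced$ids)
    forced_times <- lapply(forced$time, function(tt) {
      if (length(tt) && (min(tt) < 0 || max(tt) > duration))
        abort("forced spike outside the simulated interval.")
      sort(tt)
    })
    bg_rate[forced_ids] <- 0
  }

  if (is.null(init_v)) init_v <- runif(n, -80, -55)
  if (length(init_v) != n) abort("`init_v` must have one entry per neuron.")
  if (length(i_inj) == 1) i_inj <- rep(i_inj, n)

  if (is.null(record_window)) record_window <- c(0, duration)
  clone_ids <- as.integer(clone_ids)

  res <- sim_core(n_msn, n_fsi,
                  pv("C"), pv("g_rest"), pv("E_rest"), pv("E_exc"),
                  pv("E_inh"), pv("V_th"), pv("tau_exc"), pv("tau_inh"),
                  pv("t_ref"),
                  bg_rate, bg_peak,
                  lapply(connectivity$mm_targets, function(v) v - 1L),
                  lapply(connectivity$fm_targets, function(v) v - 1L),
                  config$g_fb, config$g_ff, config$delay_fb, config$delay_ff,
                  stim_times, stim_mult,
                  forced_ids - 1L, forced_times,
                  i_inj, init_v,
                  clone_ids - 1L, record_window[1], record_window[2],
                  config$dt, duration)

  spikes <- spike_trains(res$time, res$id, n_sources = n, duration = duration)
  vm <- NULL
  if (length(clone_ids)) {
    vm <- res$vm
    attr(vm, "time") <- res$vm_time
    attr(vm, "dt") <- config$dt
    attr(vm, "ids") <- clone_ids
    class(vm) <- c("vm_traces", class(vm))
  }
  structure(list(spikes = spikes, vm = vm, n_msn = n_msn, n_fsi = n_fsi,
                 duration = duration),
            class = "striatal_sim")
}

#' @export
print.striatal_sim <- function(x, ...) {
  cat(sprintf("<striatal_sim: %d MSN + %d FSI, %g ms, %d spikes%s>\n",
              x$n_msn, x$n_fsi, x$duration, nrow(x$spikes),
              if (is.null(x$vm)) "" else sprintf(", %d Vm clones", ncol(x$vm))))
  invisible(x)
}

# global ids of the two populations
msn_ids <- function(sim_or_config) seq_len(sim_or_config$n_msn)
fsi_ids <- function(sim_or_config)
  sim_or_config$n_msn + seq_len(sim_or_config$n_fsi)

# assemble the per-neuron stimulus aggregates for a set of stimulated neurons
# (global ids), honoring c_b across all pools and optional jitter
build_stimulus <- function(ids, protocol, config) {
  if (!length(ids)) return(NULL)
  n_pools <- length(ids)
  t0 <- protocol$t_on
  dur <- protocol$duration
  aggs <- hier_mip_aggregate(n_pools, protocol$n_trains, protocol$ensemble_rate,
                             protocol$c_w, protocol$c_b, dur, t_start = t0)
  if (protocol$jitter_sd > 0) {
    aggs <- lapply(aggs, function(a) {
      tt <- rep.int(a$time, a$mult)
      tt <- pmin(pmax(tt + rnorm(length(tt), 0, protocol$jitter_sd), t0),
                 t0 + dur - 1e-9)
      tt <- sort(tt)
      list(time = tt, mult = rep.int(1, length(tt)))
    })
  }
  list(ids = ids, time = lapply(aggs, `[[`, "time"),
       mult = lapply(aggs, `[[`, "mult"))
}

merge_stimuli <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  list(ids = c(a$ids, b$ids), time = c(a$time, b$time), mult = c(a$mult, b$mult))
}

#' Run one stimulation trial
#'
#' Assembles a full trial: independent Poisson background for every neuron,
#' MIP (or hierarchical-MIP) stimulus ensembles onto the stimulated MSNs and
#' FSIs during the stimulation epoch, optional replacement of the unstimulated
#' FSIs by correlated spike sources (`protocol$c_fsi`), fresh Uniform(-80,-55)
#' initial potentials, and integration over `sim_duration`.
#'
#' @param config a [network_config()].
#' @param connectivity a [build_connectivity()] result.
#' @param protocol a [stimulus_protocol()].
#' @param seed optional integer; when given, `set.seed(seed)` is called first
#'   so the trial is bit-reproducible.
#' @param stim_sets stimulated-id sets from [select_stimulated()]; drawn fresh
#'   when `NULL`.
#' @param clone_ids global neuron ids to clone for free-Vm recording.
#' @param record_window Vm recording window; default the stimulation epoch.
#' @param sim_duration total simulated time (ms); default
#'   `t_on + duration` of the protocol.
#' @return a `striatal_sim` with an added element `stim_sets`.
#' @export
run_trial <- function(config, connectivity, protocol, seed = NULL,
                      stim_sets = NULL, clone_ids = integer(0),
                      record_window = NULL, sim_duration = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sim_duration)) sim_duration <- protocol$t_on + protocol$duration
  if (protocol$t_on + protocol$duration > sim_duration)
    abort("stimulation epoch extends beyond the simulated interval.")
  if (is.null(stim_sets)) stim_sets <- select_stimulated(config, protocol)

  stim <- NULL
  if (protocol$f_stim > 0) {
    ids <- c(stim_sets$msn, config$n_msn + stim_sets$fsi)
    stim <- build_stimulus(ids, protocol, config)
  }

  forced <- NULL
  if (!is.null(protocol$c_fsi) && length(stim_sets$fsi_unstim)) {
    tr <- generate_correlated_fsi(length(stim_sets$fsi_unstim),
                                  protocol$fsi_rate, protocol$c_fsi,
                                  duration = sim_duration)
    sp <- st_split(tr)
    forced <- list(ids = config$n_msn + stim_sets$fsi_unstim, time = sp)
  }

  if (is.null(record_window) && length(clone_ids))
    record_window <- c(protocol$t_on, protocol$t_on + protocol$duration)

  sim <- simulate_network(config, connectivity, duration = sim_duration,
                          stim = stim, forced = forced, clone_ids = clone_ids,
                          record_window = record_window)
  sim$stim_sets <- stim_sets
  sim$protocol <- protocol
  sim
}

#' Baseline (ongoing) network activity
#'
#' Runs the unstimulated network for `duration` ms per seed (fresh
#' connectivity, initial conditions and background realization each time) and
#' summarizes the resting state: MSN and FSI population rates and the
#' Fano-factor synchrony index of the MSN population (5 ms bins).
#'
#' @param config a [network_config()].
#' @param duration run length per seed (ms).
#' @param seeds integer vector of seeds, one run each.
#' @param binwidth synchrony-index bin width (ms).
#' @return a tibble with one row per seed: `seed`, `rate_msn`, `rate_fsi`
#'   (Hz), `sync_msn`.
#' @examples
#' \donttest{
#' cfg <- scale_config(network_config(), 0.1)
#' baseline_activity(cfg, duration = 1000, seeds = 1)
#' }
#' @export
baseline_activity <- function(config, duration = 5000, seeds = 1:3,
                              binwidth = 5) {
  purrr::map_dfr(seeds, function(s) {
    set.seed(s)
    conn <- build_connectivity(config)
    sim <- simulate_network(config, conn, duration = duration)
    tibble(seed = s,
           rate_msn = mean_firing_rate(sim$spikes, msn_ids(sim)),
           rate_fsi = mean_firing_rate(sim$spikes, fsi_ids(sim)),
           sync_msn = synchrony_index(sim$spikes, msn_ids(sim),
                                      binwidth = binwidth))
  })
}
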