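#' Neuron parameter sets
#'
#' Passive and spiking parameters of the two striatal cell classes as used in
#' the network model: membrane capacitance `C` (pF), resting conductance
#' `g_rest` (nS), resting/reset potential `E_rest` (mV), synaptic reversal
#' potentials `E_exc`/`E_inh` (mV), spike threshold `V_th` (mV), alpha-function
#' rise times `tau_exc`/`tau_inh` (ms), and the refractory pause `t_ref` (ms)
#' during which the membrane is held at rest and synaptic integration is
#' suspended.
#'
#' Defaults: medium spiny neurons (MSN) have C = 200 pF, g_rest = 12.5 nS,
#' E_rest = -80 mV, E_exc = 0 mV, E_inh = -64 mV, V_th = -45 mV; fast-spiking
#' interneurons (FSI) have C = 500 pF, g_rest = 25 nS, E_rest = -80 mV,
#' E_exc = 0 mV, E_inh = -76 mV, V_th = -54 mV. Both use tau_exc = 0.3 ms,
#' tau_inh = 2 ms, t_ref = 2 ms.
#'
#' @param C membrane capacitance (pF).
#' @param g_rest resting conductance (nS).
#' @param E_rest resting/reset membrane potential (mV).
#' @param E_exc excitatory reversal potential (mV).
#' @param E_inh inhibitory reversal potential (mV).
#' @param V_th spike threshold (mV).
#' @param tau_exc excitatory alpha-function rise time (ms).
#' @param tau_inh inhibitory alpha-function rise time (ms).
#' @param t_ref refractory pause (ms).
#' @return a named list of class `neuron_params`.
#' @export
neuron_params <- function(C, g_rest, E_rest, E_exc, E_inh, V_th,
                          tau_exc = 0.3, tau_inh = 2, t_ref = 2) {
  if (C <= 0 || g_rest <= 0) abort("C and g_rest must be positive.")
  if (E_rest >= V_th) abort("E_rest must lie below V_th.")
  if (tau_exc <= 0 || tau_inh <= 0) abort("synaptic rise times must be positive.")
  if (t_ref < 0) abort("t_ref must be non-negative.")
  structure(list(C = C, g_rest = g_rest, E_rest = E_rest, E_exc = E_exc,
                 E_inh = E_inh, V_th = V_th, tau_exc = tau_exc,
                 tau_inh = tau_inh, t_ref = t_ref),
            class = "neuron_params")
}

#' @rdname neuron_params
#' @export
msn_params <- function() {
  neuron_params(C = 200, g_rest = 12.5, E_rest = -80, E_exc = 0,
                E_inh = -64, V_th = -45)
}

#' @rdname neuron_params
#' @export
fsi_params <- function() {
  neuron_params(C = 500, g_rest = 25, E_rest = -80, E_exc = 0,
                E_inh = -76, V_th = -54)
}

#' Network configuration
#'
#' Populations, connectivity statistics, synaptic strengths and integration
#' settings of the striatal network. Defaults are the model's operating point:
#' 4000 MSNs and 80 FSIs; MSN-to-MSN feedback (FB) inhibition with connection
#' probability 0.1, peak conductance 0.3 nS and 2 ms delay; FSI-to-MSN
#' feedforward (FF) inhibition with exactly 15 presynaptic FSIs per MSN
#' (15/80 = 19% connectivity), peak conductance 1.0 nS and 1 ms delay;
#' independent 2500 Hz Poisson background per neuron with cortical peak
#' conductances 3.46 nS (onto MSNs) and 5.5 nS (onto FSIs); integration step
#' 0.1 ms. MSNs do not project to FSIs.
#'
#' @param n_msn,n_fsi population sizes.
#' @param p_mm MSN-to-MSN connection probability.
#' @param n_ff presynaptic FSIs per MSN (sampled without replacement).
#' @param background_rate independent Poisson background rate per neuron (Hz).
#' @param g_cortex_msn,g_cortex_fsi peak conductance of cortical (background
#'   and stimulus) input onto MSNs / FSIs (nS).
#' @param g_fb,g_ff peak conductances of FB (MSN->MSN) and FF (FSI->MSN)
#'   inhibition (nS).
#' @param delay_fb,delay_ff transmission delays of FB / FF inhibition (ms).
#' @param dt integration step (ms).
#' @param msn,fsi [neuron_params()] for the two populations.
#' @return a named list of class `network_config`.
#' @examples
#' cfg <- network_config()
#' small <- scale_config(cfg, 0.25)
#' @export
network_config <- function(n_msn = 4000, n_fsi = 80, p_mm = 0.1, n_ff = 15,
                           background_rate = 2500,
                           g_cortex_msn = 3.46, g_cortex_fsi = 5.5,
                           g_fb = 0.3, g_ff = 1.0,
                           delay_fb = 2, delay_ff = 1, dt = 0.1,
                           msn = msn_params(), fsi = fsi_params()) {
  if (n_msn < 1 || n_fsi < 1) abort("population sizes must be >= 1.")
  if (p_mm < 0 || p_mm > 1) abort("`p_mm` must lie in [0, 1].")
  if (n_ff < 0 || n_ff > n_fsi) abort("`n_ff` must lie in 0:n_fsi.")
  if (background_rate < 0) abort("`background_rate` must be non-negative.")
  if (g_fb < 0 || g_ff < 0 || g_cortex_msn < 0 || g_cortex_fsi < 0)
    abort("peak conductances must be non-negative.")
  if (delay_fb <= 0 || delay_ff <= 0) abort("delays must be positive.")
  if (dt <= 0) abort("`dt` must be positive.")
  structure(list(n_msn = as.integer(n_msn), n_fsi = as.integer(n_fsi),
                 p_mm = p_mm, n_ff = as.integer(n_ff),
                 background_rate = background_rate,
                 g_cortex_msn = g_cortex_msn, g_cortex_fsi = g_cortex_fsi,
                 g_fb = g_fb, g_ff = g_ff,
                 delay_fb = delay_fb, delay_ff = delay_ff, dt = dt,
                 msn = msn, fsi = fsi),
            class = "network_config")
}

#' @rdname network_config
#' @param config a `network_config`.
#' @param scale linear down-scaling factor for the populations; connection
#'   statistics are rescaled so the mean number of recurrent (FB) and FF
#'   inputs per MSN is preserved.
#' @export
scale_config <- function(config, scale) {
  if (scale <= 0 || scale > 1) abort("`scale` must lie in (0, 1].")
  if (scale == 1) return(config)
  in_deg_fb <- config$p_mm * (config$n_msn - 1)
  n_msn <- max(2L, as.integer(round(scale * config$n_msn)))
  n_fsi <- max(1L, as.integer(round(scale * config$n_fsi)))
  config$n_msn <- n_msn
  config$n_fsi <- n_fsi
  config$p_mm <- min(1, in_deg_fb / (n_msn - 1))
  config$n_ff <- min(n_fsi, config$n_ff)
  config
}

#' Build the striatal connectivity graph
#'
#' Realizes the two inhibitory projections: every ordered MSN pair (i, j),
#' i != j, is connected independently with probability `p_mm` (feedback), and
#' every MSN is assigned exactly `n_ff` distinct presynaptic FSIs sampled
#' uniformly without replacement (feedforward). No self-connections; MSNs do
#' not project to FSIs. Reproducible under `set.seed()`.
#'
#' @param config a [network_config()].
#' @return a list of class `striatal_connectivity` with elements `mm_targets`
#'   (per-MSN integer vectors of postsynaptic MSNs), `fm_targets` (per-FSI
#'   integer vectors of postsynaptic MSNs), and the realizing sizes.
#' @export
build_connectivity <- function(config) {
  n_msn <- config$n_msn
  n_fsi <- config$n_fsi
  # FB: per source, Binomial(n_msn - 1, p) out-degree, uniform targets != self
  mm_targets <- vector("list", n_msn)
  if (config$p_mm > 0 && n_msn > 1) {
    degs <- rbinom(n_msn, n_msn - 1L, config$p_mm)
    for (i in seq_len(n_msn)) {
      tg <- sample.int(n_msn - 1L, degs[i])
      tg <- tg + (tg >= i)              # skip self
      mm_targets[[i]] <- sort(tg)
    }
  } else {
    mm_targets[] <- list(integer(0))
  }
  # FF: per target MSN, exactly n_ff distinct FSI sources; store as per-FSI
  # target lists for delivery
  fm_targets <- vector("list", n_fsi)
  fm_targets[] <- list(integer(0))
  if (config$n_ff > 0) {
    src <- replicate(n_msn, sample.int(n_fsi, config$n_ff), simplify = FALSE)
    flat_src <- unlist(src)
    flat_tgt <- rep.int(seq_len(n_msn), lengths(src))
    sp <- split(flat_tgt, factor(flat_src, levels = seq_len(n_fsi)))
    fm_targets <- lapply(sp, function(v) sort(as.integer(v)))
    attr(fm_targets, "names") <- NULL
  }
  structure(list(mm_targets = mm_targets, fm_targets = fm_targets,
                 n_msn = n_msn, n_fsi = n_fsi,
                 p_mm = config$p_mm, n_ff = config$n_ff),
            class = "striatal_connectivity")
}

#' @rdname build_connectivity
#' @param x a `striatal_connectivity`.
#' @return `connectivity_edges()` returns a tibble with columns `src`, `dst`,
#'   `projection` ("FB" or "FF"); FSI sources are numbered `n_msn + 1, ...`.
#' @export
connectivity_edges <- function(x) {
  fb <- tibble(src = rep.int(seq_len(x$n_msn), lengths(x$mm_targets)),
               dst = unlist(x$mm_targets, use.names = FALSE) %||% integer(0),
               projection = "FB")
  ff <- tibble(src = rep.int(x$n_msn + seq_len(x$n_fsi), lengths(x$fm_targets)),
               dst = unlist(x$fm_targets, use.names = FALSE) %||% integer(0),
               projection = "FF")
  bind_rows(fb, ff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stimulation protocol
#'
#' Which fraction of each striatal population is stimulated, when, and with
#' what input ensemble. Each stimulated neuron receives `n_trains` correlated
#' spike trains from its own MIP pool (within-pool correlation `c_w`, total
#' ensemble rate `ensemble_rate` Hz) during `[t_on, t_on + duration)`;
#' between-pool correlation `c_b` correlates the pools of different stimulated
#' neurons (configuration II; `c_b = 0` is configuration I). `c_fsi`, when
#' given, replaces the unstimulated FSIs by spike sources firing at
#' `fsi_rate` Hz with pairwise correlation `c_fsi` (correlated feedforward
#' inhibition).
#'
#' @param f_stim stimulated fraction of each population, in \[0, 1\].
#' @param t_on stimulus onset (ms).
#' @param duration stimulus duration (ms).
#' @param n_trains input trains per stimulated neuron.
#' @param ensemble_rate total input ensemble rate per stimulated neuron (Hz).
#' @param c_w within-pool input correlation.
#' @param c_b between-pool (shared) input correlation.
#' @param jitter_sd Gaussian jitter applied to stimulus spikes (ms).
#' @param c_fsi pairwise correlation of replaced FSI trains, or `NULL` for the
#'   ordinary simulated FSIs.
#' @param fsi_rate firing rate of replaced FSI sources (Hz).
#' @param n_trials default number of trials for sweep aggregation.
#' @return a named list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(f_stim = 0.3, t_on = 600, duration = 100,
                              n_trains = 1000, ensemble_rate = 400,
                              c_w = 0.01, c_b = 0, jitter_sd = 0,
                              c_fsi = NULL, fsi_rate = 15, n_trials = 50) {
  if (f_stim < 0 || f_stim > 1) abort("`f_stim` must lie in [0, 1].")
  if (duration <= 0) abort("stimulus `duration` must be positive.")
  if (t_on < 0) abort("`t_on` must be non-negative.")
  if (c_w < 0 || c_w > 1 || c_b < 0 || c_b > 1)
    abort("`c_w` and `c_b` must lie in [0, 1].")
  if (!is.null(c_fsi) && (c_fsi < 0 || c_fsi > 1))
    abort("`c_fsi` must lie in [0, 1].")
  if (jitter_sd < 0) abort("`jitter_sd` must be non-negative.")
  structure(list(f_stim = f_stim, t_on = t_on, duration = duration,
                 n_trains = as.integer(n_trains), ensemble_rate = ensemble_rate,
                 c_w = c_w, c_b = c_b, jitter_sd = jitter_sd,
                 c_fsi = c_fsi, fsi_rate = fsi_rate,
                 n_trials = as.integer(n_trials)),
            class = "stimulus_protocol")
}

#' Select the stimulated neurons
#'
#' Uniform random samples of size `round(f_stim * N)` from each population.
#'
#' @param config a [network_config()].
#' @param protocol a [stimulus_protocol()].
#' @return list with integer id vectors `msn`, `fsi` (stimulated, ids within
#'   each population) and their complements `msn_unstim`, `fsi_unstim`.
#' @export
select_stimulated <- function(config, protocol) {
  k_msn <- round(protocol$f_stim * config$n_msn)
  k_fsi <- round(protocol$f_stim * config$n_fsi)
  msn <- if (k_msn > 0) sort(sample.int(config$n_msn, k_msn)) else integer(0)
  fsi <- if (k_fsi > 0) sort(sample.int(config$n_fsi, k_fsi)) else integer(0)
  list(msn = msn, fsi = fsi,
       msn_unstim = setdiff(seq_len(config$n_msn), msn),
       fsi_unstim = setdiff(seq_len(config$n_fsi), fsi))
}
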