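# shared fixtures and oracles for the test suite

# single isolated neuron configs (no network, optional background)
single_msn_config <- function(background_rate = 0) {
  network_config(n_msn = 1, n_fsi = 1, p_mm = 0, n_ff = 0,
                 background_rate = background_rate)
}

quarter_config <- function() scale_config(network_config(), 0.25)

# memoize expensive simulations so several acceptance checks share one run
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, force(expr), .sim_cache)
  get(key, envir = .sim_cache)
}

full_baseline <- function() {
  cached("full_baseline",
         baseline_activity(network_config(), duration = 5000, seeds = 1:3))
}

# hand-built vm_traces object for analysis tests
make_vm <- function(m, dt = 0.1, ids = seq_len(ncol(m))) {
  structure(m, time = seq_len(nrow(m)) * dt, dt = dt, ids = ids,
            class = c("vm_traces", class(m)))
}

# independent-replicate estimate of a MIP ensemble's mean pairwise
# correlation: returns c(mean, se) over `reps` fresh ensembles
replicate_mip_correlation <- function(c_w, reps = 4, n_trains = 100,
                                      rate_per_train = 5, duration = 6e4) {
  est <- vapply(seq_len(reps), function(i) {
    st <- generate_mip(n_trains, ensemble_rate = n_trains * rate_per_train,
                       c_w = c_w, duration = duration)
    as.numeric(estimate_pairwise_correlation(st, max_trains = n_trains))
  }, numeric(1))
  c(mean = mean(est), se = sd(est) / sqrt(reps))
}

# reference EPSP: classical RK4 at dt = 0.001 ms on the closed-form
# alpha-conductance membrane equation, independent of the kernel-state solver
epsp_reference_peak <- function(peak_g = 3.46, tau = 0.3, spike_at = 5,
                                p = msn_params(), t_max = 20, dt = 0.001) {
  g <- function(t) alpha_conductance(t - spike_at, peak_g, tau)
  f <- function(t, v) (-p$g_rest * (v - p$E_rest) - g(t) * (v - p$E_exc)) / p$C
  v <- p$E_rest
  vmax <- v
  tt <- seq(0, t_max, dt)
  for (i in seq_len(length(tt) - 1)) {
    t0 <- tt[i]
    k1 <- f(t0, v)
    k2 <- f(t0 + dt / 2, v + dt / 2 * k1)
    k3 <- f(t0 + dt / 2, v + dt / 2 * k2)
    k4 <- f(t0 + dt, v + dt * k3)
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    vmax <- max(vmax, v)
  }
  vmax
}

# stimulation trial batch with free-Vm clones; returns per-trial zero-lag
# correlation and mean fluctuation sd over cloned stimulated MSNs
vm_point <- function(config, protocol, n_clones = 8, n_trials = 4, seed = 1) {
  set.seed(seed)
  structure_seed <- sample.int(.Machine$integer.max, 1)
  trial_seeds <- sample.int(.Machine$integer.max, n_trials)
  set.seed(structure_seed)
  conn <- build_connectivity(config)
  sets <- select_stimulated(config, protocol)
  clones <- sets$msn[seq_len(n_clones)]
  out <- lapply(seq_len(n_trials), function(k) {
    sim <- run_trial(config, conn, protocol, seed = trial_seeds[k],
                     stim_sets = sets, clone_ids = clones)
    cc <- vm_cross_correlation(sim$vm, max_lag = 10)
    list(zero_lag = cc$zero_lag, sd = mean(vm_fluctuation_std(sim$vm)$sd_mv))
  })
  list(zero_lag = mean(vapply(out, `[[`, numeric(1), "zero_lag")),
       sd = mean(vapply(out, `[[`, numeric(1), "sd")))
}
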