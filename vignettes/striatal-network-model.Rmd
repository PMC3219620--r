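---
title: "A striatal network model and the statistics of its correlated inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A striatal network model and the statistics of its correlated inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatnet)
```

## The model

The striatum is modelled as a purely inhibitory recurrent network of two
GABAergic populations driven by excitatory cortical input: 4000 medium spiny
neurons (MSNs) and 80 fast-spiking interneurons (FSIs). Two inhibitory
pathways are anatomically segregated — MSNs inhibit each other through sparse,
weak recurrent collaterals (*feedback*, FB), while FSIs provide divergent,
strong inhibition onto MSNs (*feedforward*, FF). MSNs do not project back to
FSIs, so the two modes of inhibition can be manipulated independently.

Each neuron is a conductance-based leaky integrate-and-fire unit,

$$C \frac{dV}{dt} = -g_{rest}(V - E_{rest}) - G_{exc}(t)(V - E_{exc})
  - G_{inh}(t)(V - E_{inh}),$$

spiking when $V$ reaches the threshold $\theta$, resetting to $E_{rest}$, and
pausing synaptic integration for a refractory period. Synaptic events produce
alpha-function conductance transients
$g(t) = \hat g \,(t/\tau)\, e^{1 - t/\tau}$ that peak at $\hat g$ exactly
$\tau$ after the (delayed) spike arrival. FF inhibition arrives with a 1 ms
delay (somatic synapses), FB inhibition with 2 ms (dendritic synapses).

Parameter defaults (all exposed through `neuron_params()` and
`network_config()`):

| quantity | MSN | FSI | units |
|---|---|---|---|
| $C$ | 200 | 500 | pF |
| $g_{rest}$ | 12.5 | 25 | nS |
| $E_{rest}$ | −80 | −80 | mV |
| $E_{exc}$ | 0 | 0 | mV |
| $E_{inh}$ | −64 | −76 | mV |
| $\theta$ | −45 | −54 | mV |
| $\tau_{exc}$, $\tau_{inh}$ | 0.3, 2 | 0.3, 2 | ms |
| cortical peak conductance | 3.46 | 5.5 | nS |
| background rate | 2500 | 2500 | Hz |

Connectivity: every ordered MSN pair is connected with probability 0.1 (FB
peak conductance 0.3 nS, biological range 0–0.5 nS), and every MSN receives
input from exactly 15 of the 80 FSIs (FF peak conductance 1.0 nS, range
0–2.5 nS), i.e. a 19% FF connectivity. The membrane time constants
($\tau_m = C/g_{rest} = 16$ ms for MSNs, 20 ms for FSIs) and the strong
hyperpolarized rest relative to threshold make MSNs fluctuation-driven
coincidence detectors — the property that all input-correlation effects below
hinge on.

Two parameter tables list one fast (0.3 ms) and one slow (2 ms) synaptic rise
time per cell type without labelling them; we assign the fast constant to the
excitatory (AMPA-like) and the slow one to the inhibitory (GABA-A-like)
transient, the conventional ordering. The refractory pause is likewise left
open by the source material; we use 2 ms for both populations and expose it
in `neuron_params()` so its influence can be probed.

## Correlated cortical input: MIP ensembles

Task-related cortical activity is modelled as ensembles of correlated Poisson
trains built by the *multiple interaction process* (MIP): a mother Poisson
process is copied into $n$ child trains, each spike independently with copy
probability $c_w$. Children are Poisson at rate
$\nu_{ens}/n$ (with mother rate $\nu_{ens}/(n\,c_w)$, so the ensemble rate
$\nu_{ens}$ is conserved across $c_w$), and the pairwise spike-count
correlation between children equals $c_w$ at any bin width. This lets rate
and correlation be varied independently.

Two stimulus configurations are distinguished:

* **Configuration I** (`c_b = 0`): each stimulated neuron has its own,
  mutually independent MIP pool of `n_trains = 1000` inputs at a total of
  200–400 Hz — the anatomical scenario where striatal neurons do not share
  presynaptic pools.
* **Configuration II** (`c_b > 0`): the pools' mother processes are
  correlated. The sources state only that mothers are "correlated by a
  factor"; we implement this with the same primitive one level up — a shared
  grandmother Poisson process thinned into each pool's mother with copy
  probability $c_b$ (`generate_hierarchical_mip()`). This reproduces both
  stated limiting cases exactly ($c_b = 0$: independent pools; $c_b = 1$: all
  trains drawn from one common MIP) and makes the between-pool pairwise
  correlation the product $c_w c_b$, which the test suite verifies
  empirically rather than assumes.

Correlated feedforward inhibition is modelled by replacing the unstimulated
FSIs by spike *sources* whose trains form a MIP with pairwise correlation
`c_fsi` at the baseline FSI rate (15 Hz): the mechanism generating FSI
synchrony (gap junctions, shared input) is deliberately left unspecified,
only its statistical consequence is imposed.

Optional spike-time jitter (`apply_jitter()`) displaces every spike by
zero-mean Gaussian noise, clipped at the interval edges — the conventional
model for the few-ms dispersion of near-coincident cortical spikes. The
generators use R's session RNG throughout, so `set.seed()` makes every
ensemble bit-reproducible.

What the synthetic inputs do *not* emulate: non-Poisson (bursting,
refractory, gamma-renewal) interval statistics, rate nonstationarity within
the stimulus epoch, topographic structure of the cortico-striatal projection,
and oscillatory cortical states. Conclusions drawn from passing tests
therefore concern the correlation structure of stationary Poisson-like
drive, not arbitrary in vivo spike statistics.

## Numerical scheme

The integrator (`simulate_network()`, compiled core) is clock-driven at a
fixed `dt = 0.1` ms. Each alpha kernel is realized as a linear two-state
system advanced by its exact matrix exponential per step; a presynaptic spike
adds an impulse $\hat g\, e/\tau$ to the first state. The membrane equation
is advanced by exponential Euler using the *exact time-average* of the
conductances over the step (available in closed form from the kernel states),
not their instantaneous samples. This matters because
$\tau_{exc} = 0.3\,\mathrm{ms}$ is comparable to `dt`: with step-averaged
conductances the EPSP peak agrees with a 100×-finer reference integration
well inside the 1% tolerance the test suite enforces, where instantaneous
sampling of so fast a kernel would not.

Further conventions:

* Spikes (threshold crossings, background events, stimulus events, forced
  FSI emissions) are aligned to the step grid; a crossing is reported at the
  end of its step.
* During the refractory pause the membrane is clamped at $E_{rest}$ and
  *arriving synaptic input is discarded*, not buffered — the "pause for
  synaptic integration" reading. Kernels keep decaying.
* Background input is drawn inside the core as one Poisson count per neuron
  per step (rate × dt), which is distributionally identical to materializing
  grid-aligned 2500 Hz trains and avoids storing ~5·10⁷ spikes per run.
* Free membrane potentials are recorded from *clones*: duplicate state
  vectors receiving the identical input stream (including input the twin
  discards while refractory) with threshold and reset switched off. Below
  threshold, a clone reproduces its twin's trajectory sample for sample up
  to the twin's first spike.
* Stimulus ensembles converging on a single neuron are fed in aggregate
  form — mother event times with Binomial($n$, $c_w$) multiplicities — which
  is the exact distribution of the summed ensemble and removes any cost of
  materializing 1000 trains per stimulated neuron.
* Initial potentials are drawn Uniform(−80, −55) mV per neuron per trial to
  avoid synchrony from initial conditions.
* Degenerate inputs: `c_w = 0` falls back to independent Poisson trains;
  zero-spike windows make the synchrony index an `NA` sentinel with a
  warning; a zero unstimulated rate makes the SNR `NA`; non-finite membrane
  states abort with a diagnostic.

## Activity descriptors

* `mean_firing_rate()`: population mean spike count per second.
* `synchrony_index()`: Fano factor of the summed population spike count in
  5 ms bins — 1 for independent Poisson activity, >1 under synchrony. Bins
  are anchored at the analysis-window start (for stimulation experiments,
  the stimulus onset).
* `signal_to_noise_ratio()`: stimulated over unstimulated mean MSN rate over
  the stimulation epoch — the model's measure of how salient a represented
  signal is against the background.
* `vm_cross_correlation()` / `vm_fluctuation_std()`: zero-lag Pearson
  correlation (window-mean removed) and standard deviation of the free
  membrane potentials of stimulated clone pairs.

Across trials the sweeps (`run_sweep()`) average the stimulated and
unstimulated rates first and take their ratio second; this order is robust
to zero-spike trials in the denominator (the alternative, averaging
per-trial ratios, is undefined whenever one trial has a silent unstimulated
population). Synchrony over trials is computed on the pooled per-trial bin
counts of the stimulation epoch.

## Experiment pipelines and problem sizes

`run_baseline_sweep()` maps ongoing activity over the biological FB × FF
conductance ranges (5 s runs); `run_sweep()` runs the stimulation protocols
(default: 30% of both populations stimulated for 100 ms, onset 600 ms,
1000 trains per neuron); `run_competition()` stimulates two disjoint MSN
groups, the "red" one at twice the "green" ensemble rate with its
within-pool correlation swept, and reports the output-rate crossover. Every
per-point, per-trial seed derives from one base seed and is recorded in the
result's `seeds` attribute.

`scale_config(config, s)` down-scales the populations while rescaling
`p_mm` (and capping `n_ff`) so the *mean number* of FB and FF inputs per MSN
is preserved; at quarter scale the baseline regime (sub-2 Hz, weakly
synchronous MSN activity) is preserved within a factor of two of the
full-scale rate, which the acceptance suite checks. The test suite runs the
qualitative input-correlation properties at quarter scale with ~10–20 trials
per grid point and a 300 ms pre-stimulus interval; the full-scale baseline
(3 × 5 s) is used for the operating-point checks. These sizes are the
package's desk-scale defaults; the full protocol sizes (50 and 150 trials,
600 ms onset) remain the documented defaults of `stimulus_protocol()`.

## Design choices on genuinely open points

* **FF in-degree fixed at 15**, not Binomial with mean 15: the sources give
  a 4–27 range with "average value of 15" and print 19% = 15/80; the fixed
  in-degree is the simplest reading that makes the printed fraction exact.
  Recorded as a choice, not as the original model's certain intent.
* **Stimulated FSI fraction equals the MSN fraction**, as the stimulation is
  described for "both MSNs and FSIs" without separate fractions; in
  configuration II the FSI pools join the same grandmother hierarchy.
* **Stimulus synapses use the cortical peak conductance** of the target
  population (3.46 / 5.5 nS), since the extra input enters through the same
  excitatory pathway as the background.
* **Competition defaults**: green group at 200 Hz ensemble rate and
  $c_w = 0.01$ (the configuration-I optimum region), red at double rate —
  the original figure's exact green parameters are not printed, so these are
  config-exposed assumptions and the crossover is a qualitative, not
  quantitative, target.
* **HDF5 archives are not provided**; spike sets round-trip through a plain
  two-column text dialect (`write_spike_text()`), and result tables are
  tidy tibbles that write to CSV.

## Limitations

Beyond the input statistics noted above: no dopaminergic, cholinergic (TAN)
or persistent-low-threshold-spiking interneurons (their net effects are
absorbed into the FF/FB strengths); no gap-junction biophysics — correlated
FSI activity is imposed, not emergent; no NMDA or short-term synaptic
dynamics; distance-independent random connectivity, valid only for a small
striatal volume; and a single MSN class, although D1/D2 differences in
passive properties would shift the optimal input correlation. The
non-monotonic dependence of stimulated-MSN output on $c_w$ — rising while
coincident input clusters are too small to reach threshold, falling once
clusters overshoot it and spikes are wasted — is a threshold phenomenon and
is expected to survive all of these simplifications, shifting only the
location of the optimum.
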