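test_that("mean firing rate is spike count per neuron per second", {
  st <- spike_trains(seq(10, 70, 10), rep(1L, 7), n_sources = 1, duration = 100)
  expect_equal(mean_firing_rate(st), 70)                     # 7 spikes / 100 ms
  expect_equal(mean_firing_rate(st, window = c(0, 50)), 80)  # 4 spikes / 50 ms
  # 1200 neurons, 60 spikes, 100 ms -> 0.5 Hz
  st2 <- spike_trains(runif(60) * 100, sample.int(1200, 60, TRUE),
                      n_sources = 1200, duration = 100)
  expect_equal(mean_firing_rate(st2), 0.5)
  empty <- spike_trains(numeric(0), integer(0), n_sources = 5, duration = 100)
  expect_equal(mean_firing_rate(empty), 0)
  expect_error(mean_firing_rate(st, ids = integer(0)), "empty")
  expect_error(mean_firing_rate(st, window = c(50, 50)), "t1 > t0")
})

test_that("synchrony index calibrates on known count processes", {
  set.seed(10)
  # independent Poisson population -> ~ 1
  st <- generate_poisson_trains(500, rate = 2, duration = 20000)
  expect_lt(abs(synchrony_index(st) - 1), 0.1)
  # k perfectly coincident spikes at Poisson event times -> ~ k
  k <- 5
  ev <- sort(runif(3000) * 1e5)
  st_k <- spike_trains(rep(ev, each = k), rep(seq_len(k), times = 3000),
                       n_sources = k, duration = 1e5)
  expect_lt(abs(synchrony_index(st_k) - k), 0.5)
  # a regular train at binwidth << period is sub-Poisson
  reg <- spike_trains(seq(10, 9990, by = 20), rep(1L, 500), n_sources = 1,
                      duration = 10000)
  expect_lt(synchrony_index(reg, binwidth = 5), 1)
  # empty record -> NA sentinel with warning
  empty <- spike_trains(numeric(0), integer(0), n_sources = 3, duration = 100)
  expect_warning(s <- synchrony_index(empty), "no spikes")
  expect_true(is.na(s))
})

test_that("SNR is the stimulated/unstimulated rate ratio with guarded zero", {
  expect_equal(signal_to_noise_ratio(1.5, 1.5), 1)
  expect_equal(signal_to_noise_ratio(2, 0.5), 4)
  expect_warning(s <- signal_to_noise_ratio(2, 0), "undefined")
  expect_true(is.na(s))
  # scale invariance
  expect_equal(signal_to_noise_ratio(3 * 2, 3 * 0.5),
               signal_to_noise_ratio(2, 0.5))
  expect_error(signal_to_noise_ratio(-1, 1), "non-negative")
})

test_that("PSTH conserves the spike count and localizes events", {
  set.seed(11)
  st <- generate_poisson_trains(50, 10, duration = 2000)
  h <- psth(st, binwidth = 10)
  expect_equal(sum(h$rate) * 50 * 10 / 1000, nrow(st))
  # all spikes in one bin -> single nonzero bin
  burst <- spike_trains(rep(52, 20), seq_len(20), n_sources = 20,
                        duration = 100)
  hb <- psth(burst, binwidth = 10)
  expect_equal(sum(hb$rate > 0), 1L)
  expect_equal(hb$time[hb$rate > 0], 50)
})

test_that("group summaries come back tidy", {
  set.seed(12)
  st <- generate_poisson_trains(20, 5, duration = 5000)
  s <- summarize_activity(st, list(a = 1:10, b = 11:20))
  expect_s3_class(s, "tbl_df")
  expect_equal(s$group, c("a", "b"))
  expect_true(all(s$rate > 0))
})

test_that("Vm cross-correlation behaves on constructed traces", {
  set.seed(13)
  n <- 4000
  base <- rnorm(n)
  # identical traces -> 1 at zero lag
  vm_id <- make_vm(cbind(base, base))
  cc <- vm_cross_correlation(vm_id, max_lag = 2)
  expect_equal(cc$zero_lag, 1)
  # independent noise -> ~ 0 at all lags
  vm_ind <- make_vm(cbind(rnorm(n), rnorm(n), rnorm(n)))
  ci <- vm_cross_correlation(vm_ind, max_lag = 2)
  expect_lt(max(abs(ci$ccf$ccf)), 0.1)
  # CCF symmetry: swapping the pair mirrors the lag axis
  a <- rnorm(n)
  b <- c(rnorm(5), a[1:(n - 5)])     # b lags a by 5 samples
  c_ab <- vm_cross_correlation(make_vm(cbind(a, b)), max_lag = 1)$ccf
  c_ba <- vm_cross_correlation(make_vm(cbind(b, a)), max_lag = 1)$ccf
  expect_equal(c_ab$ccf, rev(c_ba$ccf), tolerance = 1e-10)
  # constant traces are excluded with a warning
  expect_warning(
    vm_cross_correlation(make_vm(cbind(a, b, rep(1, n))), max_lag = 1),
    "constant")
})

test_that("Vm fluctuation std matches closed forms", {
  tt <- seq(0.1, 400, by = 0.1)
  A <- 3
  vm <- make_vm(cbind(rep(-70, length(tt)), -70 + A * sin(2 * pi * tt / 50)))
  s <- vm_fluctuation_std(vm)
  expect_equal(s$sd_mv[1], 0)
  expect_equal(s$sd_mv[2], A / sqrt(2), tolerance = 0.01)
  expect_error(vm_fluctuation_std(vm, window = c(1000, 2000)), "outside")
})

test_that("tidy_vm returns one row per sample per neuron", {
  vm <- make_vm(matrix(rnorm(20), 10, 2), ids = c(7L, 9L))
  d <- tidy_vm(vm)
  expect_equal(nrow(d), 20L)
  expect_equal(unique(d$neuron), c(7L, 9L))
})
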