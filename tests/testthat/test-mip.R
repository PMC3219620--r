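test_that("copy probability 1 makes every child an identical copy of the mother", {
  set.seed(1)
  st <- generate_mip(5, ensemble_rate = 50, c_w = 1, duration = 10000)
  trains <- striatnet:::st_split(st)
  for (j in 2:5) expect_equal(trains[[j]], trains[[1]])
})

test_that("MIP conserves the ensemble rate and the per-child rate", {
  set.seed(2)
  # n = 1000, ensemble 400 Hz, c_w = 0.02 -> mother 20 Hz, per-child 0.4 Hz
  dur <- 2e5
  st <- generate_mip(1000, ensemble_rate = 400, c_w = 0.02, duration = dur)
  expected <- 400 * dur / 1000
  # total-count sd from the compound-Poisson representation:
  # var = rate_mother*T * E[B^2], B ~ Binomial(n, c_w)
  n_mother <- 20 * dur / 1000
  eb2 <- (1000 * 0.02)^2 + 1000 * 0.02 * 0.98
  expect_lt(abs(nrow(st) - expected), 4 * sqrt(n_mother * eb2))
  per_child <- 1000 * nrow(st) / 1000 / dur
  expect_lt(abs(per_child - 0.4), 0.05)

  # rate conservation across the correlation range
  for (cw in c(0.01, 0.1, 1)) {
    st2 <- generate_mip(200, ensemble_rate = 1000, c_w = cw, duration = 3e4)
    expect_lt(abs(nrow(st2) - 3e4), 5 * sqrt((1000 / (200 * cw)) * 30 *
                                               ((200 * cw)^2 + 200 * cw)))
  }
})

test_that("estimated pairwise correlation recovers c_w", {
  set.seed(3)
  st <- generate_mip(150, ensemble_rate = 150 * 4, c_w = 0.1, duration = 1e5)
  r <- estimate_pairwise_correlation(st, max_trains = 150)
  expect_lt(abs(as.numeric(r) - 0.1), 0.01)

  # c_w = 0 degenerates to independent Poisson trains: correlation ~ 0
  st0 <- generate_mip(100, ensemble_rate = 500, c_w = 0, duration = 1e5)
  expect_lt(abs(as.numeric(estimate_pairwise_correlation(st0))), 0.005)

  # two identical trains -> exactly 1
  st1 <- spike_trains(rep(c(3, 8, 22), 2), rep(1:2, each = 3),
                      n_sources = 2, duration = 30)
  expect_equal(as.numeric(estimate_pairwise_correlation(st1, binwidth = 5)), 1)
})

test_that("hierarchical MIP composes within- and between-pool correlation", {
  set.seed(4)
  # c_b = 0 reduces to independent pools: cross-pool correlation ~ 0
  pools0 <- generate_hierarchical_mip(2, 100, 400, c_w = 0.05, c_b = 0,
                                      duration = 1e5)
  m1 <- binned_counts(pools0[[1]], 5)
  m2 <- binned_counts(pools0[[2]], 5)
  cross0 <- mean(cor(m1[, 1:40], m2[, 1:40]))
  expect_lt(abs(cross0), 0.01)

  # within-pool correlation stays ~ c_w regardless of c_b
  pools <- generate_hierarchical_mip(2, 100, 400, c_w = 0.05, c_b = 0.5,
                                     duration = 1e5)
  within <- as.numeric(estimate_pairwise_correlation(pools[[1]]))
  expect_lt(abs(within - 0.05), 0.012)

  # multiplicative composition: cross-pool ~ c_w * c_b
  m1 <- binned_counts(pools[[1]], 5)
  m2 <- binned_counts(pools[[2]], 5)
  cross <- mean(cor(m1[, 1:40], m2[, 1:40]))
  expect_lt(abs(cross - 0.025), 0.012)

  # c_b = 1: one common mother, cross-pool correlation equals c_w
  pools1 <- generate_hierarchical_mip(2, 100, 400, c_w = 0.05, c_b = 1,
                                      duration = 1e5)
  m1 <- binned_counts(pools1[[1]], 5)
  m2 <- binned_counts(pools1[[2]], 5)
  cross1 <- mean(cor(m1[, 1:40], m2[, 1:40]))
  expect_lt(abs(cross1 - 0.05), 0.012)
})

test_that("aggregate representation matches the summed child ensemble", {
  # the aggregate fast path and the explicit ensemble are the same compound
  # Poisson process: compare total counts under one RNG state
  set.seed(5)
  agg <- striatnet:::mip_aggregate(500, 400, 0.02, duration = 1e5)
  set.seed(6)
  st <- generate_mip(500, 400, 0.02, duration = 1e5)
  expect_lt(abs(sum(agg$mult) - nrow(st)) / nrow(st), 0.1)
  expect_true(all(agg$mult >= 1))
  # and its rate is the ensemble rate
  expect_lt(abs(sum(agg$mult) - 400 * 100) / (400 * 100), 0.05)
})

test_that("generators are bit-reproducible under a seed", {
  set.seed(99)
  a <- generate_mip(50, 200, 0.05, 5000)
  set.seed(99)
  b <- generate_mip(50, 200, 0.05, 5000)
  expect_identical(a, b)
  set.seed(99)
  h1 <- generate_hierarchical_mip(3, 50, 200, 0.05, 0.5, 5000)
  set.seed(99)
  h2 <- generate_hierarchical_mip(3, 50, 200, 0.05, 0.5, 5000)
  expect_identical(h1, h2)
})

test_that("jitter displaces spikes with the requested scale and keeps order", {
  st <- spike_trains(rep(50, 10000), seq_len(10000), n_sources = 10000,
                     duration = 100)
  expect_identical(apply_jitter(st, 0), st)
  set.seed(7)
  j <- apply_jitter(st, 1)
  expect_lt(abs(sd(j$time) - 1), 0.05)
  expect_lt(abs(mean(j$time) - 50), 0.05)
  expect_true(all(j$time >= 0 & j$time < 100))
  # per-train order invariant
  sp <- striatnet:::st_split(apply_jitter(generate_poisson_trains(5, 50, 1000), 2))
  for (v in sp) expect_false(is.unsorted(v))
})

test_that("parameter validation rejects malformed specs", {
  expect_error(generate_mip(10, 100, c_w = 1.2, duration = 100), "\\[0, 1\\]")
  expect_error(generate_mip(10, 100, c_w = 0.5, duration = 0), "positive")
  expect_error(generate_poisson_trains(3, rate = -1, duration = 10),
               "non-negative")
  expect_error(apply_jitter(generate_poisson_trains(2, 1, 10), sd = -1),
               "non-negative")
  st <- generate_poisson_trains(1, 10, 1000)
  expect_error(estimate_pairwise_correlation(st), "at least 2")
})

test_that("zero-variance trains are excluded from the correlation estimate", {
  set.seed(8)
  st <- generate_poisson_trains(5, 20, 10000)
  silent <- spike_trains(st$time, st$source, n_sources = 6, duration = 10000)
  expect_warning(r <- estimate_pairwise_correlation(silent), "zero count")
  expect_true(is.finite(as.numeric(r)))
})
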