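test_that("active patterns mark exactly the overlapping ROIs", {
  ev <- events_at(c(NA, 10.4, NA, 10.2, NA, NA, 10.402, NA))
  expect_equal(active_pattern(ev, 10.4), c(0, 1, 0, 1, 0, 0, 1, 0))
  # an event starting just past the +5 ms window edge does not count
  expect_equal(active_pattern(events_at(10.41), 10.4), 0L)
  expect_equal(active_pattern(events_at(rep(NA, 4)), 10.4), rep(0L, 4))
  expect_equal(active_pattern(events_at(rep(10.4, 4)), 10.4), rep(1L, 4))
})

test_that("Hamming distance satisfies the metric axioms", {
  expect_equal(hamming(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(hamming(rep(0, 6), rep(0, 6)), 0)  # two silent epochs agree
  expect_equal(hamming(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_error(hamming(c(1, 0), c(1, 0, 1)), "equal length")

  set.seed(17)
  for (i in 1:500) {
    n <- sample(3:40, 1)
    p <- rbinom(n, 1, 0.5); q <- rbinom(n, 1, 0.5); r <- rbinom(n, 1, 0.5)
    expect_identical(hamming(p, q), hamming(q, p))
    expect_identical(hamming(p, p), 0)
    expect_lte(hamming(p, r), hamming(p, q) + hamming(q, r) + 1e-12)
  }
})

test_that("epoch distance separates reliable from unreliable ensembles", {
  pats <- matrix(rep(c(1, 0), 25), nrow = 10, ncol = 50, byrow = TRUE)
  expect_equal(epoch_distance(pats)$distance, 0)
  expect_equal(epoch_distance(pats)$n_pairs, choose(10, 2))
  expect_error(epoch_distance(pats[1, , drop = FALSE]), "two")

  # independently uniform patterns sit at the Bernoulli expectation 0.5
  set.seed(23)
  d <- replicate(100, {
    epoch_distance(matrix(rbinom(2 * 50, 1, 0.5), nrow = 2))$distance
  })
  expect_lt(abs(mean(d) - 0.5), 0.03)

  # membership reliability orders the distance (few seeds; full sweep in
  # the acceptance suite)
  wins <- 0
  for (s in 1:6) {
    dd <- vapply(c(0.95, 0.6), function(pr) {
      sess <- generate_session(
        synthetic_params(seed = 600 + s,
                         membership = list(p_repeat = pr)))
      ev <- detect_all_rois(sess$bundle$dff)
      onsets <- sess$bundle$stimulus_table$onset_s
      pats <- t(vapply(onsets, function(on) active_pattern(ev, on + 0.4),
                       integer(length(ev))))
      epoch_distance(pats)$distance
    }, numeric(1))
    wins <- wins + (dd[1] < dd[2])
  }
  expect_gte(wins, 5)
})

test_that("pairwise correlation handles identical, opposite and silent rows", {
  a <- sin(seq(0, 10, length.out = 200))
  expect_equal(pairwise_correlation(rbind(a, a))$mean_r, 1.0)
  expect_equal(pairwise_correlation(rbind(a, mean(a) - (a - mean(a))))$mean_r,
               -1.0)
  flat <- rbind(a, rep(1, 200))
  pc <- pairwise_correlation(flat)
  expect_equal(pc$n_skipped, 1)
  expect_true(is.na(pc$mean_r))

  # independent noise: mean correlation near zero
  set.seed(29)
  ms <- replicate(20, {
    pairwise_correlation(matrix(rnorm(20 * 720), nrow = 20))$mean_r
  })
  expect_lt(max(abs(ms)), 0.05)
  expect_error(pairwise_correlation(matrix(1, 1, 10)), "two ROIs")
})

test_that("circular shifts permute rows without changing their content", {
  set.seed(31)
  m <- matrix(rnorm(5 * 100), nrow = 5)
  expect_identical(circular_shuffle(m, rep(0, 5)), m)
  sh <- sample(0:99, 5)
  ms <- circular_shuffle(m, sh)
  for (i in 1:5) {
    expect_identical(sort(ms[i, ]), sort(m[i, ]))  # multiset conserved
    expect_equal(sum(ms[i, ]), sum(m[i, ]))
  }
  # order-independent time average of the ensemble trace is bit-identical
  before <- mean(vapply(1:5, function(i) trace_time_average(m[i, ]),
                        numeric(1)))
  after <- mean(vapply(1:5, function(i) trace_time_average(ms[i, ]),
                       numeric(1)))
  expect_identical(before, after)
})

test_that("the shuffle null is reproducible and sized by n_shuffles", {
  sess <- generate_session(synthetic_params(seed = 41))
  ev <- detect_all_rois(sess$bundle$dff)
  onsets <- sess$bundle$stimulus_table$onset_s
  dur <- sess$bundle$duration_s
  ep <- epoch_set(t1_s = 0.4)

  n1 <- build_null(ev, ep, onsets, dur,
                   analysis_config(n_shuffles = 1, rng_seed = 5))
  expect_length(n1$epochs$epoch1$fraction, 1)
  expect_length(n1$epochs$epoch1$distance, 1)

  cfg <- analysis_config(n_shuffles = 50, rng_seed = 7)
  na <- build_null(ev, ep, onsets, dur, cfg)
  nb <- build_null(ev, ep, onsets, dur, cfg)
  expect_identical(na$epochs$epoch1$fraction, nb$epochs$epoch1$fraction)
  expect_identical(na$epochs$epoch1$distance, nb$epochs$epoch1$distance)

  # stimulus-locked activity exceeds its own null
  fr <- attr(ensemble_fraction(ev, 0.4, onsets), "mean_fraction")
  expect_gt(fr, quantile(na$epochs$epoch1$fraction, 0.975, type = 1))
  expect_equal(compare_to_null(2, c(1, 1, 3, 3)), 50)
})
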