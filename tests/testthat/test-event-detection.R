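test_that("detrend removes smooth trends and spares fast structure", {
  n <- 720
  ramp <- seq(0, 1, length.out = n)
  out <- detrend(ramp, span_frames = 101)
  expect_lt(max(abs(out)), 1e-6)  # pure linear trend removed entirely

  set.seed(3)
  noise <- rnorm(n, 0, 0.02)
  dn <- detrend(noise, span_frames = 101)
  expect_lt(abs(sd(dn) - sd(noise)) / sd(noise), 0.10)

  # sharp transient attenuated < 10% when the span is much wider
  tr <- numeric(n)
  tr[300:303] <- c(0.6, 1, 0.5, 0.2)
  dt <- detrend(tr + noise, span_frames = 101)
  expect_gt(dt[301], 0.9 * 1)

  expect_error(detrend(ramp, span_frames = 5), "span_frames")
  expect_error(detrend(ramp[1:50], span_frames = 100), "span_frames")
})

test_that("iterative Gaussian baseline recovers known noise parameters", {
  set.seed(9)
  x <- rnorm(1e4, 0, 0.02)
  b <- fit_baseline(x)
  expect_lt(abs(b$mu), 0.002)
  expect_lt(abs(b$sigma - 0.02) / 0.02, 0.05)
  expect_equal(b$thr_event, b$mu + 4 * b$sigma)
  expect_equal(b$thr_bound, b$mu + 2 * b$sigma)
  expect_gt(b$thr_event, b$thr_bound)

  expect_error(fit_baseline(rep(1, 500)), "constant")
  expect_error(fit_baseline(rnorm(50)), "100")
})

test_that("baseline sigma is robust where the naive SD is not", {
  set.seed(21)
  sigma <- 0.02
  x <- rnorm(1e4, 0, sigma)
  starts <- round(seq(100, 9900, length.out = 20))
  for (s in starts) {  # 20 x 50 samples inside transients = 10%
    x[s:(s + 49)] <- x[s:(s + 49)] + 8 * sigma * exp(-(0:49) / 20)
  }
  b <- fit_baseline(x)
  expect_lt(abs(b$sigma - sigma) / sigma, 0.10)
  expect_gt(abs(sd(x) - sigma) / sigma, 0.25)  # contrast oracle
})

test_that("the 4 SD / 2 SD rule defines events exactly", {
  rate <- 7.5
  base <- fake_baseline(mu = 0, sigma = 0.01)
  times <- (seq_len(40) - 0.5) / rate

  flat <- rep(0, 40)
  expect_equal(nrow(detect_events(flat, base, rate)), 0)

  # rectangular excursion to 5 sigma for 5 samples
  rect <- rep(0, 40); rect[11:15] <- 0.05
  ev <- detect_events(rect, base, rate)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, times[11])
  expect_equal(ev$end_s, times[16])
  expect_equal(ev$duration_s, 5 / rate)
  expect_equal(ev$amplitude, 0.05)

  # 3 sigma crosses the boundary but never the event threshold
  low <- rep(0, 40); low[11:15] <- 0.03
  expect_equal(nrow(detect_events(low, base, rate)), 0)

  # events are disjoint, ordered, and all reach 4 sigma
  two <- rep(0, 40); two[5:7] <- 0.06; two[25:28] <- 0.05
  ev2 <- detect_events(two, base, rate)
  expect_equal(nrow(ev2), 2)
  expect_true(all(diff(ev2$start_s) > 0))
  expect_true(all(ev2$end_s[-nrow(ev2)] <= ev2$start_s[-1]))
  expect_true(all(ev2$amplitude >= 4 * base$sigma))
})

test_that("event features summarize counts, IEI and frequency", {
  ev0 <- data.frame(start_s = numeric(0), peak_s = numeric(0),
                    end_s = numeric(0), amplitude = numeric(0),
                    duration_s = numeric(0))
  f0 <- summarize_events(ev0, 96)
  expect_equal(f0$n_events, 0)
  expect_equal(f0$frequency_hz, 0)
  expect_true(is.na(f0$mean_iei_s))
  expect_false(f0$active)

  ev2 <- data.frame(start_s = c(10, 25), peak_s = c(10.2, 25.2),
                    end_s = c(10.5, 25.5), amplitude = c(0.1, 0.2),
                    duration_s = c(0.5, 0.5))
  f2 <- summarize_events(ev2, 96)
  expect_equal(f2$mean_iei_s, 15)
  expect_true(f2$active)

  ev6 <- ev2[c(1, 1, 1, 1, 1, 1), ]
  expect_equal(summarize_events(ev6, 96)$frequency_hz, 0.0625)
  expect_error(summarize_events(ev2, 0), "duration_s")
})

test_that("session validity requires at least 3 active ROIs, inclusively", {
  feats <- function(k, n = 10) data.frame(active = seq_len(n) <= k)
  expect_false(session_activity_filter(feats(2)))
  expect_true(session_activity_filter(feats(3)))
  expect_true(session_activity_filter(feats(10, 50)))
  expect_equal(attr(session_activity_filter(feats(3)), "n_active"), 3)
})
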