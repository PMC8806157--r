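test_that("threshold normalization zeroes noise and scales to the session max", {
  b1 <- fake_baseline(mu = 0, sigma = 0.025)  # thr_event = 0.1
  traces <- rbind(
    c(0.01, 0.02, -0.01, 0.03),   # all subthreshold
    c(0.00, 0.50, 0.05, 1.00),    # two suprathreshold samples
    c(0.00, 0.20, 0.00, 0.00)     # one suprathreshold sample
  )
  nm <- threshold_normalize(traces, list(b1, b1, b1))
  expect_true(all(nm$values >= 0 & nm$values <= 1))
  expect_true(all(nm$values[1, ] == 0))
  expect_equal(nm$values[2, ], c(0, 0.5, 0, 1))
  expect_equal(max(nm$values[3, ]), 1)
  expect_true(is.na(nm$roi_max[1]))
})

test_that("the ensemble trace is the across-ROI mean", {
  m <- rbind(rep(1, 4), rep(0, 4), c(1, 0, 1, 0))
  expect_equal(compute_ensemble_trace(m), c(2/3, 1/3, 2/3, 1/3))
  single <- matrix(c(0.2, 0.8), nrow = 1)
  expect_equal(compute_ensemble_trace(single), c(0.2, 0.8))
  expect_equal(compute_ensemble_trace(matrix(0, 2, 3)), rep(0, 3))
  # at a time where 5 of 10 ROIs read 1
  m10 <- matrix(0, 10, 1); m10[1:5, 1] <- 1
  expect_equal(compute_ensemble_trace(m10), 0.5)
})

test_that("sweep averaging is the pointwise mean and shrinks noise like 1/sqrt(n)", {
  rate <- 2000
  x <- rep(sin(2 * pi * (1:20000) / 20000), 10)
  onsets <- 10 * (0:9) + 0.0001
  ss <- bin_sweeps(x[1:(96 * rate)], rate, onsets[onsets < 86], 10)
  avg <- average_sweeps(ss)
  expect_equal(avg$values, ss$sweeps[1, ], tolerance = 1e-9)  # identical sweeps

  set.seed(13)
  ss9 <- structure(list(sweeps = matrix(rnorm(9 * 1000), nrow = 9),
                        time_s = (0:999) / rate, rate_hz = rate),
                   class = "sweep_set")
  a9 <- average_sweeps(ss9)
  expect_equal(a9$n_sweeps, 9)
  expect_lt(abs(sd(a9$values) - 1 / 3), 0.035)  # CLT: sd/sqrt(9)
})

test_that("epoch detection recovers programmed extrema and encodes absence", {
  rate <- 2000
  t <- (0:19999) / rate
  base <- 0.08
  sweep <- function(vals) {
    structure(list(values = vals, time_s = t, rate_hz = rate),
              class = "averaged_sweep")
  }
  # bump at 0.4 s, suppression trough over [1.0, 2.6], bump at 3.5 s
  vals <- base +
    0.25 * exp(-(t - 0.4)^2 / (2 * 0.08^2)) +
    0.12 * exp(-(t - 3.5)^2 / (2 * 0.12^2))
  vals[t >= 1.0 & t <= 2.6] <- 0
  ep <- detect_epochs(sweep(vals))
  expect_true(all(ep$present))
  expect_lt(abs(ep$t1_s - 0.4), 0.2)
  expect_lt(abs(ep$t2_s - 1.8), 0.2)
  expect_lt(abs(ep$t3_s - 3.5), 0.2)
  expect_gt(ep$amp1, ep$amp3)

  # monotone decay with a trough only: no maxima, minimum present -> Type C
  dec <- sweep(0.3 * exp(-t / 0.8))
  epd <- detect_epochs(dec)
  expect_false(epd$present["epoch1"])
  expect_true(epd$present["epoch2"])
  expect_false(epd$present["epoch3"])
  expect_equal(classify_pattern(epd), "C")

  # flat zero sweep: nothing present
  epz <- detect_epochs(sweep(rep(0, length(t))))
  expect_false(any(epz$present))
  expect_equal(classify_pattern(epz), "none")
})

test_that("ensemble fraction counts event-window overlaps per stimulus", {
  onsets <- c(10, 20)
  ev_all <- events_at(c(10.4, 10.38, 10.402))    # 3 ROIs active at t1 = 0.4
  fr <- ensemble_fraction(ev_all, 0.4, onsets)
  expect_equal(fr$fraction[1], 1.0)
  expect_equal(fr$fraction[2], 0.0)

  ev_mix <- events_at(c(10.4, 10.4, 10.4, NA, NA, NA, NA, NA, NA, NA))
  fr2 <- ensemble_fraction(ev_mix, 0.4, onsets[1])
  expect_equal(fr2$fraction, 0.3)

  # absent epoch gives missing values, not zeros
  fna <- ensemble_fraction(ev_all, NA_real_, onsets)
  expect_true(all(is.na(fna$fraction)))

  # monotone: adding an active ROI never lowers the fraction
  f3 <- attr(ensemble_fraction(events_at(c(10.4, 10.4, NA)), 0.4, 10),
             "mean_fraction")
  f4 <- attr(ensemble_fraction(events_at(c(10.4, 10.4, 10.4)), 0.4, 10),
             "mean_fraction")
  expect_gte(f4, f3)
})

test_that("pattern typing follows the epoch combination rules", {
  expect_equal(classify_pattern(epoch_set(t1_s = 0.4, t2_s = 1.8, t3_s = 3.5,
                                          amp1 = 0.4, amp3 = 0.1)), "A")
  expect_equal(classify_pattern(epoch_set(t2_s = 1.8, t3_s = 3.5,
                                          amp3 = 0.2)), "B")
  expect_equal(classify_pattern(epoch_set(t1_s = 0.4, t2_s = 1.8, t3_s = 3.5,
                                          amp1 = 0.1, amp3 = 0.4)), "B")
  expect_equal(classify_pattern(epoch_set(t2_s = 1.8)), "C")
  expect_equal(classify_pattern(epoch_set()), "none")
  # a lone maximum without the minimum is not a recognized pattern
  expect_equal(classify_pattern(epoch_set(t1_s = 0.4, amp1 = 0.4)), "none")
})
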