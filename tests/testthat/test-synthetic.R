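test_that("transient kernel is normalized and matches the analytic integral", {
  k <- make_transient_kernel(0.05, 0.3, 7.5)
  expect_equal(max(k), 1)
  expect_true(all(k >= 0))
  expect_error(make_transient_kernel(0.3, 0.3), "decay_tau")
  expect_error(make_transient_kernel(-0.1, 0.3), "rise_tau")

  # at 2 kHz the discrete sum approximates the closed-form integral of the
  # peak-normalized double exponential: (decay - rise) / peak_value
  rise <- 0.05; decay <- 0.3
  tp <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  analytic <- (decay - rise) / peak
  k2 <- make_transient_kernel(rise, decay, 2000)
  expect_lt(abs(sum(k2) / 2000 - analytic) / analytic, 0.02)
})

test_that("identical seeds give bit-identical sessions", {
  a <- generate_session(synthetic_params(seed = 33))
  b <- generate_session(synthetic_params(seed = 33))
  expect_identical(a$bundle$dff, b$bundle$dff)
  expect_identical(a$bundle$lfp$samples, b$bundle$lfp$samples)
  expect_identical(a$truth$events, b$truth$events)
  expect_equal(ncol(a$bundle$dff), 720)
  expect_equal(nrow(a$bundle$stimulus_table), 10)
})

test_that("quiescent sessions are pure Gaussian noise", {
  p <- synthetic_params(seed = 8, spont_rate_hz = 0,
                        epoch_structure = list(type = "none"),
                        drift = list(amp = 0))
  s <- generate_session(p)
  x <- as.vector(s$bundle$dff)
  # pooled SD across 50 ROIs x 720 frames within 5% of noise_sd
  expect_lt(abs(sd(x) - 0.02) / 0.02, 0.05)
  # 4 SD tail exceedance close to the Gaussian tail probability
  pp <- synthetic_params(seed = 801, n_rois = 1400, spont_rate_hz = 0,
                         epoch_structure = list(type = "none"),
                         drift = list(amp = 0))
  x <- as.vector(generate_session(pp)$bundle$dff)
  expect_gte(length(x), 1e6)
  rate <- mean(x > 4 * 0.02)
  expected <- pnorm(4, lower.tail = FALSE)
  tol <- 3 * sqrt(expected * (1 - expected) / length(x))
  expect_lt(abs(rate - expected), tol)
})

test_that("ground-truth epoch events honor the programmed structure", {
  s <- generate_session(synthetic_params(seed = 5))
  tr <- s$truth
  e1 <- tr$events[tr$events$kind == "epoch1", ]
  expect_gt(nrow(e1), 0)
  # every epoch-1 onset within [stimulus, stimulus + latency + slack]
  ons <- tr$onsets_s[e1$stimulus]
  expect_true(all(e1$onset_s > ons & e1$onset_s < ons + 0.4 + 0.2))
  # suppression windows are empty of spontaneous onsets
  sp <- tr$events[tr$events$kind == "spont", ]
  for (i in seq_len(nrow(tr$suppression_windows))) {
    w <- tr$suppression_windows[i, ]
    expect_false(any(sp$onset_s >= w[1] & sp$onset_s <= w[2]))
  }
  # all events inside the recording
  expect_true(all(tr$events$onset_s >= 0 &
                  tr$events$onset_s <= s$bundle$duration_s))
})

test_that("cohort generation applies the group profile deterministically", {
  expect_error(generate_cohort(0, 3), "n_sham")
  base <- synthetic_params(n_rois = 20, epoch_structure = list(type = "none"))
  coh <- generate_cohort(3, 3, base, seed = 9)
  coh2 <- generate_cohort(3, 3, base, seed = 9)
  expect_identical(coh[[1]]$bundle$dff, coh2[[1]]$bundle$dff)
  expect_equal(attr(coh, "group"), rep(c("sham", "hfhi"), each = 3))
  # HFHI-like sessions carry more ground-truth events on average
  n_ev <- vapply(coh, function(s) nrow(s$truth$events), numeric(1))
  expect_gt(mean(n_ev[4:6]), mean(n_ev[1:3]) * 0.9)
})

test_that("planted transients are recovered by the detector", {
  p <- synthetic_params(seed = 14, n_rois = 30,
                        planted = list(n_per_roi = 5, amplitude_sd = 8))
  s <- generate_session(p)
  truth <- s$truth$events
  evs <- detect_all_rois(s$bundle$dff)
  matched <- vapply(seq_along(evs), function(i) {
    tt <- truth$onset_s[truth$roi == i]
    sum(vapply(tt, function(t0) {
      any(evs[[i]]$start_s <= t0 + 0.5 & evs[[i]]$end_s >= t0)
    }, logical(1)))
  }, numeric(1))
  n_found <- vapply(evs, nrow, integer(1))
  # every planted 8-sigma event recovered in >= 95% of ROIs, with spurious
  # extras (late-tail re-crossings, see the methods vignette) <= 5%
  expect_gte(mean(matched == 5), 0.95)
  expect_lte(sum(n_found - matched) / sum(matched), 0.05)
})
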