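test_that("shape features separate compact disks from bars", {
  d <- compute_shape_features(disk_mask(10))
  # analytic disk: area ~ pi r^2, perimeter ~ 2 pi r, roundness ~ 1
  expect_gt(d$area, pi * 10^2 * 0.9)
  expect_lt(d$area, pi * 10^2 * 1.1)
  expect_gte(d$roundness, 1.0)
  expect_lte(d$roundness, 1.3)
  expect_gte(d$oblongness, 1.0)
  expect_lte(d$oblongness, 1.1)

  bar <- matrix(0, 5, 26); bar[3, 4:23] <- 1
  b <- compute_shape_features(bar)
  expect_gt(b$oblongness, 3.6)  # 1x20 bar is far past the limit
  expect_false(apply_qc(b)$include)
  expect_true("oblongness" %in% apply_qc(b)$reasons)

  one <- matrix(0, 3, 3); one[2, 2] <- 1
  s1 <- compute_shape_features(one)
  expect_equal(s1$area, 1)
  expect_true("area" %in% apply_qc(s1)$reasons)  # below the 5-pixel floor

  expect_error(compute_shape_features(matrix(0, 3, 3)), "empty")
})

test_that("trace QC measures drift against the window median", {
  # constant trace: no drift, perfectly stable
  qc <- compute_trace_qc(rep(5, 200))
  expect_equal(qc$baseline_drift_pct, 0)
  expect_true(is.infinite(qc$baseline_stability))
  expect_equal(qc$n_saturated_frames, 0)

  # ramp of 30% of the median across 100 frames -> drift 30 > 25
  ramp <- 1 + 0.3 * ((0:99) - 49.5) / 99
  qr <- compute_trace_qc(ramp)
  expect_equal(qr$baseline_drift_pct, 30, tolerance = 0.02)
  expect_true("drift" %in% apply_qc(list(baseline_drift_pct =
                                           qr$baseline_drift_pct))$reasons)

  # saturation counting needs a declared representable max
  sat <- c(rep(10, 150), rep(2^16 - 1, 3))
  expect_equal(compute_trace_qc(sat,
                                saturation_level = 2^16 - 1)$n_saturated_frames,
               3)
  expect_error(compute_trace_qc(rep(1, 50)), "100")
})

test_that("skewness and kurtosis are recorded but never decide inclusion", {
  set.seed(2)
  qc <- compute_trace_qc(100 + rexp(300))  # heavily skewed
  expect_true(is.finite(qc$skewness))
  expect_gt(qc$skewness, 1)
  dec <- apply_qc(list(skewness = qc$skewness, kurtosis = qc$kurtosis))
  expect_true(dec$include)  # no criterion consumes them
})

test_that("QC thresholds are inclusive and reason codes partition failures", {
  at_boundary <- list(baseline_drift_pct = 25, baseline_stability = 1000,
                      roundness = 2.2, oblongness = 3.6, area = 500,
                      n_saturated_frames = 0)
  expect_true(apply_qc(at_boundary)$include)
  expect_length(apply_qc(at_boundary)$reasons, 0)

  expect_equal(apply_qc(list(roundness = 2.5))$reasons, "roundness")
  expect_equal(apply_qc(list(area = 501))$reasons, "area")
  expect_equal(apply_qc(list(area = 4))$reasons, "area")

  multi <- list(roundness = 3, oblongness = 4, area = 600)
  dec <- apply_qc(multi)
  expect_false(dec$include)
  expect_setequal(dec$reasons, c("roundness", "oblongness", "area"))
})

test_that("worsening any single feature never rescues an excluded ROI", {
  set.seed(7)
  crit <- qc_criteria()
  worsen <- list(
    baseline_drift_pct = function(v) v + runif(1, 0, 30),
    baseline_stability = function(v) v - runif(1, 0, 1500),
    roundness = function(v) v + runif(1, 0, 2),
    oblongness = function(v) v + runif(1, 0, 3),
    area = function(v) v + runif(1, 0, 300),
    n_saturated_frames = function(v) v + sample(0:3, 1)
  )
  for (i in 1:50) {
    f <- list(baseline_drift_pct = runif(1, 0, 50),
              baseline_stability = runif(1, 0, 3000),
              roundness = runif(1, 0.8, 3.5),
              oblongness = runif(1, 1, 5),
              area = runif(1, 1, 700),
              n_saturated_frames = sample(0:2, 1))
    before <- apply_qc(f, crit)
    which_f <- sample(names(worsen), 1)
    f[[which_f]] <- worsen[[which_f]](f[[which_f]])
    after <- apply_qc(f, crit)
    if (!before$include) expect_false(after$include)
    expect_identical(after$include, length(after$reasons) == 0L)
  }
})
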