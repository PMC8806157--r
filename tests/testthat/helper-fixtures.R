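# Shared fixtures built in code at test time.

# Detrend + baseline-fit + detect events for every ROI of a trace matrix.
detect_all_rois <- function(dff, frame_rate = 7.5) {
  lapply(seq_len(nrow(dff)), function(i) {
    tr <- detrend(dff[i, ])
    detect_events(tr, fit_baseline(tr), frame_rate)
  })
}

# Hand-built baseline object for constructed-trace detector tests.
fake_baseline <- function(mu = 0, sigma = 0.01, peak_sd = 4, bound_sd = 2) {
  structure(list(mu = mu, sigma = sigma,
                 thr_event = mu + peak_sd * sigma,
                 thr_bound = mu + bound_sd * sigma,
                 n_iterations = 1L, converged = TRUE),
            class = "baseline")
}

# Rasterized disk mask of the given radius.
disk_mask <- function(r, pad = 5) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  g <- expand.grid(x = 1:n, y = 1:n)
  matrix(as.numeric((g$x - ctr)^2 + (g$y - ctr)^2 <= r^2), n, n)
}

# One-event-per-ROI binary pattern helper.
events_at <- function(times, width = 0.4) {
  lapply(times, function(tt) {
    if (is.na(tt)) {
      data.frame(start_s = numeric(0), peak_s = numeric(0),
                 end_s = numeric(0), amplitude = numeric(0),
                 duration_s = numeric(0))
    } else {
      data.frame(start_s = tt, peak_s = tt + width / 2, end_s = tt + width,
                 amplitude = 0.1, duration_s = width)
    }
  })
}
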