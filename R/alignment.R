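#' Upsample calcium traces to the aligned timebase
#'
#' Linear interpolation from the native frame rate (frame-center timestamps)
#' to the aligned rate. Values at the original frame times are preserved
#' exactly and no extrapolation happens beyond the first/last frame.
#'
#' @param traces numeric matrix (ROIs x frames) or vector.
#' @param frame_rate_hz native rate (Hz).
#' @param target_rate_hz aligned rate (Hz, default 2000).
#' @param times_out optional explicit output times (seconds); defaults to a
#'   uniform grid at `target_rate_hz` spanning the frame-time range.
#' @return list with `values` (matrix, ROIs x T), `times` (seconds) and
#'   `rate_hz`.
#' @export
upsample_calcium <- function(traces, frame_rate_hz = 7.5,
                             target_rate_hz = 2000, times_out = NULL) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  nf <- ncol(traces)
  if (nf < 2) fail_validation("traces", "need at least two frames")
  ft <- sample_times(nf, frame_rate_hz)
  if (is.null(times_out)) {
    times_out <- seq(ft[1], ft[nf], by = 1 / target_rate_hz)
  }
  if (any(times_out < ft[1] - 1e-12 | times_out > ft[nf] + 1e-12)) {
    fail_validation("times_out", "no extrapolation beyond the frame range")
  }
  vals <- t(vapply(seq_len(nrow(traces)), function(i) {
    stats::approx(ft, traces[i, ], xout = times_out, rule = 1)$y
  }, numeric(length(times_out))))
  rownames(vals) <- rownames(traces)
  list(values = vals, times = times_out, rate_hz = target_rate_hz)
}

#' Downsample the LFP to the aligned timebase
#'
#' Zero-phase anti-alias low-pass (4th-order Butterworth, cutoff at 40% of
#' the target rate, applied forward and backward) followed by decimation by
#' the integer rate ratio. Zero-phase filtering keeps stimulus-onset timing
#' intact.
#'
#' @param lfp list with `samples` and `rate_hz`.
#' @param target_rate_hz aligned rate (must divide `rate_hz`).
#' @return list with `samples` and `rate_hz = target_rate_hz`.
#' @export
downsample_lfp <- function(lfp, target_rate_hz = 2000) {
  fac <- lfp$rate_hz / target_rate_hz
  if (abs(fac - round(fac)) > 1e-9) {
    fail_validation("target_rate_hz", "rate ratio must be an integer")
  }
  fac <- as.integer(round(fac))
  if (fac == 1L) return(lfp)
  cutoff <- 0.4 * target_rate_hz
  bf <- signal::butter(4, cutoff / (lfp$rate_hz / 2))
  y <- signal::filtfilt(bf, lfp$samples)
  list(samples = y[seq(1, length(y), by = fac)], rate_hz = target_rate_hz)
}

#' Segment an aligned channel into inter-stimulus sweeps
#'
#' One sweep per inter-stimulus interval (onset k to onset k + 1), each
#' truncated to the common length implied by the sweep period — so 10
#' stimuli 10 s apart yield 9 sweeps. The period after the final stimulus is
#' not a sweep.
#'
#' @param x numeric channel at `rate_hz` (e.g. the ensemble trace).
#' @param rate_hz sampling rate of `x`.
#' @param onsets_s stimulus onsets (seconds, >= 2, roughly `sweep_period_s`
#'   apart; gaps shorter than 95% of the period are rejected).
#' @param sweep_period_s nominal sweep length (seconds).
#' @return object of class `sweep_set`: `sweeps` (matrix, one row per
#'   sweep), `time_s` (stimulus-relative axis), `rate_hz`, `onsets_s`.
#' @export
bin_sweeps <- function(x, rate_hz, onsets_s, sweep_period_s = 10) {
  if (length(onsets_s) < 2) {
    fail_validation("onsets_s", "need at least two stimulus onsets")
  }
  gaps <- diff(onsets_s)
  if (any(gaps < 0.95 * sweep_period_s)) {
    fail_validation("onsets_s",
                    "inter-onset interval shorter than the sweep period")
  }
  n_sweeps <- length(onsets_s) - 1L
  nominal <- round(sweep_period_s * rate_hz)
  starts <- pmax(1L, floor(onsets_s[-length(onsets_s)] * rate_hz) + 1L)
  lens <- pmin(nominal, floor(gaps * rate_hz + 1e-9),
               length(x) - starts + 1L)
  L <- min(lens)
  sweeps <- t(vapply(seq_len(n_sweeps), function(k) {
    x[starts[k]:(starts[k] + L - 1L)]
  }, numeric(L)))
  structure(list(sweeps = sweeps, time_s = (seq_len(L) - 1L) / rate_hz,
                 rate_hz = rate_hz, onsets_s = onsets_s),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples @ %g Hz\n",
              nrow(x$sweeps), ncol(x$sweeps), x$rate_hz))
  invisible(x)
}
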