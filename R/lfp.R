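#' Detect stimulus events in the LFP by threshold search
#'
#' Finds maximal supra-threshold excursions of the (median-centered,
#' rectified) LFP and merges crossings closer than the refractory window, so
#' a biphasic artifact yields one event. With no explicit threshold, half
#' the largest absolute deflection is used — far above the fEPSP itself for
#' artifact-bearing recordings. A warning (not an error) is raised when the
#' threshold does not exceed 5x the robust baseline SD, or when metadata
#' promises stimuli but none are found.
#'
#' @param lfp list with `samples` (mV) and `rate_hz`.
#' @param threshold_mV detection threshold; `NULL` for automatic.
#' @param refractory_s merge window for nearby crossings (seconds).
#' @param expected_n optional promised stimulus count (warning on mismatch).
#' @return data frame with `start_s`, `peak_s`, `end_s`.
#' @export
detect_stimuli <- function(lfp, threshold_mV = NULL, refractory_s = 0.05,
                           expected_n = NULL) {
  x <- lfp$samples - stats::median(lfp$samples)
  a <- abs(x)
  rate <- lfp$rate_hz
  times <- sample_times(length(x), rate)
  if (is.null(threshold_mV)) threshold_mV <- 0.5 * max(a)
  robust_sd <- stats::mad(lfp$samples)
  if (robust_sd > 0 && threshold_mV <= 5 * robust_sd) {
    warning("stimulus threshold does not exceed 5x the baseline SD")
  }
  empty <- data.frame(start_s = numeric(0), peak_s = numeric(0),
                      end_s = numeric(0))
  above <- threshold_mV > 0 & a > threshold_mV
  if (!any(above)) {
    if (!is.null(expected_n) && expected_n > 0) {
      warning("metadata promises ", expected_n, " stimuli but none detected")
    }
    return(empty)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # refractory merging of crossings closer than refractory_s
  gap <- refractory_s * rate
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      if (runs[k, 1] - merged[nrow(merged), 2] < gap) {
        merged[nrow(merged), 2] <- runs[k, 2]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(k) {
    s <- merged[k, 1]; e <- merged[k, 2]
    pk <- s + which.max(a[s:e]) - 1L
    data.frame(start_s = times[s], peak_s = times[pk], end_s = times[e])
  }))
  if (!is.null(expected_n) && nrow(out) != expected_n) {
    warning("detected ", nrow(out), " stimuli but metadata promises ",
            expected_n)
  }
  out
}

#' Measure an fEPSP from the LFP
#'
#' Peak amplitude is the largest absolute deflection from the local
#' pre-stimulus baseline inside the response window (default 2-50 ms after
#' the stimulus; the 2 ms lower edge blanks the artifact). Slope is the
#' linear fit over the 20-80% span of the rising phase toward the peak,
#' signed, in mV/ms. Both are invariant to a constant offset on the LFP.
#'
#' @param lfp list with `samples` (mV) and `rate_hz`.
#' @param stim_onset_s stimulus onset time (seconds).
#' @param window_s two-element post-stimulus response window (seconds).
#' @param baseline_s length of the pre-stimulus baseline segment (seconds).
#' @return list with `peak_amplitude_mV` (magnitude, >= 0),
#'   `slope_mV_per_ms` (signed), `peak_time_s`.
#' @export
measure_fepsp <- function(lfp, stim_onset_s, window_s = c(0.002, 0.050),
                          baseline_s = 0.010) {
  rate <- lfp$rate_hz
  n <- length(lfp$samples)
  duration <- n / rate
  if (stim_onset_s + window_s[2] > duration) {
    fail_validation("window_s", "response window extends past recording end")
  }
  times <- sample_times(n, rate)
  b_lo <- max(0, stim_onset_s - baseline_s - 0.001)
  b_hi <- max(0, stim_onset_s - 0.001)
  bidx <- which(times >= b_lo & times < b_hi)
  base <- if (length(bidx) > 0) mean(lfp$samples[bidx]) else lfp$samples[1]
  widx <- which(times >= stim_onset_s + window_s[1] &
                times <= stim_onset_s + window_s[2])
  defl <- lfp$samples[widx] - base
  if (length(defl) == 0 || max(abs(defl)) == 0) {
    return(list(peak_amplitude_mV = 0, slope_mV_per_ms = 0,
                peak_time_s = NA_real_))
  }
  pk <- which.max(abs(defl))
  peak_val <- defl[pk]
  peak_amp <- abs(peak_val)
  # 20-80% rise toward the peak
  mag <- abs(defl[seq_len(pk)])
  i20 <- which(mag <= 0.2 * peak_amp)
  i20 <- if (length(i20) > 0) max(i20) else 1L
  i80 <- which(mag[i20:pk] >= 0.8 * peak_amp)
  i80 <- if (length(i80) > 0) i20 + min(i80) - 1L else pk
  slope <- if (i80 > i20) {
    tms <- times[widx[i20:i80]] * 1000
    unname(stats::coef(stats::lm(defl[i20:i80] ~ tms))[2])
  } else 0
  list(peak_amplitude_mV = peak_amp, slope_mV_per_ms = slope,
       peak_time_s = times[widx[pk]])
}

#' Build an input/output curve
#'
#' Mean fEPSP peak amplitude per tested stimulus intensity across the
#' session's stimuli.
#'
#' @param measures data frame with `intensity_mA` and `peak_amplitude_mV`.
#' @return data frame of class `io_curve` with `intensity_mA`,
#'   `mean_peak_mV`, `n`.
#' @export
build_io_curve <- function(measures) {
  if (any(measures$intensity_mA < 0 | measures$intensity_mA > 90,
          na.rm = TRUE)) {
    fail_validation("intensity_mA", "intensities must lie within [0, 90] mA")
  }
  agg <- stats::aggregate(peak_amplitude_mV ~ intensity_mA, data = measures,
                          FUN = mean)
  names(agg) <- c("intensity_mA", "mean_peak_mV")
  agg$n <- stats::aggregate(peak_amplitude_mV ~ intensity_mA,
                            data = measures, FUN = length)$peak_amplitude_mV
  agg <- agg[order(agg$intensity_mA), ]
  class(agg) <- c("io_curve", "data.frame")
  agg
}

#' Select the test intensity from an input/output curve
#'
#' Picks the smallest tested intensity whose mean peak lies within 30-50% of
#' the maximum response. When the band is empty the intensity nearest to 40%
#' of the maximum is chosen with a warning.
#'
#' @param io an [build_io_curve()] result with at least two intensities.
#' @return selected intensity (mA).
#' @export
pick_test_intensity <- function(io) {
  if (nrow(io) < 2) {
    fail_validation("io", "need at least two tested intensities")
  }
  maxp <- max(io$mean_peak_mV)
  if (maxp == 0) stop("selection error: all-zero input/output curve",
                      call. = FALSE)
  in_band <- io$mean_peak_mV >= 0.3 * maxp & io$mean_peak_mV <= 0.5 * maxp
  if (any(in_band)) {
    return(min(io$intensity_mA[in_band]))
  }
  warning("no intensity falls in the 30-50% band; choosing nearest to 40%")
  dev <- abs(io$mean_peak_mV - 0.4 * maxp)
  cand <- io$intensity_mA[dev == min(dev)]
  min(cand)
}

#' Normalize post-HFS responses and flag depressed slices
#'
#' Each post-HFS fEPSP peak is divided by the mean baseline-session peak.
#' Three post-HFS sessions are expected (30 s, 5 min, 10 min after HFS); a
#' slice is excluded when its mean normalized amplitude across the post-HFS
#' sessions falls below 1 (depression instead of potentiation).
#'
#' @param baseline_peaks numeric vector of baseline-session fEPSP peaks.
#' @param post_sessions named list of numeric peak vectors, one per post-HFS
#'   session.
#' @return list of class `ltp_result`: `normalized` (list, same shape as
#'   `post_sessions`), `session_means`, `excluded`.
#' @export
normalize_ltp <- function(baseline_peaks, post_sessions) {
  if (length(baseline_peaks) < 1) {
    fail_validation("baseline_peaks", "need at least one baseline measure")
  }
  base_mean <- mean(baseline_peaks)
  if (base_mean == 0) {
    stop("division error: zero baseline mean amplitude", call. = FALSE)
  }
  normalized <- lapply(post_sessions, function(p) p / base_mean)
  session_means <- vapply(normalized, mean, numeric(1))
  structure(list(normalized = normalized,
                 session_means = session_means,
                 excluded = mean(unlist(normalized)) < 1),
            class = "ltp_result")
}

#' High-frequency stimulation protocol bookkeeping
#'
#' Stores and validates the LTP-induction protocol: four tetanic trains at
#' 100 Hz, 1 s each, 10 s inter-train interval. The package records and
#' checks the protocol; it does not deliver stimulation.
#'
#' @param n_trains,freq_hz,train_s,isi_s protocol fields.
#' @return validated list of class `hfs_protocol`.
#' @export
hfs_protocol <- function(n_trains = 4, freq_hz = 100, train_s = 1,
                         isi_s = 10) {
  ref <- list(n_trains = 4, freq_hz = 100, train_s = 1, isi_s = 10)
  given <- list(n_trains = n_trains, freq_hz = freq_hz, train_s = train_s,
                isi_s = isi_s)
  for (nm in names(ref)) {
    if (given[[nm]] != ref[[nm]]) {
      fail_validation(nm, sprintf("HFS protocol expects %s = %s",
                                  nm, format(ref[[nm]])))
    }
  }
  structure(given, class = "hfs_protocol")
}
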