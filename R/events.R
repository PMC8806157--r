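#' Remove slow fluorescence drift with locally weighted regression
#'
#' Fits a LOWESS trend (robust iterations on, so sparse transients barely
#' pull the fit) and returns the residual trace. Used to remove slow
#' photobleaching or focal-drift components before baseline estimation.
#'
#' @param trace numeric dF/F trace.
#' @param span_frames smoothing span in frames (>= 10).
#' @return detrended trace (same length).
#' @export
detrend <- function(trace, span_frames = 101) {
  n <- length(trace)
  if (span_frames < 10) fail_validation("span_frames", "must be >= 10")
  if (span_frames > n) {
    fail_validation("span_frames", "span longer than the trace")
  }
  trend <- stats::lowess(seq_len(n), trace, f = span_frames / n, iter = 3)$y
  trace - trend
}

#' Baseline estimation by iterative Gaussian fitting
#'
#' Estimates the noise baseline of a dF/F trace by least-squares fitting a
#' Gaussian to the histogram of all data points (Freedman-Diaconis bins),
#' censoring samples above `mu + censor_sd * sigma`, refitting on the
#' censored sample, and iterating until the relative change in sigma falls
#' below `tol` (or `max_iter` is reached). Transient-contaminated traces
#' keep an accurate sigma because the positive excursions are censored out,
#' where the naive whole-trace SD overestimates badly.
#'
#' @param trace numeric trace (>= 100 samples, non-constant).
#' @param event_peak_sd,event_bound_sd thresholds (in fitted SDs above the
#'   mean) stored on the result: events must reach `thr_event`, and event
#'   start/end are set at `thr_bound`.
#' @param censor_sd censor level in fitted SDs.
#' @param tol relative sigma convergence tolerance.
#' @param max_iter iteration cap.
#' @return An object of class `baseline`: `mu`, `sigma`, `thr_event`,
#'   `thr_bound`, `n_iterations`, `converged`.
#' @export
fit_baseline <- function(trace, event_peak_sd = 4, event_bound_sd = 2,
                         censor_sd = 2, tol = 1e-3, max_iter = 20) {
  if (length(trace) < 100) {
    fail_validation("trace", "needs at least 100 samples")
  }
  if (stats::sd(trace) == 0) {
    stop("degenerate input: constant trace has no noise baseline",
         call. = FALSE)
  }
  fit_gauss_hist <- function(x) {
    br <- tryCatch(hist(x, breaks = "FD", plot = FALSE),
                   error = function(e) hist(x, plot = FALSE))
    xs <- br$mids
    ys <- br$counts
    mu0 <- xs[which.max(ys)]
    s0 <- max(stats::IQR(x) / 1.349, diff(range(x)) / 100, 1e-12)
    obj <- function(par) {
      A <- exp(par[1]); mu <- par[2]; s <- exp(par[3])
      sum((ys - A * exp(-(xs - mu)^2 / (2 * s^2)))^2)
    }
    fit <- stats::optim(c(log(max(ys)), mu0, log(s0)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-10))
    list(mu = fit$par[2], sigma = exp(fit$par[3]))
  }
  x <- trace
  est <- fit_gauss_hist(x)
  converged <- FALSE
  iter <- 1L
  while (iter < max_iter) {
    kept <- trace[trace <= est$mu + censor_sd * est$sigma]
    if (length(kept) < 50) break
    new_est <- fit_gauss_hist(kept)
    iter <- iter + 1L
    if (abs(new_est$sigma - est$sigma) / est$sigma < tol) {
      est <- new_est
      converged <- TRUE
      break
    }
    est <- new_est
  }
  structure(list(mu = est$mu, sigma = est$sigma,
                 thr_event = est$mu + event_peak_sd * est$sigma,
                 thr_bound = est$mu + event_bound_sd * est$sigma,
                 n_iterations = iter, converged = converged),
            class = "baseline")
}

#' Detect calcium transients with the 4 SD / 2 SD rule
#'
#' An event is a maximal contiguous run of samples above the 2 SD boundary
#' threshold that contains at least one sample at or above the 4 SD event
#' threshold. Start is the first sample of the run; end is the first sample
#' after the run drops back below the boundary (one sample interval past the
#' last run sample when the run touches the trace end); peak is the argmax
#' within the run. Events are disjoint and sorted by start time.
#'
#' @param trace numeric trace (typically detrended, native frame rate).
#' @param baseline a [fit_baseline()] object.
#' @param frame_rate sampling rate of `trace` (Hz).
#' @param times optional sample-center times (seconds); derived from
#'   `frame_rate` when absent.
#' @return data frame with `start_s`, `peak_s`, `end_s`, `amplitude`
#'   (peak dF/F minus baseline mean), `duration_s`.
#' @export
detect_events <- function(trace, baseline, frame_rate = 7.5, times = NULL) {
  n <- length(trace)
  if (is.null(times)) times <- sample_times(n, frame_rate)
  dt <- if (n > 1) times[2] - times[1] else 1 / frame_rate
  above <- trace > baseline$thr_bound
  empty <- data.frame(start_s = numeric(0), peak_s = numeric(0),
                      end_s = numeric(0), amplitude = numeric(0),
                      duration_s = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- empty
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    seg <- trace[s:e]
    if (max(seg) >= baseline$thr_event) {
      pk <- s + which.max(seg) - 1L
      end_t <- if (e < n) times[e + 1L] else times[n] + dt
      out <- rbind(out, data.frame(
        start_s = times[s], peak_s = times[pk], end_s = end_t,
        amplitude = trace[pk] - baseline$mu,
        duration_s = end_t - times[s]))
    }
  }
  out
}

#' Per-ROI event features
#'
#' Event count, frequency (count / recording duration), mean inter-event
#' interval (onset-to-onset, defined only for two or more events), mean
#' amplitude, mean duration, and the active flag (at least one event).
#'
#' @param events event table from [detect_events()].
#' @param duration_s recording duration (seconds, > 0).
#' @param roi_id identifier carried into the output row.
#' @return one-row data frame of features.
#' @export
summarize_events <- function(events, duration_s, roi_id = NA_character_) {
  if (!is_scalar_num(duration_s) || duration_s <= 0) {
    fail_validation("duration_s", "must be > 0")
  }
  n <- nrow(events)
  data.frame(
    roi_id = roi_id,
    n_events = n,
    frequency_hz = n / duration_s,
    mean_iei_s = if (n >= 2) mean(diff(events$start_s)) else NA_real_,
    mean_amplitude = if (n >= 1) mean(events$amplitude) else NA_real_,
    mean_duration_s = if (n >= 1) mean(events$duration_s) else NA_real_,
    active = n >= 1
  )
}

#' Session validity by active-ROI count
#'
#' A session is valid only when at least `min_active_rois` ROIs show at
#' least one calcium transient (inclusive bound: exactly 3 active ROIs is
#' valid at the default minimum of 3).
#'
#' @param features data frame with an `active` column (one row per ROI).
#' @param min_active_rois inclusive minimum.
#' @return logical validity flag with attribute `n_active`.
#' @export
session_activity_filter <- function(features, min_active_rois = 3) {
  n_active <- sum(features$active)
  structure(n_active >= min_active_rois, n_active = n_active)
}
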