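#' Threshold-normalize a trace matrix
#'
#' On a cell-by-cell basis, all values below the 4 SD event threshold are
#' set to 0 and the remaining suprathreshold signal is divided by that ROI's
#' session maximum, so every value lies in [0, 1], a ROI with any
#' suprathreshold sample attains exactly 1 at its session maximum, and
#' all-subthreshold ROIs become all-zero rows. This keeps relative transient
#' magnitude while removing spurious baseline-noise contributions.
#'
#' @param traces numeric matrix (ROIs x time).
#' @param baselines list of [fit_baseline()] objects, one per ROI.
#' @return list of class `normalized_matrix`: `values` (same shape, in
#'   [0, 1]) and `roi_max` (per-ROI scaling maximum, NA for silent ROIs).
#' @export
threshold_normalize <- function(traces, baselines) {
  stopifnot(nrow(traces) == length(baselines))
  vals <- traces
  roi_max <- rep(NA_real_, nrow(traces))
  for (i in seq_len(nrow(traces))) {
    v <- traces[i, ]
    v[v < baselines[[i]]$thr_event] <- 0
    m <- max(v)
    if (m > 0) {
      v <- v / m
      roi_max[i] <- m
    }
    vals[i, ] <- v
  }
  structure(list(values = vals, roi_max = roi_max),
            class = "normalized_matrix")
}

#' Ensemble trace: mean normalized activity across ROIs
#'
#' The per-timepoint mean across ROIs of the thresholded-normalized matrix;
#' the resulting one-dimensional signal represents the fraction of the total
#' active ensemble through time (0 wherever every ROI is subthreshold).
#'
#' @param nm a [threshold_normalize()] result (or a plain matrix).
#' @return numeric vector in [0, 1].
#' @export
compute_ensemble_trace <- function(nm) {
  vals <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  if (nrow(vals) < 1) fail_validation("nm", "need at least one ROI")
  colMeans(vals)
}

#' Average inter-stimulus sweeps
#'
#' Pointwise mean of the sweeps on the stimulus-relative axis, giving the
#' session's characteristic post-stimulus ensemble pattern.
#'
#' @param ss a [bin_sweeps()] result.
#' @return object of class `averaged_sweep`: `values`, `time_s`, `rate_hz`,
#'   `n_sweeps`.
#' @export
average_sweeps <- function(ss) {
  if (!inherits(ss, "sweep_set")) fail_validation("ss", "need a sweep_set")
  if (nrow(ss$sweeps) < 1) fail_validation("ss", "need at least one sweep")
  structure(list(values = colMeans(ss$sweeps), time_s = ss$time_s,
                 rate_hz = ss$rate_hz, n_sweeps = nrow(ss$sweeps)),
            class = "averaged_sweep")
}

# Local maxima of a numeric vector with plateau handling; boundary runs are
# never maxima. Returns the middle index of each maximal plateau.
find_local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  if (m < 3) return(integer(0))
  j <- 2:(m - 1L)
  is_max <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  sel <- j[is_max]
  as.integer(floor((starts[sel] + ends[sel]) / 2))
}

# Topographic prominence of each peak index: height above the higher of the
# two lowest saddles separating it from higher ground (or the range edge).
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- if (p > 1) {
      seg <- y[1:(p - 1L)]
      higher <- which(seg > h)
      lo <- if (length(higher) > 0) (max(higher) + 1L) else 1L
      min(y[lo:(p - 1L)])
    } else h
    right <- if (p < length(y)) {
      seg <- y[(p + 1L):length(y)]
      higher <- which(seg > h)
      hi <- if (length(higher) > 0) (p + min(higher) - 1L) else length(y)
      min(y[(p + 1L):hi])
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' Construct an epoch set from known latencies
#'
#' Builds the same structure [detect_epochs()] returns, from explicitly
#' supplied epoch latencies (NA = absent). Useful for evaluating ensemble
#' fraction or the shuffle null at nominal or ground-truth epoch times.
#'
#' @param t1_s,t2_s,t3_s epoch latencies (seconds, stimulus-relative).
#' @param amp1,amp2,amp3 optional epoch amplitudes.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(t1_s = NA_real_, t2_s = NA_real_, t3_s = NA_real_,
                      amp1 = NA_real_, amp2 = NA_real_, amp3 = NA_real_) {
  structure(list(t1_s = t1_s, t2_s = t2_s, t3_s = t3_s,
                 amp1 = amp1, amp2 = amp2, amp3 = amp3,
                 present = c(epoch1 = !is.na(t1_s), epoch2 = !is.na(t2_s),
                             epoch3 = !is.na(t3_s))),
            class = "epoch_set")
}

#' Detect the three post-stimulus ensemble epochs
#'
#' On the smoothed averaged sweep: epoch 1 is the most prominent local
#' maximum within (0, `epoch1_limit_s`]; epoch 2 is the ensemble minimum in
#' [max(t1, lower epoch-2 bound), upper epoch-2 bound], located at the
#' midpoint of the longest run of near-minimal values (the minimal plateau);
#' epoch 3 is the most prominent local maximum within (t2,
#' `epoch3_limit_s`]. Maxima must clear a prominence floor (a fraction of
#' the sweep's dynamic range); ties go to the earliest candidate. Absent
#' epochs are encoded in presence flags, never as errors.
#'
#' @param avg an [average_sweeps()] result.
#' @param config an [analysis_config()] (epoch bounds, smoothing window,
#'   prominence and plateau-tolerance fractions).
#' @return object of class `epoch_set`: `t1_s`, `t2_s`, `t3_s` (NA when
#'   absent), `amp1`, `amp2`, `amp3`, `present` (named logical vector).
#' @export
detect_epochs <- function(avg, config = analysis_config()) {
  y <- moving_average(avg$values, round(config$smooth_window_s * avg$rate_hz))
  t <- avg$time_s
  out <- list(t1_s = NA_real_, t2_s = NA_real_, t3_s = NA_real_,
              amp1 = NA_real_, amp2 = NA_real_, amp3 = NA_real_,
              present = c(epoch1 = FALSE, epoch2 = FALSE, epoch3 = FALSE))
  class(out) <- "epoch_set"
  rng <- max(y) - min(y)
  if (rng <= 0) return(out)
  p_min <- config$prominence_frac * rng

  peaks <- find_local_maxima(y)
  proms <- peak_prominence(y, peaks)

  pick_peak <- function(lo, hi) {
    cand <- which(t[peaks] > lo & t[peaks] <= hi & proms >= p_min)
    if (length(cand) == 0) return(NULL)
    best <- cand[proms[cand] == max(proms[cand])][1]  # earliest on ties
    peaks[best]
  }

  p1 <- pick_peak(0, config$epoch1_limit_s)
  if (!is.null(p1)) {
    out$t1_s <- t[p1]
    out$amp1 <- y[p1]
    out$present["epoch1"] <- TRUE
  }

  e2 <- config$epoch2_range_s
  lo2 <- max(out$t1_s, e2[1], na.rm = TRUE)
  win <- which(t >= lo2 & t <= e2[2])
  if (length(win) > 0) {
    seg <- y[win]
    mn <- min(seg)
    below <- seg <= mn + config$plateau_tol_frac * rng
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    true_runs <- which(r$values)
    k <- true_runs[which.max(r$lengths[true_runs])]
    mid <- win[as.integer(floor((starts[k] + ends[k]) / 2))]
    out$t2_s <- t[mid]
    out$amp2 <- mn
    out$present["epoch2"] <- TRUE
  }

  if (out$present["epoch2"]) {
    p3 <- pick_peak(out$t2_s, config$epoch3_limit_s)
    if (!is.null(p3)) {
      out$t3_s <- t[p3]
      out$amp3 <- y[p3]
      out$present["epoch3"] <- TRUE
    }
  }
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>\n")
  for (e in 1:3) {
    nm <- paste0("epoch", e)
    if (x$present[nm]) {
      cat(sprintf("  %s: t = %.3f s, amplitude = %.4f\n",
                  nm, x[[paste0("t", e, "_s")]], x[[paste0("amp", e)]]))
    } else {
      cat(sprintf("  %s: absent\n", nm))
    }
  }
  invisible(x)
}

#' Ensemble fraction in the epoch window
#'
#' Fraction of ROIs with a calcium transient overlapping the 10 ms window
#' centered on the (session-level) epoch time, computed per stimulus by
#' applying the stimulus-relative epoch latency at each stimulus onset. An
#' ROI counts as active when any event interval [start, end] intersects the
#' window; the fraction is active count / total ROIs.
#'
#' @param events_by_roi list of [detect_events()] tables, one per ROI.
#' @param epoch_time_s stimulus-relative epoch latency (seconds); `NA`
#'   returns missing values rather than zeros.
#' @param onsets_s stimulus onsets (seconds).
#' @param window_s window width (seconds, default 0.010).
#' @return data frame with `stimulus` and `fraction`, plus attribute
#'   `mean_fraction`.
#' @export
ensemble_fraction <- function(events_by_roi, epoch_time_s, onsets_s,
                              window_s = 0.010) {
  n_roi <- length(events_by_roi)
  if (is.na(epoch_time_s)) {
    out <- data.frame(stimulus = seq_along(onsets_s),
                      fraction = NA_real_)
    attr(out, "mean_fraction") <- NA_real_
    return(out)
  }
  frac <- vapply(onsets_s, function(on) {
    lo <- on + epoch_time_s - window_s / 2
    hi <- on + epoch_time_s + window_s / 2
    active <- vapply(events_by_roi, function(ev) {
      nrow(ev) > 0 && any(ev$start_s <= hi & ev$end_s >= lo)
    }, logical(1))
    sum(active) / n_roi
  }, numeric(1))
  out <- data.frame(stimulus = seq_along(onsets_s), fraction = frac)
  attr(out, "mean_fraction") <- mean(frac)
  out
}

#' Classify the session's post-stimulus pattern type
#'
#' Type A: first maximum and ensemble minimum present, with the first
#' maximum at least as large as the second (or no second). Type B: second
#' maximum and minimum present, with no first maximum (or a dominant second
#' maximum). Type C: minimum only. Anything else (including a featureless
#' sweep) is `"none"`. Classification is meaningful at the
#' highest-intensity session, where the pattern is most consistent.
#'
#' @param epochs an [detect_epochs()] result.
#' @return one of `"A"`, `"B"`, `"C"`, `"none"`.
#' @export
classify_pattern <- function(epochs) {
  p <- epochs$present
  amp1 <- if (p["epoch1"]) epochs$amp1 else -Inf
  amp3 <- if (p["epoch3"]) epochs$amp3 else -Inf
  if (p["epoch1"] && p["epoch2"] && amp1 >= max(amp3, 0)) return("A")
  if (p["epoch3"] && p["epoch2"] && (!p["epoch1"] || amp3 > amp1)) {
    return("B")
  }
  if (p["epoch2"] && !p["epoch1"] && !p["epoch3"]) return("C")
  "none"
}

#' Plot an averaged ensemble sweep with detected epochs
#'
#' @param x an [average_sweeps()] result.
#' @param epochs optional [detect_epochs()] result to annotate.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.averaged_sweep <- function(x, epochs = NULL, ...) {
  graphics::plot(x$time_s, x$values, type = "l",
                 xlab = "time after stimulus (s)",
                 ylab = "ensemble fraction", ...)
  if (!is.null(epochs)) {
    for (e in 1:3) {
      nm <- paste0("epoch", e)
      if (epochs$present[nm]) {
        graphics::abline(v = epochs[[paste0("t", e, "_s")]], lty = 2,
                         col = c("firebrick", "steelblue", "darkorange")[e])
      }
    }
  }
  invisible(x)
}
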