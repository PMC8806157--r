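#' Binary active-ROI pattern for one epoch window
#'
#' Entry i is 1 iff ROI i has an event interval intersecting the window of
#' width `window_s` centered on `center_s`.
#'
#' @param events_by_roi list of [detect_events()] tables, one per ROI.
#' @param center_s window center (seconds, absolute time).
#' @param window_s window width (seconds).
#' @return integer 0/1 vector of length `length(events_by_roi)`.
#' @export
active_pattern <- function(events_by_roi, center_s, window_s = 0.010) {
  lo <- center_s - window_s / 2
  hi <- center_s + window_s / 2
  vapply(events_by_roi, function(ev) {
    as.integer(nrow(ev) > 0 && any(ev$start_s <= hi & ev$end_s >= lo))
  }, integer(1))
}

#' Normalized Hamming distance between two binary patterns
#'
#' Number of differing positions divided by the pattern length. Unlike the
#' Jaccard index or cosine similarity, it is well defined for two all-zero
#' patterns (distance 0) — the situation routinely produced by the ensemble
#' minimum epoch.
#'
#' @param p,q equal-length binary vectors.
#' @return distance in [0, 1].
#' @export
hamming <- function(p, q) {
  if (length(p) != length(q)) {
    fail_validation("q", "patterns must have equal length")
  }
  mean(p != q)
}

#' Mean ensemble distance within an epoch
#'
#' Mean normalized Hamming distance over all unordered stimulus pairs of the
#' epoch's active-ROI patterns (active ROIs of one epoch versus the same
#' epoch following a different stimulation).
#'
#' @param patterns matrix (stimuli x ROIs) or list of binary vectors.
#' @return list with `distance` (mean over pairs) and `n_pairs`.
#' @export
epoch_distance <- function(patterns) {
  if (is.list(patterns)) patterns <- do.call(rbind, patterns)
  n <- nrow(patterns)
  if (is.null(n) || n < 2) {
    fail_validation("patterns", "need at least two stimulus patterns")
  }
  pairs <- utils::combn(n, 2)
  d <- vapply(seq_len(ncol(pairs)), function(k) {
    hamming(patterns[pairs[1, k], ], patterns[pairs[2, k], ])
  }, numeric(1))
  list(distance = mean(d), n_pairs = ncol(pairs))
}

#' Mean pairwise ROI correlation
#'
#' Mean Pearson correlation over all ROI pairs of the (detrended, raw dF/F)
#' trace matrix; pairs involving a constant trace have undefined correlation
#' and are skipped and counted.
#'
#' @param mat numeric matrix (ROIs x time, >= 2 ROIs).
#' @return list with `mean_r` (NA when every pair is undefined), `n_pairs`,
#'   `n_skipped`.
#' @export
pairwise_correlation <- function(mat) {
  if (nrow(mat) < 2) fail_validation("mat", "need at least two ROIs")
  cc <- suppressWarnings(stats::cor(t(mat)))
  vals <- cc[upper.tri(cc)]
  n_skipped <- sum(is.na(vals))
  mean_r <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  list(mean_r = mean_r, n_pairs = length(vals), n_skipped = n_skipped)
}

#' Circularly shift each row of a matrix
#'
#' Rotates every ROI's time series independently by the given number of
#' samples (value at time t moves to t + shift, wrapping around), exactly
#' preserving each row's multiset of values.
#'
#' @param mat numeric matrix (ROIs x time).
#' @param shifts integer vector of shifts, one per row.
#' @return shifted matrix.
#' @export
circular_shuffle <- function(mat, shifts) {
  if (length(shifts) != nrow(mat)) {
    fail_validation("shifts", "need one shift per row")
  }
  n <- ncol(mat)
  out <- mat
  for (i in seq_len(nrow(mat))) {
    s <- shifts[i] %% n
    if (s != 0) out[i, ] <- mat[i, c((n - s + 1L):n, 1L:(n - s))]
  }
  out
}

# Overlap of circularly shifted event intervals with a window, treating the
# recording as a circle of circumference duration_s. Intervals wrapping past
# the end are tested in both pieces; a wrapped event stays one event.
shifted_overlap <- function(starts, durs, shift_by_event, duration_s,
                            lo, hi) {
  s2 <- (starts + shift_by_event) %% duration_s
  e2 <- s2 + durs
  (s2 <= hi & e2 >= lo) | (e2 > duration_s & (e2 - duration_s) >= lo)
}

#' Circular-shift shuffle null for ensemble fraction and distance
#'
#' For each of `n_shuffles` iterations a random circular shift is drawn for
#' each ROI; the ROI's detected event intervals are rotated by that amount
#' (mod the recording duration), and the ensemble fraction and ensemble
#' distance are recomputed at the FIXED epoch times observed on the real
#' data. The result is the chance-level distribution of both metrics per
#' epoch, plus the observed values' percentiles.
#'
#' @param events_by_roi list of [detect_events()] tables, one per ROI.
#' @param epochs an [detect_epochs()] result from the unshuffled session.
#' @param onsets_s stimulus onsets (seconds).
#' @param duration_s recording duration (seconds).
#' @param config an [analysis_config()] (`n_shuffles`, `epoch_window_s`,
#'   `rng_seed`).
#' @param metrics which null metrics to compute (subset of
#'   `c("fraction", "distance")`).
#' @param observed optional list of observed values per epoch (elements
#'   `fraction`, `distance`); percentiles are reported when supplied.
#' @return object of class `shuffle_null`: per present epoch, the null
#'   vectors and observed percentiles; absent epochs are omitted.
#' @export
build_null <- function(events_by_roi, epochs, onsets_s, duration_s,
                       config = analysis_config(),
                       metrics = c("fraction", "distance"),
                       observed = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  n_roi <- length(events_by_roi)
  n_sh <- config$n_shuffles
  w <- config$epoch_window_s

  roi_of <- rep.int(seq_len(n_roi),
                    vapply(events_by_roi, nrow, integer(1)))
  all_ev <- do.call(rbind, events_by_roi)
  starts <- all_ev$start_s %||% numeric(0)
  durs <- (all_ev$end_s - all_ev$start_s) %||% numeric(0)

  present <- names(which(epochs$present))
  lat <- c(epoch1 = epochs$t1_s, epoch2 = epochs$t2_s, epoch3 = epochs$t3_s)

  shifts <- with_seed(config$rng_seed,
                      matrix(stats::runif(n_sh * n_roi, 0, duration_s),
                             nrow = n_sh))

  out <- list(n_shuffles = n_sh, seed = config$rng_seed, epochs = list())
  for (ep in present) {
    centers <- onsets_s + lat[[ep]]
    lo <- centers - w / 2
    hi <- centers + w / 2
    n_win <- length(centers)
    frac_null <- if ("fraction" %in% metrics) numeric(n_sh) else NULL
    dist_null <- if ("distance" %in% metrics) numeric(n_sh) else NULL
    for (k in seq_len(n_sh)) {
      sh <- shifts[k, ][roi_of]
      pat <- matrix(0L, nrow = n_win, ncol = n_roi)
      for (wdx in seq_len(n_win)) {
        ov <- shifted_overlap(starts, durs, sh, duration_s,
                              lo[wdx], hi[wdx])
        if (any(ov)) pat[wdx, unique(roi_of[ov])] <- 1L
      }
      if (!is.null(frac_null)) frac_null[k] <- mean(rowMeans(pat))
      if (!is.null(dist_null) && n_win >= 2) {
        dist_null[k] <- epoch_distance(pat)$distance
      }
    }
    res <- list(fraction = frac_null, distance = dist_null)
    if (!is.null(observed[[ep]])) {
      res$observed <- observed[[ep]]
      if (!is.null(frac_null) && !is.null(observed[[ep]]$fraction)) {
        res$fraction_percentile <-
          compare_to_null(observed[[ep]]$fraction, frac_null)
      }
      if (!is.null(dist_null) && !is.null(observed[[ep]]$distance)) {
        res$distance_percentile <-
          compare_to_null(observed[[ep]]$distance, dist_null)
      }
    }
    out$epochs[[ep]] <- res
  }
  class(out) <- "shuffle_null"
  out
}

#' Percentile of an observed value within a null distribution
#'
#' Mid-rank percentile: ties between the observed value and null draws count
#' half.
#'
#' @param observed scalar observed value.
#' @param null numeric null distribution.
#' @return percentile in [0, 100].
#' @export
compare_to_null <- function(observed, null) {
  100 * (sum(null < observed) + 0.5 * sum(null == observed)) / length(null)
}
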