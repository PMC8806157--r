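#' ROI quality-control criteria
#'
#' Semi-automatic ROI refinement thresholds: no more than 25% baseline drift
#' over 100 frames, baseline stability of at least 1,000, roundness at most
#' 2.2, oblongness at most 3.6, area between 5 and 500 pixels, and zero
#' saturated frames. All thresholds are inclusive ("maximum 2.2" admits 2.2).
#' Skewness and kurtosis are recorded by [compute_trace_qc()] but never used
#' for exclusion.
#'
#' @param max_drift_pct maximum baseline drift (% per 100 frames).
#' @param stability_threshold minimum baseline stability (inverse coefficient
#'   of variation of 100-frame window medians; see [compute_trace_qc()]).
#' @param max_roundness maximum roundness (`perimeter^2 / (4 * pi * area)`,
#'   1 for a perfect circle).
#' @param max_oblongness maximum major/minor second-moment axis ratio.
#' @param area_range closed pixel-area range.
#' @param max_saturated_frames maximum saturated frames allowed.
#' @return An object of class `qc_criteria`.
#' @export
qc_criteria <- function(max_drift_pct = 25, stability_threshold = 1000,
                        max_roundness = 2.2, max_oblongness = 3.6,
                        area_range = c(5, 500), max_saturated_frames = 0) {
  if (area_range[1] >= area_range[2]) {
    fail_validation("area_range", "must be an increasing pair")
  }
  structure(list(max_drift_pct = max_drift_pct,
                 stability_threshold = stability_threshold,
                 max_roundness = max_roundness,
                 max_oblongness = max_oblongness,
                 area_range = area_range,
                 max_saturated_frames = max_saturated_frames),
            class = "qc_criteria")
}

#' Shape features of an ROI mask
#'
#' Area is the pixel count. Roundness is `perimeter^2 / (4 * pi * area)`
#' (dimensionless, 1 for a perfect circle, larger = less round), with the
#' perimeter measured as the Euclidean length of the 8-connected boundary
#' contour. Oblongness is the major/minor axis ratio of the second-moment
#' ellipse, with each pixel treated as a unit square (variance 1/12) so that
#' one-pixel-wide masks have a finite, large ratio.
#'
#' @param mask logical or 0/1 matrix with a single connected component.
#' @return list with `area`, `roundness`, `oblongness`, `perimeter`.
#' @export
compute_shape_features <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow = nrow(mask))
  area <- sum(m)
  if (area == 0) fail_validation("mask", "mask is empty")
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1) {
    fail_validation("mask", "mask must be a single connected component")
  }
  if (area == 1) {
    perim <- 4  # unit-square convention for a single pixel
  } else {
    oc <- EBImage::ocontour(m)[[1]]
    d <- rbind(diff(oc), oc[1, , drop = FALSE] - oc[nrow(oc), , drop = FALSE])
    perim <- sum(sqrt(rowSums(d^2)))
  }
  roundness <- perim^2 / (4 * pi * area)
  px <- which(m == 1, arr.ind = TRUE)
  cv <- if (nrow(px) > 1) {
    stats::cov(px) * (nrow(px) - 1) / nrow(px) + diag(1 / 12, 2)
  } else {
    diag(1 / 12, 2)
  }
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  oblongness <- sqrt(max(ev) / min(ev))
  list(area = area, roundness = roundness, oblongness = oblongness,
       perimeter = perim)
}

#' Trace-stability features of an ROI
#'
#' Baseline drift is the maximum over sliding 100-frame windows of the
#' absolute endpoint difference of a linear fit, expressed as a percentage of
#' that window's median. Baseline stability is the median of the window
#' medians divided by their SD (large = stable; infinite for a perfectly
#' flat baseline). A saturated frame is a sample at or above the declared
#' representable maximum of the source data. Skewness and kurtosis are
#' computed and reported but carry no exclusion weight.
#'
#' @param trace numeric trace, length >= `window_frames`.
#' @param window_frames sliding-window length (frames; default 100).
#' @param saturation_level representable maximum of the source data, or
#'   `NULL` when unknown (then no frame counts as saturated).
#' @return list with `baseline_drift_pct`, `baseline_stability`,
#'   `n_saturated_frames`, `skewness`, `kurtosis`.
#' @export
compute_trace_qc <- function(trace, window_frames = 100,
                             saturation_level = NULL) {
  n <- length(trace)
  W <- as.integer(window_frames)
  if (n < W) {
    fail_validation("trace", sprintf("needs at least %d frames", W))
  }
  starts <- seq_len(n - W + 1L)
  tt <- seq_len(W)
  stt <- sum((tt - mean(tt))^2)
  csx <- cumsum(c(0, trace))
  csxt <- cumsum(c(0, trace * seq_len(n)))
  sum_x <- csx[starts + W] - csx[starts]
  sum_xt <- csxt[starts + W] - csxt[starts] - (starts - 1) * sum_x
  slope <- (sum_xt - mean(tt) * sum_x) / stt
  meds <- vapply(starts, function(s) stats::median(trace[s:(s + W - 1L)]),
                 numeric(1))
  delta <- abs(slope * (W - 1L))
  drift <- ifelse(abs(meds) > 1e-12, delta / abs(meds) * 100,
                  ifelse(delta < 1e-12, 0, Inf))
  med_sd <- stats::sd(meds)
  stability <- if (is.na(med_sd) || med_sd == 0) Inf
               else abs(stats::median(meds)) / med_sd
  n_sat <- if (is.null(saturation_level)) 0L
           else sum(trace >= saturation_level)
  list(baseline_drift_pct = max(drift),
       baseline_stability = stability,
       n_saturated_frames = n_sat,
       skewness = e1071::skewness(trace),
       kurtosis = e1071::kurtosis(trace))
}

#' Apply ROI refinement criteria
#'
#' Pure decision: include iff every available criterion passes; every failing
#' criterion appears as a reason code (`"drift"`, `"stability"`,
#' `"roundness"`, `"oblongness"`, `"area"`, `"saturated"`). Features absent
#' from the input (`NULL` or `NA`) are skipped, supporting partial feature
#' tables.
#'
#' @param features named list combining [compute_shape_features()] and
#'   [compute_trace_qc()] outputs (any subset).
#' @param criteria a [qc_criteria()] object.
#' @return list with `include` (logical) and `reasons` (character vector,
#'   empty iff included).
#' @export
apply_qc <- function(features, criteria = qc_criteria()) {
  reasons <- character(0)
  chk <- function(value, fails, code) {
    if (!is.null(value) && !is.na(value) && fails(value)) {
      reasons <<- c(reasons, code)
    }
  }
  chk(features$baseline_drift_pct,
      function(v) v > criteria$max_drift_pct, "drift")
  chk(features$baseline_stability,
      function(v) v < criteria$stability_threshold, "stability")
  chk(features$roundness, function(v) v > criteria$max_roundness, "roundness")
  chk(features$oblongness,
      function(v) v > criteria$max_oblongness, "oblongness")
  chk(features$area,
      function(v) v < criteria$area_range[1] | v > criteria$area_range[2],
      "area")
  chk(features$n_saturated_frames,
      function(v) v > criteria$max_saturated_frames, "saturated")
  list(include = length(reasons) == 0, reasons = reasons)
}
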