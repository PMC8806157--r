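#' Analysis configuration
#'
#' Container for every constant the pipeline uses: the imaging and
#' electrophysiology rates, the 4 SD event / 2 SD boundary detection rule,
#' the 10 ms epoch window, 10 s sweep period, the 1,000-iteration shuffle
#' null, the minimum of 3 active ROIs for a valid session, the post-stimulus
#' epoch timing bounds (first maximum < 1 s, minimum 1-3 s, second maximum
#' within 5 s), and the 1.5x interquartile-range outlier fence.
#'
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param n_frames expected frames per session.
#' @param lfp_rate_hz native LFP sampling rate (Hz).
#' @param aligned_rate_hz common timebase after alignment (Hz).
#' @param event_peak_sd event threshold in baseline SDs (a transient must
#'   reach this far above the baseline mean).
#' @param event_bound_sd boundary threshold in baseline SDs (event start/end
#'   crossings).
#' @param epoch_window_s width of the window around an epoch time used for
#'   ensemble fraction and active patterns (seconds).
#' @param sweep_period_s inter-stimulus sweep length (seconds).
#' @param n_shuffles circular-shift iterations in the shuffle null.
#' @param min_active_rois minimum active ROIs for a valid session
#'   (inclusive).
#' @param epoch1_limit_s latest allowed first-maximum latency (seconds).
#' @param epoch2_range_s two-element search range for the ensemble minimum.
#' @param epoch3_limit_s latest allowed second-maximum latency (seconds).
#' @param outlier_iqr_mult multiplier on the interquartile range for outlier
#'   fences.
#' @param rng_seed integer seed used by all randomized operations.
#' @param detrend_span_frames LOWESS span for slow-drift removal (frames).
#' @param smooth_window_s moving-average window applied to the averaged sweep
#'   before extremum search (seconds).
#' @param prominence_frac minimum peak prominence for epoch maxima, as a
#'   fraction of the averaged sweep's dynamic range.
#' @param plateau_tol_frac tolerance (fraction of dynamic range) defining the
#'   minimal plateau whose midpoint is the ensemble-minimum latency.
#' @param refractory_s merge window for stimulus-artifact threshold crossings
#'   (seconds).
#' @param fepsp_window_s two-element post-stimulus response window for fEPSP
#'   measurement (seconds; the lower edge blanks the stimulus artifact).
#' @return An object of class `analysis_config` (a validated named list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$event_peak_sd  # 4
analysis_config <- function(frame_rate_hz = 7.5,
                            n_frames = 720,
                            lfp_rate_hz = 20000,
                            aligned_rate_hz = 2000,
                            event_peak_sd = 4,
                            event_bound_sd = 2,
                            epoch_window_s = 0.010,
                            sweep_period_s = 10,
                            n_shuffles = 1000,
                            min_active_rois = 3,
                            epoch1_limit_s = 1.0,
                            epoch2_range_s = c(1.0, 3.0),
                            epoch3_limit_s = 5.0,
                            outlier_iqr_mult = 1.5,
                            rng_seed = 1L,
                            detrend_span_frames = 101,
                            smooth_window_s = 0.050,
                            prominence_frac = 0.10,
                            plateau_tol_frac = 0.01,
                            refractory_s = 0.050,
                            fepsp_window_s = c(0.002, 0.050)) {
  cfg <- list(
    frame_rate_hz = frame_rate_hz, n_frames = n_frames,
    lfp_rate_hz = lfp_rate_hz, aligned_rate_hz = aligned_rate_hz,
    event_peak_sd = event_peak_sd, event_bound_sd = event_bound_sd,
    epoch_window_s = epoch_window_s, sweep_period_s = sweep_period_s,
    n_shuffles = n_shuffles, min_active_rois = min_active_rois,
    epoch1_limit_s = epoch1_limit_s, epoch2_range_s = epoch2_range_s,
    epoch3_limit_s = epoch3_limit_s, outlier_iqr_mult = outlier_iqr_mult,
    rng_seed = as.integer(rng_seed),
    detrend_span_frames = detrend_span_frames,
    smooth_window_s = smooth_window_s,
    prominence_frac = prominence_frac,
    plateau_tol_frac = plateau_tol_frac,
    refractory_s = refractory_s,
    fepsp_window_s = fepsp_window_s
  )
  class(cfg) <- "analysis_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (f in c("frame_rate_hz", "lfp_rate_hz", "aligned_rate_hz")) {
    if (!is_scalar_num(cfg[[f]]) || cfg[[f]] <= 0) {
      fail_validation(f, "rates must be positive numbers")
    }
  }
  if (!is_scalar_num(cfg$event_bound_sd) || cfg$event_bound_sd <= 0) {
    fail_validation("event_bound_sd", "must be > 0")
  }
  if (!is_scalar_num(cfg$event_peak_sd) ||
      cfg$event_peak_sd <= cfg$event_bound_sd) {
    fail_validation("event_peak_sd", "must exceed event_bound_sd")
  }
  if (!is.numeric(cfg$epoch2_range_s) || length(cfg$epoch2_range_s) != 2 ||
      cfg$epoch2_range_s[1] >= cfg$epoch2_range_s[2]) {
    fail_validation("epoch2_range_s", "must be an increasing pair")
  }
  if (cfg$epoch1_limit_s >= cfg$epoch2_range_s[2]) {
    fail_validation("epoch1_limit_s", "must precede the end of epoch2_range_s")
  }
  if (cfg$epoch2_range_s[2] > cfg$epoch3_limit_s) {
    fail_validation("epoch3_limit_s", "must be >= end of epoch2_range_s")
  }
  if (cfg$epoch3_limit_s >= cfg$sweep_period_s) {
    fail_validation("epoch3_limit_s", "must lie inside the sweep period")
  }
  if (!is_scalar_num(cfg$n_shuffles) || cfg$n_shuffles < 1) {
    fail_validation("n_shuffles", "must be >= 1")
  }
  if (!is_scalar_num(cfg$min_active_rois) || cfg$min_active_rois < 1) {
    fail_validation("min_active_rois", "must be >= 1")
  }
  if (!is_scalar_num(cfg$outlier_iqr_mult) || cfg$outlier_iqr_mult <= 0) {
    fail_validation("outlier_iqr_mult", "must be > 0")
  }
  cfg
}

#' Load an analysis configuration from a YAML file
#'
#' Keys missing from the file keep their documented defaults; an empty file
#' yields the full default configuration. Unknown keys raise an error so that
#' typos never silently fall back to defaults.
#'
#' @param path path to a YAML (key: value) configuration file.
#' @return An [analysis_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("parse error in config file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) {
    stop("parse error in config file '", path,
         "': expected a key-value mapping", call. = FALSE)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    fail_validation(unknown[1], "unknown configuration key")
  }
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
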