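#' Run the full per-session analysis
#'
#' Orchestrates QC (optional) -> detrend -> baseline -> event detection ->
#' LFP measures -> alignment -> threshold normalization -> ensemble trace ->
#' sweeps -> epoch detection -> ensemble fraction -> ensemble distance ->
#' shuffle null -> pattern classification. Sessions with fewer active ROIs
#' than the configured minimum are marked invalid and the ensemble stages
#' are skipped. Deterministic given the configuration seed; any stage's
#' validation error propagates with the stage name prepended.
#'
#' @param bundle a [session_bundle()].
#' @param config an [analysis_config()].
#' @param roi_features optional list of per-ROI feature lists for
#'   [apply_qc()]; ROIs failing QC are dropped before analysis.
#' @param criteria [qc_criteria()] used when `roi_features` is given.
#' @param run_null compute the circular-shift shuffle null (the most
#'   expensive stage); disable for epoch-recovery-only runs.
#' @param null_metrics passed to [build_null()].
#' @return object of class `session_result` with the per-stage outputs.
#' @export
run_session <- function(bundle, config = analysis_config(),
                        roi_features = NULL, criteria = qc_criteria(),
                        run_null = TRUE,
                        null_metrics = c("fraction", "distance")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  dff <- bundle$dff
  qc_decisions <- NULL
  if (!is.null(roi_features)) {
    qc_decisions <- stage("roi_qc", lapply(roi_features, apply_qc, criteria))
    keep <- vapply(qc_decisions, `[[`, logical(1), "include")
    note("roi_qc: %d/%d ROIs pass", sum(keep), length(keep))
    dff <- dff[keep, , drop = FALSE]
  }
  n_roi <- nrow(dff)
  duration_s <- bundle$duration_s
  frame_times <- sample_times(ncol(dff), bundle$frame_rate_hz)

  detrended <- stage("detrend", t(apply(dff, 1, detrend,
                                        span_frames = config$detrend_span_frames)))
  baselines <- stage("fit_baseline", lapply(seq_len(n_roi), function(i) {
    fit_baseline(detrended[i, ],
                 event_peak_sd = config$event_peak_sd,
                 event_bound_sd = config$event_bound_sd)
  }))
  events_by_roi <- stage("detect_events", lapply(seq_len(n_roi), function(i) {
    detect_events(detrended[i, ], baselines[[i]],
                  frame_rate = bundle$frame_rate_hz, times = frame_times)
  }))
  names(events_by_roi) <- rownames(dff)
  event_features <- stage("summarize_events", do.call(rbind,
    lapply(seq_len(n_roi), function(i) {
      summarize_events(events_by_roi[[i]], duration_s,
                       roi_id = rownames(dff)[i])
    })))
  valid <- session_activity_filter(event_features, config$min_active_rois)
  note("activity filter: %d active ROIs, valid = %s",
       attr(valid, "n_active"), valid)

  events_table <- do.call(rbind, lapply(seq_len(n_roi), function(i) {
    ev <- events_by_roi[[i]]
    if (nrow(ev) == 0) return(NULL)
    cbind(roi_id = rownames(dff)[i], ev)
  }))

  # Stimulus onsets: trust the stimulus table, else threshold search on LFP.
  onsets <- NULL
  fepsp <- NULL
  lfp2k <- NULL
  if (!is.null(bundle$stimulus_table) && nrow(bundle$stimulus_table) > 0) {
    onsets <- bundle$stimulus_table$onset_s
  } else if (!is.null(bundle$lfp)) {
    stims <- stage("detect_stimuli",
                   detect_stimuli(bundle$lfp,
                                  refractory_s = config$refractory_s))
    onsets <- stims$start_s
    note("detect_stimuli: %d events", length(onsets))
  }
  if (!is.null(bundle$lfp)) {
    lfp2k <- stage("downsample_lfp",
                   downsample_lfp(bundle$lfp, config$aligned_rate_hz))
    if (!is.null(onsets)) {
      measurable <- onsets[onsets + config$fepsp_window_s[2] <= duration_s]
      if (length(measurable) < length(onsets)) {
        note("fepsp: %d onsets too close to the recording end skipped",
             length(onsets) - length(measurable))
      }
      fepsp <- stage("measure_fepsp", do.call(rbind,
        lapply(seq_along(measurable), function(k) {
          m <- measure_fepsp(lfp2k, measurable[k],
                             window_s = config$fepsp_window_s)
          data.frame(stimulus = k, peak_amplitude_mV = m$peak_amplitude_mV,
                     slope_mV_per_ms = m$slope_mV_per_ms)
        })))
    }
  }

  res <- list(
    session_id = bundle$metadata$session_id %||% NA_character_,
    group = bundle$metadata$group %||% NA_character_,
    n_roi = n_roi,
    qc_decisions = qc_decisions,
    baselines = baselines,
    events_by_roi = events_by_roi,
    events = events_table,
    event_features = event_features,
    valid = valid,
    n_active = attr(valid, "n_active"),
    onsets_s = onsets,
    fepsp = fepsp,
    log = log
  )
  class(res) <- "session_result"
  if (!valid || is.null(onsets) || length(onsets) < 2) {
    res$log <- c(res$log, "ensemble stages skipped (invalid session)")
    return(res)
  }

  nm <- stage("threshold_normalize", threshold_normalize(detrended, baselines))
  ens_native <- stage("ensemble_trace", compute_ensemble_trace(nm))
  # Linear interpolation commutes with the across-ROI mean, so upsampling
  # the 1-D ensemble trace equals the ensemble trace of upsampled ROIs.
  up <- stage("upsample", upsample_calcium(ens_native, bundle$frame_rate_hz,
                                           config$aligned_rate_hz))
  # Shift to absolute time: the upsampled grid starts at the first frame
  # center; re-grid from t = 0 for stimulus-aligned indexing.
  t2k <- seq(0, duration_s, by = 1 / config$aligned_rate_hz)
  ens2k <- stats::approx(up$times, up$values[1, ], xout = t2k, rule = 2)$y
  sweeps <- stage("bin_sweeps", bin_sweeps(ens2k, config$aligned_rate_hz,
                                           onsets, config$sweep_period_s))
  avg <- stage("average_sweeps", average_sweeps(sweeps))
  epochs <- stage("detect_epochs", detect_epochs(avg, config))

  lat <- c(epoch1 = epochs$t1_s, epoch2 = epochs$t2_s, epoch3 = epochs$t3_s)
  fractions <- list()
  distances <- list()
  observed <- list()
  epoch_rows <- list()
  for (ep in names(which(epochs$present))) {
    fr <- ensemble_fraction(events_by_roi, lat[[ep]], onsets,
                            window_s = config$epoch_window_s)
    pats <- t(vapply(onsets, function(on) {
      active_pattern(events_by_roi, on + lat[[ep]],
                     window_s = config$epoch_window_s)
    }, integer(n_roi)))
    dd <- epoch_distance(pats)
    fractions[[ep]] <- fr
    distances[[ep]] <- dd
    observed[[ep]] <- list(fraction = attr(fr, "mean_fraction"),
                           distance = dd$distance)
    epoch_rows[[ep]] <- data.frame(
      epoch = ep, time_s = lat[[ep]],
      amplitude = epochs[[paste0("amp", sub("epoch", "", ep))]],
      mean_fraction = attr(fr, "mean_fraction"),
      distance = dd$distance)
  }

  res$normalized <- nm
  res$ensemble_trace <- ens2k
  res$aligned_rate_hz <- config$aligned_rate_hz
  res$sweeps <- sweeps
  res$avg_sweep <- avg
  res$epochs <- epochs
  res$fractions <- fractions
  res$distances <- distances
  res$epoch_table <- do.call(rbind, epoch_rows)
  res$pattern <- classify_pattern(epochs)
  res$pairwise <- stage("pairwise_correlation",
                        if (n_roi >= 2) pairwise_correlation(detrended)
                        else NULL)

  if (run_null && length(observed) > 0) {
    null <- stage("build_null",
                  build_null(events_by_roi, epochs, onsets, duration_s,
                             config, metrics = null_metrics,
                             observed = observed))
    res$null <- null
    res$null_summary <- do.call(rbind, lapply(names(null$epochs),
      function(ep) {
        e <- null$epochs[[ep]]
        data.frame(epoch = ep,
                   fraction_percentile = e$fraction_percentile %||% NA_real_,
                   distance_percentile = e$distance_percentile %||% NA_real_)
      }))
  }
  res
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %s: %d ROIs, %d active, valid = %s\n",
              x$session_id, x$n_roi, x$n_active, x$valid))
  if (!is.null(x$pattern)) cat("  pattern type:", x$pattern, "\n")
  if (!is.null(x$epoch_table)) {
    print(x$epoch_table, row.names = FALSE)
  }
  invisible(x)
}

#' Flag outliers by the 1.5x interquartile-range rule
#'
#' A value is an outlier when it lies more than `multiplier` times the
#' interquartile range above the upper quartile or below the lower quartile.
#' Quartiles are Tukey hinges (the inclusive-median method), which the
#' flags depend on: for values 1, 2, 3, 4, 100 the hinges are 2 and 4, the
#' fence 4 + 1.5 x 2 = 7, and 100 is flagged.
#'
#' @param values numeric vector (>= 4 values, else no flags and a warning).
#' @param multiplier IQR multiplier.
#' @return logical flags, same length as `values`.
#' @export
flag_outliers <- function(values, multiplier = 1.5) {
  flags <- rep(FALSE, length(values))
  ok <- is.finite(values)
  if (sum(ok) < 4) {
    warning("fewer than 4 values; no outlier flags assigned")
    return(flags)
  }
  fn <- stats::fivenum(values[ok])
  q1 <- fn[2]; q3 <- fn[4]
  iqr <- q3 - q1
  flags[ok] <- values[ok] > q3 + multiplier * iqr |
               values[ok] < q1 - multiplier * iqr
  flags
}

#' Summarize a cohort of session results
#'
#' Builds a tidy long table (one row per session x metric) plus descriptive
#' group summaries (mean, SEM — SEM is missing for single-session groups)
#' and per-metric, per-group outlier flags by the IQR rule.
#'
#' @param session_results list of [run_session()] results.
#' @param groups optional group label per session (defaults to each
#'   result's `group`).
#' @param config an [analysis_config()] (outlier multiplier).
#' @return list of class `cohort_summary`: `long`, `group_summary`.
#' @export
summarize_cohort <- function(session_results, groups = NULL,
                             config = analysis_config()) {
  if (length(session_results) < 1) {
    fail_validation("session_results", "need at least one session")
  }
  if (is.null(groups)) {
    groups <- vapply(session_results, function(r) {
      as.character(r$group %||% NA_character_)
    }, character(1))
  }
  metric_rows <- function(r, g) {
    vals <- c(
      n_active_rois = as.numeric(r$n_active),
      mean_events_per_roi = mean(r$event_features$n_events),
      mean_event_frequency_hz = mean(r$event_features$frequency_hz),
      mean_event_amplitude = mean(r$event_features$mean_amplitude,
                                  na.rm = TRUE),
      mean_pairwise_r = r$pairwise$mean_r %||% NA_real_
    )
    if (!is.null(r$epoch_table)) {
      for (i in seq_len(nrow(r$epoch_table))) {
        ep <- r$epoch_table$epoch[i]
        vals[paste0(ep, "_fraction")] <- r$epoch_table$mean_fraction[i]
        vals[paste0(ep, "_distance")] <- r$epoch_table$distance[i]
      }
    }
    data.frame(session_id = r$session_id, group = g,
               metric = names(vals), value = unname(vals),
               row.names = NULL)
  }
  long <- do.call(rbind, Map(metric_rows, session_results, groups))

  sem <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x))
                     else NA_real_
  gs <- do.call(rbind, lapply(split(long, long[c("metric", "group")]),
    function(d) {
      if (nrow(d) == 0) return(NULL)
      v <- d$value[is.finite(d$value)]
      data.frame(metric = d$metric[1], group = d$group[1],
                 n = length(v), mean = mean(v), sem = sem(v),
                 n_outliers = sum(suppressWarnings(
                   flag_outliers(v, config$outlier_iqr_mult))))
    }))
  rownames(gs) <- NULL
  structure(list(long = long, group_summary = gs),
            class = "cohort_summary")
}
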