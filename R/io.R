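#' Session bundle
#'
#' One recording session: the per-ROI dF/F trace matrix at the imaging frame
#' rate, the matched LFP voltage trace, the stimulus-onset table, and session
#' metadata (id, group label, stimulus intensity, session type). All times
#' are in seconds with t = 0 at recording start and timestamps at sample
#' centers.
#'
#' @param dff numeric matrix, ROIs x frames, dF/F units. Row names are ROI
#'   ids (generated when absent).
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param lfp list with elements `samples` (mV) and `rate_hz`, or `NULL`.
#' @param stimulus_table data frame with column `onset_s` (and optionally
#'   `peak_s`, `end_s`, `intensity_mA`), or `NULL`.
#' @param metadata named list: `session_id`, `group`, `intensity_mA`,
#'   `session_type` (one of `"input-output"`, `"baseline"`, `"post-HFS"`),
#'   `align_offset_s` (explicit calcium/LFP alignment offset, default 0).
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(dff, frame_rate_hz = 7.5, lfp = NULL,
                           stimulus_table = NULL, metadata = list()) {
  if (!is.matrix(dff) || !is.numeric(dff)) {
    fail_validation("dff", "must be a numeric ROIs x frames matrix")
  }
  if (is.null(rownames(dff))) {
    rownames(dff) <- sprintf("roi_%03d", seq_len(nrow(dff)))
  }
  duration_s <- ncol(dff) / frame_rate_hz
  if (!is.null(lfp)) {
    if (!is.numeric(lfp$samples) || !is_scalar_num(lfp$rate_hz) ||
        lfp$rate_hz <= 0) {
      fail_validation("lfp", "needs numeric samples and a positive rate_hz")
    }
    if (any(!is.finite(lfp$samples))) {
      fail_validation("lfp", "samples must be finite")
    }
  }
  if (!is.null(stimulus_table)) {
    if (!"onset_s" %in% names(stimulus_table)) {
      fail_validation("stimulus_table", "missing onset_s column")
    }
    on <- stimulus_table$onset_s
    if (length(on) > 1 && any(diff(on) <= 0)) {
      fail_validation("stimulus_table", "onset times must be strictly increasing")
    }
    if (any(on < 0 | on > duration_s)) {
      fail_validation("stimulus_table", "onset times outside recording duration")
    }
  }
  metadata$align_offset_s <- metadata$align_offset_s %||% 0
  metadata$n_rois <- nrow(dff)
  metadata$n_frames <- ncol(dff)
  structure(
    list(dff = dff, frame_rate_hz = frame_rate_hz, lfp = lfp,
         stimulus_table = stimulus_table, metadata = metadata,
         duration_s = duration_s),
    class = "session_bundle"
  )
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %d ROIs x %d frames @ %.3g Hz (%.1f s)\n",
              nrow(x$dff), ncol(x$dff), x$frame_rate_hz, x$duration_s))
  if (!is.null(x$lfp)) {
    cat(sprintf("  LFP: %d samples @ %g Hz\n",
                length(x$lfp$samples), x$lfp$rate_hz))
  }
  if (!is.null(x$stimulus_table)) {
    cat(sprintf("  stimuli: %d onsets\n", nrow(x$stimulus_table)))
  }
  invisible(x)
}

# Format numeric columns so doubles survive a CSV round trip bit-identically.
format_num <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

write_table_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, format_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

read_table_csv <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) {
    stop("format error: ragged rows in ", path, call. = FALSE)
  }
  utils::read.csv(path, check.names = FALSE)
}

#' Read a session from delimited files
#'
#' Trace tables are UTF-8 comma-delimited with a mandatory header. Two
#' orientations are accepted and auto-detected: rows-are-ROIs (a `roi_id`
#' column followed by one column per frame) or columns-are-ROIs (one named
#' column per ROI, one row per frame). The orientation found is recorded in
#' the bundle metadata. The LFP table has a single `voltage_mV` column; the
#' stimulus table has an `onset_s` column in seconds.
#'
#' @param trace_path path to the dF/F trace CSV.
#' @param lfp_path optional path to the LFP CSV.
#' @param stim_path optional path to the stimulus-onset CSV.
#' @param metadata named list merged into the bundle metadata; supply
#'   `lfp_rate_hz` (default 20000) and `frame_rate_hz` (default 7.5) here.
#' @return A [session_bundle()].
#' @export
read_session <- function(trace_path, lfp_path = NULL, stim_path = NULL,
                         metadata = list()) {
  frame_rate_hz <- metadata$frame_rate_hz %||% 7.5
  tr <- read_table_csv(trace_path)
  if ("roi_id" %in% names(tr)) {
    ids <- as.character(tr$roi_id)
    dff <- as.matrix(tr[, setdiff(names(tr), "roi_id"), drop = FALSE])
    storage.mode(dff) <- "double"
    rownames(dff) <- ids
    metadata$trace_orientation <- "rows"
  } else {
    dff <- t(as.matrix(tr))
    storage.mode(dff) <- "double"
    rownames(dff) <- names(tr)
    metadata$trace_orientation <- "columns"
  }
  lfp <- NULL
  if (!is.null(lfp_path)) {
    lt <- read_table_csv(lfp_path)
    if (!"voltage_mV" %in% names(lt)) {
      stop("format error: LFP table needs a voltage_mV column", call. = FALSE)
    }
    lfp <- list(samples = as.numeric(lt$voltage_mV),
                rate_hz = metadata$lfp_rate_hz %||% 20000)
  }
  stim <- NULL
  if (!is.null(stim_path)) {
    stim <- read_table_csv(stim_path)
    if (!"onset_s" %in% names(stim)) {
      stop("format error: stimulus table needs an onset_s column",
           call. = FALSE)
    }
    stim[] <- lapply(stim, function(col) {
      if (is.numeric(col)) as.double(col) else col
    })
  }
  session_bundle(dff, frame_rate_hz = frame_rate_hz, lfp = lfp,
                 stimulus_table = stim, metadata = metadata)
}

#' Write a session bundle to delimited files
#'
#' Inverse of [read_session()]: numeric payloads are formatted so that a
#' read/write round trip is bit-identical.
#'
#' @param bundle a [session_bundle()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_session <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(traces = file.path(dir, "traces.csv"))
  tr <- data.frame(roi_id = rownames(bundle$dff), check.names = FALSE,
                   stringsAsFactors = FALSE)
  frames <- as.data.frame(bundle$dff, check.names = FALSE)
  names(frames) <- sprintf("f%04d", seq_len(ncol(bundle$dff)))
  write_table_csv(cbind(tr, frames), paths["traces"])
  if (!is.null(bundle$lfp)) {
    paths["lfp"] <- file.path(dir, "lfp.csv")
    write_table_csv(data.frame(voltage_mV = bundle$lfp$samples),
                    paths["lfp"])
  }
  if (!is.null(bundle$stimulus_table)) {
    paths["stimuli"] <- file.path(dir, "stimuli.csv")
    write_table_csv(bundle$stimulus_table, paths["stimuli"])
  }
  meta <- bundle$metadata
  meta$frame_rate_hz <- bundle$frame_rate_hz
  if (!is.null(bundle$lfp)) meta$lfp_rate_hz <- bundle$lfp$rate_hz
  paths["metadata"] <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Write pipeline results and a run manifest
#'
#' Emits per-session delimited tables (event features, per-event rows, epoch
#' metrics, null-percentile summaries) plus a machine-readable JSON manifest
#' recording the configuration, seed, and package version. Empty results
#' produce the manifest only.
#'
#' @param results list of per-session results from [run_session()] (possibly
#'   empty), or a single result.
#' @param out_dir output directory.
#' @param config the [analysis_config()] used (stored in the manifest).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(results, out_dir, config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(results, "session_result")) results <- list(results)
  written <- character(0)

  bind_stage <- function(field) {
    rows <- lapply(results, function(r) {
      df <- r[[field]]
      if (is.null(df) || !is.data.frame(df) || nrow(df) == 0) return(NULL)
      cbind(session_id = r$session_id %||% NA_character_, df)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) == 0) return(NULL)
    do.call(rbind, rows)
  }
  for (field in c("event_features", "events", "epoch_table",
                  "null_summary")) {
    tab <- bind_stage(field)
    if (!is.null(tab)) {
      p <- file.path(out_dir, paste0(field, ".csv"))
      write_table_csv(tab, p)
      written <- c(written, p)
    }
  }
  manifest <- list(
    package = "ca1ensemble",
    version = as.character(utils::packageVersion("ca1ensemble")),
    r_version = R.version.string,
    rng_seed = config$rng_seed,
    n_sessions = length(results),
    config = unclass(config)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(written, mp))
}
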