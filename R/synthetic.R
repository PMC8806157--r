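#' Double-exponential transient kernel
#'
#' Difference-of-exponentials waveform `exp(-t/decay) - exp(-t/rise)`
#' emulating GCaMP6f-like calcium-indicator kinetics, discretized at the
#' given sampling rate with its maximum sample normalized to 1. The kernel
#' extends five decay constants past the peak so the tail is negligible.
#'
#' @param rise_tau rise time constant (s), must satisfy 0 < rise < decay.
#' @param decay_tau decay time constant (s).
#' @param frame_rate sampling rate (Hz).
#' @return Numeric kernel vector with attributes `dt` (sample interval, s)
#'   and `peak_time_s` (continuous-time location of the kernel maximum).
#' @export
make_transient_kernel <- function(rise_tau = 0.05, decay_tau = 0.3,
                                  frame_rate = 7.5) {
  if (!is_scalar_num(rise_tau) || rise_tau <= 0) {
    fail_validation("rise_tau", "must be > 0")
  }
  if (!is_scalar_num(decay_tau) || decay_tau <= rise_tau) {
    fail_validation("decay_tau", "must exceed rise_tau")
  }
  tp <- transient_peak_time(rise_tau, decay_tau)
  t <- seq(0, tp + 5 * decay_tau, by = 1 / frame_rate)
  k <- exp(-t / decay_tau) - exp(-t / rise_tau)
  k <- k / max(k)
  attr(k, "dt") <- 1 / frame_rate
  attr(k, "peak_time_s") <- tp
  k
}

# Continuous-time peak location and unit-peak evaluation of the kernel.
transient_peak_time <- function(rise_tau, decay_tau) {
  rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
}

transient_value <- function(t, rise_tau, decay_tau) {
  tp <- transient_peak_time(rise_tau, decay_tau)
  pk <- exp(-tp / decay_tau) - exp(-tp / rise_tau)
  v <- numeric(length(t))
  pos <- t >= 0
  v[pos] <- (exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)) / pk
  v
}

#' Synthetic-session parameters
#'
#' Parameters of the seeded generator that emulates one simultaneous
#' calcium-imaging + LFP recording: 720 frames of 50 ROIs at 7.5 Hz with
#' Gaussian baseline noise and a slow decaying-exponential drift; spontaneous
#' Poisson transients convolved with a double-exponential GCaMP6f-like
#' kernel; 10 stimuli 10 s apart; a three-epoch evoked structure (first
#' ensemble maximum, suppression trough, second maximum) with repeating
#' core-ensemble membership; and an LFP carrying a one-sample stimulus
#' artifact plus a negative-going alpha-function fEPSP.
#'
#' @param n_rois,n_frames,frame_rate_hz imaging geometry (defaults 50 ROIs,
#'   720 frames, 7.5 Hz).
#' @param noise_sd baseline Gaussian noise SD in dF/F units.
#' @param drift list: `amp` (dF/F), `tau_s` (decay constant of the slow
#'   additive component), `slope_per_s` (optional linear term).
#' @param kernel list: `rise_tau_s`, `decay_tau_s`, `amp_sd` (transient peak
#'   amplitude in multiples of `noise_sd`), `amp_jitter_sdlog` (lognormal
#'   amplitude jitter).
#' @param spont_rate_hz per-ROI spontaneous event rate (Hz).
#' @param stimuli list: `n`, `period_s`, `first_onset_s`.
#' @param epoch_structure list: `type` ("A", "B", "C" or "none"), `t1_s` and
#'   `t3_s` (latencies of the evoked ensemble maxima, measured at the
#'   transient peak), `t2_s` and `t2_dur_s` (center and width of the
#'   suppression window), `frac1`/`frac3` (fraction of ROIs in each epoch's
#'   core ensemble), `suppress_factor` (multiplier on the spontaneous rate
#'   inside the suppression window), `jitter_sd_s` (evoked latency jitter).
#' @param membership list: `p_repeat` (probability a core member
#'   participates on a given stimulus) and `p_leak` (probability a
#'   non-member does).
#' @param group_profile list from [group_profile()]: multiplies
#'   `spont_rate_hz` by `rate_mult` and `p_repeat` by `p_repeat_mult`.
#' @param fepsp list: `amp_mV`, `tau_s` (alpha-function time constant),
#'   `delay_s` (synaptic delay), `artifact_mV` (one-sample stimulus spike),
#'   `noise_sd_mV`.
#' @param lfp_rate_hz LFP sampling rate (Hz).
#' @param planted optional list(`n_per_roi`, `amplitude_sd`) that replaces
#'   all spontaneous/evoked activity with evenly spaced planted transients of
#'   known amplitude, for detector recovery tests.
#' @param seed integer RNG seed; identical seeds give bit-identical sessions.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_rois = 50, n_frames = 720, frame_rate_hz = 7.5,
                             noise_sd = 0.02,
                             drift = list(amp = 0.05, tau_s = 40,
                                          slope_per_s = 0),
                             kernel = list(rise_tau_s = 0.05,
                                           decay_tau_s = 0.3,
                                           amp_sd = 6,
                                           amp_jitter_sdlog = 0.1),
                             spont_rate_hz = 0.1,
                             stimuli = list(n = 10, period_s = 10,
                                            first_onset_s = 2),
                             epoch_structure = list(type = "A", t1_s = 0.4,
                                                    t2_s = 1.8,
                                                    t2_dur_s = 1.6,
                                                    t3_s = 3.5,
                                                    frac1 = 0.6, frac3 = 0.3,
                                                    suppress_factor = 0,
                                                    jitter_sd_s = 0.03),
                             membership = list(p_repeat = 0.9,
                                               p_leak = 0.02),
                             group_profile = NULL,
                             fepsp = list(amp_mV = 0.5, tau_s = 0.005,
                                          delay_s = 0.003, artifact_mV = 5,
                                          noise_sd_mV = 0.02),
                             lfp_rate_hz = 20000,
                             planted = NULL,
                             seed = 1L) {
  defaults <- formals(synthetic_params)
  merge_sub <- function(given, name) {
    def <- eval(defaults[[name]])
    for (nm in names(given)) def[[nm]] <- given[[nm]]
    def
  }
  p <- list(
    n_rois = n_rois, n_frames = n_frames, frame_rate_hz = frame_rate_hz,
    noise_sd = noise_sd,
    drift = merge_sub(drift, "drift"),
    kernel = merge_sub(kernel, "kernel"),
    spont_rate_hz = spont_rate_hz,
    stimuli = merge_sub(stimuli, "stimuli"),
    epoch_structure = merge_sub(epoch_structure, "epoch_structure"),
    membership = merge_sub(membership, "membership"),
    group_profile = group_profile %||% group_profile("sham"),
    fepsp = merge_sub(fepsp, "fepsp"),
    lfp_rate_hz = lfp_rate_hz,
    planted = planted,
    seed = as.integer(seed)
  )
  class(p) <- "synthetic_params"
  validate_synthetic_params(p)
}

validate_synthetic_params <- function(p) {
  if (p$n_rois < 1) fail_validation("n_rois", "must be >= 1")
  if (p$spont_rate_hz < 0) fail_validation("spont_rate_hz", "must be >= 0")
  if (p$noise_sd <= 0) fail_validation("noise_sd", "must be > 0")
  k <- p$kernel
  if (k$rise_tau_s <= 0) fail_validation("kernel$rise_tau_s", "must be > 0")
  if (k$decay_tau_s <= k$rise_tau_s) {
    fail_validation("kernel$decay_tau_s", "must exceed rise_tau_s")
  }
  m <- p$membership
  if (m$p_repeat < 0 || m$p_repeat > 1) {
    fail_validation("membership$p_repeat", "must be in [0, 1]")
  }
  if (m$p_leak < 0 || m$p_leak > 1) {
    fail_validation("membership$p_leak", "must be in [0, 1]")
  }
  es <- p$epoch_structure
  if (!es$type %in% c("A", "B", "C", "none")) {
    fail_validation("epoch_structure$type", "must be A, B, C or none")
  }
  duration <- p$n_frames / p$frame_rate_hz
  st <- p$stimuli
  last_onset <- st$first_onset_s + (st$n - 1) * st$period_s
  if (st$n >= 1 && (st$first_onset_s < 0 || last_onset >= duration)) {
    fail_validation("stimuli", "stimuli must fit inside the recording")
  }
  p
}

#' Group profile for cohort generation
#'
#' Sham-like sessions keep the base spontaneous rate and membership
#' reliability; HFHI-like sessions (emulating the high-frequency head impact
#' group) elevate the spontaneous event rate and reduce how consistently the
#' same core ROIs participate across stimuli.
#'
#' @param label `"sham"` or `"hfhi"`.
#' @param rate_mult multiplier on `spont_rate_hz`.
#' @param p_repeat_mult multiplier on membership reliability.
#' @return A named list with class `group_profile`.
#' @export
group_profile <- function(label = c("sham", "hfhi"), rate_mult = NULL,
                          p_repeat_mult = NULL) {
  label <- match.arg(label)
  defaults <- if (label == "sham") c(1.0, 1.0) else c(1.5, 0.7)
  structure(list(label = label,
                 rate_mult = rate_mult %||% defaults[1],
                 p_repeat_mult = p_repeat_mult %||% defaults[2]),
            class = "group_profile")
}

#' Generate one synthetic session with ground truth
#'
#' Builds `dF/F = drift + noise + sum(events (x) kernel)` per ROI, an LFP
#' with per-stimulus artifact spikes and negative alpha-function fEPSPs, and
#' a fully populated ground-truth record (event onsets, per-stimulus epoch
#' membership, true latencies, true fEPSP amplitudes). Identical seeds give
#' bit-identical output.
#'
#' @param params a [synthetic_params()] object.
#' @return list with elements `bundle` (a [session_bundle()]) and `truth`.
#' @export
generate_session <- function(params = synthetic_params()) {
  params <- validate_synthetic_params(params)
  with_seed(params$seed, generate_session_impl(params))
}

generate_session_impl <- function(p) {
  nf <- p$n_frames
  nr <- p$n_rois
  duration <- nf / p$frame_rate_hz
  ft <- sample_times(nf, p$frame_rate_hz)
  es <- p$epoch_structure
  st <- p$stimuli
  gp <- p$group_profile
  onsets <- if (st$n >= 1) st$first_onset_s + (seq_len(st$n) - 1) * st$period_s
            else numeric(0)
  tp <- transient_peak_time(p$kernel$rise_tau_s, p$kernel$decay_tau_s)
  p_rep <- min(1, p$membership$p_repeat * gp$p_repeat_mult)
  rate <- p$spont_rate_hz * gp$rate_mult

  suppress_win <- NULL
  if (es$type %in% c("A", "B", "C") && length(onsets) > 0) {
    suppress_win <- cbind(onsets + es$t2_s - es$t2_dur_s / 2,
                          onsets + es$t2_s + es$t2_dur_s / 2)
  }
  # Suppression silences suprathreshold activity throughout the window, so
  # events are thinned when their transient would still be elevated inside
  # it: onsets up to one transient envelope before the window count too.
  lead <- tp + p$kernel$decay_tau_s * log(max(p$kernel$amp_sd, exp(1)))
  in_suppression <- function(t) {
    if (is.null(suppress_win)) return(rep(FALSE, length(t)))
    hit <- rep(FALSE, length(t))
    for (i in seq_len(nrow(suppress_win))) {
      hit <- hit | (t >= suppress_win[i, 1] - lead & t <= suppress_win[i, 2])
    }
    hit
  }

  # Core ensembles: fixed per session, one set per evoked epoch.
  active_epochs <- switch(es$type, A = c(1, 3), B = 3, C = integer(0),
                          none = integer(0))
  cores <- list()
  fracs <- c(`1` = es$frac1, `3` = es$frac3)
  for (e in active_epochs) {
    n_core <- round(fracs[[as.character(e)]] * nr)
    cores[[as.character(e)]] <- sort(sample.int(nr, n_core))
  }
  lat <- c(`1` = if (1 %in% active_epochs) es$t1_s else NA_real_,
           `3` = if (3 %in% active_epochs) es$t3_s else NA_real_)

  draw_amp <- function(n) {
    p$kernel$amp_sd * p$noise_sd *
      exp(stats::rnorm(n, 0, p$kernel$amp_jitter_sdlog))
  }

  ev_roi <- integer(0); ev_onset <- numeric(0); ev_amp <- numeric(0)
  ev_kind <- character(0); ev_stim <- integer(0)
  members <- list()

  if (!is.null(p$planted)) {
    npr <- p$planted$n_per_roi
    amp <- (p$planted$amplitude_sd %||% p$kernel$amp_sd) * p$noise_sd
    span <- duration - 4  # keep transients clear of the recording edges
    base_times <- 2 + (seq_len(npr) - 0.5) / npr * span
    for (i in seq_len(nr)) {
      jit <- stats::runif(npr, -0.4, 0.4)
      ev_roi <- c(ev_roi, rep.int(i, npr))
      ev_onset <- c(ev_onset, base_times + jit)
      ev_amp <- c(ev_amp, rep.int(amp, npr))
      ev_kind <- c(ev_kind, rep.int("planted", npr))
      ev_stim <- c(ev_stim, rep.int(NA_integer_, npr))
    }
  } else {
    # Spontaneous Poisson events, thinned inside the suppression windows.
    for (i in seq_len(nr)) {
      n_sp <- stats::rpois(1, rate * duration)
      if (n_sp > 0) {
        t_sp <- sort(stats::runif(n_sp, 0, duration))
        keep <- !in_suppression(t_sp) |
          (stats::runif(n_sp) < es$suppress_factor)
        t_sp <- t_sp[keep]
        if (length(t_sp) > 0) {
          ev_roi <- c(ev_roi, rep.int(i, length(t_sp)))
          ev_onset <- c(ev_onset, t_sp)
          ev_amp <- c(ev_amp, draw_amp(length(t_sp)))
          ev_kind <- c(ev_kind, rep.int("spont", length(t_sp)))
          ev_stim <- c(ev_stim, rep.int(NA_integer_, length(t_sp)))
        }
      }
    }
    # Evoked events: core members participate with probability p_repeat,
    # non-members with the leak probability; transient PEAK lands at
    # stimulus + epoch latency (+ jitter), so onsets are shifted back by the
    # kernel peak time.
    for (e in active_epochs) {
      key <- as.character(e)
      core <- cores[[key]]
      is_core <- seq_len(nr) %in% core
      p_fire <- ifelse(is_core, p_rep, p$membership$p_leak)
      for (s in seq_along(onsets)) {
        fired <- which(stats::runif(nr) < p_fire)
        members[[paste0("stim", s, "_epoch", e)]] <- fired
        if (length(fired) > 0) {
          t_ev <- onsets[s] + lat[[key]] - tp +
            stats::rnorm(length(fired), 0, es$jitter_sd_s)
          ev_roi <- c(ev_roi, fired)
          ev_onset <- c(ev_onset, t_ev)
          ev_amp <- c(ev_amp, draw_amp(length(fired)))
          ev_kind <- c(ev_kind, rep.int(paste0("epoch", e), length(fired)))
          ev_stim <- c(ev_stim, rep.int(s, length(fired)))
        }
      }
    }
  }

  # Assemble dF/F: drift + i.i.d. Gaussian noise + kernel-shaped transients
  # evaluated in continuous time at the frame centers.
  drift <- p$drift$amp * exp(-ft / p$drift$tau_s) + p$drift$slope_per_s * ft
  dff <- matrix(stats::rnorm(nr * nf, 0, p$noise_sd), nrow = nr)
  dff <- sweep(dff, 2, drift, `+`)
  if (length(ev_roi) > 0) {
    for (j in seq_along(ev_roi)) {
      rel <- ft - ev_onset[j]
      sel <- rel >= 0 & rel <= 5 * p$kernel$decay_tau_s + tp
      if (any(sel)) {
        dff[ev_roi[j], sel] <- dff[ev_roi[j], sel] +
          ev_amp[j] * transient_value(rel[sel], p$kernel$rise_tau_s,
                                      p$kernel$decay_tau_s)
      }
    }
  }
  rownames(dff) <- sprintf("roi_%03d", seq_len(nr))

  # LFP: Gaussian noise + one-sample artifact spike at each onset + a
  # negative alpha-function fEPSP after a short synaptic delay.
  n_lfp <- round(duration * p$lfp_rate_hz)
  lft <- sample_times(n_lfp, p$lfp_rate_hz)
  lfp <- stats::rnorm(n_lfp, 0, p$fepsp$noise_sd_mV)
  fp <- p$fepsp
  for (s in seq_along(onsets)) {
    ai <- floor(onsets[s] * p$lfp_rate_hz) + 1L
    if (ai >= 1 && ai <= n_lfp) lfp[ai] <- lfp[ai] + fp$artifact_mV
    t0 <- onsets[s] + fp$delay_s
    idx <- which(lft >= t0 & lft <= t0 + 10 * fp$tau_s)
    if (length(idx) > 0) {
      tt <- (lft[idx] - t0) / fp$tau_s
      lfp[idx] <- lfp[idx] - fp$amp_mV * tt * exp(1 - tt)
    }
  }

  stim_tab <- if (length(onsets) > 0) {
    data.frame(onset_s = onsets,
               intensity_mA = rep(NA_real_, length(onsets)))
  } else NULL

  bundle <- session_bundle(
    dff, frame_rate_hz = p$frame_rate_hz,
    lfp = list(samples = lfp, rate_hz = p$lfp_rate_hz),
    stimulus_table = stim_tab,
    metadata = list(session_id = sprintf("synthetic_seed%d", p$seed),
                    group = gp$label, session_type = "baseline",
                    synthetic = TRUE)
  )
  truth <- list(
    events = data.frame(roi = ev_roi, onset_s = ev_onset,
                        amplitude = ev_amp, kind = ev_kind,
                        stimulus = ev_stim),
    epoch_members = members,
    cores = cores,
    latencies = list(t1_s = if ("1" %in% names(cores)) es$t1_s else NA_real_,
                     t2_s = if (!is.null(suppress_win)) es$t2_s else NA_real_,
                     t3_s = if ("3" %in% names(cores)) es$t3_s else NA_real_),
    suppression_windows = suppress_win,
    fepsp_amp_mV = rep(fp$amp_mV, length(onsets)),
    onsets_s = onsets,
    params = p
  )
  list(bundle = bundle, truth = truth)
}

#' Generate a two-group cohort of synthetic sessions
#'
#' Sham-like sessions use the base parameters; HFHI-like sessions apply the
#' HFHI [group_profile()] (elevated spontaneous rate, reduced membership
#' reliability). Per-session seeds are derived deterministically from the
#' master seed.
#'
#' @param n_sham,n_hfhi sessions per group (each >= 1).
#' @param base_params a [synthetic_params()] shared by both groups.
#' @param seed master seed.
#' @param hfhi_profile [group_profile()] for the HFHI-like group.
#' @return list of `list(bundle, truth)` with a `group` attribute vector.
#' @export
generate_cohort <- function(n_sham, n_hfhi,
                            base_params = synthetic_params(),
                            seed = 1L,
                            hfhi_profile = group_profile("hfhi")) {
  if (!is_scalar_num(n_sham) || n_sham < 1) {
    fail_validation("n_sham", "must be >= 1")
  }
  if (!is_scalar_num(n_hfhi) || n_hfhi < 1) {
    fail_validation("n_hfhi", "must be >= 1")
  }
  n <- n_sham + n_hfhi
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  groups <- c(rep("sham", n_sham), rep("hfhi", n_hfhi))
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- base_params
    pi$seed <- seeds[i]
    pi$group_profile <- if (groups[i] == "sham") group_profile("sham")
                        else hfhi_profile
    sessions[[i]] <- generate_session(pi)
  }
  attr(sessions, "group") <- groups
  sessions
}
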