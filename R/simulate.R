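#' Generative model configuration for synthetic eyelid traces
#'
#' Parameters of the generative mixture model used to emulate the
#' experiment. On every CS trial the animal produces a conditioned response
#' (CR) with a session-dependent probability
#' `p_s = p_max * (1 - exp(-s / tau_sessions))`; when a CR occurs its
#' amplitude is drawn from a truncated normal whose mean follows the same
#' saturating growth, and its time course is a smooth monotone bell rising
#' from an onset drawn around `cr_onset_mean_ms` to a peak near the expected
#' US time. US delivery always evokes a reflex blink (UR) whose raw peak
#' voltage sets the normalization scale. Traces also carry Gaussian sensor
#' noise, slow baseline drift, and occasional negative-going photic eyelid
#' openings.
#'
#' During extinction the true response probability decays as
#' `p_end * exp(-s / tau_extinction)`; during reacquisition it regrows
#' toward `p_max` with time constant `tau_reacquisition` (faster than
#' acquisition: savings).
#'
#' @param sampling_rate_hz Digitization rate of the simulated sensor.
#' @param trace_duration_ms Trial record length.
#' @param cs_onset_ms CS onset time within the record (leaves a pre-CS
#'   baseline window).
#' @param noise_sigma Gaussian sensor noise SD, in UR-normalized units.
#' @param drift_amplitude,drift_timescale_s Slow baseline drift: SD of the
#'   smoothed random walk (normalized units) and its knot spacing (s).
#' @param p_max,tau_sessions Asymptote and session time constant of the
#'   acquisition learning curve for response probability.
#' @param tau_extinction,tau_reacquisition Session time constants of the
#'   extinction decay and reacquisition regrowth of probability.
#' @param amp_max,amp_tau_sessions,amp_sd Asymptote, growth time constant and
#'   trial-to-trial SD of CR amplitude (normalized units; truncated at 0).
#' @param cr_onset_mean_ms,cr_onset_sd_ms CR onset latency distribution (ms
#'   from CS onset).
#' @param cr_peak_jitter_ms SD of the CR peak time around the US onset.
#' @param cr_rise_10_90_ms Target 10-90% rise time of the CR (ms); `NA`
#'   means 60% of the onset-to-peak span. Capped per trial at 90% of the
#'   span so the waveform stays monotone.
#' @param cr_decay_ms Post-peak decay width on unpaired CS trials; `NA`
#'   (default) mirrors the rise for a symmetric bell.
#' @param ur_latency_mean_ms,ur_latency_sd_ms UR onset latency after US.
#' @param ur_rise_ms,ur_decay_ms UR linear rise duration and exponential
#'   decay constant.
#' @param ur_peak_volts Raw UR peak (volts above baseline); the sensor gain.
#' @param baseline_volts Raw baseline offset (volts).
#' @param opening_prob Per-CS-trial probability of a negative photic eyelid
#'   opening.
#' @param opening_depth Depth of the opening (normalized units, positive
#'   number; the deflection is negative-going).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate_hz = 1000,
                              trace_duration_ms = 2500,
                              cs_onset_ms = 1000,
                              noise_sigma = 0.02,
                              drift_amplitude = 0.01,
                              drift_timescale_s = 1,
                              p_max = 0.55,
                              tau_sessions = 4,
                              tau_extinction = 1.2,
                              tau_reacquisition = 1.2,
                              amp_max = 0.45,
                              amp_tau_sessions = 4,
                              amp_sd = 0.1,
                              cr_onset_mean_ms = 145,
                              cr_onset_sd_ms = 10,
                              cr_peak_jitter_ms = 5,
                              cr_rise_10_90_ms = NA_real_,
                              cr_decay_ms = NA_real_,
                              ur_latency_mean_ms = 30,
                              ur_latency_sd_ms = 5,
                              ur_rise_ms = 65,
                              ur_decay_ms = 150,
                              ur_peak_volts = 1,
                              baseline_volts = 0.2,
                              opening_prob = 0.1,
                              opening_depth = 0.12) {
  cfg <- as.list(environment())
  vals <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(!is.finite(vals) & !is.na(vals)))
    stopf("simulation_config: non-finite parameter value")
  if (p_max < 0 || p_max > 1) stopf("p_max must lie in [0, 1]")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (sampling_rate_hz <= 0) stopf("sampling_rate_hz must be positive")
  if (tau_sessions <= 0) stopf("tau_sessions must be positive")
  structure(cfg, class = "simulation_config")
}

#' True (generative) learning state for a session
#'
#' Closed-form per-session response probability and CR amplitude mean under
#' the saturating learning model. Acquisition: `p_s = p_max (1 - e^{-s/tau})`
#' (non-decreasing in `s`). Extinction decays from the end-of-acquisition
#' level; reacquisition regrows toward `p_max` with its own, faster time
#' constant (savings). Amplitude follows the same growth during acquisition
#' and holds its end-of-acquisition mean afterwards.
#'
#' @param cfg A [simulation_config()].
#' @param protocol A [protocol_config()] (supplies phase lengths).
#' @param phase One of `"acquisition"`, `"extinction"`, `"reacquisition"`.
#' @param session Session index within the phase (1-based).
#' @return A list with `p` (true response probability) and `amp_mean`
#'   (true CR amplitude mean).
#' @export
true_session_state <- function(cfg, protocol = protocol_config(),
                               phase = "acquisition", session = 1L) {
  phase <- match.arg(phase, c("acquisition", "extinction", "reacquisition"))
  s_acq <- protocol$n_acquisition_sessions
  p_acq_end <- cfg$p_max * (1 - exp(-s_acq / cfg$tau_sessions))
  amp_end <- cfg$amp_max * (1 - exp(-s_acq / cfg$amp_tau_sessions))
  if (phase == "acquisition") {
    list(p = cfg$p_max * (1 - exp(-session / cfg$tau_sessions)),
         amp_mean = cfg$amp_max * (1 - exp(-session / cfg$amp_tau_sessions)))
  } else if (phase == "extinction") {
    list(p = p_acq_end * exp(-session / cfg$tau_extinction),
         amp_mean = amp_end)
  } else {
    p_ext_end <- p_acq_end *
      exp(-protocol$n_extinction_sessions / cfg$tau_extinction)
    list(p = cfg$p_max - (cfg$p_max - p_ext_end) *
           exp(-session / cfg$tau_reacquisition),
         amp_mean = amp_end)
  }
}

# CR waveform: monotone Hermite spline through
# (onset, 0), (t10, 0.1), (t90, 0.9), (peak, 1). Parameterized directly by
# onset, peak time and the 10-90% rise so the generated timing statistics
# are known exactly. The fall is the time-mirror of the rise (a symmetric
# bell) unless `decay_ms` is given, in which case a raised cosine of that
# width is used. Returns values at `t_ms`.
cr_waveform <- function(t_ms, onset_ms, peak_ms, rise_10_90_ms = NA_real_,
                        decay_ms = NA_real_) {
  span <- peak_ms - onset_ms
  if (span <= 0) return(numeric(length(t_ms)))
  rise <- if (is.na(rise_10_90_ms)) 0.6 * span else
    min(rise_10_90_ms, 0.9 * span)
  slack <- span - rise
  t10 <- onset_ms + slack / 3
  t90 <- t10 + rise
  knots_x <- c(onset_ms - span, onset_ms, t10, (t10 + t90) / 2, t90, peak_ms)
  knots_y <- c(0, 0, 0.1, 0.5, 0.9, 1)
  f <- stats::splinefun(knots_x, knots_y, method = "hyman")
  y <- numeric(length(t_ms))
  up <- t_ms >= onset_ms & t_ms <= peak_ms
  y[up] <- pmin(1, pmax(0, f(t_ms[up])))
  if (is.na(decay_ms)) {
    post <- t_ms > peak_ms & t_ms < peak_ms + span
    y[post] <- pmin(1, pmax(0, f(2 * peak_ms - t_ms[post])))
  } else {
    post <- t_ms > peak_ms & t_ms <= peak_ms + decay_ms
    y[post] <- 0.5 * (1 + cos(pi * (t_ms[post] - peak_ms) / decay_ms))
  }
  y
}

# UR waveform in normalized units (peak 1): latency, linear rise,
# exponential decay.
ur_waveform <- function(t_ms, us_onset_ms, latency_ms, rise_ms, decay_ms) {
  t0 <- us_onset_ms + latency_ms
  y <- numeric(length(t_ms))
  ris <- t_ms >= t0 & t_ms < t0 + rise_ms
  y[ris] <- (t_ms[ris] - t0) / rise_ms
  dec <- t_ms >= t0 + rise_ms
  y[dec] <- exp(-(t_ms[dec] - t0 - rise_ms) / decay_ms)
  y
}

# Raised-cosine negative deflection (photic eyelid opening).
opening_waveform <- function(t_ms, onset_ms, depth, width_ms = 120) {
  y <- numeric(length(t_ms))
  inw <- t_ms >= onset_ms & t_ms <= onset_ms + width_ms
  y[inw] <- -depth * 0.5 * (1 - cos(2 * pi * (t_ms[inw] - onset_ms) / width_ms))
  y
}

# Slow baseline drift: Gaussian knots every drift_timescale_s seconds,
# linearly interpolated.
drift_process <- function(n, fs_hz, amplitude, timescale_s) {
  if (amplitude <= 0) return(numeric(n))
  step <- max(2L, round(timescale_s * fs_hz))
  knots <- stats::rnorm(ceiling(n / step) + 2L, 0, amplitude)
  stats::approx(x = (seq_along(knots) - 1L) * step, y = knots,
                xout = seq_len(n) - 1L, rule = 2)$y
}

#' Simulate one eyelid-position trace
#'
#' Draws one trial from the generative model: baseline drift + Gaussian
#' sensor noise, plus a UR on US trials, plus (on CS trials, with
#' probability `state$p`) a bell-shaped CR whose onset is sampled from the
#' timing distribution and whose peak falls near the expected US time, plus
#' an occasional negative photic opening with onset 70-250 ms after the CS.
#' Raw samples are in volts (`baseline_volts` offset, UR peak =
#' `ur_peak_volts` above baseline). Uses the current RNG state.
#'
#' @param plan One-row trial plan (see [build_acquisition_schedule()]), or a
#'   list with elements `kind`, `phase`, `session`, `block`, `trial`.
#' @param state Session state: list with `p` and `amp_mean` (see
#'   [true_session_state()]).
#' @param cfg A [simulation_config()].
#' @param protocol A [protocol_config()].
#' @return A list with `samples` (raw volts), `time_ms`, `markers`
#'   (`cs_onset`, `cs_offset`, `us_onset`, `us_offset`, ms from trace start;
#'   NA where the stimulus is absent) and `ground_truth`
#'   (`is_response`, `true_amplitude`, `true_onset_ms`).
#' @export
simulate_trace <- function(plan, state, cfg = simulation_config(),
                           protocol = protocol_config()) {
  kind <- as.character(plan$kind)
  fs <- cfg$sampling_rate_hz
  n <- round(cfg$trace_duration_ms * fs / 1000)
  time_ms <- (seq_len(n) - 1L) * 1000 / fs

  has_cs <- kind %in% c("paired", "cs_only")
  has_us <- kind %in% c("paired", "us_only")
  cs_on <- if (has_cs) cfg$cs_onset_ms else NA_real_
  # us_only trials are aligned so the US falls at the usual post-baseline
  # position
  us_on <- if (has_us) cfg$cs_onset_ms + protocol$us_onset_ms else NA_real_

  x <- drift_process(n, fs, cfg$drift_amplitude, cfg$drift_timescale_s) +
    stats::rnorm(n, 0, cfg$noise_sigma)

  is_response <- FALSE
  true_amplitude <- NA_real_
  true_onset <- NA_real_
  if (has_cs && stats::runif(1) < state$p) {
    is_response <- TRUE
    amp <- -1
    while (amp < 0) amp <- stats::rnorm(1, state$amp_mean, cfg$amp_sd)
    onset <- stats::rnorm(1, cfg$cr_onset_mean_ms, cfg$cr_onset_sd_ms)
    # CRs peak at the expected US time unless the configured rise needs a
    # longer onset-to-peak span (slow-rise phenotypes peak later)
    peak_target <- protocol$us_onset_ms
    if (!is.na(cfg$cr_rise_10_90_ms))
      peak_target <- max(peak_target,
                         cfg$cr_onset_mean_ms + cfg$cr_rise_10_90_ms / 0.9)
    peak <- peak_target + stats::rnorm(1, 0, cfg$cr_peak_jitter_ms)
    onset <- min(onset, peak - 20)  # keep the bell well-formed
    true_amplitude <- amp
    true_onset <- onset
    x <- x + amp * cr_waveform(time_ms - cs_on, onset, peak,
                               cfg$cr_rise_10_90_ms, cfg$cr_decay_ms)
  }
  if (has_us) {
    lat <- max(5, stats::rnorm(1, cfg$ur_latency_mean_ms, cfg$ur_latency_sd_ms))
    x <- x + ur_waveform(time_ms, us_on, lat, cfg$ur_rise_ms, cfg$ur_decay_ms)
  }
  if (has_cs && stats::runif(1) < cfg$opening_prob) {
    x <- x + opening_waveform(time_ms - cs_on,
                              stats::runif(1, 70, 250), cfg$opening_depth)
  }

  samples <- cfg$baseline_volts + cfg$ur_peak_volts * x
  list(
    samples = samples,
    time_ms = time_ms,
    markers = list(
      cs_onset = cs_on,
      cs_offset = if (has_cs) cs_on + protocol$cs_duration_ms else NA_real_,
      us_onset = us_on,
      us_offset = if (has_us) us_on + protocol$us_duration_ms else NA_real_
    ),
    ground_truth = list(is_response = is_response,
                        true_amplitude = true_amplitude,
                        true_onset_ms = true_onset)
  )
}

#' Cohort specification
#'
#' @param groups A list of group descriptions; each element is a list with
#'   `label`, `n_subjects`, and optionally `config` (a list of
#'   [simulation_config()] overrides, e.g. `list(p_max = 0.35)`) and
#'   `age_mean_days`/`age_sd_days` (subject ages; default 90 +/- 15 d).
#' @param protocol Shared [protocol_config()].
#' @param config Baseline [simulation_config()] shared by all groups.
#' @param master_seed Integer; all subject seeds derive deterministically
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, protocol = protocol_config(),
                        config = simulation_config(), master_seed = 1L) {
  if (!length(groups)) stopf("cohort_spec: at least one group is required")
  for (g in groups) {
    if (is.null(g$label) || is.null(g$n_subjects) || g$n_subjects < 1)
      stopf("each group needs a label and n_subjects >= 1")
  }
  structure(list(groups = groups, protocol = protocol, config = config,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

apply_overrides <- function(cfg, overrides) {
  if (is.null(overrides) || !length(overrides)) return(cfg)
  do.call(simulation_config, utils::modifyList(unclass(cfg), overrides))
}

#' Simulate a full cohort of eyelid traces
#'
#' Generates, for each subject, the configured acquisition, extinction and
#' reacquisition sessions (12/4/3 by default), with per-trial ground-truth
#' labels and a per-session ground-truth table of the true probability and
#' amplitude. Fully reproducible from `spec$master_seed`.
#'
#' Traces are stored in a dense trials x samples matrix; with the full
#' protocol (220 trials/session) a subject-phase block is large, so tests
#' and examples typically reduce `blocks_per_session` or the session counts
#' through the protocol configuration.
#'
#' @param spec A [cohort_spec()].
#' @param phases Phases to simulate, in order.
#' @return An object of class `eyeblink_cohort`: a list with
#'   `trials` (tibble: subject, group, age_days, phase, session, block,
#'   trial, kind, cs/us marker times, iti_extensions, ground-truth columns),
#'   `traces` (matrix, one row per trial, raw volts), `time_ms`,
#'   `ground_truth` (per subject x session true `p` and `amp_mean`),
#'   `protocol` and `config`.
#' @export
simulate_cohort <- function(spec,
                            phases = c("acquisition", "extinction",
                                       "reacquisition")) {
  stopifnot(inherits(spec, "cohort_spec"))
  phases <- match.arg(phases, c("acquisition", "extinction", "reacquisition"),
                      several.ok = TRUE)
  protocol <- spec$protocol
  trial_rows <- list()
  trace_rows <- list()
  gt_rows <- list()
  subj_counter <- 0L
  for (gi in seq_along(spec$groups)) {
    grp <- spec$groups[[gi]]
    gcfg <- apply_overrides(spec$config, grp$config)
    for (si in seq_len(grp$n_subjects)) {
      subj_counter <- subj_counter + 1L
      subject_id <- sprintf("%s_%02d", grp$label, si)
      age <- round(withr::with_seed(
        derive_seed(spec$master_seed, gi, si, 9999L),
        stats::rnorm(1, grp$age_mean_days %||% 90, grp$age_sd_days %||% 15)))
      for (phase in phases) {
        n_sess <- switch(phase,
                         acquisition = protocol$n_acquisition_sessions,
                         extinction = protocol$n_extinction_sessions,
                         reacquisition = protocol$n_reacquisition_sessions)
        for (sess in seq_len(n_sess)) {
          seed <- derive_seed(spec$master_seed, gi, si,
                              match(phase, phase_levels), sess)
          state <- true_session_state(gcfg, protocol, phase, sess)
          out <- withr::with_seed(seed, {
            sched <- if (phase == "extinction")
              build_extinction_schedule(protocol, seed = seed,
                                        session_index = sess)
            else
              build_acquisition_schedule(protocol, seed = seed,
                                         session_index = sess, phase = phase)
            simulate_session_traces(sched, state, gcfg, protocol)
          })
          sched <- out$sched
          sched$subject <- subject_id
          sched$group <- grp$label
          sched$age_days <- age
          trial_rows[[length(trial_rows) + 1L]] <- sched
          trace_rows[[length(trace_rows) + 1L]] <- out$traces
          gt_rows[[length(gt_rows) + 1L]] <- tibble::tibble(
            subject = subject_id, group = grp$label, phase = phase,
            session = sess, true_p = state$p, true_amp_mean = state$amp_mean)
        }
      }
    }
  }
  trials <- dplyr::bind_rows(trial_rows)
  trials <- dplyr::relocate(trials, "subject", "group", "age_days")
  structure(list(
    trials = trials,
    traces = do.call(rbind, trace_rows),
    time_ms = (seq_len(ncol(trace_rows[[1]])) - 1L) *
      1000 / spec$config$sampling_rate_hz,
    ground_truth = dplyr::bind_rows(gt_rows),
    protocol = protocol,
    config = spec$config
  ), class = "eyeblink_cohort")
}

# Simulate all traces of one session; returns the schedule augmented with
# marker times and ground truth plus the trace matrix. Assumes the caller
# has seeded the RNG.
simulate_session_traces <- function(sched, state, cfg, protocol) {
  n <- nrow(sched)
  n_samp <- round(cfg$trace_duration_ms * cfg$sampling_rate_hz / 1000)
  traces <- matrix(NA_real_, n, n_samp)
  cs_on <- us_on <- gt_amp <- gt_onset <- rep(NA_real_, n)
  gt_resp <- logical(n)
  iti_ext <- integer(n)
  for (i in seq_len(n)) {
    tr <- simulate_trace(sched[i, ], state, cfg, protocol)
    traces[i, ] <- tr$samples
    cs_on[i] <- tr$markers$cs_onset
    us_on[i] <- tr$markers$us_onset
    gt_resp[i] <- tr$ground_truth$is_response
    gt_amp[i] <- tr$ground_truth$true_amplitude
    gt_onset[i] <- tr$ground_truth$true_onset_ms
  }
  sched$cs_onset_ms <- cs_on
  sched$us_onset_ms <- us_on
  sched$gt_is_response <- gt_resp
  sched$gt_amplitude <- gt_amp
  sched$gt_onset_ms <- gt_onset
  sched$iti_extensions <- iti_ext
  list(sched = sched, traces = traces)
}

#' Simulate per-session peak-amplitude samples (amplitude-level fast path)
#'
#' Draws the session's distribution of per-trial window peaks directly from
#' the generative two-component mixture the decomposition models: with
#' probability `p` a trial carries a response with amplitude
#' `Normal(amp_mean, amp_sd)` truncated at 0 (negative draws reflected)
#' plus sensor noise, otherwise the
#' peak is noise alone, `Normal(0, noise_sigma)`. This is the natural scale
#' for calibration and power studies where simulating every raw trace would
#' be wasteful; the trace-level generator is exercised by the timing and
#' pipeline analyses.
#'
#' @param n_trials Trials in the session.
#' @param p True response probability.
#' @param amp_mean,amp_sd Response-amplitude component (normalized units).
#' @param noise_sigma Non-response noise SD.
#' @return A list with `values` (length `n_trials`) and `is_response`
#'   (ground-truth labels).
#' @export
simulate_session_peaks <- function(n_trials, p, amp_mean = 0.4,
                                   amp_sd = 0.05, noise_sigma = 0.02) {
  resp <- stats::runif(n_trials) < p
  amps <- abs(stats::rnorm(n_trials, amp_mean, amp_sd))
  vals <- stats::rnorm(n_trials, 0, noise_sigma) + ifelse(resp, amps, 0)
  list(values = vals, is_response = resp)
}
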