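#' Score an unpaired CS trial as CR / none / excluded
#'
#' A normalized unpaired-CS trace scores as a CR when it exceeds 0.15
#' between 100 and 400 ms after CS onset while remaining below 0.05 between
#' 0 and 99 ms; trials breaking the early-quiet rule are excluded outright.
#' All comparisons are strict.
#'
#' @param samples Normalized trace (smoothing is the caller's choice; the
#'   thresholds are amplitude-scale decisions, not slope decisions).
#' @param time_ms Sample times.
#' @param cs_onset_ms CS onset (ms from trace start).
#' @param kind Trial kind; must be `"cs_only"`.
#' @param cr_threshold,pre_threshold Thresholds (defaults 0.15 / 0.05).
#' @param window_ms CR search window (default `c(100, 400)`).
#' @return One of `"cr"`, `"none"`, `"excluded"`.
#' @export
classify_cr <- function(samples, time_ms, cs_onset_ms, kind = "cs_only",
                        cr_threshold = 0.15, pre_threshold = 0.05,
                        window_ms = c(100, 400)) {
  if (!identical(as.character(kind), "cs_only"))
    stopf("classify_cr applies to unpaired CS trials only")
  if (early_movement_flag(samples, time_ms, cs_onset_ms, pre_threshold))
    return("excluded")
  peak <- max(samples[window_mask(time_ms, cs_onset_ms, window_ms[1],
                                  window_ms[2])])
  if (peak > cr_threshold) "cr" else "none"
}

#' Timing metrics of a conditioned response
#'
#' On a smoothed unpaired-CS trace scored as a CR: the peak latency is the
#' argmax within the CR window (ties resolved to the earliest sample); the
#' onset latency is the change in concavity of the eyeblink, operationalized
#' as the latest time before the 10%-of-peak crossing at which the centered
#' second difference turns from <= 0 to > 0 (falling back to the 5%-of-peak
#' crossing if no concavity change is found, flagged in the output); the
#' 10-90% rise time is the time between the first crossings of 10% and 90%
#' of the peak amplitude after onset, with sub-sample linear interpolation.
#'
#' @param samples Normalized trace; smoothed internally unless
#'   `smooth_width_ms` is 0.
#' @param time_ms Sample times.
#' @param cs_onset_ms CS onset.
#' @param window_ms CR window (default `c(100, 400)` ms after CS onset).
#' @param smooth_width_ms Zero-phase moving-average width applied first.
#' @return A list of class `cr_metrics`: `is_cr`, `onset_latency_ms`,
#'   `rise_time_10_90_ms`, `peak_latency_ms`, `peak_amplitude`,
#'   `onset_fallback` (TRUE when the 5% fallback was used). Latencies are
#'   in ms from CS onset.
#' @export
cr_timing <- function(samples, time_ms, cs_onset_ms,
                      window_ms = c(100, 400), smooth_width_ms = 10) {
  fs <- 1000 / (time_ms[2] - time_ms[1])
  x <- if (smooth_width_ms > 0) smooth_trace(samples, fs, smooth_width_ms)
       else samples
  t_rel <- time_ms - cs_onset_ms
  win <- which(t_rel >= window_ms[1] & t_rel <= window_ms[2])
  pk_i <- win[which.max(x[win])]
  peak_amp <- x[pk_i]
  peak_lat <- t_rel[pk_i]

  det <- detect_onset(x, t_rel, pk_i, peak_amp, search_from_ms = 0)
  onset <- det$onset_ms
  # 10/90% crossings after onset
  from <- which(t_rel >= onset)[1]
  t10 <- first_crossing_ms(x, t_rel, 0.1 * peak_amp, from)
  t90 <- first_crossing_ms(x, t_rel, 0.9 * peak_amp, from)
  rise <- if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10

  structure(list(is_cr = TRUE, onset_latency_ms = onset,
                 rise_time_10_90_ms = rise, peak_latency_ms = peak_lat,
                 peak_amplitude = peak_amp, onset_fallback = det$fallback),
            class = "cr_metrics")
}

# Onset detector shared by CR and UR timing: latest sign change (<=0 to >0)
# of the smoothed centered second difference of the trace before the
# 10%-of-peak crossing; falls back to the 5% crossing when no concavity
# change exists in the search range. The second difference is itself
# lightly smoothed so that sensor-noise flickers do not masquerade as
# concavity changes.
detect_onset <- function(x, t_rel, pk_i, peak_amp, search_from_ms = 0) {
  start_i <- which(t_rel >= search_from_ms)[1]
  c10 <- first_crossing_ms(x, t_rel, 0.1 * peak_amp, start_i)
  if (is.na(c10)) c10 <- t_rel[pk_i]
  c10_i <- max(which(t_rel <= c10))
  d2 <- c(0, diff(x, differences = 2), 0)  # centered second difference
  if (length(d2) > 3) d2 <- smooth_trace(d2, width_samples = 3)
  lo <- max(start_i + 1L, 2L)
  hi <- min(c10_i, length(x) - 1L)
  onset <- NA_real_
  if (hi > lo) {
    sign_change <- which(d2[lo:hi] > 0 & d2[(lo - 1L):(hi - 1L)] <= 0)
    if (length(sign_change)) onset <- t_rel[lo + sign_change[length(sign_change)] - 1L]
  }
  if (!is.na(onset)) return(list(onset_ms = onset, fallback = FALSE))
  c5 <- first_crossing_ms(x, t_rel, 0.05 * peak_amp, start_i)
  list(onset_ms = if (is.na(c5)) t_rel[pk_i] else c5, fallback = TRUE)
}

#' Timing and kinematics of the unconditioned reflex blink
#'
#' On a normalized trace containing a US: the UR onset latency (same
#' concavity detector as [cr_timing()], measured from US onset and searched
#' within `latency_limit_ms` = 75 ms), the 10-90% rise time of the UR peak,
#' the peak amplitude (1 by construction on the trial that defined the
#' normalization), and the peak velocity (maximum first difference per ms
#' within the UR epoch).
#'
#' @param samples Normalized trace.
#' @param time_ms Sample times.
#' @param us_onset_ms US onset (ms from trace start).
#' @param latency_limit_ms Onset must occur within this window after the US.
#' @param epoch_ms UR measurement epoch after US onset.
#' @param smooth_width_ms Smoothing width.
#' @return A list of class `ur_metrics`: `latency_ms`, `rise_time_ms`,
#'   `peak_amplitude`, `peak_latency_ms`, `peak_velocity` (normalized
#'   units/ms). Errors if no deflection above 10% of the UR scale occurs
#'   within the latency window.
#' @export
ur_metrics <- function(samples, time_ms, us_onset_ms,
                       latency_limit_ms = 75, epoch_ms = 200,
                       smooth_width_ms = 10) {
  fs <- 1000 / (time_ms[2] - time_ms[1])
  x <- if (smooth_width_ms > 0) smooth_trace(samples, fs, smooth_width_ms)
       else samples
  t_rel <- time_ms - us_onset_ms
  epoch <- which(t_rel >= 0 & t_rel <= epoch_ms)
  pk_i <- epoch[which.max(x[epoch])]
  peak_amp <- x[pk_i]
  lat_win <- which(t_rel >= 0 & t_rel <= latency_limit_ms)
  if (!any(x[lat_win] > 0.1 * peak_amp) || peak_amp <= 0)
    stopf("no UR detected within %g ms of US onset", latency_limit_ms)

  det <- detect_onset(x, t_rel, pk_i, peak_amp, search_from_ms = 0)
  latency <- min(det$onset_ms, latency_limit_ms)
  from <- which(t_rel >= latency)[1]
  t10 <- first_crossing_ms(x, t_rel, 0.1 * peak_amp, from)
  t90 <- first_crossing_ms(x, t_rel, 0.9 * peak_amp, from)
  vel <- max(diff(x[epoch])) * fs / 1000

  structure(list(latency_ms = latency,
                 rise_time_ms = if (is.na(t10) || is.na(t90)) NA_real_
                                else t90 - t10,
                 peak_amplitude = peak_amp,
                 peak_latency_ms = t_rel[pk_i],
                 peak_velocity = vel),
            class = "ur_metrics")
}

#' Detect a photic eyelid opening
#'
#' Non-associative negative deflection to the light CS: detected when the
#' normalized trace dips more than 5% below baseline between 70 and 250 ms
#' after CS onset — but not before — and only while the animal has not yet
#' begun to produce CRs in the session (`session_has_crs` gate).
#'
#' @param samples Normalized trace.
#' @param time_ms Sample times.
#' @param cs_onset_ms CS onset.
#' @param session_has_crs TRUE when a CR-scored trial occurred earlier in
#'   the session (suppresses detection).
#' @param depth_threshold Detection threshold (default 0.05 below baseline).
#' @param window_ms Detection window (default `c(70, 250)`).
#' @return A list of class `opening_event`: `detected`, `depth`
#'   (normalized, negative) and `time_ms` (ms from CS onset), the latter
#'   two NA when not detected.
#' @export
detect_photic_opening <- function(samples, time_ms, cs_onset_ms,
                                  session_has_crs = FALSE,
                                  depth_threshold = 0.05,
                                  window_ms = c(70, 250)) {
  t_rel <- time_ms - cs_onset_ms
  inw <- which(t_rel >= window_ms[1] & t_rel <= window_ms[2])
  pre <- which(t_rel >= 0 & t_rel < window_ms[1])
  min_i <- inw[which.min(samples[inw])]
  depth <- samples[min_i]
  detected <- !session_has_crs &&
    depth < -depth_threshold &&
    (!length(pre) || min(samples[pre]) >= -depth_threshold)
  structure(list(detected = detected,
                 depth = if (detected) depth else NA_real_,
                 time_ms = if (detected) t_rel[min_i] else NA_real_),
            class = "opening_event")
}

#' Per-trial response metrics for a normalized cohort
#'
#' Runs [classify_cr()] + [cr_timing()] on unpaired CS trials,
#' [ur_metrics()] on US trials, and [detect_photic_opening()] on CS trials
#' (gated per session by whether any CR has been scored earlier in that
#' session), returning one tidy row per analyzed trial.
#'
#' @param cohort A cohort from [normalize_cohort()].
#' @param smooth_width_ms Smoothing width for the timing detectors.
#' @return A tibble with columns `subject`, `group`, `phase`, `session`,
#'   `trial`, `kind`, `status`, `onset_latency_ms`, `rise_time_10_90_ms`,
#'   `peak_latency_ms`, `peak_amplitude`, `ur_latency_ms`,
#'   `ur_rise_time_ms`, `ur_peak_velocity`, `opening_detected`,
#'   `opening_depth`, `opening_time_ms`.
#' @export
trial_response_metrics <- function(cohort, smooth_width_ms = 10) {
  stopifnot(!is.null(cohort$norm))
  trials <- cohort$trials
  time_ms <- cohort$time_ms
  n <- nrow(trials)
  status <- rep(NA_character_, n)
  onset <- rise <- plat <- pamp <- rep(NA_real_, n)
  ur_lat <- ur_rise <- ur_vel <- rep(NA_real_, n)
  op_det <- rep(NA, n)
  op_depth <- op_time <- rep(NA_real_, n)

  key <- paste(trials$subject, trials$phase, trials$session)
  for (kk in unique(key)) {
    rows <- which(key == kk)
    has_cr_yet <- FALSE
    for (i in rows) {
      if (!trials$valid[i]) next
      kind <- as.character(trials$kind[i])
      x <- cohort$norm[i, ]
      if (kind == "cs_only") {
        st <- classify_cr(x, time_ms, trials$cs_onset_ms[i])
        status[i] <- st
        if (st == "cr") {
          m <- cr_timing(x, time_ms, trials$cs_onset_ms[i],
                         smooth_width_ms = smooth_width_ms)
          onset[i] <- m$onset_latency_ms
          rise[i] <- m$rise_time_10_90_ms
          plat[i] <- m$peak_latency_ms
          pamp[i] <- m$peak_amplitude
        }
      }
      if (kind %in% c("paired", "us_only")) {
        m <- tryCatch(
          ur_metrics(x, time_ms, trials$us_onset_ms[i],
                     smooth_width_ms = smooth_width_ms),
          error = function(e) NULL)
        if (!is.null(m)) {
          ur_lat[i] <- m$latency_ms
          ur_rise[i] <- m$rise_time_ms
          ur_vel[i] <- m$peak_velocity
        }
      }
      if (kind %in% c("paired", "cs_only")) {
        op <- detect_photic_opening(x, time_ms, trials$cs_onset_ms[i],
                                    session_has_crs = has_cr_yet)
        op_det[i] <- op$detected
        op_depth[i] <- op$depth
        op_time[i] <- op$time_ms
      }
      if (identical(status[i], "cr")) has_cr_yet <- TRUE
    }
  }
  tibble::tibble(
    subject = trials$subject, group = trials$group, phase = trials$phase,
    session = trials$session, trial = trials$trial, kind = trials$kind,
    status = status, onset_latency_ms = onset, rise_time_10_90_ms = rise,
    peak_latency_ms = plat, peak_amplitude = pamp, ur_latency_ms = ur_lat,
    ur_rise_time_ms = ur_rise, ur_peak_velocity = ur_vel,
    opening_detected = op_det, opening_depth = op_depth,
    opening_time_ms = op_time)
}
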