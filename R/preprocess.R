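#' Baseline stability criterion
#'
#' The adaptive intertrial-interval rule: a trial may start only when every
#' sample of the eyelid signal in the 1 s before the planned CS stays within
#' an allowed band, typically +/-10% of the average UR amplitude; each
#' violation postpones the trial by 1 s.
#'
#' @param window_s Length of the pre-CS window (s).
#' @param allowed_range Half-width of the band, as a fraction of the average
#'   UR amplitude.
#' @param iti_extension_s Postponement added per unstable check (s).
#' @return An object of class `baseline_criterion`.
#' @export
baseline_criterion <- function(window_s = 1, allowed_range = 0.10,
                               iti_extension_s = 1) {
  if (allowed_range <= 0) stopf("allowed_range must be positive")
  if (window_s <= 0) stopf("window_s must be positive")
  structure(list(window_s = window_s, allowed_range = allowed_range,
                 iti_extension_s = iti_extension_s),
            class = "baseline_criterion")
}

#' Check pre-CS baseline stability
#'
#' Judges the final `window_s` seconds of `segment` (the recording leading
#' up to the planned CS): the baseline is stable when every sample lies
#' within `allowed_range * ur_average` of the window median.
#' `extensions_needed` reconstructs the adaptive-ITI loop from the same
#' segment: it counts how many consecutive windows, each shifted back by one
#' `iti_extension_s` step from the final window, fail the criterion — i.e.
#' how many 1 s postponements immediately preceded the moment the final
#' window was reached (0 when all earlier visible windows were also quiet).
#'
#' @param segment Numeric vector of raw samples ending at the planned CS.
#' @param fs_hz Sampling rate of `segment`.
#' @param criterion A [baseline_criterion()].
#' @param ur_average Average UR amplitude in raw units (baseline to peak);
#'   must be positive.
#' @return A list with `stable` (flag for the final window) and
#'   `extensions_needed` (count).
#' @export
check_baseline_stability <- function(segment, fs_hz = 1000,
                                     criterion = baseline_criterion(),
                                     ur_average) {
  if (ur_average <= 0) stopf("ur_average must be positive")
  wlen <- round(criterion$window_s * fs_hz)
  if (length(segment) < wlen)
    stopf("segment shorter than the stability window")
  step <- round(criterion$iti_extension_s * fs_hz)
  band <- criterion$allowed_range * ur_average
  window_ok <- function(w) all(abs(w - stats::median(w)) <= band)

  n <- length(segment)
  stable <- window_ok(segment[(n - wlen + 1L):n])
  ext <- 0L
  end <- n - step
  while (end >= wlen) {
    if (window_ok(segment[(end - wlen + 1L):end])) break
    ext <- ext + 1L
    end <- end - step
  }
  list(stable = stable, extensions_needed = ext)
}

exclusion_levels <- c("none", "early_movement", "unstable_baseline",
                      "no_ur_reference", "degenerate_reference")

#' Normalize a cohort's traces against the unconditioned reflex
#'
#' Converts every trace to UR-normalized units: baseline (mean of the
#' pre-CS window) maps to 0 and the UR peak maps to 1. Paired and US-only
#' trials use their own UR (maximum in the `ur_window_ms` after US onset);
#' unpaired CS trials use the UR range carried forward from the most recent
#' US-containing trial of the same session. A CS-only trial with no earlier
#' US trial in its session is marked invalid (`no_ur_reference`); a trial
#' whose UR peak does not exceed its baseline is marked invalid
#' (`degenerate_reference`). With `normalization = "session_average"` the
#' scale is instead the session-wide mean UR range, an alternative the
#' per-trial scheme is expected to match closely.
#'
#' @param cohort An `eyeblink_cohort` from [simulate_cohort()] (or the same
#'   structure read from disk).
#' @param baseline_window_ms Length of the pre-CS baseline window.
#' @param ur_window_ms UR peak search window after US onset.
#' @param normalization `"per_trial"` (carry-forward, default) or
#'   `"session_average"`.
#' @param criterion A [baseline_criterion()] used to flag unstable-baseline
#'   trials (and to fill the `iti_extensions` bookkeeping column).
#' @return The cohort with a `norm` trace matrix added and new trial
#'   columns `baseline_value`, `ur_peak_raw`, `valid`, `exclusion_reason`,
#'   `early_movement`.
#' @export
normalize_cohort <- function(cohort,
                             baseline_window_ms = 500,
                             ur_window_ms = 200,
                             normalization = c("per_trial",
                                               "session_average"),
                             criterion = baseline_criterion()) {
  normalization <- match.arg(normalization)
  trials <- cohort$trials
  traces <- cohort$traces
  time_ms <- cohort$time_ms
  fs <- 1000 / (time_ms[2] - time_ms[1])
  n <- nrow(trials)
  norm <- matrix(NA_real_, n, ncol(traces))
  baseline_value <- ur_peak_raw <- rep(NA_real_, n)
  valid <- rep(TRUE, n)
  reason <- rep("none", n)
  iti_ext <- integer(n)
  stable <- logical(n)

  sess_key <- paste(trials$subject, trials$phase, trials$session)
  for (key in unique(sess_key)) {
    rows <- which(sess_key == key)
    last_ur_range <- NA_real_
    ur_ranges <- c()
    for (i in rows) {
      x <- traces[i, ]
      kind <- as.character(trials$kind[i])
      origin <- if (is.na(trials$cs_onset_ms[i])) trials$us_onset_ms[i]
                else trials$cs_onset_ms[i]
      base_mask <- window_mask(time_ms, origin, -baseline_window_ms, 0,
                               right_open = TRUE)
      baseline <- mean(x[base_mask])
      baseline_value[i] <- baseline
      if (kind %in% c("paired", "us_only")) {
        urw <- window_mask(time_ms, trials$us_onset_ms[i], 0, ur_window_ms)
        urp <- max(x[urw])
        ur_peak_raw[i] <- urp
        rng <- urp - baseline
        if (rng <= 0) {
          valid[i] <- FALSE; reason[i] <- "degenerate_reference"
        } else {
          last_ur_range <- rng
          ur_ranges <- c(ur_ranges, rng)
          norm[i, ] <- (x - baseline) / rng
        }
      } else {  # cs_only
        if (is.na(last_ur_range)) {
          valid[i] <- FALSE; reason[i] <- "no_ur_reference"
        } else {
          ur_peak_raw[i] <- baseline + last_ur_range
          norm[i, ] <- (x - baseline) / last_ur_range
        }
      }
    }
    if (normalization == "session_average" && length(ur_ranges)) {
      scale <- mean(ur_ranges)
      for (i in rows) {
        if (!valid[i] && reason[i] == "no_ur_reference" &&
            !is.na(baseline_value[i])) {
          valid[i] <- TRUE; reason[i] <- "none"
        }
        if (valid[i])
          norm[i, ] <- (traces[i, ] - baseline_value[i]) / scale
      }
    }
    # baseline-stability bookkeeping against the session mean UR
    if (length(ur_ranges)) {
      ur_avg <- mean(ur_ranges)
      for (i in rows) {
        origin <- if (is.na(trials$cs_onset_ms[i])) trials$us_onset_ms[i]
                  else trials$cs_onset_ms[i]
        seg <- traces[i, time_ms < origin]
        if (length(seg) >= round(criterion$window_s * fs)) {
          st <- check_baseline_stability(seg, fs, criterion, ur_avg)
          stable[i] <- st$stable
          iti_ext[i] <- st$extensions_needed
        }
      }
    }
  }

  trials$baseline_value <- baseline_value
  trials$ur_peak_raw <- ur_peak_raw
  trials$valid <- valid
  trials$exclusion_reason <- factor(reason, levels = exclusion_levels)
  trials$baseline_stable <- stable
  trials$iti_extensions <- iti_ext
  em <- rep(NA, n)
  for (i in which(valid)) {
    em[i] <- early_movement_flag(norm[i, ], time_ms, trials$cs_onset_ms[i])
  }
  trials$early_movement <- em

  cohort$trials <- trials
  cohort$norm <- norm
  cohort
}

#' Normalize a single trial trace
#'
#' Lower-level normalization used by [normalize_cohort()]:
#' `(x - baseline) / (ur_peak - baseline)`, with the baseline taken as the
#' mean of the pre-CS window and the UR peak searched within
#' `ur_window_ms` of US onset, or carried forward via `ref_ur_range` for
#' unpaired CS trials.
#'
#' @param samples Raw trace.
#' @param time_ms Sample times (ms from trace start).
#' @param cs_onset_ms,us_onset_ms Marker times (ms from trace start; NA if
#'   the stimulus was absent).
#' @param ref_ur_range UR range (peak minus baseline, raw units) carried
#'   forward from the most recent US trial; required when `us_onset_ms` is
#'   NA.
#' @param baseline_window_ms,ur_window_ms Window lengths as in
#'   [normalize_cohort()].
#' @return A list with `samples` (normalized, or NULL if invalid),
#'   `baseline`, `ur_peak`, `valid` and `exclusion_reason`.
#' @export
normalize_trial <- function(samples, time_ms, cs_onset_ms,
                            us_onset_ms = NA_real_, ref_ur_range = NA_real_,
                            baseline_window_ms = 500, ur_window_ms = 200) {
  origin <- if (is.na(cs_onset_ms)) us_onset_ms else cs_onset_ms
  baseline <- mean(samples[window_mask(time_ms, origin, -baseline_window_ms,
                                       0, right_open = TRUE)])
  if (!is.na(us_onset_ms)) {
    urp <- max(samples[window_mask(time_ms, us_onset_ms, 0, ur_window_ms)])
    rng <- urp - baseline
    if (rng <= 0)
      return(list(samples = NULL, baseline = baseline, ur_peak = urp,
                  valid = FALSE, exclusion_reason = "degenerate_reference"))
    return(list(samples = (samples - baseline) / rng, baseline = baseline,
                ur_peak = urp, valid = TRUE, exclusion_reason = "none"))
  }
  if (is.na(ref_ur_range))
    return(list(samples = NULL, baseline = baseline, ur_peak = NA_real_,
                valid = FALSE, exclusion_reason = "no_ur_reference"))
  list(samples = (samples - baseline) / ref_ur_range, baseline = baseline,
       ur_peak = baseline + ref_ur_range, valid = TRUE,
       exclusion_reason = "none")
}

#' Zero-phase moving-average smoothing
#'
#' Centered (and hence zero-phase) moving average; the kernel width is
#' `width_ms` rounded to an odd number of samples. Edges are padded by
#' replicating the end samples so the output has the input's length and a
#' constant trace maps to itself.
#'
#' @param x Numeric trace.
#' @param fs_hz Sampling rate.
#' @param width_ms Kernel width in ms (default 10).
#' @param width_samples Kernel width in samples; overrides `width_ms`.
#' @return Smoothed trace, same length as `x`.
#' @export
smooth_trace <- function(x, fs_hz = 1000, width_ms = 10,
                         width_samples = NULL) {
  k <- width_samples %||% max(1L, round(width_ms * fs_hz / 1000))
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  if (k > length(x)) stopf("smoothing kernel wider than the trace")
  if (k == 1L) return(x)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[
    (half + 1L):(half + length(x))]
}

#' Early-movement exclusion flag
#'
#' A trial is excluded from CR scoring when the normalized response exceeds
#' 0.05 between 0 and 99 ms after CS onset (strict inequality; the window
#' is closed on both ends).
#'
#' @param samples Normalized trace.
#' @param time_ms Sample times.
#' @param cs_onset_ms CS onset (ms from trace start).
#' @param threshold Exclusion threshold (default 0.05).
#' @param window_ms Early window (default `c(0, 99)`).
#' @return TRUE when the trial must be excluded.
#' @export
early_movement_flag <- function(samples, time_ms, cs_onset_ms,
                                threshold = 0.05, window_ms = c(0, 99)) {
  if (is.na(cs_onset_ms)) return(FALSE)
  m <- window_mask(time_ms, cs_onset_ms, window_ms[1], window_ms[2])
  max(samples[m]) > threshold
}
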