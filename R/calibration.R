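#' Simulate a cohort at the session-metrics level
#'
#' Monte-Carlo harness for calibration and power studies: subjects are
#' drawn with a between-subject spread around their group's learning
#' asymptote, each session's peak-amplitude samples come from the
#' generative mixture ([simulate_session_peaks()]), and each session is
#' decomposed with [session_metrics()]. Returns a per-session metrics table
#' ready for [rm_anova_2way()], [last_four_mean()] and friends. This is the
#' natural problem size for repeated-replicate studies (type-I error,
#' power), where simulating every raw trace would add nothing but runtime;
#' the trace-level generator is exercised by the timing and pipeline
#' analyses.
#'
#' @param groups List of groups: each a list with `label`, `n_subjects`,
#'   `p_max` (and optionally `amp_max`).
#' @param n_sessions Acquisition sessions.
#' @param n_trials Trials per session contributing peaks.
#' @param tau_sessions,amp_tau Learning time constants (probability,
#'   amplitude).
#' @param amp_max,amp_sd CR amplitude asymptote and trial-to-trial SD.
#' @param noise_sigma Non-response noise SD.
#' @param subject_sd Between-subject SD of the probability asymptote
#'   (truncated to `[0, 1]`).
#' @param bin_width,cr_threshold Decomposition parameters.
#' @param seed Integer seed.
#' @return Tibble with `subject`, `group`, `session`, `true_p`,
#'   `probability`, `amplitude`, `percent_cr`, `phase` (all
#'   `"acquisition"`), `n_trials`.
#' @export
simulate_metrics_cohort <- function(groups,
                                    n_sessions = 12L, n_trials = 220L,
                                    tau_sessions = 4, amp_max = 0.45,
                                    amp_tau = 4, amp_sd = 0.1,
                                    noise_sigma = 0.02, subject_sd = 0.05,
                                    bin_width = 0.025, cr_threshold = 0.15,
                                    seed = 1L) {
  withr::with_seed(seed, {
    n_rows <- sum(vapply(groups, `[[`, 1, "n_subjects")) * n_sessions
    subject <- group <- character(n_rows)
    session <- integer(n_rows)
    true_p <- probability <- amplitude <- percent_cr <- numeric(n_rows)
    r <- 0L
    for (grp in groups) {
      a_max <- grp$amp_max %||% amp_max
      for (si in seq_len(grp$n_subjects)) {
        p_max_i <- min(1, max(0, stats::rnorm(1, grp$p_max, subject_sd)))
        sid <- sprintf("%s_%02d", grp$label, si)
        for (s in seq_len(n_sessions)) {
          p_s <- p_max_i * (1 - exp(-s / tau_sessions))
          amp_s <- a_max * (1 - exp(-s / amp_tau))
          pk <- simulate_session_peaks(n_trials, p_s, amp_s, amp_sd,
                                       noise_sigma)
          met <- session_metrics(pk$values, bin_width, cr_threshold)
          r <- r + 1L
          subject[r] <- sid; group[r] <- grp$label; session[r] <- s
          true_p[r] <- p_s; probability[r] <- met$probability
          amplitude[r] <- met$amplitude; percent_cr[r] <- met$percent_cr
        }
      }
    }
    tibble::tibble(subject = subject, group = group, phase = "acquisition",
                   session = session, true_p = true_p, n_trials = n_trials,
                   probability = probability, amplitude = amplitude,
                   percent_cr = percent_cr)
  })
}

#' Simulate a cohort of CR timing estimates
#'
#' Trace-level harness for timing power studies: every subject contributes
#' `n_trials` unpaired-CS traces generated with a subject-specific 10-90%
#' rise-time target, and the per-subject mean of the detected
#' [cr_timing()] metrics is returned. Traces use a compact record
#' (short baseline) since only the CS epoch is analyzed.
#'
#' @param groups List of groups: each a list with `label`, `n_subjects`,
#'   `rise_10_90_ms` (and optionally `onset_mean_ms`).
#' @param n_trials Unpaired CS trials per subject.
#' @param subject_rise_sd Between-subject SD of the rise-time target.
#' @param noise_sigma Sensor noise SD.
#' @param seed Integer seed.
#' @return Tibble with one row per subject: `subject`, `group`,
#'   `onset_latency_ms`, `rise_time_10_90_ms`, `peak_latency_ms`
#'   (means over the subject's scored trials).
#' @export
simulate_timing_cohort <- function(groups, n_trials = 12L,
                                   subject_rise_sd = 8,
                                   noise_sigma = 0.02, seed = 1L) {
  protocol <- protocol_config()
  withr::with_seed(seed, {
    rows <- list()
    for (grp in groups) {
      for (si in seq_len(grp$n_subjects)) {
        rise_i <- max(20, stats::rnorm(1, grp$rise_10_90_ms,
                                       subject_rise_sd))
        cfg <- simulation_config(
          trace_duration_ms = 1200, cs_onset_ms = 300,
          noise_sigma = noise_sigma, drift_amplitude = 0,
          opening_prob = 0,
          cr_onset_mean_ms = grp$onset_mean_ms %||% 145,
          cr_rise_10_90_ms = rise_i)
        est <- matrix(NA_real_, n_trials, 3)
        for (tr_i in seq_len(n_trials)) {
          tr <- simulate_trace(list(kind = "cs_only"),
                               list(p = 1, amp_mean = 0.4), cfg, protocol)
          x <- (tr$samples - cfg$baseline_volts) / cfg$ur_peak_volts
          if (classify_cr(x, tr$time_ms, cfg$cs_onset_ms) != "cr") next
          m <- cr_timing(x, tr$time_ms, cfg$cs_onset_ms)
          est[tr_i, ] <- c(m$onset_latency_ms, m$rise_time_10_90_ms,
                           m$peak_latency_ms)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = sprintf("%s_%02d", grp$label, si), group = grp$label,
          onset_latency_ms = mean(est[, 1], na.rm = TRUE),
          rise_time_10_90_ms = mean(est[, 2], na.rm = TRUE),
          peak_latency_ms = mean(est[, 3], na.rm = TRUE))
      }
    }
    dplyr::bind_rows(rows)
  })
}
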