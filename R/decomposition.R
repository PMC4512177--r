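#' Collect per-trial peak amplitudes for one session
#'
#' For every included trial the collected value is the trace value of
#' greatest displacement from zero within the measurement window, carrying
#' its sign, so eyelid openings populate the negative bins. The default
#' window is 100-250 ms after CS onset on paired trials (stopping at the US)
#' and 100-280 ms on unpaired CS trials; US-only trials carry no CS window
#' and are excluded. Invalid trials are skipped; early-movement trials are
#' kept unless `exclude_early_movement` is set.
#'
#' @param norm Matrix of normalized traces (rows = trials) or a single
#'   numeric trace.
#' @param time_ms Sample times (ms from trace start).
#' @param trials Tibble of trial metadata (`kind`, `cs_onset_ms`, `valid`,
#'   `early_movement`), one row per trace row. Optional for a bare matrix of
#'   CS-aligned traces, in which case all rows are treated as valid paired
#'   trials.
#' @param window_paired_ms,window_cs_only_ms Measurement windows (ms after
#'   CS onset).
#' @param exclude_early_movement Drop trials flagged by the 0-99 ms rule.
#' @return A list of class `amplitude_samples`: `values` (signed peaks),
#'   `rows` (source row indices), `n_trials`, `window`.
#' @export
collect_peak_amplitudes <- function(norm, time_ms, trials = NULL,
                                    window_paired_ms = c(100, 250),
                                    window_cs_only_ms = c(100, 280),
                                    exclude_early_movement = FALSE) {
  if (is.null(dim(norm))) norm <- matrix(norm, nrow = 1)
  n <- nrow(norm)
  if (is.null(trials)) {
    trials <- tibble::tibble(kind = factor(rep("paired", n), kind_levels),
                             cs_onset_ms = rep(0, n),
                             valid = TRUE, early_movement = FALSE)
  }
  keep <- trials$valid & trials$kind %in% c("paired", "cs_only")
  if (exclude_early_movement)
    keep <- keep & !isTRUE_vec(trials$early_movement)
  rows <- which(keep)
  if (!length(rows)) stopf("no included trials in session")
  vals <- vapply(rows, function(i) {
    w <- if (trials$kind[i] == "cs_only") window_cs_only_ms else
      window_paired_ms
    signed_extremum(norm[i, window_mask(time_ms, trials$cs_onset_ms[i],
                                        w[1], w[2])])
  }, numeric(1))
  structure(list(values = vals, rows = rows, n_trials = length(rows),
                 window = list(paired = window_paired_ms,
                               cs_only = window_cs_only_ms)),
            class = "amplitude_samples")
}

isTRUE_vec <- function(x) !is.na(x) & x

# Largest-magnitude value in a window, keeping its sign; ties favor the
# positive (closing) direction.
signed_extremum <- function(x) {
  hi <- max(x); lo <- min(x)
  if (abs(lo) > abs(hi)) lo else hi
}

#' Histogram of peak amplitudes with a zero-centered bin
#'
#' Bins are tiled so that one bin spans exactly
#' `[-bin_width/2, +bin_width/2)`; with the default width 0.025 the zero bin
#' runs from -0.0125 to 0.0125. Values map to the nearest bin center
#' (half-open bins, left edge inclusive).
#'
#' @param values Numeric vector of signed peak amplitudes, or an
#'   `amplitude_samples` object.
#' @param bin_width Bin width in normalized units.
#' @return A list of class `response_histogram`: `centers`, `counts`,
#'   `bin_width`, `total`.
#' @export
build_histogram <- function(values, bin_width = 0.025) {
  if (inherits(values, "amplitude_samples")) values <- values$values
  if (bin_width <= 0) stopf("bin_width must be positive")
  idx <- floor(values / bin_width + 0.5)
  kmin <- min(idx, 0); kmax <- max(idx, 0)
  centers <- (kmin:kmax) * bin_width
  counts <- tabulate(idx - kmin + 1L, nbins = kmax - kmin + 1L)
  structure(list(centers = centers, counts = counts, bin_width = bin_width,
                 total = length(values)),
            class = "response_histogram")
}

new_response_histogram <- function(centers, counts, bin_width) {
  structure(list(centers = centers, counts = as.numeric(counts),
                 bin_width = bin_width, total = sum(counts)),
            class = "response_histogram")
}

#' Reflect the non-response histogram and decompose
#'
#' The pipeline's central statistic. The part of the peak-amplitude histogram
#' below zero, plus its reflection across the zero axis, plus the
#' zero-centered bin (which holds the trials that failed to respond) forms
#' the non-response distribution; its integral divided by the trial count is
#' the failure rate. Response probability = 1 - failure rate. The response
#' distribution is what remains of the positive side after subtracting the
#' reflected mass (floored at zero per bin), and the response amplitude is
#' its center of mass — undefined when no response mass remains.
#'
#' @param hist A `response_histogram` (see [build_histogram()]).
#' @param zero_bin `"nonresponse"` (default: the whole zero bin counts as
#'   failures) or `"split"` (half the zero bin is left on the response
#'   side, at amplitude 0).
#' @return A list of class `blink_decomposition`: `failure_rate`,
#'   `probability`, `amplitude` (NA when undefined), `response_mass` and
#'   `nonresponse_mass` (per-bin masses on `centers`), `total`.
#' @export
reflect_and_decompose <- function(hist, zero_bin = c("nonresponse",
                                                     "split")) {
  zero_bin <- match.arg(zero_bin)
  stopifnot(inherits(hist, "response_histogram"))
  if (hist$total <= 0) stopf("empty histogram")
  w <- hist$bin_width
  k <- round(hist$centers / w)
  K <- max(abs(k))
  # counts on symmetric index -K..K
  full <- numeric(2L * K + 1L)
  full[k + K + 1L] <- hist$counts
  zero_count <- full[K + 1L]
  neg <- rev(full[seq_len(K)])        # counts at -1..-K mirrored to +1..+K
  pos <- full[(K + 2L):(2L * K + 1L)] # counts at +1..+K
  if (K == 0L) { neg <- numeric(0); pos <- numeric(0) }

  zero_nonresp <- if (zero_bin == "nonresponse") zero_count else
    zero_count / 2
  nonresp_total <- zero_nonresp + 2 * sum(neg)
  failure_rate <- min(1, max(0, nonresp_total / hist$total))
  probability <- 1 - failure_rate

  resp_pos <- pmax(0, pos - neg)
  resp_zero <- zero_count - zero_nonresp
  resp_mass <- c(numeric(K), resp_zero, resp_pos)
  nonresp_mass <- c(rev(neg), zero_nonresp, neg)
  centers_full <- (-K:K) * w

  resp_total <- sum(resp_mass)
  amplitude <- if (resp_total > 0)
    sum(centers_full * resp_mass) / resp_total else NA_real_

  structure(list(failure_rate = failure_rate, probability = probability,
                 amplitude = amplitude, centers = centers_full,
                 response_mass = resp_mass, nonresponse_mass = nonresp_mass,
                 bin_width = w, total = hist$total),
            class = "blink_decomposition")
}

#' @export
print.blink_decomposition <- function(x, ...) {
  cat(sprintf(
    "Histogram-reflection decomposition (n = %d trials)\n  response probability: %.3f\n  response amplitude:   %s\n  failure rate:         %.3f\n",
    x$total, x$probability,
    if (is.na(x$amplitude)) "undefined (no response mass)" else
      sprintf("%.3f", x$amplitude),
    x$failure_rate))
  invisible(x)
}

#' Session-level learning metrics
#'
#' Probability and amplitude from the histogram-reflection decomposition,
#' plus the classical %CR measure: the percentage of trials whose window
#' peak exceeds a fixed threshold (0.15).
#'
#' @param values Signed peak amplitudes (vector or `amplitude_samples`).
#' @param bin_width Histogram bin width.
#' @param cr_threshold Fixed %CR threshold.
#' @param zero_bin Passed to [reflect_and_decompose()].
#' @return A list with `probability`, `amplitude`, `percent_cr`,
#'   `n_trials`, and the `decomposition` object.
#' @export
session_metrics <- function(values, bin_width = 0.025, cr_threshold = 0.15,
                            zero_bin = "nonresponse") {
  if (inherits(values, "amplitude_samples")) values <- values$values
  if (!length(values)) stopf("empty session")
  dec <- reflect_and_decompose(build_histogram(values, bin_width), zero_bin)
  list(probability = dec$probability,
       amplitude = dec$amplitude,
       percent_cr = 100 * mean(values > cr_threshold),
       n_trials = length(values),
       decomposition = dec)
}

#' Per-session metrics table for a normalized cohort
#'
#' Applies [collect_peak_amplitudes()] and [session_metrics()] to every
#' (subject, phase, session) cell of a normalized cohort. Traces are
#' smoothed before peak collection.
#'
#' @param cohort A cohort from [normalize_cohort()].
#' @param smooth_width_ms Moving-average width applied before peak
#'   collection.
#' @inheritParams collect_peak_amplitudes
#' @inheritParams session_metrics
#' @return A tibble with one row per subject x phase x session:
#'   `subject`, `group`, `age_days`, `phase`, `session`, `n_trials`,
#'   `probability`, `amplitude`, `percent_cr`.
#' @export
decompose_cohort <- function(cohort,
                             window_paired_ms = c(100, 250),
                             window_cs_only_ms = c(100, 280),
                             bin_width = 0.025, cr_threshold = 0.15,
                             smooth_width_ms = 10,
                             exclude_early_movement = FALSE,
                             zero_bin = "nonresponse") {
  stopifnot(!is.null(cohort$norm))
  trials <- cohort$trials
  time_ms <- cohort$time_ms
  fs <- 1000 / (time_ms[2] - time_ms[1])
  key <- paste(trials$subject, trials$phase, trials$session)
  out <- lapply(unique(key), function(kk) {
    rows <- which(key == kk)
    sm <- cohort$norm[rows, , drop = FALSE]
    ok <- trials$valid[rows]
    for (j in which(ok)) sm[j, ] <- smooth_trace(sm[j, ], fs, smooth_width_ms)
    samp <- collect_peak_amplitudes(
      sm, time_ms, trials[rows, ],
      window_paired_ms = window_paired_ms,
      window_cs_only_ms = window_cs_only_ms,
      exclude_early_movement = exclude_early_movement)
    met <- session_metrics(samp, bin_width, cr_threshold, zero_bin)
    tibble::tibble(
      subject = trials$subject[rows[1]],
      group = trials$group[rows[1]],
      age_days = trials$age_days[rows[1]],
      phase = trials$phase[rows[1]],
      session = trials$session[rows[1]],
      n_trials = met$n_trials,
      probability = met$probability,
      amplitude = met$amplitude,
      percent_cr = met$percent_cr)
  })
  dplyr::bind_rows(out)
}
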