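# Independent oracles used to verify the package's own implementations.

# Brute-force reflect-subtract arithmetic on a histogram given as bin
# centers (multiples of bin_width, including 0) and integer counts.
# Deliberately written as an explicit per-bin loop, independent of the
# package's vectorized path.
oracle_decompose <- function(centers, counts, bin_width) {
  total <- sum(counts)
  stopifnot(total > 0)
  fail <- 0
  resp <- counts
  for (i in seq_along(centers)) {
    ci <- centers[i]
    if (ci < -bin_width / 4) {           # negative bin
      fail <- fail + 2 * counts[i]       # itself + its reflection
      resp[i] <- 0
      j <- which(abs(centers + ci) < bin_width / 4)  # mirror bin at -ci
      if (length(j) == 1) resp[j] <- max(0, resp[j] - counts[i])
    } else if (abs(ci) < bin_width / 4) {  # zero bin -> all non-response
      fail <- fail + counts[i]
      resp[i] <- 0
    }
  }
  failure_rate <- max(0, min(1, fail / total))
  rtot <- sum(resp)
  list(probability = 1 - failure_rate,
       failure_rate = failure_rate,
       amplitude = if (rtot > 0) sum(centers * resp) / rtot else NA_real_)
}

# Histogram object on centers k*w for k in kmin:(kmin+length-1) (must
# include 0).
hist_from_counts <- function(counts, kmin, bin_width = 0.025) {
  centers <- (kmin:(kmin + length(counts) - 1)) * bin_width
  stopifnot(any(abs(centers) < bin_width / 4))
  structure(list(centers = centers, counts = as.numeric(counts),
                 bin_width = bin_width, total = sum(counts)),
            class = "response_histogram")
}

# Classical sums-of-squares decomposition for a balanced two-way mixed
# design (group between, session within, one observation per cell).
oracle_mixed_anova <- function(d) {
  d$subject <- as.character(d$subject)
  d$group <- as.character(d$group)
  grand <- mean(d$y)
  t_lev <- sort(unique(d$session))
  nt <- length(t_lev)
  subj <- unique(d[, c("subject", "group")])
  a_lev <- unique(subj$group)
  n_subj <- nrow(subj)

  m_subj <- tapply(d$y, d$subject, mean)
  m_grp <- tapply(d$y, d$group, mean)
  m_sess <- tapply(d$y, d$session, mean)
  m_cell <- tapply(d$y, list(d$group, d$session), mean)

  n_per_g <- table(subj$group)
  ss_group <- nt * sum(n_per_g[a_lev] * (m_grp[a_lev] - grand)^2)
  ss_subj <- nt * sum((m_subj[subj$subject] - m_grp[subj$group])^2)
  ss_sess <- n_subj * sum((m_sess - grand)^2)
  ss_inter <- 0
  for (g in a_lev) for (s in t_lev) {
    ss_inter <- ss_inter + n_per_g[[g]] *
      (m_cell[g, as.character(s)] - m_grp[[g]] -
         m_sess[[as.character(s)]] + grand)^2
  }
  ss_total <- sum((d$y - grand)^2)
  ss_res <- ss_total - ss_group - ss_subj - ss_sess - ss_inter

  a <- length(a_lev)
  df_g <- a - 1; df_s <- n_subj - a
  df_t <- nt - 1; df_gt <- df_g * df_t; df_res <- df_s * df_t
  list(
    F_group = (ss_group / df_g) / (ss_subj / df_s),
    F_session = (ss_sess / df_t) / (ss_res / df_res),
    F_inter = (ss_inter / df_gt) / (ss_res / df_res),
    df = c(df_g, df_s, df_t, df_gt, df_res))
}

# Deterministic synthetic trace: linear ramp from 0 to `amp` between
# t_start and t_end (ms), held at `amp` until hold_end, zero elsewhere.
ramp_trace <- function(time_ms, t_start, t_end, amp, hold_end = NULL) {
  y <- numeric(length(time_ms))
  ris <- time_ms >= t_start & time_ms <= t_end
  y[ris] <- amp * (time_ms[ris] - t_start) / (t_end - t_start)
  if (!is.null(hold_end)) {
    h <- time_ms > t_end & time_ms <= hold_end
    y[h] <- amp
  }
  y
}

# Minimal single-subject cohort wrapper around a trace matrix.
make_cohort <- function(traces, trials, fs_hz = 1000,
                        protocol = protocol_config(),
                        config = simulation_config()) {
  structure(list(
    trials = trials, traces = traces,
    time_ms = (seq_len(ncol(traces)) - 1) * 1000 / fs_hz,
    ground_truth = NULL, protocol = protocol, config = config),
    class = "eyeblink_cohort")
}

# Small simulated cohort via the trace generator (reduced protocol for
# test runtime).
tiny_cohort_spec <- function(master_seed = 1, n_subjects = 1,
                             blocks = 4, n_acq = 2, n_ext = 1, n_reacq = 1,
                             p_max = 0.8, ...) {
  proto <- protocol_config(blocks_per_session = blocks,
                           n_acquisition_sessions = n_acq,
                           n_extinction_sessions = n_ext,
                           n_reacquisition_sessions = n_reacq)
  cohort_spec(
    groups = list(list(label = "wt", n_subjects = n_subjects)),
    protocol = proto,
    config = simulation_config(p_max = p_max, ...),
    master_seed = master_seed)
}
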