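#' Conditioning protocol configuration
#'
#' Describes the delay eyeblink conditioning protocol: 22 blocks of 10 trials
#' per session; during acquisition each block holds 9 paired CS-US trials and
#' 1 unpaired CS trial placed pseudorandomly; the CS is a 280 ms light flash
#' and the US a 30 ms airpuff co-terminating with it (US onset 250 ms after
#' CS onset); trials are separated by at least 12 s. Extinction sessions use
#' blocks of 5 CS-only and 5 US-only trials.
#'
#' @param blocks_per_session Blocks per daily session.
#' @param trials_per_block Trials per block.
#' @param paired_per_block Paired CS-US trials per acquisition block.
#' @param unpaired_cs_per_block Unpaired CS trials per acquisition block.
#' @param cs_duration_ms CS duration in ms.
#' @param us_duration_ms US duration in ms.
#' @param us_onset_ms US onset in ms after CS onset (co-terminating default).
#' @param min_iti_s Minimum intertrial interval in seconds.
#' @param n_acquisition_sessions,n_extinction_sessions,n_reacquisition_sessions
#'   Number of daily sessions per phase.
#' @param extinction_cs_per_block,extinction_us_per_block Block composition
#'   during extinction.
#' @return An object of class `protocol_config` (a validated list).
#' @export
protocol_config <- function(blocks_per_session = 22L,
                            trials_per_block = 10L,
                            paired_per_block = 9L,
                            unpaired_cs_per_block = 1L,
                            cs_duration_ms = 280,
                            us_duration_ms = 30,
                            us_onset_ms = 250,
                            min_iti_s = 12,
                            n_acquisition_sessions = 12L,
                            n_extinction_sessions = 4L,
                            n_reacquisition_sessions = 3L,
                            extinction_cs_per_block = 5L,
                            extinction_us_per_block = 5L) {
  cfg <- list(
    blocks_per_session = as.integer(blocks_per_session),
    trials_per_block = as.integer(trials_per_block),
    paired_per_block = as.integer(paired_per_block),
    unpaired_cs_per_block = as.integer(unpaired_cs_per_block),
    cs_duration_ms = cs_duration_ms,
    us_duration_ms = us_duration_ms,
    us_onset_ms = us_onset_ms,
    min_iti_s = min_iti_s,
    n_acquisition_sessions = as.integer(n_acquisition_sessions),
    n_extinction_sessions = as.integer(n_extinction_sessions),
    n_reacquisition_sessions = as.integer(n_reacquisition_sessions),
    extinction_cs_per_block = as.integer(extinction_cs_per_block),
    extinction_us_per_block = as.integer(extinction_us_per_block)
  )
  validate_protocol_config(cfg)
  structure(cfg, class = "protocol_config")
}

validate_protocol_config <- function(cfg) {
  with(cfg, {
    if (paired_per_block + unpaired_cs_per_block != trials_per_block)
      stopf("paired_per_block + unpaired_cs_per_block must equal trials_per_block (%d + %d != %d)",
            paired_per_block, unpaired_cs_per_block, trials_per_block)
    if (extinction_cs_per_block + extinction_us_per_block != trials_per_block)
      stopf("extinction block composition must sum to trials_per_block")
    if (us_onset_ms + us_duration_ms != cs_duration_ms)
      stopf("US must co-terminate with the CS: us_onset_ms + us_duration_ms must equal cs_duration_ms")
    if (any(c(cs_duration_ms, us_duration_ms, min_iti_s) <= 0))
      stopf("durations must be positive")
    if (any(c(blocks_per_session, trials_per_block, paired_per_block) < 1L))
      stopf("counts must be >= 1")
  })
  invisible(cfg)
}

phase_levels <- c("habituation", "acquisition", "extinction", "reacquisition")
kind_levels <- c("paired", "cs_only", "us_only")

new_trial_plan <- function(session_index, phase, block_index, trial_index, kind) {
  tibble::tibble(
    session = as.integer(session_index),
    phase = factor(phase, levels = phase_levels),
    block = as.integer(block_index),
    trial = as.integer(trial_index),
    kind = factor(kind, levels = kind_levels)
  )
}

#' Build one acquisition (or reacquisition) session schedule
#'
#' Each block contains `paired_per_block` paired CS-US trials and
#' `unpaired_cs_per_block` unpaired CS trials; the position of the unpaired
#' trials within each block is drawn uniformly from a seeded generator
#' ("pseudorandomly within the block"). With default settings a session holds
#' 220 trials, 10% of them CS-only.
#'
#' @param cfg A [protocol_config()].
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param session_index Session number stored in the plan rows.
#' @param phase `"acquisition"` or `"reacquisition"`.
#' @return A tibble of trial plans (one row per trial, in delivery order)
#'   with columns `session`, `phase`, `block`, `trial`, `kind`.
#' @export
build_acquisition_schedule <- function(cfg = protocol_config(), seed = 1L,
                                       session_index = 1L,
                                       phase = "acquisition") {
  validate_protocol_config(cfg)
  phase <- match.arg(phase, c("acquisition", "reacquisition"))
  kinds <- withr::with_seed(seed, {
    lapply(seq_len(cfg$blocks_per_session), function(b) {
      k <- rep("paired", cfg$trials_per_block)
      slots <- sample.int(cfg$trials_per_block, cfg$unpaired_cs_per_block)
      k[slots] <- "cs_only"
      k
    })
  })
  plan_from_kinds(kinds, cfg, session_index, phase)
}

#' Build one extinction session schedule
#'
#' Each block contains `extinction_cs_per_block` unpaired CS trials and
#' `extinction_us_per_block` unpaired US trials, arranged pseudorandomly
#' within the block (22 blocks of 10 by default: 110 CS-only and 110 US-only
#' trials per session).
#'
#' @inheritParams build_acquisition_schedule
#' @return A tibble of trial plans, as [build_acquisition_schedule()].
#' @export
build_extinction_schedule <- function(cfg = protocol_config(), seed = 1L,
                                      session_index = 1L) {
  validate_protocol_config(cfg)
  kinds <- withr::with_seed(seed, {
    lapply(seq_len(cfg$blocks_per_session), function(b) {
      k <- c(rep("cs_only", cfg$extinction_cs_per_block),
             rep("us_only", cfg$extinction_us_per_block))
      sample(k)
    })
  })
  plan_from_kinds(kinds, cfg, session_index, "extinction")
}

plan_from_kinds <- function(kinds, cfg, session_index, phase) {
  kinds <- unlist(kinds)
  n <- length(kinds)
  new_trial_plan(
    session_index = session_index,
    phase = phase,
    block_index = rep(seq_len(cfg$blocks_per_session),
                      each = cfg$trials_per_block),
    trial_index = seq_len(n),
    kind = kinds
  )
}
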