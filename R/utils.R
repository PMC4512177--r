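# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash used to give every subject/session its own
#' reproducible RNG stream. Kept below 2^31 so it is a valid R integer.
#'
#' @param master_seed Integer master seed.
#' @param ... Further integer indices (e.g. subject index, session index).
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  idx <- c(...)
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (k in seq_along(idx)) {
    h <- (h * 48271 + as.numeric(idx[k]) * 2654435761 %% m + k) %% m
  }
  as.integer(h %% (m - 1L)) + 1L
}

# Logical mask of samples with time (relative to `origin_ms`) inside
# [start_ms, end_ms]; `right_open` drops the right endpoint.
window_mask <- function(time_ms, origin_ms, start_ms, end_ms,
                        right_open = FALSE) {
  t_rel <- time_ms - origin_ms
  if (right_open) t_rel >= start_ms & t_rel < end_ms
  else t_rel >= start_ms & t_rel <= end_ms
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear-interpolated time of first upward crossing of `level` in x at or
# after index `from`. Returns NA if never crossed.
first_crossing_ms <- function(x, time_ms, level, from = 1L) {
  n <- length(x)
  if (from > n) return(NA_real_)
  idx <- which(x[from:n] >= level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1L] + from - 1L
  if (i == 1L || i == from && x[i] >= level && (i == 1L)) return(time_ms[i])
  if (i == from) return(time_ms[i])
  x0 <- x[i - 1L]; x1 <- x[i]
  if (x1 == x0) return(time_ms[i])
  frac <- (level - x0) / (x1 - x0)
  time_ms[i - 1L] + frac * (time_ms[i] - time_ms[i - 1L])
}
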