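# Shared conventions: all latencies in ms, sample indices 0-based,
# epoch windows half-open [t0, t1), time 0 = aligning event.

#' Convert a time in ms to a 0-based sample index
#'
#' Uses the package-wide convention that sample k (0-based) sits at
#' `k * 1000 / fs` ms.
#'
#' @param ms time in milliseconds.
#' @param fs sampling rate in Hz.
#' @return integer 0-based sample index (rounded to nearest sample).
#' @keywords internal
ms_to_sample <- function(ms, fs) as.integer(round(ms * fs / 1000))

#' @keywords internal
sample_to_ms <- function(k, fs) k * 1000 / fs

# Indices (1-based, into a time axis in ms) covered by a window.
# `closed = TRUE` gives inclusive endpoints (used for the baseline window);
# the default is the half-open [t0, t1) convention.
window_index <- function(time_ms, t0, t1, closed = FALSE) {
  if (closed) which(time_ms >= t0 & time_ms <= t1) else which(time_ms >= t0 & time_ms < t1)
}

#' Derive a per-stage random seed from a global seed
#'
#' Stage seeds are the global seed offset by a small hash of the stage name so
#' that each pipeline stage is independently reproducible. The result is kept
#' inside the 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) + h) %% 2147483647L)
}

# FNV-1a 32-bit hash of a string, returned as 8 hex digits. Used to stamp
# outputs with a configuration fingerprint (no cryptographic intent).
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2147483648 - (h >= 2147483648) * 0), b)
    if (h < 0) h <- h + 4294967296
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648)) # fold into signed range for sprintf
}

# quiet assert with a formatted message
.fail <- function(...) stop(sprintf(...), call. = FALSE)
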