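#' Re-reference to the average of all scalp channels
#'
#' Subtracts the per-sample mean over scalp channels from every channel.
#' External (non-scalp) channels, if named, are excluded from the mean but
#' still re-referenced.
#'
#' @param x channels x samples matrix, or an [epoch_set()].
#' @param scalp integer/logical index of scalp channels (default: all).
#' @return same type as `x`.
#' @export
rereference_average <- function(x, scalp = NULL) {
  if (inherits(x, "epoch_set")) {
    for (i in seq_len(dim(x$data)[1L]))
      x$data[i, , ] <- rereference_average(x$data[i, , ], scalp)
    return(x)
  }
  if (nrow(x) < 2L) .fail("need >= 2 channels to average-reference")
  sc <- if (is.null(scalp)) seq_len(nrow(x)) else scalp
  sweep(x, 2L, colMeans(x[sc, , drop = FALSE]))
}

#' Extract epochs from continuous data
#'
#' Cuts half-open windows `[span[1], span[2])` ms around event samples. At
#' 512 Hz the default target-locked span of \[-600, 400) yields exactly 512
#' samples. Events too close to the recording edge are dropped with a message.
#'
#' @param x channels x samples continuous matrix (µV).
#' @param events 0-based sample indices of the aligning events.
#' @param fs sampling rate (Hz).
#' @param span numeric length 2, ms relative to the event.
#' @param labels channel labels.
#' @param align `"target"` or `"response"`.
#' @return an [epoch_set()]; `$meta$kept` gives the indices of retained events.
#' @export
extract_epochs <- function(x, events, fs = 512, span = c(-600, 400),
                           labels = rownames(x), align = "target") {
  n_sp <- as.integer(round((span[2L] - span[1L]) * fs / 1000))
  off0 <- ms_to_sample(span[1L], fs)
  total <- ncol(x)
  first <- events + off0
  ok <- first >= 0L & (first + n_sp) <= total
  if (any(!ok))
    message(sprintf("dropping %d event(s) too close to the recording edge", sum(!ok)))
  events <- events[ok]
  if (length(events) == 0L) .fail("no events remain after edge trimming")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(x)))
  dat <- array(0, dim = c(length(events), nrow(x), n_sp))
  for (i in seq_along(events)) {
    s0 <- events[i] + off0
    dat[i, , ] <- x[, (s0 + 1L):(s0 + n_sp), drop = FALSE]
  }
  # the event sample carries time 0 exactly; the axis starts at the nearest
  # sample to span[1]
  t_ms <- (off0 + seq_len(n_sp) - 1L) * 1000 / fs
  epoch_set(dat, t_ms, fs, labels, align, meta = list(kept = which(ok)))
}

#' Re-align target-locked epochs to the response
#'
#' Re-cuts each trial's samples around its response time, producing
#' response-locked epochs with a half-open span. Trials whose response-locked
#' window is not fully covered by the source epoch are dropped (recorded in
#' `$meta$kept`).
#'
#' @param e target-locked [epoch_set()].
#' @param rt_ms per-trial response times (ms relative to target onset).
#' @param span response-locked span in ms, half-open (default c(-600, 100)).
#' @return a response-locked `epoch_set`.
#' @export
response_lock <- function(e, rt_ms, span = c(-600, 100)) {
  fs <- e$fs
  n_sp <- as.integer(round((span[2L] - span[1L]) * fs / 1000))
  t0 <- e$time_ms[1L]
  keep <- integer(0); pieces <- list()
  for (i in seq_len(dim(e$data)[1L])) {
    s0 <- as.integer(round((rt_ms[i] + span[1L] - t0) * fs / 1000))  # 0-based into epoch
    if (s0 >= 0L && (s0 + n_sp) <= dim(e$data)[3L]) {
      keep <- c(keep, i)
      pieces[[length(pieces) + 1L]] <- e$data[i, , (s0 + 1L):(s0 + n_sp), drop = FALSE]
    }
  }
  if (length(keep) == 0L) .fail("no trials cover the response-locked span")
  dat <- array(0, dim = c(length(keep), dim(e$data)[2L], n_sp))
  for (j in seq_along(pieces)) dat[j, , ] <- pieces[[j]]
  t_ms <- (as.integer(round(span[1L] * fs / 1000)) + seq_len(n_sp) - 1L) * 1000 / fs
  epoch_set(dat, t_ms, fs, e$labels, align = "response",
            meta = c(e$meta, list(kept = keep)))
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (endpoints inclusive; default -50 to 30 ms). Idempotent.
#'
#' @param e an [epoch_set()].
#' @param window numeric length 2, ms.
#' @return baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(e, window = c(-50, 30)) {
  idx <- window_index(e$time_ms, window[1L], window[2L], closed = TRUE)
  if (length(idx) == 0L) .fail("baseline window [%g, %g] ms is empty", window[1L], window[2L])
  bl <- apply(e$data[, , idx, drop = FALSE], c(1L, 2L), mean)
  e$data <- e$data - array(rep(bl, dim(e$data)[3L]), dim = dim(e$data))
  e
}

# band power (sum of periodogram power over bins with centre in [lo, hi) Hz)
band_power <- function(v, fs, lo, hi) {
  n <- length(v)
  p <- Mod(stats::fft(v))^2 / n
  f <- (seq_len(n) - 1L) * fs / n
  half <- f <= fs / 2
  sum(p[half & f >= lo & f < hi])
}

#' Screen epochs for artifacts
#'
#' Applies the study's fixed screening thresholds: blinks where the absolute
#' vertical-EOG difference exceeds 40 µV (the 50 ms before and after the
#' violation are included in the blink segment); slow-wave drift where the
#' (0-3)/(3-7) Hz power ratio exceeds 5; muscle where the (20-40)/(3-7) Hz
#' ratio exceeds 2; absolute-voltage where any |sample| exceeds 50 µV; and
#' baseline-range where the peak-to-peak range within the baseline window
#' exceeds 40 µV. A trial is rejected in full when a blink overlaps stimulus
#' presentation, a saccade occurred, or median gaze deviation exceeds 1 degree
#' within 100 ms of stimulus onset. Channel-level flags exclude only analyses
#' whose measurement window overlaps the flagged segment.
#'
#' @param e an [epoch_set()] (target-locked).
#' @param veog trials x samples matrix of the vertical EOG difference (µV), or
#'   `NULL` to skip blink screening with a warning.
#' @param gaze per-trial data.frame with `saccade` (logical) and
#'   `gaze_dev_deg` (median deviation within +/-100 ms of onset), or `NULL`.
#' @param stim_window_ms stimulus presentation interval (default c(0, 39)).
#' @param thresholds named list overriding the default screening thresholds.
#' @return an `artifact_report`: list with `flags` (data.frame: trial, channel,
#'   flag, t_start_ms, t_end_ms), `full_reject` (logical per trial),
#'   `trial_loss` (fraction), and `n_trials`.
#' @export
screen_artifacts <- function(e, veog = NULL, gaze = NULL,
                             stim_window_ms = c(0, 39),
                             thresholds = list()) {
  th <- utils::modifyList(list(blink_uv = 40, blink_pad_ms = 50,
                               drift_ratio = 5, muscle_ratio = 2,
                               abs_uv = 50, baseline_range_uv = 40,
                               gaze_deg = 1), thresholds)
  nd <- dim(e$data); n_tr <- nd[1L]; n_ch <- nd[2L]
  t_ms <- e$time_ms; fs <- e$fs
  span <- c(t_ms[1L], t_ms[length(t_ms)] + 1000 / fs)
  rows <- list()
  add <- function(trial, channel, flag, t0, t1)
    rows[[length(rows) + 1L]] <<- data.frame(trial = trial, channel = channel,
      flag = flag, t_start_ms = t0, t_end_ms = t1, stringsAsFactors = FALSE)
  stim_blink <- rep(FALSE, n_tr)

  if (is.null(veog)) {
    warning("no vEOG supplied: blink screening skipped")
  } else {
    for (i in seq_len(n_tr)) {
      over <- abs(veog[i, ]) > th$blink_uv
      if (!any(over)) next
      r <- rle(over); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        t0 <- t_ms[starts[j]] - th$blink_pad_ms
        t1 <- t_ms[ends[j]] + th$blink_pad_ms
        add(i, NA_character_, "blink", max(t0, span[1L]), min(t1, span[2L]))
        if (t0 < stim_window_ms[2L] && t1 > stim_window_ms[1L]) stim_blink[i] <- TRUE
      }
    }
  }

  bl_idx <- window_index(t_ms, -50, 30, closed = TRUE)
  n_sp <- nd[3L]
  f_axis <- (seq_len(n_sp) - 1L) * fs / n_sp
  half <- f_axis <= fs / 2
  b_lo  <- half & f_axis > 0   & f_axis < 3   # DC bin excluded: offset, not drift
  b_mid <- half & f_axis >= 3  & f_axis < 7
  b_hi  <- half & f_axis >= 20 & f_axis < 40
  for (i in seq_len(n_tr)) {
    for (c in seq_len(n_ch)) {
      v <- e$data[i, c, ]
      p <- Mod(stats::fft(v))^2 / n_sp
      p_mid <- sum(p[b_mid])
      if (sum(p[b_lo]) > th$drift_ratio * p_mid)
        add(i, e$labels[c], "drift", span[1L], span[2L])
      if (sum(p[b_hi]) > th$muscle_ratio * p_mid)
        add(i, e$labels[c], "muscle", span[1L], span[2L])
      if (max(abs(v)) > th$abs_uv)
        add(i, e$labels[c], "absolute", span[1L], span[2L])
      if (length(bl_idx) && diff(range(v[bl_idx])) > th$baseline_range_uv)
        add(i, e$labels[c], "baseline_range", -50, 30)
    }
  }
  flags <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial = integer(0), channel = character(0), flag = character(0),
               t_start_ms = numeric(0), t_end_ms = numeric(0))
  full <- stim_blink
  if (!is.null(gaze))
    full <- full | isTRUE_vec(gaze$saccade) | (gaze$gaze_dev_deg > th$gaze_deg)
  rep <- list(flags = flags, full_reject = full,
              trial_loss = mean(full), n_trials = n_tr)
  class(rep) <- "artifact_report"
  rep
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("<artifact_report> %d trials, %.1f%% fully rejected, %d channel flags\n",
              x$n_trials, 100 * x$trial_loss, nrow(x$flags)))
  invisible(x)
}

#' Is a trial/channel measurement window artifact-flagged?
#'
#' @param report an `artifact_report`.
#' @param trial trial index.
#' @param channel channel label (or NA to query trial-level blink segments).
#' @param t0,t1 measurement window (ms).
#' @return logical.
#' @export
is_flagged <- function(report, trial, channel, t0, t1) {
  f <- report$flags
  hit <- f$trial == trial & (is.na(f$channel) | f$channel == channel) &
         f$t_start_ms < t1 & f$t_end_ms > t0
  any(hit)
}

#' Interpolate noisy channels by inverse-distance weighting
#'
#' Replaces each listed channel with the inverse-distance-weighted average of
#' its `k` nearest montage neighbours (a documented simple alternative to
#' spherical-spline interpolation).
#'
#' @param e an [epoch_set()].
#' @param montage the [make_montage()] layout used to find neighbours.
#' @param bad character vector of channel labels.
#' @param k number of neighbours (default 4).
#' @return an `epoch_set` with the channels replaced.
#' @export
interpolate_channels <- function(e, montage, bad, k = 4L) {
  for (b in bad) {
    nb <- montage_neighbours(montage, b, k)
    nb <- intersect(nb, e$labels)
    if (length(nb) == 0L) .fail("no montage neighbours of '%s' present", b)
    i <- match(b, montage$label)
    d <- sqrt((montage$x[match(nb, montage$label)] - montage$x[i])^2 +
              (montage$y[match(nb, montage$label)] - montage$y[i])^2)
    w <- (1 / d) / sum(1 / d)
    bi <- chan_index(e, b); ni <- chan_index(e, nb)
    for (tr in seq_len(dim(e$data)[1L])) {
      mat <- e$data[tr, ni, , drop = FALSE]
      dim(mat) <- dim(mat)[2:3]          # neighbours x samples
      e$data[tr, bi, ] <- colSums(mat * w)
    }
  }
  e
}
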