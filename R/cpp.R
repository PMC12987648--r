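#' Select the CPP measurement electrode
#'
#' Averages response-locked epochs over trials and the pre-response window
#' (default -150 to -50 ms) and returns the centroparietal-pool channel with
#' the highest mean amplitude. Ties break deterministically to the first pool
#' channel (logged via message).
#'
#' @param resp_epochs response-locked [epoch_set()].
#' @param pool candidate channel labels; default the centroparietal pool of
#'   the montage implied by the channel count.
#' @param window ms window (endpoints inclusive).
#' @return channel label.
#' @export
select_cpp_electrode <- function(resp_epochs, pool = NULL, window = c(-150, -50)) {
  if (is.null(pool)) {
    m <- make_montage(length(resp_epochs$labels))
    pool <- intersect(montage_pool(m, "centroparietal"), resp_epochs$labels)
  }
  if (length(pool) == 0L) .fail("empty centroparietal pool")
  idx <- window_index(resp_epochs$time_ms, window[1L], window[2L], closed = TRUE)
  if (length(idx) == 0L) .fail("epochs do not cover [%g, %g] ms", window[1L], window[2L])
  ci <- chan_index(resp_epochs, pool)
  amp <- vapply(ci, function(c) mean(resp_epochs$data[, c, idx]), numeric(1L))
  if (all(amp == amp[1L]) && length(amp) > 1L)
    message("flat topography: tie broken to first pool channel")
  pool[which.max(amp)]
}

#' Sliding-window CPP slope series by condition
#'
#' For each participant and condition, computes the ordinary-least-squares
#' slope of the condition-average waveform at the CPP electrode within sliding
#' 50 ms windows stepped by 10 ms, then a paired one-sided t-test (easy >
#' hard) across participants per window.
#'
#' @param resp_epochs response-locked [epoch_set()] (all conditions).
#' @param trials trial table aligned to `resp_epochs` (needs `participant`,
#'   `block_type` with values in `conditions`, `rt_ms`).
#' @param channel CPP channel label (from [select_cpp_electrode()]).
#' @param conditions conditions to extract (default hard/easy/single).
#' @param rt_split `"all"`, `"fast"` or `"slow"`: optionally restrict to RTs
#'   below/above each participant's median.
#' @param window_ms,step_ms slope window length and step.
#' @return object of class `slope_series`: list with `centers_ms`, `slopes`
#'   (participant x window x condition array, µV/ms), `t` / `p` (paired
#'   easy-vs-hard per window), `conditions`, `peak_ms` (grand-average easy
#'   waveform peak), `mean_rt_ms`.
#' @export
slope_series <- function(resp_epochs, trials, channel,
                         conditions = c("hard", "easy"),
                         rt_split = c("all", "fast", "slow"),
                         window_ms = 50, step_ms = 10) {
  rt_split <- match.arg(rt_split)
  stopifnot(nrow(trials) == dim(resp_epochs$data)[1L])
  ci <- chan_index(resp_epochs, channel)
  t_ms <- resp_epochs$time_ms; fs <- resp_epochs$fs
  keep <- rep(TRUE, nrow(trials))
  if (rt_split != "all") {
    med <- stats::ave(trials$rt_ms, trials$participant, FUN = stats::median)
    keep <- if (rt_split == "fast") trials$rt_ms < med else trials$rt_ms >= med
  }
  parts <- sort(unique(trials$participant))
  n_win <- as.integer(round(window_ms * fs / 1000))
  starts <- seq(1L, length(t_ms) - n_win + 1L,
                by = max(1L, as.integer(round(step_ms * fs / 1000))))
  centers <- vapply(starts, function(s) mean(t_ms[s:(s + n_win - 1L)]), numeric(1L))
  tt_rel <- (seq_len(n_win) - 1L) / fs * 1000            # ms within window
  slopes <- array(NA_real_, dim = c(length(parts), length(starts), length(conditions)),
                  dimnames = list(NULL, NULL, conditions))
  waves_easy <- matrix(NA_real_, length(parts), length(t_ms))
  for (pi in seq_along(parts)) {
    for (k in seq_along(conditions)) {
      sel <- keep & trials$participant == parts[pi] & trials$block_type == conditions[k]
      if (!any(sel)) {
        warning(sprintf("participant %s has no '%s' trials; contrast skipped there",
                        parts[pi], conditions[k]))
        next
      }
      sub <- resp_epochs$data[sel, ci, , drop = FALSE]
      avg <- apply(sub, 3L, mean)
      if (conditions[k] == "easy") waves_easy[pi, ] <- avg
      # OLS slope per window (exact closed form on the window time axis)
      sl <- vapply(starts, function(s) {
        yv <- avg[s:(s + n_win - 1L)]
        stats::cov(tt_rel, yv) / stats::var(tt_rel)
      }, numeric(1L))
      slopes[pi, , k] <- sl
    }
  }
  tstat <- pval <- rep(NA_real_, length(starts))
  if (all(c("easy", "hard") %in% conditions)) {
    for (w in seq_along(starts)) {
      d <- slopes[, w, "easy"] - slopes[, w, "hard"]
      d <- d[is.finite(d)]
      if (length(d) >= 2L && stats::sd(d) > 0) {
        tv <- mean(d) / (stats::sd(d) / sqrt(length(d)))
        tstat[w] <- tv
        pval[w] <- stats::pt(tv, df = length(d) - 1L, lower.tail = FALSE) # one-sided easy > hard
      }
    }
  }
  ga_easy <- colMeans(waves_easy, na.rm = TRUE)
  peak_ms <- t_ms[which.max(ga_easy)][1L]
  structure(list(centers_ms = centers, slopes = slopes, t = tstat, p = pval,
                 conditions = conditions, participants = parts,
                 peak_ms = peak_ms,
                 mean_rt_ms = mean(trials$rt_ms[keep & trials$block_type %in% conditions])),
            class = "slope_series")
}

# onset rule: earliest window significant and continuously significant
# through to the peak. Windows straddling the peak are excluded: at the peak
# both conditions' slopes pass through zero, so the contrast vanishes there by
# construction; "up to the peak" covers the windows lying before it.
.cpp_onset_from_p <- function(p, centers, peak_ms, alpha, window_ms = 50) {
  before <- which(centers <= peak_ms - window_ms / 2)
  if (length(before) == 0L) return(NA_real_)
  peak_w <- max(before)
  sig <- !is.na(p) & p < alpha
  upto <- which(sig[seq_len(peak_w)])
  if (length(upto) == 0L) return(NA_real_)
  # earliest w such that all windows w..peak_w are significant
  runs <- rev(cumprod(rev(sig[seq_len(peak_w)])))
  w <- which(runs == 1L)
  if (length(w) == 0L) return(NA_real_)
  centers[w[1L]]
}

#' Estimate the onset of evidence-dependent CPP buildup
#'
#' The onset is the first sliding window where the easy-block slope is
#' significantly higher than the hard-block slope and remains so in every
#' window up to the peak of the grand-average easy waveform. Uncertainty is
#' captured by bootstrapping participants (slopes are re-used; only the
#' paired tests are recomputed per sample). The response-locked onset is also
#' converted to a stimulus-locked latency by subtracting its magnitude from
#' mean RT.
#'
#' @param ss a [slope_series()].
#' @param n_boot bootstrap samples (default 500).
#' @param seed integer seed.
#' @param alpha one-sided significance level.
#' @return list with `onset_ms` (response-locked point estimate),
#'   `stimulus_locked_ms`, bootstrap `median_ms`, `ci`,
#'   `stimulus_locked_median_ms`, `n_empty`, `n_boot`.
#' @export
estimate_cpp_onset <- function(ss, n_boot = 500L, seed = 1L, alpha = 0.05) {
  if (!all(c("easy", "hard") %in% ss$conditions))
    .fail("slope series lacks the easy/hard contrast")
  point <- .cpp_onset_from_p(ss$p, ss$centers_ms, ss$peak_ms, alpha)
  de <- ss$slopes[, , "easy"] - ss$slopes[, , "hard"]
  de <- de[stats::complete.cases(de), , drop = FALSE]
  np <- nrow(de)
  if (np < 2L) .fail("need >= 2 participants with both conditions")
  set.seed(seed)
  ons <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    i <- sample(np, np, replace = TRUE)
    d <- de[i, , drop = FALSE]
    m <- colMeans(d); s <- apply(d, 2L, stats::sd)
    tv <- m / (s / sqrt(np))
    p <- stats::pt(tv, df = np - 1L, lower.tail = FALSE)
    p[!is.finite(p)] <- NA_real_
    ons[b] <- .cpp_onset_from_p(p, ss$centers_ms, ss$peak_ms, alpha)
  }
  med <- stats::median(ons, na.rm = TRUE)
  list(onset_ms = point,
       stimulus_locked_ms = if (is.na(point)) NA_real_ else ss$mean_rt_ms - abs(point),
       median_ms = med,
       ci = stats::quantile(ons, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
       stimulus_locked_median_ms = if (is.na(med)) NA_real_ else ss$mean_rt_ms - abs(med),
       n_empty = sum(is.na(ons)), n_boot = n_boot, seed = seed)
}

#' Pool stimulus-locked CPP onset estimates
#'
#' Arithmetic mean of the available stimulus-locked onset medians (typically
#' the all-trials, fast-half and slow-half estimates), with the implied delay
#' from the C1 latency.
#'
#' @param estimates list of [estimate_cpp_onset()] results (or plain numbers,
#'   taken as stimulus-locked onsets in ms).
#' @param c1_latency_ms reference C1 latency (default 80).
#' @return list with `pooled_ms`, `delay_from_c1_ms`, `n_used`, `incomplete`.
#' @export
pooled_onset <- function(estimates, c1_latency_ms = 80) {
  vals <- vapply(estimates, function(e)
    if (is.numeric(e)) e else e$stimulus_locked_median_ms, numeric(1L))
  ok <- is.finite(vals)
  if (!any(ok)) .fail("no onset estimates available to pool")
  pooled <- mean(vals[ok])
  list(pooled_ms = pooled, delay_from_c1_ms = pooled - c1_latency_ms,
       n_used = sum(ok), incomplete = any(!ok))
}
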